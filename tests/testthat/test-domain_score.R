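test_that("max similarity over a DBD's consensus motifs", {
  coll <- tiny_collection()
  p <- det_pfm(rep("A", 6), "query")
  # alpha's single consensus is the all-A motif itself
  expect_equal(max_similarity(p, coll, "alpha"),
               s_max(p, coll$dbds$alpha[[1]]$consensus)$s_max)
  # all-incompatible DBD maps the -Inf sentinel to the clip value 0
  expect_equal(max_similarity(det_pfm(rep("A", 6), "q"), coll, "gamma"), 0)
  expect_error(max_similarity(p, coll, "zzz"), "available")
})

test_that("domain scores are clipped, normalized, and flag degeneracy", {
  coll <- tiny_collection()
  p <- det_pfm(rep("A", 6), "query")
  ds <- domain_score(p, coll)
  # identical to alpha's consensus, incompatible with gamma's
  expect_equal(unname(ds$score["alpha"]), 1)
  expect_equal(unname(ds$score["gamma"]), 0)
  expect_false(ds$degenerate)

  # single-DBD collection: the score is 1 by construction
  m <- det_pfm(rep("A", 6), "m1")
  one <- build_collection(list(m), c(m1 = "alpha"))
  expect_equal(unname(domain_score(rand_pfm(6, "q"), one)$score), 1)

  # a motif incompatible with every DBD (C/G-only consensus motifs, both
  # orientations) degenerates to uniform, flagged
  mg <- det_pfm(rep("C", 6), "mc")
  mt <- det_pfm(c("C", "G", "C", "G", "C", "G"), "mt")
  cc <- build_collection(list(mg, mt), c(mc = "d1", mt = "d2"))
  dg <- domain_score(det_pfm(rep("A", 6), "qa"), cc)
  expect_true(dg$degenerate)
  expect_equal(unname(dg$score), c(0.5, 0.5))

  # conservation across random candidates
  set.seed(111)
  for (i in 1:5) {
    ds <- domain_score(rand_pfm(sample(6:12, 1), "q"), coll)
    expect_equal(sum(ds$score), 1, tolerance = 1e-9)
    expect_true(all(ds$score >= 0))
  }
})

test_that("random PFM sampler honors length and entropy constraints", {
  set.seed(121)
  ls <- integer(200)
  for (i in 1:200) {
    p <- sample_random_pfm(length_range = c(6, 21), min_avg_entropy = 0.6)
    ls[i] <- pfm_length(p)
    expect_gte(mean(column_entropy(p)), 0.6)
  }
  expect_true(all(ls >= 6 & ls <= 21))
  expect_gt(length(unique(ls)), 8) # lengths spread over the range

  # entropy reference points
  expect_equal(column_entropy(pfm(matrix(0.25, 4, 1), "u")), 2)
  expect_equal(column_entropy(det_pfm("A")), 0)

  set.seed(5); a <- sample_random_pfm()
  set.seed(5); b <- sample_random_pfm()
  expect_identical(a$matrix, b$matrix)
})

test_that("null distributions are reproducible, shared across DBDs, in [0,1]", {
  coll <- make_toy_collection(n_dbds = 2, motifs_per_dbd = 2, seed = 131,
                              length_range = c(6, 6))
  n1 <- build_null(coll, n = 30, seed = 7)
  n2 <- build_null(coll, n = 30, seed = 7)
  expect_identical(lapply(n1$dists, `[[`, "scores"),
                   lapply(n2$dists, `[[`, "scores"))
  for (d in names(n1$dists)) {
    sc <- n1$dists[[d]]$scores
    expect_length(sc, 30)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_false(is.unsorted(sc))
  }
  expect_identical(n1$fingerprint, collection_fingerprint(coll))
  # shared sample R: with two DBDs and the zero clip the per-sample scores
  # sum to 1, so the sorted samples are mirror images
  expect_equal(sort(1 - n1$dists[[1]]$scores), n1$dists[[2]]$scores,
               tolerance = 1e-9)
})

test_that("empirical p-values count ties upward and respect the floor", {
  null <- structure(list(dbd = "d", scores = sort(c(.1, .2, .3, .3, .5, .6,
                                                    .7, .8, .8, .9)),
                         n = 10L, seed = NULL), class = "null_distribution")
  # x equal to the 3rd largest sample (ties counted by >=)
  expect_equal(domain_pvalue(0.8, null), 0.3)
  expect_equal(domain_pvalue(2, null), 0.1)    # above all: floor 1/|R|
  expect_equal(domain_pvalue(0.05, null), 1)   # at or below the minimum
  # monotone: higher score, smaller or equal p
  xs <- seq(0, 1, by = 0.01)
  ps <- domain_pvalue(xs, null)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 0.1 & ps <= 1))
})

test_that("null archives round-trip and are pinned to their collection", {
  coll <- make_toy_collection(n_dbds = 2, motifs_per_dbd = 2, seed = 141,
                              length_range = c(6, 6))
  null <- build_null(coll, n = 25, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  save_null(null, f)
  back <- load_null(f)
  expect_equal(back$n, 25L)
  expect_equal(back$seed, 9L)
  expect_identical(back$fingerprint, null$fingerprint)
  for (d in names(null$dists))
    expect_equal(back$dists[[d]]$scores, null$dists[[d]]$scores,
                 tolerance = 1e-15)

  # corrupt archive refuses to load
  lines <- readLines(f)
  writeLines(c(lines, "DBD_1\tnot_a_number"), f)
  expect_error(load_null(f), "corrupt")

  # a null built for another collection is rejected at query time
  other <- make_toy_collection(n_dbds = 2, motifs_per_dbd = 2, seed = 999,
                               length_range = c(6, 6))
  expect_error(score_motifs(list(rand_pfm(6, "q")), other, null, "DBD_1"),
               "fingerprint")
})
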
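test_that("collections partition motifs by DBD and cluster within each", {
  coll <- tiny_collection()
  expect_setequal(names(coll$dbds), c("alpha", "gamma"))
  expect_length(coll$dbds$alpha, 1) # m1, m2 merge
  expect_setequal(coll$dbds$alpha[[1]]$members, c("m1", "m2"))
  expect_length(coll$dbds$gamma, 1)
  expect_length(coll$skipped, 0)
  # member counts add up to the annotated motifs
  expect_equal(sum(vapply(unlist(coll$dbds, recursive = FALSE),
                          function(cl) cl$size, integer(1))), 3)
})

test_that("unannotated motifs land in the skipped report, not the collection", {
  m1 <- det_pfm(rep("A", 6), "m1")
  m2 <- det_pfm(rep("C", 6), "m2")
  coll <- build_collection(list(m1, m2), c(m1 = "alpha"))
  expect_equal(coll$skipped, "m2")
  expect_length(coll$motifs, 1)

  empty <- build_collection(list(m1, m2), character())
  expect_length(empty$dbds, 0)
  expect_setequal(empty$skipped, c("m1", "m2"))
})

test_that("multiply-annotated motifs go to every listed DBD by default", {
  m1 <- det_pfm(rep("A", 6), "m1")
  ann <- data.frame(motif_id = c("m1", "m1"), dbd = c("alpha", "beta"))
  coll <- build_collection(list(m1), ann)
  expect_setequal(names(coll$dbds), c("alpha", "beta"))
  expect_length(coll$motifs, 2)
  first <- build_collection(list(m1), ann, multi_dbd = "first")
  expect_equal(names(first$dbds), "alpha")
})

test_that("consensus lookup is order-stable and validates the DBD name", {
  coll <- tiny_collection()
  cons <- consensus_motifs(coll, "alpha")
  expect_length(cons, length(coll$dbds$alpha))
  expect_equal(cons[[1]]$id, coll$dbds$alpha[[1]]$consensus$id)
  expect_error(consensus_motifs(coll, "nope"), "available")
  # whitespace-normalized matching
  expect_length(consensus_motifs(coll, "  alpha "), 1)
})

test_that("collection archives round-trip losslessly and reject corruption", {
  coll <- build_collection(
    list(det_pfm(rep("A", 6), "m1"), rand_pfm(7, "m2"), rand_pfm(5, "m3")),
    c(m1 = "alpha", m2 = "alpha", m3 = "gamma"),
    provenance = "unit test v1.2 (verbatim)")
  d <- withr::local_tempdir()
  save_collection(coll, file.path(d, "coll"))
  back <- load_collection(file.path(d, "coll"))
  expect_equal(collection_fingerprint(back), collection_fingerprint(coll))
  expect_identical(back$provenance, "unit test v1.2 (verbatim)")
  expect_equal(back$parameters, coll$parameters)
  for (dbd in names(coll$dbds)) {
    expect_equal(lapply(back$dbds[[dbd]], function(cl) cl$members),
                 lapply(coll$dbds[[dbd]], function(cl) cl$members))
    for (i in seq_along(coll$dbds[[dbd]])) {
      expect_lt(max(abs(back$dbds[[dbd]][[i]]$consensus$matrix -
                        coll$dbds[[dbd]][[i]]$consensus$matrix)), 1e-9)
    }
  }

  # version mismatch is an explicit error
  meta <- readLines(file.path(d, "coll", "meta.txt"))
  writeLines(sub("^format_version=.*", "format_version=99", meta),
             file.path(d, "coll", "meta.txt"))
  expect_error(load_collection(file.path(d, "coll")), "version")

  # corrupted matrices do not load as a partial object
  writeLines(meta, file.path(d, "coll", "meta.txt"))
  cons <- readLines(file.path(d, "coll", "consensus.jaspar"))
  writeLines(cons[-2], file.path(d, "coll", "consensus.jaspar"))
  expect_error(load_collection(file.path(d, "coll")), "corrupt")
})

test_that("rebuilding from identical inputs is deterministic", {
  set.seed(101)
  motifs <- lapply(1:8, function(i) rand_pfm(6, paste0("m", i), alpha = 0.5))
  ann <- stats::setNames(rep(c("d1", "d2"), each = 4), paste0("m", 1:8))
  c1 <- build_collection(motifs, ann)
  c2 <- build_collection(motifs, ann)
  expect_identical(collection_fingerprint(c1), collection_fingerprint(c2))
  expect_identical(lapply(c1$dbds, function(x) lapply(x, `[[`, "members")),
                   lapply(c2$dbds, function(x) lapply(x, `[[`, "members")))
})
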
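test_that("consensus merging is a weighted aligned-column average", {
  set.seed(71)
  p <- rand_pfm(5, "p")
  # merging a motif with itself at zero offset reproduces it
  expect_equal(merge_consensus(p, p, 0, "forward", 1, 1)$matrix, p$matrix)

  a <- det_pfm("A", "a")
  c_ <- det_pfm("C", "c")
  expect_equal(unname(merge_consensus(a, c_, 0, "forward", 1, 1)$matrix[, 1]),
               c(0.5, 0.5, 0, 0))
  expect_equal(unname(merge_consensus(a, c_, 0, "forward", 3, 1)$matrix[, 1]),
               c(0.75, 0.25, 0, 0))

  # non-overlap flanks mix the covering motif with the background
  m <- merge_consensus(det_pfm(c("A", "A"), "aa"), det_pfm(c("A", "A"), "bb"),
                       1, "forward", 1, 1)
  expect_equal(pfm_length(m), 3)
  expect_equal(unname(m$matrix[, 1]), c(0.625, 0.125, 0.125, 0.125))
  expect_equal(unname(m$matrix[, 2]), c(1, 0, 0, 0))

  # revcomp orientation merges against the reverse complement
  m2 <- merge_consensus(a, det_pfm("T", "t"), 0, "revcomp", 1, 1)
  expect_equal(unname(m2$matrix[, 1]), c(1, 0, 0, 0))

  expect_error(merge_consensus(a, c_, 5, "forward"), "overlap")
})

test_that("greedy clustering merges similar motifs and separates others", {
  m1 <- det_pfm(rep("A", 6), "m1")
  m2 <- det_pfm(rep("A", 6), "m2")
  m3 <- det_pfm(rep("C", 6), "m3")
  # S^max(m1, m2) = 6 ln 4 ~ 8.3 >= 3; S^max(m1, m3) = -Inf
  cl <- greedy_cluster(list(m1, m2, m3), merge_threshold = 3)
  expect_length(cl, 2)
  expect_setequal(cl[[1]]$members, c("m1", "m2"))
  expect_equal(cl[[2]]$members, "m3")
  # merged consensus of two identical motifs is that motif
  expect_equal(cl[[1]]$consensus$matrix, m1$matrix)
  # singleton keeps its member untouched
  expect_equal(cl[[2]]$consensus$id, "m3")

  single <- greedy_cluster(list(m1))
  expect_length(single, 1)
  expect_equal(single[[1]]$consensus$id, "m1")

  expect_length(greedy_cluster(list()), 0)
})

test_that("threshold extremes give all-singletons or one cluster", {
  set.seed(81)
  motifs <- lapply(1:5, function(i) rand_pfm(6, paste0("r", i)))
  expect_length(greedy_cluster(motifs, merge_threshold = Inf), 5)
  one <- greedy_cluster(motifs, merge_threshold = -Inf, member_check = FALSE)
  expect_length(one, 1)
  expect_setequal(one[[1]]$members, paste0("r", 1:5))
})

test_that("clustering partitions the input, deterministically and monotonely", {
  set.seed(91)
  motifs <- lapply(1:15, function(i)
    rand_pfm(sample(6:8, 1), sprintf("m%02d", i), alpha = 0.5))
  cl1 <- greedy_cluster(motifs, merge_threshold = 2)
  ids <- unlist(lapply(cl1, function(x) x$members))
  expect_setequal(ids, sprintf("m%02d", 1:15))
  expect_equal(anyDuplicated(ids), 0L)

  cl2 <- greedy_cluster(motifs, merge_threshold = 2)
  expect_identical(lapply(cl1, function(x) x$members),
                   lapply(cl2, function(x) x$members))

  n_lo <- length(greedy_cluster(motifs, merge_threshold = 1))
  n_hi <- length(greedy_cluster(motifs, merge_threshold = 4))
  expect_lte(n_lo, n_hi)
  expect_lte(n_hi, 15)
})
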
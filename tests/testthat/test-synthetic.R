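test_that("toy collections have the requested structure and reproduce", {
  coll <- make_toy_collection(n_dbds = 2, motifs_per_dbd = 3, seed = 171)
  expect_length(coll$dbds, 2)
  expect_length(coll$motifs, 6)
  expect_equal(sum(vapply(unlist(coll$dbds, recursive = FALSE),
                          function(cl) cl$size, integer(1))), 6)

  coll2 <- make_toy_collection(n_dbds = 2, motifs_per_dbd = 3, seed = 171)
  expect_identical(collection_fingerprint(coll), collection_fingerprint(coll2))
})

test_that("within-DBD similarity exceeds between-DBD similarity", {
  coll <- make_toy_collection(n_dbds = 2, motifs_per_dbd = 3, seed = 181)
  ms <- coll$motifs
  dbds <- vapply(ms, function(p) p$dbd, character(1))
  within <- c(); between <- c()
  ids <- names(ms)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      s <- s_max(ms[[i]], ms[[j]])$s_max
      if (dbds[i] == dbds[j]) within <- c(within, s) else between <- c(between, s)
    }
  }
  expect_gt(mean(within), mean(between[is.finite(between)]))
})

test_that("implanted sequence sets carry the motif at the requested rate", {
  m <- det_pfm(c("A", "C", "G", "T", "A", "C"), "imp")
  s0 <- implant_sequences(m, n = 10, length = 30, implant_rate = 0, seed = 1)
  expect_length(s0, 10)
  expect_false(any(attr(s0, "implanted")))

  s1 <- implant_sequences(m, n = 10, length = 30, implant_rate = 1, seed = 2)
  expect_true(all(attr(s1, "implanted")))
  # deterministic motif: the consensus word sits at the center of every read
  center <- floor((30 - 6) / 2) + 1
  words <- substr(as.character(s1), center, center + 5)
  expect_true(all(words == "ACGTAC"))
  expect_true(all(grepl(";signal=", names(s1))))

  half <- implant_sequences(m, n = 10, length = 30, implant_rate = 0.45,
                            seed = 3)
  expect_equal(sum(attr(half, "implanted")), ceiling(0.45 * 10))

  a <- implant_sequences(m, 5, 20, 0.5, seed = 9)
  b <- implant_sequences(m, 5, 20, 0.5, seed = 9)
  expect_identical(as.character(a), as.character(b))
})

test_that("mock enrichment tables can be adversarial and reproduce", {
  tab <- mock_method_table(c("t", "d1", "d2"), true_id = "t", true_p = 1e-4,
                           adversarial = TRUE, seed = 5)
  expect_equal(tab$p_value[tab$motif_id == "t"], 1e-4)
  expect_lt(tab$p_value[tab$motif_id == "d1"],
            tab$p_value[tab$motif_id == "t"])
  tab2 <- mock_method_table(c("t", "d1", "d2"), true_id = "t", true_p = 1e-4,
                            adversarial = TRUE, seed = 5)
  expect_identical(tab, tab2)
})

test_that("domain filtering repairs the adversarial ranking end to end", {
  scen <- make_adversarial_scenario(n_datasets = 4, seed = 191)
  null <- build_null(scen$collection, n = 500, seed = 192)
  ev <- evaluate_scenario(scen, null, variants = c("C", "M_C"), pi = 0.0025)
  expect_gte(ev$M_C$accuracy, ev$C$accuracy)
  # under plain enrichment the planted decoy wins the adversarial datasets
  expect_lt(ev$C$accuracy, 1)
})
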
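test_that("method p-value tables parse, clip zeros, and reject bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("motif_id\tp_value", "m1\t1e-4", "m2\t0.2"), f)
  pv <- read_method_pvalues(f)
  expect_equal(pv, c(m1 = 1e-4, m2 = 0.2))

  # headerless works too
  writeLines(c("m1\t0.5"), f)
  expect_equal(read_method_pvalues(f), c(m1 = 0.5))

  writeLines(c("m1\t0", "m2\t0.1"), f)
  expect_warning(pv0 <- read_method_pvalues(f), "clipped")
  expect_equal(unname(pv0["m1"]), 1e-300)

  writeLines(c("m1\t0.1", "m1\t0.2"), f)
  expect_error(read_method_pvalues(f), "duplicate")

  writeLines(c("m1\t0.1", "m2\toops"), f)
  expect_error(read_method_pvalues(f), "row 2")

  writeLines(c("m1\t1.5"), f)
  expect_error(read_method_pvalues(f), "outside")
})

test_that("Fisher combination matches the even-df chi-squared closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(0.05), 0.05) # m = 1 identity
  # frozen: X = 9.21034, p = exp(-X/2) * (1 + X/2)
  expect_equal(fisher_combine(c(0.1, 0.1)), 0.0560517019, tolerance = 1e-9)

  # independent oracle: chi-squared survival function
  set.seed(151)
  for (i in 1:20) {
    m <- sample(1:6, 1)
    p <- stats::runif(m)
    x <- -2 * sum(log(p))
    expect_equal(fisher_combine(p),
                 stats::pchisq(x, df = 2 * m, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  # monotone: decreasing any p never increases the combined p
  p <- c(0.3, 0.08, 0.6)
  for (j in 1:3) {
    q <- p
    q[j] <- p[j] / 10
    expect_lte(fisher_combine(q), fisher_combine(p))
  }

  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_combine(numeric()), "at least one")
})

make_table <- function(pC, pP = NULL, pd) {
  ids <- names(pd)
  methods <- list(C = pC)
  if (!is.null(pP)) methods$P <- pP
  motif_table("ds1", "TF1", "alpha", methods, pd)
}

test_that("the pi filter excludes on strict inequality and reports emptiness", {
  pd <- c(m1 = 0.0005, m2 = 0.01, m3 = 0.001)
  tab <- make_table(pC = c(m1 = .2, m2 = .1, m3 = .3), pd = pd)
  filt <- apply_domain_filter(tab, pi = 0.001)
  # m3 sits exactly at pi: kept
  expect_equal(filt$filtered[match(c("m1", "m2", "m3"), filt$motif_id)],
               c(FALSE, TRUE, FALSE))
  expect_false(attr(filt, "empty_after_filter"))

  none <- apply_domain_filter(tab, pi = 1)
  expect_false(any(none$filtered))

  all_gone <- apply_domain_filter(tab, pi = 1e-6)
  expect_true(attr(all_gone, "empty_after_filter"))
})

test_that("ranking variants compose filtering and Fisher per the naming scheme", {
  pC <- c(m1 = 0.01, m2 = 0.001, m3 = 0.2)
  pP <- c(m1 = 0.02, m2 = 0.5, m3 = 0.1)
  pd <- c(m1 = 0.0005, m2 = 0.8, m3 = 0.0002)
  tab <- motif_table("ds1", "TF1", "alpha", list(C = pC, P = pP), pd)

  rc <- rank_variant(tab, "C")
  expect_equal(rc$motif_id[rc$rank == 1], "m2")
  expect_equal(rc$p_combined, unname(sort(pC)))

  rcp <- rank_variant(tab, "CP")
  i1 <- which(rcp$motif_id == "m1")
  expect_equal(rcp$p_combined[i1], fisher_combine(c(0.01, 0.02)))

  rmcp <- rank_variant(tab, "MCP")
  expect_equal(rmcp$p_combined[rmcp$motif_id == "m1"],
               fisher_combine(c(0.01, 0.02, 0.0005)))
  expect_false(any(rmcp$filtered))

  # M_C: filter (m2 out), then rank by C alone
  rmc <- rank_variant(tab, "M_C", pi = 0.001)
  expect_true(rmc$filtered[rmc$motif_id == "m2"])
  expect_true(is.na(rmc$rank[rmc$motif_id == "m2"]))
  kept <- rmc[!rmc$filtered, ]
  expect_equal(kept$motif_id[order(kept$rank)], c("m1", "m3"))
  # filtering never reorders survivors of a single-method variant
  c_order <- rc$motif_id[rc$motif_id %in% kept$motif_id][1:2]
  expect_equal(kept$motif_id[order(kept$rank)], c_order)

  rmcp2 <- rank_variant(tab, "M_CP", pi = 0.001)
  expect_equal(rmcp2$p_combined[rmcp2$motif_id == "m3"],
               fisher_combine(c(0.2, 0.1)))

  # a variant requiring a missing method errors by name
  tab1 <- make_table(pC = pC, pd = pd)
  expect_error(rank_variant(tab1, "CP"), "method")
  expect_error(rank_variant(tab1, "P"), "method")

  # ties broken by motif id
  tabt <- make_table(pC = c(b = .1, a = .1, c = .1), pd = c(a = 1, b = 1, c = 1))
  rt <- rank_variant(tabt, "C")
  expect_equal(rt$motif_id, c("a", "b", "c"))

  # top_hit reports emptiness explicitly
  gone <- rank_variant(make_table(pC = c(m1 = .1), pd = c(m1 = 0.9)),
                       "M_C", pi = 0.001)
  expect_true(attr(gone, "empty_after_filter"))
  th <- top_hit(gone)
  expect_true(th$empty)
  expect_true(is.na(th$motif_id))
})
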
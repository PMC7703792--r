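# Shared fixture builders: everything is generated in code, no data files.

# deterministic motif: probability 1 on one base per column
det_pfm <- function(bases, id = paste0("det_", paste(bases, collapse = ""))) {
  idx <- match(bases, c("A", "C", "G", "T"))
  stopifnot(!anyNA(idx))
  m <- matrix(0, 4, length(bases))
  m[cbind(idx, seq_along(idx))] <- 1
  pfm(m, id = id)
}

# random Dirichlet(alpha) motif
rand_pfm <- function(L, id = "rand", alpha = 1) {
  g <- matrix(stats::rgamma(4 * L, shape = alpha), nrow = 4)
  pfm(sweep(g, 2, colSums(g), "/"), id = id)
}

uniform_bg <- background_model()

# tiny two-DBD collection built from sharply distinct motifs: DBD "alpha"
# holds A-rich motifs, DBD "gamma" holds C-rich ones
tiny_collection <- function() {
  m1 <- det_pfm(rep("A", 6), "m1")
  m2 <- det_pfm(rep("A", 6), "m2")
  m3 <- det_pfm(rep("C", 6), "m3")
  build_collection(list(m1, m2, m3),
                   c(m1 = "alpha", m2 = "alpha", m3 = "gamma"),
                   provenance = "unit-test")
}

expect_smax_equal <- function(a, b, tol = 1e-9) {
  if (!is.finite(a) && !is.finite(b)) return(invisible(TRUE))
  expect_lt(abs(a - b), tol)
}
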
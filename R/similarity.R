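#' Log-odds score of a word under a PFM
#'
#' Natural-log likelihood ratio of `word` under the motif model versus the
#' background: `sum_i log(((p[i,w_i] + pseudo/4) / (1 + pseudo)) / bg[w_i])`.
#' With `pseudo = 0` a zero motif frequency gives `-Inf`.
#'
#' @param p a [pfm()]
#' @param word DNA string of length `pfm_length(p)` over ACGT
#' @param background a [background_model()]
#' @param pseudo non-negative pseudo-frequency (default 0)
#' @return numeric scalar (possibly `-Inf`)
#' @export
log_odds_score <- function(p, word, background = background_model(),
                           pseudo = 0) {
  stopifnot(is_pfm(p), pseudo >= 0)
  letters <- strsplit(toupper(word), "")[[1]]
  if (length(letters) != pfm_length(p))
    stop("word length ", length(letters), " != motif length ", pfm_length(p))
  idx <- match(letters, c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("word contains non-ACGT character: ", word)
  f <- p$matrix[cbind(idx, seq_along(idx))]
  f <- (f + pseudo / 4) / (1 + pseudo)
  sum(log(f / background[idx]))
}

# Internal: per-column per-letter log-odds contributions on the integer bin
# grid; NA marks -Inf (zero frequency with pseudo = 0).
binned_contrib <- function(mat, background, bin_width, pseudo) {
  m <- adjust_matrix(mat, pseudo)
  lo <- log(m / as.numeric(background))
  out <- matrix(NA_integer_, 4L, ncol(m))
  fin <- is.finite(lo)
  out[fin] <- as.integer(round(lo[fin] / bin_width))
  out
}

#' Exact score distribution of a PFM
#'
#' Column-by-column convolution of the binned per-letter log-odds
#' contributions. Under `generator = "background"` letters are weighted by the
#' background probabilities (giving the null score distribution used for the
#' false-positive rate); under `generator = "motif"` by the PFM's own column
#' frequencies (giving the distribution of scores of motif-generated words,
#' used for the false-negative rate). `-Inf` contributions accumulate in a
#' dedicated `sink` mass.
#'
#' @inheritParams log_odds_score
#' @param generator `"background"` or `"motif"`
#' @param bin_width positive score bin width (default 0.01)
#' @return object of class `score_distribution`: list with `bin_width`, `bins`
#'   (integer bin indices; score = bin * bin_width), `probs`, and `sink`
#' @export
score_distribution <- function(p, generator = c("background", "motif"),
                               background = background_model(),
                               bin_width = 0.01, pseudo = 0) {
  generator <- match.arg(generator)
  stopifnot(is_pfm(p), bin_width > 0)
  contrib <- binned_contrib(p$matrix, background, bin_width, pseudo)
  w <- if (generator == "background") {
    matrix(as.numeric(background), 4L, ncol(p$matrix))
  } else {
    adjust_matrix(p$matrix, pseudo)
  }
  d <- cpp_score_dist(contrib, w)
  keep <- d$probs > 0
  structure(list(bin_width = bin_width,
                 bins = as.integer(d$offset + which(keep) - 1L),
                 probs = d$probs[keep],
                 sink = d$sink),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("score_distribution:", length(x$bins), "bins, bin_width", x$bin_width,
      ", sink mass", format(x$sink), "\n")
  invisible(x)
}

# Internal: dense tail/cdf bookkeeping shared by the threshold rules.
dense_dists <- function(contrib, mat_adj, background) {
  bgw <- matrix(as.numeric(background), 4L, ncol(contrib))
  list(bg = cpp_score_dist(contrib, bgw),
       mot = cpp_score_dist(contrib, mat_adj))
}

#' Hit model: log-odds threshold and background hit probability for a PFM
#'
#' Discretizes the motif's log-odds scores onto a bin grid and chooses the hit
#' threshold `t`. The default `"balanced"` rule picks the grid point
#' minimizing `|FPR(t) - FNR(t)|`, where `FPR(t) = P_bg(score >= t)` and
#' `FNR(t) = P_motif(score < t)`; ties prefer the larger threshold.
#' `"fpr"` picks the smallest `t` with `FPR(t) <= target_fpr`. Either way the
#' background hit probability `alpha = FPR(t)` is guaranteed positive by
#' falling back to the highest score bin the background can reach.
#'
#' When the matrix contains zero frequencies a pseudo-frequency (default 1e-6)
#' is folded in so contributions stay finite.
#'
#' @inheritParams score_distribution
#' @param pseudo pseudo-frequency applied only when zero frequencies are
#'   present (default 1e-6)
#' @param rule `"balanced"` or `"fpr"`
#' @param target_fpr target false-positive rate for `rule = "fpr"`
#' @return object of class `hit_model` with elements `pfm`, `contrib` (binned
#'   integer contributions), `threshold` (bin index), `alpha`, `bin_width`,
#'   `background`, `fpr`, `fnr`
#' @export
hit_model <- function(p, background = background_model(), bin_width = 0.01,
                      pseudo = 1e-6, rule = c("balanced", "fpr"),
                      target_fpr = 1e-3) {
  rule <- match.arg(rule)
  stopifnot(is_pfm(p), bin_width > 0, pseudo >= 0)
  if (!inherits(background, "background_model"))
    background <- background_model(background)
  mat_adj <- adjust_matrix(p$matrix, pseudo)
  contrib <- binned_contrib(p$matrix, background, bin_width, pseudo)
  dd <- dense_dists(contrib, mat_adj, background)
  nbg <- length(dd$bg$probs)
  bins <- as.integer(dd$bg$offset) + seq_len(nbg) - 1L
  # both dists share the same support range (same contributions)
  tail_bg <- rev(cumsum(rev(dd$bg$probs)))           # FPR at threshold = bin
  below_mot <- dd$mot$sink + c(0, cumsum(dd$mot$probs))[seq_len(nbg)] # FNR
  cand <- which(dd$bg$probs > 0 | dd$mot$probs > 0)
  if (length(cand) == 0) stop("motif has no attainable finite score")
  diffs <- abs(tail_bg[cand] - below_mot[cand])
  if (rule == "balanced") {
    best <- cand[diffs == min(diffs)]
    ti <- best[length(best)] # tie: larger threshold
  } else {
    ok <- cand[tail_bg[cand] <= target_fpr]
    ti <- if (length(ok) > 0) ok[1] else cand[length(cand)]
  }
  if (tail_bg[ti] <= 0) { # fall back to the highest bin the background reaches
    nz <- which(dd$bg$probs > 0)
    ti <- nz[length(nz)]
  }
  structure(list(pfm = p, contrib = contrib, threshold = bins[ti],
                 alpha = tail_bg[ti], fpr = tail_bg[ti],
                 fnr = below_mot[ti], bin_width = bin_width,
                 pseudo = pseudo, background = background),
            class = "hit_model")
}

#' @rdname hit_model
#' @export
balanced_threshold <- function(p, background = background_model(), ...) {
  hit_model(p, background = background, rule = "balanced", ...)
}

#' @export
print.hit_model <- function(x, ...) {
  cat("hit_model for", x$pfm$id, ": threshold",
      format(x$threshold * x$bin_width), "(log-odds), alpha",
      format(x$alpha), "\n")
  invisible(x)
}

check_pair <- function(x, y) {
  if (!inherits(x, "hit_model") || !inherits(y, "hit_model"))
    stop("overlap statistics need two hit_model objects")
  if (x$bin_width != y$bin_width)
    stop("hit models use different bin widths")
  if (any(abs(x$background - y$background) > 1e-12))
    stop("hit models use different background models")
}

#' Overlap probability of two motif hit events
#'
#' `gamma_{X,Y}(k)`: the probability, under an iid background sequence
#' covering the union of the two motif windows (X at position 0, Y at
#' position k), that both motifs hit. Computed exactly by a joint dynamic
#' program over the overlap columns followed by the independent non-overlap
#' tails.
#'
#' @param x,y [hit_model()] objects sharing background and bin width
#' @param k integer offset of y relative to x; must leave at least one
#'   overlapping column, i.e. `k` in `[-(L_y - 1), L_x - 1]`
#' @return numeric scalar in `[0, min(alpha_x, alpha_y)]`
#' @export
overlap_probability <- function(x, y, k) {
  check_pair(x, y)
  Lx <- ncol(x$contrib); Ly <- ncol(y$contrib)
  if (k < -(Ly - 1) || k > Lx - 1)
    stop("offset k = ", k, " outside the overlap range [",
         -(Ly - 1), ", ", Lx - 1, "]")
  cpp_gamma(x$contrib, x$threshold, y$contrib, y$threshold,
            as.numeric(x$background), as.integer(k))
}

#' Similarity of two motifs at a fixed offset
#'
#' `S_{X,Y}(k) = log(gamma_{X,Y}(k) / (alpha_X * alpha_Y))` (natural log):
#' the log-ratio of the probability of overlapping hits to the probability of
#' independent hits. Returns `-Inf` when the overlap probability is zero.
#'
#' @inheritParams overlap_probability
#' @return numeric scalar (possibly `-Inf`)
#' @export
similarity_at <- function(x, y, k) {
  g <- overlap_probability(x, y, k)
  if (g > 0) log(g / (x$alpha * y$alpha)) else -Inf
}

as_similarity_result <- function(res, alpha_x, alpha_y_f, alpha_y_r) {
  structure(list(s_max = res$s_max,
                 best_offset = as.integer(res$offset),
                 best_orientation = if (res$orientation == 0) "forward"
                                    else "revcomp",
                 gamma = res$gamma,
                 alpha_x = alpha_x,
                 alpha_y = if (res$orientation == 0) alpha_y_f else alpha_y_r),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("S^max =", format(x$s_max), "at offset", x$best_offset,
      paste0("(", x$best_orientation, ")"), "\n")
  invisible(x)
}

# Internal: build the three hit models (x, y, revcomp y) a pair comparison
# needs, or accept prebuilt ones.
pair_models <- function(x, y, background, bin_width, pseudo,
                        rule = "balanced", target_fpr = 1e-3) {
  hx <- if (inherits(x, "hit_model")) x
        else hit_model(x, background, bin_width, pseudo, rule, target_fpr)
  if (inherits(y, "hit_model")) {
    hyf <- y
    hyr <- hit_model(reverse_complement(y$pfm), y$background, y$bin_width,
                     y$pseudo, rule, target_fpr)
  } else {
    hyf <- hit_model(y, background, bin_width, pseudo, rule, target_fpr)
    hyr <- hit_model(reverse_complement(y), background, bin_width, pseudo,
                     rule, target_fpr)
  }
  check_pair(hx, hyf)
  list(x = hx, yf = hyf, yr = hyr)
}

#' Maximal overlap similarity of two PFMs
#'
#' Maximizes [similarity_at()] over every offset with at least one overlapping
#' column and over the reverse complement of `y`. Ties are broken toward the
#' forward orientation, then the smaller `|k|`, then the smaller `k`.
#'
#' @param x,y [pfm()] objects (or prebuilt [hit_model()]s)
#' @inheritParams hit_model
#' @param ... passed to [hit_model()]
#' @return object of class `similarity_result`: `s_max` (possibly `-Inf`),
#'   `best_offset`, `best_orientation`, `gamma`, and the two hit probabilities
#' @export
s_max <- function(x, y, background = background_model(), bin_width = 0.01,
                  pseudo = 1e-6, ...) {
  pm <- pair_models(x, y, background, bin_width, pseudo, ...)
  mk <- function(h) list(contrib = h$contrib, threshold = h$threshold,
                         alpha = h$alpha)
  sm <- cpp_smax_batch(pm$x$contrib, pm$x$threshold, pm$x$alpha,
                       list(mk(pm$yf), mk(pm$yr)),
                       as.numeric(pm$x$background))
  res <- list(s_max = unname(sm[1, "s_max"]), offset = unname(sm[1, "offset"]),
              orientation = unname(sm[1, "orientation"]),
              gamma = unname(sm[1, "gamma"]))
  as_similarity_result(res, pm$x$alpha, pm$yf$alpha, pm$yr$alpha)
}

#' Brute-force S^max by word enumeration
#'
#' Independent oracle for [s_max()]: enumerates every word over the union
#' window at every offset and orientation and classifies both hit events
#' directly. Refuses union windows longer than 12 columns (4^12 words).
#'
#' @inheritParams s_max
#' @return as [s_max()]
#' @export
brute_force_s_max <- function(x, y, background = background_model(),
                              bin_width = 0.01, pseudo = 1e-6, ...) {
  pm <- pair_models(x, y, background, bin_width, pseudo, ...)
  res <- cpp_smax_brute(pm$x$contrib, pm$x$threshold, pm$x$alpha,
                        pm$yf$contrib, pm$yf$threshold, pm$yf$alpha,
                        pm$yr$contrib, pm$yr$threshold, pm$yr$alpha,
                        as.numeric(pm$x$background))
  as_similarity_result(res, pm$x$alpha, pm$yf$alpha, pm$yr$alpha)
}
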
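# Domain score: how likely a candidate motif shares a DNA-binding domain with
# the motifs of a DBD family, and its Monte-Carlo empirical p-value.

# Internal: hit models (forward + reverse complement, interleaved) for every
# consensus in the collection, cached once and reused across many candidates.
consensus_models <- function(collection) {
  pars <- collection$parameters
  bg <- background_model(pars$background)
  models <- list()
  dbd_of_pair <- character()
  for (d in names(collection$dbds)) {
    for (cl in collection$dbds[[d]]) {
      hf <- hit_model(cl$consensus, bg, pars$bin_width, pars$pseudo)
      hr <- hit_model(reverse_complement(cl$consensus), bg, pars$bin_width,
                      pars$pseudo)
      models <- c(models, list(
        list(contrib = hf$contrib, threshold = hf$threshold, alpha = hf$alpha),
        list(contrib = hr$contrib, threshold = hr$threshold, alpha = hr$alpha)))
      dbd_of_pair <- c(dbd_of_pair, d)
    }
  }
  list(models = models, dbd_of_pair = dbd_of_pair,
       dbd_names = names(collection$dbds))
}

# Internal: raw per-DBD max similarities (may be -Inf) for one candidate,
# given its hit model and the cached consensus models.
raw_max_sims <- function(hx, cm, bg) {
  sm <- cpp_smax_batch(hx$contrib, hx$threshold, hx$alpha, cm$models, bg)
  vapply(cm$dbd_names, function(d) max(sm[cm$dbd_of_pair == d, 1]),
         numeric(1))
}

#' Maximal similarity of a candidate motif to one DBD
#'
#' The largest [s_max()] between the candidate and the consensus motifs of the
#' named DBD. An all-incompatible DBD (zero overlap probability against every
#' consensus) yields the clip value 0, the same sentinel handling the domain
#' score applies.
#'
#' @param p a candidate [pfm()]
#' @param collection a [build_collection()] result
#' @param dbd DBD name present in the collection
#' @return numeric scalar
#' @export
max_similarity <- function(p, collection, dbd) {
  stopifnot(is_pfm(p), inherits(collection, "dbd_collection"))
  dbd <- normalize_dbd(dbd)
  if (!dbd %in% names(collection$dbds))
    stop("unknown DBD '", dbd, "'; available: ",
         paste(names(collection$dbds), collapse = ", "))
  pars <- collection$parameters
  bg <- background_model(pars$background)
  hx <- hit_model(p, bg, pars$bin_width, pars$pseudo)
  cm <- consensus_models(collection)
  keep <- cm$dbd_of_pair == dbd
  cm$models <- cm$models[rep(keep, each = 2)]
  cm$dbd_of_pair <- cm$dbd_of_pair[keep]
  cm$dbd_names <- dbd
  v <- unname(raw_max_sims(hx, cm, as.numeric(bg)))
  if (is.finite(v)) v else 0
}

#' Domain score vector of a candidate motif
#'
#' For each DBD the maximal similarity to that DBD's consensus motifs,
#' normalized by the sum over all DBDs:
#' `I_D(P, D_l) = clip(max sim(P, D_l)) / sum_m clip(max sim(P, D_m))`.
#' S^max is a log-ratio and can be negative or `-Inf`, which the ratio cannot
#' absorb; the default clip is `max(s, 0)`, the alternative `"exp"`
#' exponentiates (i.e. uses the raw probability ratio). If every clipped
#' similarity is zero the score degenerates to the uniform `1/|D|` and the
#' result is flagged.
#'
#' @inheritParams max_similarity
#' @param clip `"zero"` (default) or `"exp"`
#' @return object of class `domain_scores`: list with `id`, `raw` (named raw
#'   max similarities), `score` (named, non-negative, sums to 1), `degenerate`
#' @export
domain_score <- function(p, collection, clip = c("zero", "exp")) {
  clip <- match.arg(clip)
  stopifnot(is_pfm(p), inherits(collection, "dbd_collection"))
  if (length(collection$dbds) == 0) stop("empty collection")
  pars <- collection$parameters
  bg <- background_model(pars$background)
  hx <- hit_model(p, bg, pars$bin_width, pars$pseudo)
  raw <- raw_max_sims(hx, consensus_models(collection), as.numeric(bg))
  structure(c(list(id = p$id), normalize_scores(raw, clip)),
            class = "domain_scores")
}

normalize_scores <- function(raw, clip) {
  cl <- if (clip == "zero") pmax(raw, 0) else exp(raw)
  cl[!is.finite(cl)] <- 0
  denom <- sum(cl)
  if (denom > 0) {
    list(raw = raw, score = cl / denom, degenerate = FALSE)
  } else {
    u <- rep(1 / length(raw), length(raw))
    names(u) <- names(raw)
    list(raw = raw, score = u, degenerate = TRUE)
  }
}

#' @export
print.domain_scores <- function(x, ...) {
  cat("domain scores for", x$id,
      if (x$degenerate) "(degenerate: uniform fallback)" else "", "\n")
  print(round(x$score, 4))
  invisible(x)
}

#' Sample a random PFM under entropy and length constraints
#'
#' The Monte-Carlo null draws motifs with length uniform on `length_range`,
#' each column from a flat Dirichlet(1,1,1,1); a whole matrix is rejected and
#' redrawn until its mean per-column Shannon entropy (bits) reaches
#' `min_avg_entropy`. Uses R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param length_range integer length 2, inclusive motif length bounds
#'   (default 6 to 21, the usual TF binding-site range)
#' @param min_avg_entropy minimal mean column entropy in bits, in `[0, 2]`
#' @param max_attempts rejection cap (default 10000) before erroring
#' @param alpha Dirichlet concentration of the column sampler (default 1,
#'   flat); values below 1 give peaked, information-rich columns like real TF
#'   motifs and are used by the synthetic anchor generator
#' @return a [pfm()] with attribute `attempts`
#' @export
sample_random_pfm <- function(length_range = c(6L, 21L), min_avg_entropy = 0.6,
                              max_attempts = 10000L, alpha = 1) {
  stopifnot(length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2],
            min_avg_entropy >= 0, min_avg_entropy <= 2, alpha > 0)
  for (attempt in seq_len(max_attempts)) {
    L <- if (length_range[1] == length_range[2]) length_range[1] else
      sample(seq.int(length_range[1], length_range[2]), 1L)
    g <- matrix(stats::rgamma(4L * L, shape = alpha), nrow = 4L)
    if (any(colSums(g) == 0)) next # numerically degenerate draw (tiny alpha)
    m <- sweep(g, 2L, colSums(g), "/")
    ent <- apply(m, 2L, function(col) {
      nz <- col[col > 0]
      -sum(nz * log2(nz))
    })
    if (mean(ent) >= min_avg_entropy) {
      p <- pfm(m, id = "random")
      attr(p, "attempts") <- attempt
      return(p)
    }
  }
  stop("random PFM rejected ", max_attempts, " times; entropy bound too high?")
}

#' @rdname sample_random_pfm
#' @param n number of PFMs
#' @return for `sample_random_pfms`: a list of `n` PFMs with ids
#'   `random_000001 ...`
#' @export
sample_random_pfms <- function(n, length_range = c(6L, 21L),
                               min_avg_entropy = 0.6, max_attempts = 10000L) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sample_random_pfm(length_range, min_avg_entropy, max_attempts)
    p$id <- sprintf("random_%06d", i)
    out[[i]] <- p
  }
  out
}

#' Build per-DBD Monte-Carlo null distributions of the domain score
#'
#' Samples one shared set `R` of `n` random PFMs (see [sample_random_pfm()])
#' and computes each one's full domain-score vector against the collection --
#' one pass per random motif serves every DBD because the normalizing
#' denominator is shared. The per-DBD score samples are stored sorted,
#' together with the sampler parameters and the collection fingerprint.
#'
#' @inheritParams max_similarity
#' @param n sample size (default 100000; the smallest attainable p-value is
#'   `1/n`)
#' @param seed integer seed for the sampler (stored for audit); `NULL` leaves
#'   the RNG state alone
#' @param length_range,min_avg_entropy sampler constraints
#' @param clip see [domain_score()]
#' @return object of class `dbd_null`: `dists` (DBD name ->
#'   `null_distribution` with sorted `scores`), `n`, `seed`, `parameters`,
#'   `fingerprint`
#' @export
build_null <- function(collection, n = 100000L, seed = NULL,
                       length_range = c(6L, 21L), min_avg_entropy = 0.6,
                       clip = c("zero", "exp")) {
  clip <- match.arg(clip)
  stopifnot(inherits(collection, "dbd_collection"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  pars <- collection$parameters
  bg <- background_model(pars$background)
  bgv <- as.numeric(bg)
  cm <- consensus_models(collection)
  dbd_names <- names(collection$dbds)
  scores <- matrix(NA_real_, nrow = n, ncol = length(dbd_names),
                   dimnames = list(NULL, dbd_names))
  for (i in seq_len(n)) {
    r <- sample_random_pfm(length_range, min_avg_entropy)
    hx <- hit_model(r, bg, pars$bin_width, pars$pseudo)
    raw <- raw_max_sims(hx, cm, bgv)
    scores[i, ] <- normalize_scores(raw, clip)$score
  }
  fp <- collection_fingerprint(collection)
  dists <- lapply(dbd_names, function(d) {
    structure(list(dbd = d, scores = sort(scores[, d]), n = n, seed = seed,
                   length_range = length_range,
                   min_avg_entropy = min_avg_entropy, clip = clip,
                   fingerprint = fp),
              class = "null_distribution")
  })
  names(dists) <- dbd_names
  structure(list(dists = dists, n = n, seed = seed,
                 parameters = list(length_range = length_range,
                                   min_avg_entropy = min_avg_entropy,
                                   clip = clip),
                 fingerprint = fp),
            class = "dbd_null")
}

#' @export
print.dbd_null <- function(x, ...) {
  cat("dbd_null:", length(x$dists), "DBD(s), |R| =", x$n,
      ", seed =", if (is.null(x$seed)) "none" else x$seed,
      ", fingerprint", x$fingerprint, "\n")
  invisible(x)
}

#' Empirical p-value of a domain score
#'
#' `p = max(#\{r in R : I_D(r) >= x\}, 1) / |R|`: the fraction of random
#' motifs scoring at least `x` for the DBD, floored at `1/|R|` so a score
#' above every null sample still gets a valid (smallest attainable) p-value.
#' With the default null size of 100000 the floor is 1e-5.
#'
#' @param x numeric vector of observed domain scores
#' @param null a `null_distribution`, or a `dbd_null` together with `dbd`
#' @param dbd DBD name (required when `null` is a `dbd_null`)
#' @return numeric vector of p-values in `[1/|R|, 1]`
#' @export
domain_pvalue <- function(x, null, dbd = NULL) {
  if (inherits(null, "dbd_null")) {
    if (is.null(dbd)) stop("give the DBD name when passing a dbd_null")
    dbd <- normalize_dbd(dbd)
    if (!dbd %in% names(null$dists))
      stop("unknown DBD '", dbd, "'; available: ",
           paste(names(null$dists), collapse = ", "))
    null <- null$dists[[dbd]]
  }
  stopifnot(inherits(null, "null_distribution"))
  v <- null$scores # sorted ascending
  nr <- length(v)
  count_ge <- nr - findInterval(x, v, left.open = TRUE)
  pmax(count_ge, 1) / nr
}

NULL_FORMAT <- "1"

#' Persist / restore null distributions
#'
#' The archive is a single TSV with `#key=value` metadata lines (sample size,
#' seed, sampler parameters, collection fingerprint) followed by the sorted
#' per-DBD score samples.
#'
#' @param null a `dbd_null`
#' @param path file path
#' @return `path` (save) or a `dbd_null` (load)
#' @export
save_null <- function(null, path) {
  stopifnot(inherits(null, "dbd_null"))
  meta <- c(paste0("#format_version=", NULL_FORMAT),
            paste0("#n=", null$n),
            paste0("#seed=", if (is.null(null$seed)) "" else null$seed),
            paste0("#length_range=", paste(null$parameters$length_range,
                                           collapse = ",")),
            paste0("#min_avg_entropy=",
                   sprintf("%.17g", null$parameters$min_avg_entropy)),
            paste0("#clip=", null$parameters$clip),
            paste0("#fingerprint=", null$fingerprint),
            "#dbd\tscore")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  for (d in names(null$dists)) {
    writeLines(sprintf("%s\t%.17g", d, null$dists[[d]]$scores), con)
  }
  invisible(path)
}

#' @rdname save_null
#' @export
load_null <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  metal <- lines[startsWith(lines, "#")]
  kv <- sub("^#", "", metal[grepl("=", metal)])
  kvs <- regmatches(kv, regexpr("=", kv), invert = TRUE)
  meta <- lapply(kvs, function(x) if (length(x) == 2) x[2] else "")
  names(meta) <- vapply(kvs, `[[`, character(1), 1)
  if (!identical(meta$format_version, NULL_FORMAT))
    stop("null archive format version mismatch in ", path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("corrupted null archive: ", path)
  d <- vapply(parts, `[[`, character(1), 1)
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  if (anyNA(s)) stop("corrupted null archive (non-numeric score): ", path)
  n <- as.integer(meta$n)
  seed <- if (nzchar(meta$seed)) as.integer(meta$seed) else NULL
  lr <- as.integer(strsplit(meta$length_range, ",")[[1]])
  mae <- as.numeric(meta$min_avg_entropy)
  dists <- lapply(unique(d), function(dn) {
    structure(list(dbd = dn, scores = sort(s[d == dn]), n = n, seed = seed,
                   length_range = lr, min_avg_entropy = mae, clip = meta$clip,
                   fingerprint = meta$fingerprint),
              class = "null_distribution")
  })
  names(dists) <- unique(d)
  if (any(vapply(dists, function(x) length(x$scores), integer(1)) != n))
    stop("corrupted null archive (per-DBD sample size != n): ", path)
  structure(list(dists = dists, n = n, seed = seed,
                 parameters = list(length_range = lr, min_avg_entropy = mae,
                                   clip = meta$clip),
                 fingerprint = meta$fingerprint),
            class = "dbd_null")
}

#' Domain scores and p-values for a set of candidate motifs
#'
#' Convenience wrapper used by the ranking pipeline: for each candidate,
#' the domain score for `dbd` (one [domain_score()] pass) and its empirical
#' p-value under `null`. Errors if the null was built for a different
#' collection (fingerprint mismatch).
#'
#' @param candidates list of [pfm()]
#' @inheritParams max_similarity
#' @param null a `dbd_null` built from `collection`
#' @param clip see [domain_score()]
#' @return data.frame with columns `motif_id`, `score`, `p_value`
#' @export
score_motifs <- function(candidates, collection, null, dbd,
                         clip = c("zero", "exp")) {
  clip <- match.arg(clip)
  stopifnot(inherits(collection, "dbd_collection"), inherits(null, "dbd_null"))
  if (!identical(null$fingerprint, collection_fingerprint(collection)))
    stop("null distribution was built for a different collection ",
         "(fingerprint mismatch); rebuild with build_null()")
  dbd <- normalize_dbd(dbd)
  if (!dbd %in% names(collection$dbds))
    stop("unknown DBD '", dbd, "'; available: ",
         paste(names(collection$dbds), collapse = ", "))
  pars <- collection$parameters
  bg <- background_model(pars$background)
  cm <- consensus_models(collection)
  sc <- vapply(candidates, function(p) {
    hx <- hit_model(p, bg, pars$bin_width, pars$pseudo)
    normalize_scores(raw_max_sims(hx, cm, as.numeric(bg)), clip)$score[[dbd]]
  }, numeric(1))
  data.frame(motif_id = vapply(candidates, function(p) p$id, character(1)),
             score = sc,
             p_value = domain_pvalue(sc, null, dbd),
             stringsAsFactors = FALSE)
}
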
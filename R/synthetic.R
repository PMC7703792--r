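# Synthetic fixtures: toy DBD collections with controlled within/between-DBD
# similarity, implanted-motif sequence sets, and mock enrichment p-value
# tables. Everything is reproducible from (parameters, seed).

# Internal: perturb each column of a PFM by mixing in Dirichlet(1) noise.
perturb_pfm <- function(p, magnitude, id = p$id) {
  m <- p$matrix
  g <- matrix(stats::rgamma(length(m), shape = 1), nrow = 4L)
  noise <- sweep(g, 2L, colSums(g), "/")
  pfm((1 - magnitude) * m + magnitude * noise, id = id, dbd = p$dbd)
}

#' Build a toy DBD collection with controlled similarity structure
#'
#' Each synthetic DBD gets a distinct random anchor PFM; its member motifs are
#' lightly perturbed copies of the anchor, so within-DBD S^max exceeds
#' between-DBD S^max by construction. Two choices enforce the construction:
#' anchors are drawn with peaked columns (Dirichlet concentration below 1,
#' like real TF motifs, with no entropy floor) and are rejection-sampled until
#' every anchor pair has S^max at most `anchor_separation`, so no two
#' synthetic families accidentally share a binding preference. The members are
#' then clustered per DBD exactly as for a real collection.
#'
#' @param n_dbds number of synthetic DBD families (named `DBD_1 ...`)
#' @param motifs_per_dbd members per family
#' @param seed integer seed (`NULL` leaves the RNG state alone)
#' @param length_range anchor length bounds; short anchors (default 6 to 10)
#'   keep the exact overlap DP cheap, since its cost grows with the overlap
#'   window
#' @param perturb Dirichlet-noise mixing weight for members (default 0.05)
#' @param anchor_alpha Dirichlet concentration of the anchor columns (default
#'   0.1): anchors are peaked like real TF motifs, unlike the flat null
#'   sampler
#' @param anchor_separation maximal S^max tolerated between two anchors
#'   (default 1.5, about the median similarity of two unrelated random
#'   motifs); anchors are redrawn until separated (best-effort: after 100
#'   draws the most-separated draw is kept)
#' @param merge_threshold clustering threshold, see [greedy_cluster()]
#' @return a `dbd_collection` (provenance `"synthetic"`)
#' @export
make_toy_collection <- function(n_dbds = 2L, motifs_per_dbd = 2L, seed = NULL,
                                length_range = c(6L, 10L), perturb = 0.05,
                                anchor_alpha = 0.1, anchor_separation = 1.5,
                                merge_threshold = 3) {
  stopifnot(n_dbds >= 1, motifs_per_dbd >= 1)
  if (!is.null(seed)) set.seed(seed)
  motifs <- list()
  ann <- character()
  anchors <- list()
  for (d in seq_len(n_dbds)) {
    dbd <- paste0("DBD_", d)
    anchor <- NULL
    best <- NULL
    best_sep <- Inf
    for (try in 1:100) {
      cand <- sample_random_pfm(length_range = length_range,
                                min_avg_entropy = 0, alpha = anchor_alpha)
      sep <- max(c(-Inf, vapply(anchors, function(a) s_max(cand, a)$s_max,
                                numeric(1))))
      if (sep < best_sep) { best <- cand; best_sep <- sep }
      if (sep <= anchor_separation) { anchor <- cand; break }
    }
    # best-effort fallback: keep the most-separated draw seen
    if (is.null(anchor)) anchor <- best
    anchors[[d]] <- anchor
    for (m in seq_len(motifs_per_dbd)) {
      id <- sprintf("%s_m%d", dbd, m)
      motifs[[id]] <- perturb_pfm(anchor, perturb, id = id)
      ann[id] <- dbd
    }
  }
  build_collection(motifs, ann, merge_threshold = merge_threshold,
                   provenance = "synthetic")
}

#' Sequences with an implanted motif
#'
#' Generates iid background sequences and implants a word sampled from the
#' motif, centered (with optional position jitter), into a random subset of
#' `ceiling(implant_rate * n)` sequences. Names carry synthetic signal values
#' (`seq_<i>;signal=<x>`), mirroring peak-centered ChIP-seq sequence sets.
#'
#' @param motif a [pfm()]
#' @param n number of sequences
#' @param length sequence length, at least `pfm_length(motif)`
#' @param implant_rate fraction of sequences receiving an implant, in `[0, 1]`
#' @param seed integer seed (`NULL` leaves the RNG state alone)
#' @param background a [background_model()]
#' @param jitter maximal absolute shift of the implant from the center
#' @return a [Biostrings::DNAStringSet] with an `implanted` logical attribute
#' @export
implant_sequences <- function(motif, n, length, implant_rate = 1, seed = NULL,
                              background = background_model(), jitter = 0) {
  stopifnot(is_pfm(motif), length >= pfm_length(motif),
            implant_rate >= 0, implant_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  bg <- as.numeric(background)
  L <- pfm_length(motif)
  n_impl <- ceiling(implant_rate * n)
  which_impl <- if (n_impl > 0) sort(sample.int(n, n_impl)) else integer()
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- sample(bases, length, replace = TRUE, prob = bg)
    if (i %in% which_impl) {
      word <- vapply(seq_len(L), function(j) {
        sample(bases, 1L, prob = motif$matrix[, j])
      }, character(1))
      off <- if (jitter > 0) sample.int(2L * jitter + 1L, 1L) - jitter - 1L
             else 0L
      start <- floor((length - L) / 2) + 1L + off
      start <- max(1L, min(start, length - L + 1L))
      s[start:(start + L - 1L)] <- word
    }
    seqs[i] <- paste(s, collapse = "")
  }
  signal <- round(stats::runif(n, 1, 100), 2)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("seq_%d;signal=%s", seq_len(n), format(signal))
  attr(out, "implanted") <- seq_len(n) %in% which_impl
  out
}

#' Mock enrichment p-value table
#'
#' Stands in for the output of a motif-enrichment tool: the true motif gets
#' `true_p`, decoys draw from `decoy_p`. With `adversarial = TRUE` one decoy
#' (the first) receives a p-value ten times better than the true motif's, the
#' failure mode the domain filter is designed to repair.
#'
#' @param candidates character vector of motif ids, or a list of [pfm()]
#' @param true_id id of the true motif (must be among the candidates, unless
#'   absent by design)
#' @param true_p p-value assigned to the true motif
#' @param decoy_p function(k) returning k decoy p-values (default uniform on
#'   `[0.01, 0.5]`)
#' @param adversarial give the first decoy a better p-value than the true
#'   motif
#' @param seed integer seed (`NULL` leaves the RNG state alone)
#' @return data.frame with columns `motif_id`, `p_value`
#' @export
mock_method_table <- function(candidates, true_id, true_p = 1e-4,
                              decoy_p = function(k) stats::runif(k, 0.01, 0.5),
                              adversarial = FALSE, seed = NULL) {
  if (!is.character(candidates))
    candidates <- vapply(candidates, function(p) p$id, character(1))
  stopifnot(length(candidates) >= 1)
  if (!is.null(seed)) set.seed(seed)
  pv <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  decoys <- setdiff(candidates, true_id)
  pv[decoys] <- decoy_p(length(decoys))
  if (true_id %in% candidates) pv[true_id] <- true_p
  if (adversarial && length(decoys) > 0) pv[decoys[1]] <- true_p / 10
  data.frame(motif_id = names(pv), p_value = unname(pv),
             stringsAsFactors = FALSE)
}

#' Adversarial end-to-end scenario
#'
#' Builds a toy collection and a set of TF datasets designed so that a plain
#' enrichment ranking fails on some datasets while domain-score filtering
#' repairs it: each dataset has one true candidate (a perturbed copy of a
#' consensus motif from the TF's own DBD) and `n_decoys` decoys perturbed from
#' the *other* DBDs' consensus motifs; in `adversarial_fraction` of the
#' datasets the mock enrichment method ranks a foreign-DBD decoy above the
#' true motif. One extra dataset whose candidates are all foreign-DBD decoys
#' is attached as `empty_dataset` (the domain filter is expected to empty it).
#'
#' @param n_datasets number of regular TF datasets
#' @param n_dbds,motifs_per_dbd,length_range,perturb,anchor_alpha collection
#'   structure, see [make_toy_collection()] (anchor separation at its
#'   default)
#' @param n_decoys decoys per dataset
#' @param candidate_perturb perturbation of candidates relative to consensus
#' @param adversarial_fraction fraction of datasets where a decoy out-ranks
#'   the true motif under the mock method
#' @param true_p mock enrichment p-value of the true motif
#' @param seed integer seed driving everything
#' @return object of class `synthetic_scenario`: `collection`, `datasets`
#'   (each with `dataset_id`, `tf`, `dbd`, `true_id`, `candidates`,
#'   `methods`), `empty_dataset`, `seed`, `parameters`
#' @export
make_adversarial_scenario <- function(n_datasets = 10L, n_dbds = 2L,
                                      motifs_per_dbd = 2L,
                                      length_range = c(10L, 10L),
                                      perturb = 0.05, anchor_alpha = 0.1,
                                      n_decoys = 3L,
                                      candidate_perturb = 0.01,
                                      adversarial_fraction = 0.6,
                                      true_p = 1e-4, seed = NULL) {
  stopifnot(n_datasets >= 1, n_dbds >= 2)
  if (!is.null(seed)) set.seed(seed)
  collection <- make_toy_collection(n_dbds = n_dbds,
                                    motifs_per_dbd = motifs_per_dbd,
                                    seed = NULL, length_range = length_range,
                                    perturb = perturb,
                                    anchor_alpha = anchor_alpha)
  dbd_names <- names(collection$dbds)
  n_adv <- round(adversarial_fraction * n_datasets)
  adv <- seq_len(n_datasets) <= n_adv # deterministic given parameters
  datasets <- vector("list", n_datasets)
  pick_consensus <- function(dbd) {
    cls <- collection$dbds[[dbd]]
    cls[[sample.int(length(cls), 1L)]]$consensus
  }
  make_candidates <- function(i, own_dbd, with_true = TRUE) {
    cands <- list()
    if (with_true) {
      true_id <- sprintf("cand_%d_true", i)
      cands[[true_id]] <- perturb_pfm(pick_consensus(own_dbd),
                                      candidate_perturb, id = true_id)
    }
    foreign <- setdiff(dbd_names, own_dbd)
    for (k in seq_len(n_decoys)) {
      did <- sprintf("cand_%d_decoy%d", i, k)
      src <- foreign[((k - 1L) %% length(foreign)) + 1L]
      cands[[did]] <- perturb_pfm(pick_consensus(src), candidate_perturb,
                                  id = did)
    }
    cands
  }
  for (i in seq_len(n_datasets)) {
    own <- dbd_names[((i - 1L) %% n_dbds) + 1L]
    cands <- make_candidates(i, own, with_true = TRUE)
    true_id <- sprintf("cand_%d_true", i)
    mock <- mock_method_table(names(cands), true_id, true_p = true_p,
                              adversarial = adv[i])
    datasets[[i]] <- list(dataset_id = sprintf("ds_%02d", i),
                          tf = sprintf("TF_%02d", i), dbd = own,
                          true_id = true_id, candidates = unname(cands),
                          methods = list(
                            C = stats::setNames(mock$p_value, mock$motif_id)))
  }
  own0 <- dbd_names[1]
  cands0 <- make_candidates(n_datasets + 1L, own0, with_true = FALSE)
  mock0 <- mock_method_table(names(cands0), true_id = "none")
  empty_dataset <- list(dataset_id = "ds_all_foreign", tf = "TF_foreign",
                        dbd = own0, true_id = NA_character_,
                        candidates = unname(cands0),
                        methods = list(
                          C = stats::setNames(mock0$p_value, mock0$motif_id)))
  structure(list(collection = collection, datasets = datasets,
                 empty_dataset = empty_dataset, seed = seed,
                 parameters = list(n_datasets = n_datasets, n_dbds = n_dbds,
                                   motifs_per_dbd = motifs_per_dbd,
                                   length_range = length_range,
                                   perturb = perturb, n_decoys = n_decoys,
                                   candidate_perturb = candidate_perturb,
                                   adversarial_fraction = adversarial_fraction,
                                   true_p = true_p)),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("synthetic_scenario:", length(x$datasets), "dataset(s) over",
      length(x$collection$dbds), "DBD(s), seed",
      if (is.null(x$seed)) "none" else x$seed, "\n")
  invisible(x)
}
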
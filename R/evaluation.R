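# Cluster-aware evaluation of motif-to-TF linking: correctness, PR curves,
# PR-AUC.

#' Cluster-aware correctness of a linked motif
#'
#' A predicted motif counts as correctly linked when it falls in the same
#' cluster as the true motif, so near-identical database motifs are not
#' penalized.
#'
#' @param predicted,true_motif motif ids
#' @param clusters list of [motif_cluster()] covering both ids
#' @return logical scalar
#' @export
correctness <- function(predicted, true_motif, clusters) {
  ci <- cluster_index(predicted, clusters)
  cj <- cluster_index(true_motif, clusters)
  ci == cj
}

cluster_index <- function(id, clusters) {
  for (i in seq_along(clusters)) {
    if (id %in% clusters[[i]]$members) return(i)
  }
  stop("motif id '", id, "' not found in the clustering")
}

#' Designate the true motif among de novo candidates
#'
#' De novo discovery returns anonymous motifs; the candidate most similar (by
#' [s_max()]) to the TF's known motif is designated as the true one. Ties are
#' broken by motif id.
#'
#' @param candidates non-empty list of [pfm()]
#' @param known_true the TF's known [pfm()]
#' @param ... passed to [s_max()]
#' @return the designated candidate's motif id
#' @export
designate_true_de_novo <- function(candidates, known_true, ...) {
  stopifnot(length(candidates) >= 1)
  ids <- vapply(candidates, function(p) p$id, character(1))
  sims <- vapply(candidates, function(p) s_max(p, known_true, ...)$s_max,
                 numeric(1))
  best <- which(sims == max(sims))
  ids[best][order(ids[best])][1]
}

#' Precision-recall curve over per-dataset top predictions
#'
#' Takes one top-1 prediction (or an explicit no-prediction, `p = NA`) per
#' dataset and sweeps a threshold over the prediction confidences (p-values,
#' ascending). At threshold theta: TP = correct predictions with `p <= theta`,
#' FP = incorrect predictions with `p <= theta`, FN = datasets whose motif is
#' not yet correctly linked (`n - TP`); datasets without a prediction count as
#' FN at every threshold. The AUC is the trapezoid over the achieved recall
#' range, with the curve anchored at (recall 0, precision of the first sweep
#' point).
#'
#' @param predictions data.frame with columns `dataset_id`, `p` (confidence,
#'   `NA` for no prediction) and `correct` (logical, `NA` for no prediction)
#' @return object of class `pr_eval`: `points` (threshold, tp, fp, fn, recall,
#'   precision), `auc`, `n_datasets`, `n_no_prediction`
#' @export
pr_curve <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("dataset_id", "p", "correct") %in% names(predictions)))
  n <- nrow(predictions)
  if (n == 0) stop("no datasets to evaluate")
  has <- !is.na(predictions$p)
  if (!any(has)) stop("no predictions at all (every dataset is empty)")
  p <- predictions$p[has]
  corr <- as.logical(predictions$correct[has])
  if (anyNA(corr)) stop("predictions with a confidence need a correct flag")
  thresholds <- sort(unique(p))
  pts <- do.call(rbind, lapply(thresholds, function(th) {
    tp <- sum(corr & p <= th)
    fp <- sum(!corr & p <= th)
    fn <- n - tp
    data.frame(threshold = th, tp = tp, fp = fp, fn = fn,
               recall = tp / n, precision = tp / (tp + fp))
  }))
  rec <- c(0, pts$recall)
  prec <- c(pts$precision[1], pts$precision)
  auc <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  structure(list(points = pts, auc = auc, n_datasets = n,
                 n_no_prediction = sum(!has)),
            class = "pr_eval")
}

#' @export
print.pr_eval <- function(x, ...) {
  cat("pr_eval:", x$n_datasets, "dataset(s),", x$n_no_prediction,
      "without prediction; PR-AUC =", format(round(x$auc, 4)), "\n")
  print(x$points)
  invisible(x)
}

#' Evaluate ranking variants on a synthetic scenario
#'
#' Runs [rank_variant()] for each requested variant on every dataset of a
#' [make_adversarial_scenario()] and scores the top-1 predictions against the
#' known true motifs (exact id match: synthetic candidates are not
#' re-clustered).
#'
#' @param scenario a [make_adversarial_scenario()]
#' @param null a `dbd_null` built from `scenario$collection`
#' @param variants character vector of variant names (see [rank_variant()])
#' @param pi filter threshold
#' @return named list per variant: `predictions` data.frame, `accuracy`
#'   (top-1), `pr` ([pr_curve()] result)
#' @export
evaluate_scenario <- function(scenario, null, variants = c("C", "M_C"),
                              pi = 0.001) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(null, "dbd_null"))
  out <- list()
  for (v in variants) {
    rows <- lapply(scenario$datasets, function(ds) {
      tab <- scenario_table(ds, scenario, null)
      rk <- rank_variant(tab, v, pi = pi)
      th <- top_hit(rk)
      data.frame(dataset_id = ds$dataset_id, p = th$p,
                 correct = if (th$empty) NA else th$motif_id == ds$true_id,
                 stringsAsFactors = FALSE)
    })
    preds <- do.call(rbind, rows)
    out[[v]] <- list(predictions = preds,
                     accuracy = sum(preds$correct, na.rm = TRUE) / nrow(preds),
                     pr = if (all(is.na(preds$p))) NULL else pr_curve(preds))
  }
  out
}

# Internal: assemble the ranked_motifs table for one scenario dataset.
scenario_table <- function(ds, scenario, null) {
  sc <- score_motifs(ds$candidates, scenario$collection, null, ds$dbd)
  motif_table(ds$dataset_id, ds$tf, ds$dbd,
              method_pvalues = ds$methods,
              domain_pvalues = stats::setNames(sc$p_value, sc$motif_id))
}
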
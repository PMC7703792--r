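# Combining domain-score p-values with enrichment-tool p-values: Fisher
# meta-analysis and the pi filter, producing the final ranked motif list.

#' Read a per-method motif p-value table
#'
#' Two-column TSV (`motif_id`, `p_value`); a header line is detected and
#' skipped, `#` comment lines are ignored. This is the generic interface for
#' outputs of motif-enrichment tools (CentriMo-, PASTAA-style rankings).
#'
#' @param path TSV file path
#' @param zero_floor p-values of exactly 0 are clipped up to this floor with a
#'   warning (default 1e-300), since downstream Fisher combination needs
#'   `p > 0`
#' @return named numeric vector (motif id -> p-value)
#' @export
read_method_pvalues <- function(path, zero_floor = 1e-300) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("malformed row (need motif_id<TAB>p_value) in ", path)
  first_p <- suppressWarnings(as.numeric(parts[[1]][2]))
  if (is.na(first_p)) { # header
    lines <- lines[-1]
    parts <- parts[-1]
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  pv <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  if (anyNA(pv)) {
    bad <- which(is.na(pv))[1]
    stop("non-numeric p-value in ", path, " at data row ", bad, ": '",
         parts[[bad]][2], "'")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate motif id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(pv < 0 | pv > 1)) stop("p-value outside [0, 1] in ", path)
  if (any(pv == 0)) {
    warning(sum(pv == 0), " p-value(s) of 0 clipped to ", zero_floor,
            " in ", path)
    pv[pv == 0] <- zero_floor
  }
  stats::setNames(pv, ids)
}

#' Fisher's method for combining p-values
#'
#' `X = -2 sum(log p_i)` follows a chi-squared distribution with `2m` degrees
#' of freedom under the null of all nulls true; the combined p-value is its
#' survival function at `X`, evaluated with the even-degrees-of-freedom closed
#' form `exp(-X/2) * sum_{j=0}^{m-1} (X/2)^j / j!`.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`, length `m >= 1`
#' @return combined p-value in `(0, 1]`
#' @export
fisher_combine <- function(pvalues) {
  m <- length(pvalues)
  if (m < 1) stop("need at least one p-value")
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  xh <- -sum(log(pvalues)) # X/2
  term <- 1
  total <- 1
  for (j in seq_len(m - 1)) {
    term <- term * xh / j
    total <- total + term
  }
  min(1, exp(-xh) * total)
}

#' Assemble a per-dataset motif table
#'
#' One row per candidate motif, one p-value column per enrichment method plus
#' the domain-score p-value. The candidate set is the union of ids across
#' methods and the domain p-values; a method that did not report a motif gets
#' `NA` there (variants needing that method will refuse to rank).
#'
#' @param dataset_id,tf,dbd dataset identifier, TF name, and the TF's DBD
#' @param method_pvalues named list of named numeric vectors as returned by
#'   [read_method_pvalues()]; list names are the method names
#' @param domain_pvalues named numeric vector (motif id -> domain p-value)
#' @return data.frame of class `ranked_motifs` with columns `motif_id`,
#'   `p_<method>` ..., `p_domain`, `filtered`; attributes `dataset_id`, `tf`,
#'   `dbd`, `methods`
#' @export
motif_table <- function(dataset_id, tf, dbd, method_pvalues, domain_pvalues) {
  stopifnot(is.list(method_pvalues), length(method_pvalues) >= 1,
            !is.null(names(method_pvalues)))
  ids <- sort(unique(c(unlist(lapply(method_pvalues, names)),
                       names(domain_pvalues))))
  tab <- data.frame(motif_id = ids, stringsAsFactors = FALSE)
  for (mn in names(method_pvalues)) {
    tab[[paste0("p_", mn)]] <- unname(method_pvalues[[mn]][ids])
  }
  tab$p_domain <- unname(domain_pvalues[ids])
  tab$filtered <- FALSE
  structure(tab, dataset_id = dataset_id, tf = tf, dbd = dbd,
            methods = names(method_pvalues),
            class = c("ranked_motifs", "data.frame"))
}

#' Filter candidate motifs by domain-score p-value
#'
#' Flags motifs whose domain p-value exceeds `pi` (strictly: equality keeps
#' the motif) as filtered; ranking variants then ignore them. The table may
#' become empty, which is reported via the `empty_after_filter` attribute --
#' with de novo candidate motifs this is an expected outcome when none of them
#' resembles any known motif of the TF's DBD.
#'
#' @param table a [motif_table()]
#' @param pi significance threshold on the domain p-value (default 0.001)
#' @return the table with an updated `filtered` column and attributes
#'   `pi`, `empty_after_filter`
#' @export
apply_domain_filter <- function(table, pi = 0.001) {
  stopifnot(inherits(table, "ranked_motifs"))
  if (anyNA(table$p_domain)) stop("domain p-values missing for some motifs")
  table$filtered <- table$p_domain > pi
  attr(table, "pi") <- pi
  attr(table, "empty_after_filter") <- all(table$filtered)
  table
}

variant_spec <- function(variant) {
  switch(variant,
         C = list(methods = 1L, domain_meta = FALSE, filter = FALSE),
         P = list(methods = 2L, domain_meta = FALSE, filter = FALSE),
         CP = list(methods = 1:2, domain_meta = FALSE, filter = FALSE),
         MCP = list(methods = 1:2, domain_meta = TRUE, filter = FALSE),
         M_C = list(methods = 1L, domain_meta = FALSE, filter = TRUE),
         M_P = list(methods = 2L, domain_meta = FALSE, filter = TRUE),
         M_CP = list(methods = 1:2, domain_meta = FALSE, filter = TRUE),
         stop("unknown variant '", variant, "'"))
}

#' Rank candidate motifs under one analysis variant
#'
#' Implements the variant naming scheme for two enrichment methods plus the
#' domain score: `C` and `P` rank by a single method's p-value; `CP` combines
#' the two methods with Fisher's method; `MCP` additionally feeds the domain
#' p-value into the Fisher combination; `M_C`, `M_P` and `M_CP` first exclude
#' motifs with domain p-value above `pi` and then rank the survivors by the
#' single method or the Fisher combination. `C` maps to the first name in
#' `methods`, `P` to the second. The final order is ascending in the variant's
#' p-value with ties broken by motif id.
#'
#' @param table a [motif_table()]
#' @param variant one of `"C"`, `"P"`, `"CP"`, `"MCP"`, `"M_C"`, `"M_P"`,
#'   `"M_CP"`
#' @param pi filter threshold for the `M_*` variants (default 0.001)
#' @param methods character vector naming which method columns play the roles
#'   of C and P (default: the table's methods in order)
#' @return the table with columns `p_combined`, `filtered` and `rank`
#'   (`NA` for filtered motifs), ordered by rank; attributes `variant` and
#'   `empty_after_filter`
#' @export
rank_variant <- function(table, variant = c("C", "P", "CP", "MCP", "M_C",
                                            "M_P", "M_CP"),
                         pi = 0.001, methods = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(table, "ranked_motifs"))
  if (is.null(methods)) methods <- attr(table, "methods")
  spec <- variant_spec(variant)
  need <- spec$methods[spec$methods <= 2L]
  if (length(methods) < max(need))
    stop("variant ", variant, " needs ", max(need),
         " method column(s); table has: ", paste(methods, collapse = ", "))
  use <- methods[need]
  cols <- paste0("p_", use)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0)
    stop("variant ", variant, " needs method column(s) ",
         paste(missing_cols, collapse = ", "))
  if (spec$filter || spec$domain_meta) {
    if (anyNA(table$p_domain))
      stop("variant ", variant, " needs domain p-values for every motif")
  }
  if (spec$filter) {
    table <- apply_domain_filter(table, pi)
  } else {
    table$filtered <- FALSE
    attr(table, "empty_after_filter") <- FALSE
  }
  pm <- as.matrix(table[, cols, drop = FALSE])
  if (anyNA(pm[!table$filtered, ]))
    stop("variant ", variant, " requires p-values from method(s) ",
         paste(use, collapse = ", "), " for every unfiltered motif")
  comb <- rep(NA_real_, nrow(table))
  for (i in which(!table$filtered)) {
    ps <- pm[i, ]
    if (spec$domain_meta) ps <- c(ps, table$p_domain[i])
    comb[i] <- if (length(ps) == 1) ps else fisher_combine(ps)
  }
  table$p_combined <- comb
  ord <- order(table$filtered, table$p_combined, table$motif_id)
  table <- table[ord, , drop = FALSE]
  table$rank <- NA_integer_
  table$rank[!table$filtered] <- seq_len(sum(!table$filtered))
  rownames(table) <- NULL
  attr(table, "variant") <- variant
  table
}

#' @export
print.ranked_motifs <- function(x, ...) {
  cat("ranked_motifs for dataset", attr(x, "dataset_id"),
      "(TF", attr(x, "tf"), ", DBD", attr(x, "dbd"), ")",
      if (!is.null(attr(x, "variant"))) paste0("variant ", attr(x, "variant")),
      "\n")
  if (isTRUE(attr(x, "empty_after_filter")))
    cat("  ** all candidate motifs removed by the domain filter **\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Top-ranked motif of a ranked table
#'
#' @param table output of [rank_variant()]
#' @return list with `motif_id` and `p` (both `NA` when the filter removed
#'   every candidate), and `empty` flag
#' @export
top_hit <- function(table) {
  stopifnot(inherits(table, "ranked_motifs"))
  keep <- which(!is.na(table$rank) & table$rank == 1L)
  if (length(keep) == 0) {
    list(motif_id = NA_character_, p = NA_real_, empty = TRUE)
  } else {
    list(motif_id = table$motif_id[keep], p = table$p_combined[keep],
         empty = FALSE)
  }
}
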
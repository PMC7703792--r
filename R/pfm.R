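#' Position frequency matrix (PFM)
#'
#' A PFM describes the sequence preference of a transcription factor as a
#' 4 x L matrix of per-position nucleotide frequencies: column i is the
#' probability vector over the alphabet (A, C, G, T) at motif position i.
#' Columns are renormalized on construction, so small rounding differences
#' between database dialects are tolerated.
#'
#' @param matrix numeric 4 x L matrix (rows A, C, G, T) of frequencies or
#'   counts per column. Columns must be non-negative and sum to a positive
#'   value; they are rescaled to sum to exactly 1.
#' @param id character scalar, motif identifier.
#' @param name optional character scalar, usually the TF name.
#' @param dbd optional character scalar, DNA-binding domain family label.
#' @param counts optional non-negative integer matrix of the same shape,
#'   retained verbatim (e.g. raw database counts).
#' @return An object of class `pfm`.
#' @examples
#' p <- pfm(matrix(c(1, 0, 0, 0, 0, 1, 0, 0), nrow = 4), id = "toy")
#' reverse_complement(p)
#' @export
pfm <- function(matrix, id, name = NULL, dbd = NULL, counts = NULL) {
  m <- base::as.matrix(matrix)
  storage.mode(m) <- "double"
  if (nrow(m) != 4L) stop("a PFM needs 4 rows (A, C, G, T), got ", nrow(m))
  if (ncol(m) < 1L) stop("a PFM needs at least one column")
  if (anyNA(m) || any(m < 0)) stop("PFM entries must be non-negative and non-missing")
  cs <- colSums(m)
  if (any(cs <= 0)) {
    stop("PFM '", id, "': column(s) ", paste(which(cs <= 0), collapse = ", "),
         " sum to zero")
  }
  m <- sweep(m, 2L, cs, "/")
  dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
  if (!is.null(counts)) {
    counts <- base::as.matrix(counts)
    if (!all(dim(counts) == dim(m))) stop("counts must match the matrix shape")
    if (any(counts < 0)) stop("counts must be non-negative")
    dimnames(counts) <- dimnames(m)
  }
  structure(list(id = as.character(id), name = name, matrix = m,
                 counts = counts, dbd = dbd),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("PFM", x$id,
      if (!is.null(x$name)) paste0("(", x$name, ")") else "",
      "length", ncol(x$matrix),
      if (!is.null(x$dbd)) paste0("DBD: ", x$dbd) else "", "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Test for the pfm class
#' @param x object
#' @return logical scalar
#' @export
is_pfm <- function(x) inherits(x, "pfm")

#' Motif length (number of columns)
#' @param p a [pfm()]
#' @return integer scalar
#' @export
pfm_length <- function(p) {
  stopifnot(is_pfm(p))
  ncol(p$matrix)
}

#' Reverse complement of a PFM
#'
#' Reverses the column order and swaps complementary rows (A<->T, C<->G),
#' giving the motif as read on the opposite strand. The operation is an
#' involution and preserves per-column information content.
#'
#' @param p a [pfm()]
#' @return a `pfm` with id suffixed `::rc` (a double application restores
#'   the original id)
#' @export
reverse_complement <- function(p) {
  stopifnot(is_pfm(p))
  comp <- c(4L, 3L, 2L, 1L) # A,C,G,T -> T,G,C,A
  m <- p$matrix[comp, rev(seq_len(ncol(p$matrix))), drop = FALSE]
  dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
  cnt <- if (is.null(p$counts)) NULL else {
    k <- p$counts[comp, rev(seq_len(ncol(p$counts))), drop = FALSE]
    dimnames(k) <- dimnames(m)
    k
  }
  id <- if (endsWith(p$id, "::rc")) sub("::rc$", "", p$id) else paste0(p$id, "::rc")
  pfm(m, id = id, name = p$name, dbd = p$dbd, counts = cnt)
}

#' Background nucleotide model
#'
#' The iid single-nucleotide background under which hit probabilities and
#' overlap probabilities are computed. Default: uniform.
#'
#' @param probs length-4 positive probability vector over (A, C, G, T);
#'   must sum to 1 within 1e-12.
#' @return numeric vector of class `background_model`
#' @export
background_model <- function(probs = rep(0.25, 4)) {
  probs <- as.numeric(probs)
  if (length(probs) != 4L || anyNA(probs) || any(probs <= 0))
    stop("background needs 4 strictly positive probabilities")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("background probabilities must sum to 1 (within 1e-12)")
  names(probs) <- c("A", "C", "G", "T")
  structure(probs, class = "background_model")
}

#' Per-column Shannon entropy of a PFM, in bits
#' @param p a [pfm()]
#' @return numeric vector of length `pfm_length(p)`
#' @export
column_entropy <- function(p) {
  stopifnot(is_pfm(p))
  apply(p$matrix, 2L, function(col) {
    nz <- col[col > 0]
    -sum(nz * log2(nz))
  })
}

# Internal: apply the pseudo-frequency repair used by the hit model.
# Adds pseudo/4 to every entry and renormalizes when (and only when) the
# matrix contains zero frequencies, so log-odds stay finite for the DP.
adjust_matrix <- function(m, pseudo) {
  if (pseudo > 0 && any(m == 0)) (m + pseudo / 4) / (1 + pseudo) else m
}
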
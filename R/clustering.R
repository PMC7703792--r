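#' Merge two PFMs into a weighted consensus
#'
#' Aligns `b` to `a` at the given offset/orientation (as reported by
#' [s_max()]) and averages aligned columns weighted by the number of motifs
#' each side already represents. Flank columns covered by only one motif are
#' averaged against the background distribution carrying the other side's
#' weight, so a consensus motif never silently sharpens beyond its support.
#' The consensus spans the union of the aligned windows.
#'
#' @param a,b [pfm()] objects
#' @param offset integer offset of `b` relative to `a` (after orientation);
#'   must leave at least one overlapping column
#' @param orientation `"forward"` or `"revcomp"` (applies to `b`)
#' @param weight_a,weight_b positive motif counts behind each side
#' @param background a [background_model()] used for uncovered flanks
#' @param id identifier for the merged PFM
#' @return a [pfm()] of length `max(L_a, offset + L_b) - min(0, offset)`
#' @export
merge_consensus <- function(a, b, offset, orientation = c("forward", "revcomp"),
                            weight_a = 1, weight_b = 1,
                            background = background_model(),
                            id = paste0(a$id, "+", b$id)) {
  orientation <- match.arg(orientation)
  stopifnot(is_pfm(a), is_pfm(b), weight_a > 0, weight_b > 0)
  if (orientation == "revcomp") b <- reverse_complement(b)
  La <- pfm_length(a); Lb <- pfm_length(b)
  if (offset < -(Lb - 1) || offset > La - 1)
    stop("offset ", offset, " leaves no overlapping column")
  lo <- min(0L, offset); hi <- max(La, offset + Lb)
  bg <- as.numeric(background)
  wtot <- weight_a + weight_b
  cols <- vapply(seq.int(lo, hi - 1L), function(pos) {
    ca <- if (pos >= 0 && pos < La) a$matrix[, pos + 1L] else bg
    cb <- if (pos >= offset && pos < offset + Lb) b$matrix[, pos - offset + 1L]
          else bg
    (weight_a * ca + weight_b * cb) / wtot
  }, numeric(4))
  pfm(cols, id = id, dbd = a$dbd)
}

#' A motif cluster
#'
#' @param members character vector of member motif ids (non-empty)
#' @param consensus the cluster's consensus [pfm()]; for a singleton cluster
#'   it is the member itself
#' @return object of class `motif_cluster`
#' @export
motif_cluster <- function(members, consensus) {
  stopifnot(length(members) >= 1, is_pfm(consensus))
  structure(list(members = as.character(members), consensus = consensus,
                 size = length(members)),
            class = "motif_cluster")
}

#' @export
print.motif_cluster <- function(x, ...) {
  cat("motif_cluster <", x$consensus$id, ">:", x$size, "member(s):",
      paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Greedy agglomerative clustering of PFMs under S^max
#'
#' Every motif starts as its own cluster (its consensus being itself). The
#' pair of consensus motifs with the highest S^max is merged, provided
#' (i) that S^max reaches `merge_threshold`, and (ii) every member of the
#' tentative merged cluster still has S^max at least `merge_threshold` to the
#' new consensus -- the "members must stay similar to their consensus" stop
#' rule. Rejected pairs are cached so each consensus pair is considered at
#' most once; the algorithm stops when no unrejected pair reaches the
#' threshold. Tied similarities are resolved lexicographically on the
#' clusters' representative (smallest) member ids, so the result is
#' deterministic for a given input.
#'
#' @param motifs list of [pfm()] with unique ids
#' @param merge_threshold minimum S^max (natural-log scale) for a merge;
#'   default 3, i.e. the overlap probability must exceed e^3 times the
#'   independent-hit probability
#' @param background,bin_width,pseudo see [hit_model()]
#' @param member_check enable rule (ii) above (default TRUE)
#' @return list of [motif_cluster()]; every input id appears in exactly one
#'   cluster. Cluster consensus motifs are re-labelled `cluster_1 ...
#'   cluster_n` in order of their first member, except singletons, which keep
#'   their member motif unchanged.
#' @export
greedy_cluster <- function(motifs, merge_threshold = 3,
                           background = background_model(), bin_width = 0.01,
                           pseudo = 1e-6, member_check = TRUE) {
  if (length(motifs) == 0) return(list())
  stopifnot(all(vapply(motifs, is_pfm, logical(1))))
  ids <- vapply(motifs, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("motif ids must be unique for clustering")
  names(motifs) <- ids

  smax_of <- function(p, q) {
    s_max(p, q, background = background, bin_width = bin_width, pseudo = pseudo)
  }

  cl <- lapply(seq_along(motifs), function(i) {
    list(members = ids[i], consensus = motifs[[i]], weight = 1L,
         rep = ids[i], sid = i, first = i)
  })
  next_sid <- length(cl) + 1L
  rejected <- new.env(parent = emptyenv())
  n <- length(cl)
  S <- matrix(-Inf, n, n); K <- matrix(0L, n, n); O <- matrix("", n, n)
  alive <- rep(TRUE, n)
  fill_pair <- function(i, j) {
    r <- smax_of(cl[[i]]$consensus, cl[[j]]$consensus)
    S[i, j] <<- r$s_max; S[j, i] <<- r$s_max
    K[i, j] <<- r$best_offset; O[i, j] <<- r$best_orientation
    # store the offset from i's frame only; callers use (i, j) ordered
    K[j, i] <<- NA_integer_; O[j, i] <<- NA_character_
  }
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) fill_pair(i, j)

  repeat {
    live <- which(alive)
    if (length(live) < 2) break
    best <- NULL
    for (ii in seq_along(live)) {
      for (jj in seq_along(live)) {
        if (jj <= ii) next
        i <- live[ii]; j <- live[jj]
        key <- paste(min(cl[[i]]$sid, cl[[j]]$sid),
                     max(cl[[i]]$sid, cl[[j]]$sid), sep = "|")
        if (!is.null(rejected[[key]])) next
        s <- S[i, j]
        if (!is.finite(s) || s < merge_threshold) next
        reps <- sort(c(cl[[i]]$rep, cl[[j]]$rep))
        if (is.null(best) || s > best$s ||
            (s == best$s && (reps[1] < best$reps[1] ||
                             (reps[1] == best$reps[1] && reps[2] < best$reps[2])))) {
          best <- list(i = i, j = j, s = s, reps = reps, key = key)
        }
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    # orient the stored argmax: K/O are recorded with i < j ordering
    if (is.na(K[i, j])) { tmp <- i; i <- j; j <- tmp }
    cons <- merge_consensus(cl[[i]]$consensus, cl[[j]]$consensus,
                            offset = K[i, j], orientation = O[i, j],
                            weight_a = cl[[i]]$weight, weight_b = cl[[j]]$weight,
                            background = background)
    members <- c(cl[[i]]$members, cl[[j]]$members)
    ok <- TRUE
    if (member_check) {
      for (mid in members) {
        if (smax_of(motifs[[mid]], cons)$s_max < merge_threshold) {
          ok <- FALSE
          break
        }
      }
    }
    if (!ok) {
      rejected[[best$key]] <- TRUE
      next
    }
    cl[[i]] <- list(members = members, consensus = cons,
                    weight = cl[[i]]$weight + cl[[j]]$weight,
                    rep = min(members), sid = next_sid,
                    first = min(cl[[i]]$first, cl[[j]]$first))
    next_sid <- next_sid + 1L
    alive[j] <- FALSE
    for (o in which(alive)) if (o != i) fill_pair(min(i, o), max(i, o))
  }

  live <- which(alive)
  live <- live[order(vapply(live, function(i) cl[[i]]$first, integer(1)))]
  out <- vector("list", length(live))
  for (idx in seq_along(live)) {
    c_ <- cl[[live[idx]]]
    cons <- c_$consensus
    if (c_$weight > 1L) {
      cons$id <- paste0("cluster_", idx)
      cons$name <- paste(c_$members, collapse = ",")
    }
    out[[idx]] <- motif_cluster(c_$members, cons)
  }
  out
}
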
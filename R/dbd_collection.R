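#' Build a DBD collection
#'
#' Partitions annotated motifs by DNA-binding-domain (DBD) family and runs
#' [greedy_cluster()] within each family, so every DBD is represented by the
#' consensus motifs of its clusters. Candidate motifs are later compared
#' against these consensus motifs to score how likely they share the DBD.
#'
#' DBD names are free-form strings matched case-sensitively after whitespace
#' normalization (TFClass family names are the recommended vocabulary).
#' Motifs without an annotation are never silently dropped: they are listed in
#' the collection's `skipped` field. A motif annotated with several DBDs is by
#' default assigned to each of them (with a disambiguating id suffix);
#' `multi_dbd = "first"` keeps only the first annotation.
#'
#' @param motifs list of [pfm()] with unique ids
#' @param annotations named character vector (motif id -> DBD name) or a
#'   data.frame with columns `motif_id` and `dbd` (several rows per id
#'   allowed)
#' @param merge_threshold,background,bin_width,pseudo clustering parameters,
#'   see [greedy_cluster()]
#' @param multi_dbd `"all"` or `"first"`: handling of multiply-annotated motifs
#' @param provenance free-form source label stored with the collection
#' @return object of class `dbd_collection`: `dbds` (DBD name -> list of
#'   [motif_cluster()]), `motifs` (the annotated member PFMs), `parameters`,
#'   `provenance`, `skipped`
#' @export
build_collection <- function(motifs, annotations, merge_threshold = 3,
                             background = background_model(), bin_width = 0.01,
                             pseudo = 1e-6, multi_dbd = c("all", "first"),
                             provenance = "unspecified") {
  multi_dbd <- match.arg(multi_dbd)
  stopifnot(all(vapply(motifs, is_pfm, logical(1))))
  ids <- vapply(motifs, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("motif ids must be unique")
  names(motifs) <- ids
  if (is.data.frame(annotations)) {
    if (!all(c("motif_id", "dbd") %in% names(annotations)))
      stop("annotation data.frame needs columns motif_id and dbd")
    ann <- annotations
  } else {
    ann <- data.frame(motif_id = names(annotations),
                      dbd = as.character(annotations),
                      stringsAsFactors = FALSE)
  }
  ann$dbd <- normalize_dbd(ann$dbd)
  ann <- ann[ann$motif_id %in% ids & nzchar(ann$dbd), , drop = FALSE]
  if (multi_dbd == "first") ann <- ann[!duplicated(ann$motif_id), , drop = FALSE]
  skipped <- setdiff(ids, ann$motif_id)

  member_pfms <- list()
  dbds <- list()
  for (dbd in unique(ann$dbd)) {
    mids <- ann$motif_id[ann$dbd == dbd]
    dup <- mids %in% names(member_pfms) |
      vapply(mids, function(m) sum(ann$motif_id == m) > 1, logical(1))
    ms <- lapply(seq_along(mids), function(i) {
      p <- motifs[[mids[i]]]
      if (dup[i]) p$id <- paste0(p$id, "::", dbd)
      p$dbd <- dbd
      p
    })
    names(ms) <- vapply(ms, function(p) p$id, character(1))
    member_pfms <- c(member_pfms, ms)
    clusters <- greedy_cluster(ms, merge_threshold = merge_threshold,
                               background = background, bin_width = bin_width,
                               pseudo = pseudo)
    for (k in seq_along(clusters)) {
      clusters[[k]]$consensus$id <- paste0(dbd, ".cl", k)
      clusters[[k]]$consensus$dbd <- dbd
    }
    dbds[[dbd]] <- clusters
  }
  structure(list(dbds = dbds, motifs = member_pfms,
                 parameters = list(merge_threshold = merge_threshold,
                                   bin_width = bin_width, pseudo = pseudo,
                                   background = as.numeric(background)),
                 provenance = provenance, skipped = skipped),
            class = "dbd_collection")
}

normalize_dbd <- function(x) gsub("[ \t]+", " ", trimws(x))

#' @export
print.dbd_collection <- function(x, ...) {
  cat("dbd_collection:", length(x$dbds), "DBD(s),",
      length(x$motifs), "motif(s)",
      if (length(x$skipped)) paste0("(", length(x$skipped), " skipped)") else "",
      "\n")
  for (d in names(x$dbds)) {
    cat("  ", d, ": ", length(x$dbds[[d]]), " cluster(s), ",
        sum(vapply(x$dbds[[d]], function(cl) cl$size, integer(1))),
        " motif(s)\n", sep = "")
  }
  invisible(x)
}

#' Consensus motifs of one DBD
#'
#' @param collection a [build_collection()] result
#' @param dbd DBD name (whitespace-normalized, case-sensitive)
#' @return list of consensus [pfm()]s, in stable cluster order
#' @export
consensus_motifs <- function(collection, dbd) {
  stopifnot(inherits(collection, "dbd_collection"))
  dbd <- normalize_dbd(dbd)
  if (!dbd %in% names(collection$dbds))
    stop("unknown DBD '", dbd, "'; available: ",
         paste(names(collection$dbds), collapse = ", "))
  lapply(collection$dbds[[dbd]], function(cl) cl$consensus)
}

#' Fingerprint of a collection
#'
#' Deterministic hash over the consensus matrices and the clustering
#' parameters; null distributions record it so a stale null can never be
#' applied to a changed collection.
#'
#' @param collection a `dbd_collection`
#' @return 16-hex-character string
#' @export
collection_fingerprint <- function(collection) {
  stopifnot(inherits(collection, "dbd_collection"))
  parts <- character()
  for (d in names(collection$dbds)) {
    for (cl in collection$dbds[[d]]) {
      parts <- c(parts, d, cl$consensus$id,
                 paste(sprintf("%.12g", cl$consensus$matrix), collapse = ","))
    }
  }
  pars <- collection$parameters
  parts <- c(parts, sprintf("%.12g", pars$merge_threshold),
             sprintf("%.12g", pars$bin_width), sprintf("%.12g", pars$pseudo),
             paste(sprintf("%.12g", pars$background), collapse = ","))
  cpp_fnv1a(paste(parts, collapse = ";"))
}

COLLECTION_FORMAT <- "1"

#' Persist a DBD collection as a plain-text archive
#'
#' Writes a directory containing the member motifs and consensus motifs in
#' JASPAR format, a membership table, and a key=value metadata file. The
#' round trip through [load_collection()] is lossless to better than 1e-9.
#'
#' @param collection a `dbd_collection`
#' @param path directory to create (must not be an existing non-collection
#'   file)
#' @return `path`, invisibly
#' @export
save_collection <- function(collection, path) {
  stopifnot(inherits(collection, "dbd_collection"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_motifs(unname(collection$motifs), file.path(path, "motifs.jaspar"),
               format = "jaspar", digits = 17)
  cons <- unlist(lapply(collection$dbds, function(cls)
    lapply(cls, function(cl) cl$consensus)), recursive = FALSE)
  write_motifs(unname(cons), file.path(path, "consensus.jaspar"),
               format = "jaspar", digits = 17)
  rows <- c("#dbd\tcluster_id\tmotif_id")
  for (d in names(collection$dbds)) {
    for (cl in collection$dbds[[d]]) {
      rows <- c(rows, paste(d, cl$consensus$id, cl$members, sep = "\t"))
    }
  }
  writeLines(rows, file.path(path, "memberships.tsv"))
  pars <- collection$parameters
  meta <- c(paste0("format_version=", COLLECTION_FORMAT),
            paste0("provenance=", collection$provenance),
            paste0("merge_threshold=", sprintf("%.17g", pars$merge_threshold)),
            paste0("bin_width=", sprintf("%.17g", pars$bin_width)),
            paste0("pseudo=", sprintf("%.17g", pars$pseudo)),
            paste0("background=", paste(sprintf("%.17g", pars$background),
                                        collapse = ",")),
            paste0("skipped=", paste(collection$skipped, collapse = ",")),
            paste0("fingerprint=", collection_fingerprint(collection)))
  writeLines(meta, file.path(path, "meta.txt"))
  invisible(path)
}

read_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- lapply(kv, function(x) if (length(x) == 2) x[2] else "")
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

#' Load a DBD collection saved by [save_collection()]
#'
#' @param path directory written by [save_collection()]
#' @return a `dbd_collection`; errors (rather than returning a partial
#'   object) on a missing file, a format-version mismatch, or a fingerprint
#'   mismatch
#' @export
load_collection <- function(path) {
  files <- file.path(path, c("motifs.jaspar", "consensus.jaspar",
                             "memberships.tsv", "meta.txt"))
  if (!all(file.exists(files)))
    stop("not a collection archive (missing files): ", path)
  meta <- read_meta(files[4])
  if (!identical(meta$format_version, COLLECTION_FORMAT))
    stop("collection format version mismatch: found '", meta$format_version,
         "', expected '", COLLECTION_FORMAT, "'")
  res <- tryCatch({
    motifs <- read_motifs(files[1], "jaspar")
    names(motifs) <- vapply(motifs, function(p) p$id, character(1))
    cons <- read_motifs(files[2], "jaspar")
    names(cons) <- vapply(cons, function(p) p$id, character(1))
    mem <- utils::read.table(files[3], sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE,
                             quote = "")
    names(mem) <- c("dbd", "cluster_id", "motif_id")
    dbds <- list()
    for (d in unique(mem$dbd)) {
      sub <- mem[mem$dbd == d, , drop = FALSE]
      cls <- list()
      for (cid in unique(sub$cluster_id)) {
        members <- sub$motif_id[sub$cluster_id == cid]
        if (!cid %in% names(cons)) stop("consensus '", cid, "' missing")
        if (!all(members %in% names(motifs)))
          stop("member motif(s) missing for cluster ", cid)
        cp <- cons[[cid]]
        cp$dbd <- d
        cls[[length(cls) + 1L]] <- motif_cluster(members, cp)
      }
      dbds[[d]] <- cls
    }
    for (i in seq_along(motifs)) motifs[[i]]$dbd <-
      mem$dbd[match(names(motifs)[i], mem$motif_id)]
    bg <- as.numeric(strsplit(meta$background, ",")[[1]])
    skipped <- if (is.null(meta$skipped) || !nzchar(meta$skipped)) character()
               else strsplit(meta$skipped, ",")[[1]]
    structure(list(dbds = dbds, motifs = motifs,
                   parameters = list(
                     merge_threshold = as.numeric(meta$merge_threshold),
                     bin_width = as.numeric(meta$bin_width),
                     pseudo = as.numeric(meta$pseudo),
                     background = bg),
                   provenance = meta$provenance, skipped = skipped),
              class = "dbd_collection")
  }, error = function(e) {
    stop("corrupted collection archive at ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!identical(collection_fingerprint(res), meta$fingerprint))
    stop("corrupted collection archive at ", path,
         ": fingerprint mismatch")
  res
}
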
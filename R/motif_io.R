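#' Read motif matrices from a standard motif file
#'
#' Parses JASPAR text (">ID NAME" header plus four optionally letter-labelled,
#' optionally bracketed rows), TRANSFAC (`PO`/`P0` tables, records closed by
#' `//`) or minimal MEME motif files. Counts are normalized to column
#' frequencies; an optional pseudo-count is added to every cell before
#' normalization. A column summing to zero is a validation error.
#'
#' @param path file path
#' @param format one of `"jaspar"`, `"transfac"`, `"meme"`
#' @param pseudo_count non-negative count added to each cell before
#'   normalization (default 0)
#' @return list of [pfm()] objects (possibly empty)
#' @export
read_motifs <- function(path, format = c("jaspar", "transfac", "meme"),
                        pseudo_count = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  switch(format,
         jaspar = parse_jaspar(lines, path, pseudo_count),
         transfac = parse_transfac(lines, path, pseudo_count),
         meme = parse_meme(lines, path, pseudo_count))
}

finalize_motif <- function(mat, id, name, path, line, pseudo_count) {
  mat <- mat + pseudo_count
  if (any(colSums(mat) <= 0)) {
    stop("motif '", id, "' (", path, ", near line ", line,
         "): column sums to zero")
  }
  pfm(mat, id = id, name = name)
}

parse_jaspar <- function(lines, path, pseudo_count) {
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!startsWith(line, ">"))
      stop("parse error in ", path, " line ", i, ": expected '>' header")
    hdr <- strsplit(sub("^>", "", line), "[ \t]+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else NULL
    rows <- list()
    letters_seen <- character()
    j <- i + 1L
    while (j <= n && length(rows) < 4L) {
      rl <- trimws(lines[j])
      if (!nzchar(rl)) { j <- j + 1L; next }
      if (startsWith(rl, ">"))
        stop("parse error in ", path, " line ", j, ": motif '", id,
             "' has fewer than 4 rows")
      lab <- NA_character_
      if (grepl("^[ACGTacgt][ \t:\\[]", rl) || rl %in% c("A", "C", "G", "T")) {
        lab <- toupper(substr(rl, 1, 1))
        rl <- sub("^[ACGTacgt][ \t:]*", "", rl)
      }
      rl <- gsub("[][]", " ", rl)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(rl), "[ \t]+")[[1]]))
      if (length(vals) == 0 || anyNA(vals))
        stop("parse error in ", path, " line ", j, ": malformed matrix row")
      rows[[length(rows) + 1L]] <- vals
      letters_seen <- c(letters_seen, lab)
      j <- j + 1L
    }
    if (length(rows) < 4L)
      stop("parse error in ", path, ": motif '", id, "' has fewer than 4 rows")
    if (length(unique(lengths(rows))) != 1L)
      stop("parse error in ", path, " near line ", i, ": ragged matrix rows")
    mat <- do.call(rbind, rows)
    if (!anyNA(letters_seen)) {
      ord <- match(c("A", "C", "G", "T"), letters_seen)
      if (anyNA(ord))
        stop("parse error in ", path, " near line ", i, ": row labels must be A,C,G,T")
      mat <- mat[ord, , drop = FALSE]
    }
    out[[length(out) + 1L]] <- finalize_motif(mat, id, name, path, i, pseudo_count)
    i <- j
  }
  out
}

parse_transfac <- function(lines, path, pseudo_count) {
  out <- list()
  id <- NULL; name <- NULL; rows <- list(); in_matrix <- FALSE; start <- 1L
  flush <- function(line) {
    if (is.null(id) && length(rows) == 0) return(invisible())
    if (is.null(id)) stop("parse error in ", path, " line ", line,
                          ": matrix record without AC/ID")
    if (length(rows) == 0) stop("parse error in ", path, " line ", line,
                                ": record '", id, "' has no matrix rows")
    mat <- t(do.call(rbind, rows))
    out[[length(out) + 1L]] <<- finalize_motif(mat, id, name, path, line,
                                               pseudo_count)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    tag <- toupper(substr(line, 1, 2))
    rest <- trimws(substr(line, 3, nchar(line)))
    if (tag == "//") {
      flush(i); id <- NULL; name <- NULL; rows <- list(); in_matrix <- FALSE
    } else if (tag == "AC") {
      id <- rest; start <- i
    } else if (tag == "ID" || tag == "NA") {
      if (is.null(id)) { id <- rest; start <- i } else name <- rest
    } else if (tag %in% c("PO", "P0")) {
      hdr <- toupper(strsplit(rest, "[ \t]+")[[1]])
      if (!identical(hdr[1:4], c("A", "C", "G", "T")))
        stop("parse error in ", path, " line ", i,
             ": PO columns must be ordered A C G T")
      in_matrix <- TRUE
    } else if (in_matrix && grepl("^[0-9]+$", tag)) {
      vals <- suppressWarnings(as.numeric(strsplit(rest, "[ \t]+")[[1]][1:4]))
      if (anyNA(vals))
        stop("parse error in ", path, " line ", i, ": malformed matrix row")
      rows[[length(rows) + 1L]] <- vals
    } else if (tag == "XX") {
      in_matrix <- FALSE
    }
  }
  flush(length(lines))
  out
}

parse_meme <- function(lines, path, pseudo_count) {
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (grepl("^MOTIF\\b", line)) {
      hdr <- strsplit(line, "[ \t]+")[[1]]
      if (length(hdr) < 2)
        stop("parse error in ", path, " line ", i, ": MOTIF without identifier")
      id <- hdr[2]
      name <- if (length(hdr) > 2) paste(hdr[-(1:2)], collapse = " ") else NULL
      j <- i + 1L
      w <- NA_integer_
      while (j <= n) {
        ml <- trimws(lines[j])
        if (grepl("^letter-probability matrix", ml)) {
          wm <- regmatches(ml, regexec("w=\\s*([0-9]+)", ml))[[1]]
          if (length(wm) == 2) w <- as.integer(wm[2])
          j <- j + 1L
          break
        }
        if (grepl("^MOTIF\\b", ml))
          stop("parse error in ", path, " line ", j,
               ": MOTIF '", id, "' has no letter-probability matrix")
        j <- j + 1L
      }
      if (j > n) stop("parse error in ", path, ": MOTIF '", id,
                      "' has no letter-probability matrix")
      rows <- list()
      while (j <= n) {
        rl <- trimws(lines[j])
        if (!nzchar(rl) || grepl("^(MOTIF|URL)\\b", rl)) break
        vals <- suppressWarnings(as.numeric(strsplit(rl, "[ \t]+")[[1]]))
        if (length(vals) != 4 || anyNA(vals))
          stop("parse error in ", path, " line ", j, ": malformed matrix row")
        rows[[length(rows) + 1L]] <- vals
        j <- j + 1L
        if (!is.na(w) && length(rows) == w) break
      }
      if (!is.na(w) && length(rows) != w)
        stop("parse error in ", path, ": MOTIF '", id, "' declares w=", w,
             " but has ", length(rows), " rows")
      mat <- t(do.call(rbind, rows))
      out[[length(out) + 1L]] <- finalize_motif(mat, id, name, path, i,
                                                pseudo_count)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Write motifs to a standard motif file
#'
#' @param motifs list of [pfm()]
#' @param path output file
#' @param format one of `"jaspar"`, `"transfac"`, `"meme"`
#' @param digits significant digits for frequencies (default 10, enough for a
#'   1e-6 round trip)
#' @return `path`, invisibly
#' @export
write_motifs <- function(motifs, path, format = c("jaspar", "transfac", "meme"),
                         digits = 10) {
  format <- match.arg(format)
  if (is_pfm(motifs)) motifs <- list(motifs)
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  lines <- character()
  for (p in motifs) {
    stopifnot(is_pfm(p))
    m <- p$matrix
    if (format == "jaspar") {
      hdr <- paste0(">", p$id, if (!is.null(p$name)) paste0(" ", p$name) else "")
      lines <- c(lines, hdr, vapply(1:4, function(b) {
        paste0(c("A", "C", "G", "T")[b], " [ ",
               paste(fmt(m[b, ]), collapse = " "), " ]")
      }, character(1)))
    } else if (format == "transfac") {
      lines <- c(lines, paste("AC", p$id),
                 if (!is.null(p$name)) paste("ID", p$name),
                 "XX", "PO A C G T",
                 vapply(seq_len(ncol(m)), function(j) {
                   paste(sprintf("%02d", j), paste(fmt(m[, j]), collapse = " "))
                 }, character(1)),
                 "XX", "//")
    } else {
      lines <- c(lines,
                 paste0("MOTIF ", p$id,
                        if (!is.null(p$name)) paste0(" ", p$name) else ""),
                 sprintf("letter-probability matrix: alength= 4 w= %d", ncol(m)),
                 vapply(seq_len(ncol(m)), function(j) {
                   paste(fmt(m[, j]), collapse = " ")
                 }, character(1)),
                 "")
    }
  }
  if (format == "meme") {
    lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "", lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read ChIP-seq peaks from a BED file
#'
#' BED is 0-based half-open. The ENCODE `signalValue` is taken from column 7
#' when at least 7 columns are present (narrowPeak layout), otherwise from the
#' BED score in column 5; peaks with fewer than 5 columns get signal `NA`.
#' Peak strand is ignored downstream (ChIP-seq peaks are unstranded).
#'
#' @param path BED file path
#' @return data.frame with columns `chrom`, `start`, `end`, `signal`, `strand`
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "", fill = TRUE)
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns: ", path)
  start <- as.integer(bed[[2]])
  end <- as.integer(bed[[3]])
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("BED record ", bad, " has start >= end (", path, ")")
  }
  # signalValue: column 7 (narrowPeak) when present, else the BED score in
  # column 5; rows shorter than the widest row fall back per row
  signal <- rep(NA_real_, nrow(bed))
  if (ncol(bed) >= 5) signal <- suppressWarnings(as.numeric(bed[[5]]))
  if (ncol(bed) >= 7) {
    s7 <- suppressWarnings(as.numeric(bed[[7]]))
    signal <- ifelse(is.na(s7), signal, s7)
  }
  strand <- if (ncol(bed) >= 6) as.character(bed[[6]]) else rep("*", nrow(bed))
  data.frame(chrom = as.character(bed[[1]]), start = start, end = end,
             signal = signal, strand = strand, stringsAsFactors = FALSE)
}

#' Extract fixed-length peak-centered sequences from a genome
#'
#' For each peak the window of `length` bases centered on
#' `floor((start + end) / 2)` is extracted (the extra base goes to the right
#' for odd lengths) and clipped at chromosome bounds, with a warning when
#' clipping shortens a sequence. Sequence names carry the extracted window and
#' the peak signal as `chrom:start-end;signal=<value>`, so downstream tools
#' that rank sequences by ChIP signal can use it.
#'
#' @param peaks data.frame as returned by [read_bed_peaks()] (columns `chrom`,
#'   `start`, `end` and optionally `signal`)
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file
#' @param length window size in bases (>= 1)
#' @return a [Biostrings::DNAStringSet]
#' @export
extract_centered_sequences <- function(peaks, genome, length) {
  stopifnot(length >= 1)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  # FASTA headers often carry descriptions; match on the first word
  names(genome) <- vapply(strsplit(names(genome), "[ \t]"), `[[`, character(1), 1)
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing) > 0) {
    idx <- which(peaks$chrom %in% missing)[1]
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "),
         " (first offending record: ", peaks$chrom[idx], ":", peaks$start[idx],
         "-", peaks$end[idx], ")")
  }
  center <- floor((peaks$start + peaks$end) / 2)
  w_start <- center - floor(length / 2)
  w_end <- w_start + length
  chrlen <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  c_start <- pmax(w_start, 0L)
  c_end <- pmin(w_end, chrlen)
  clipped <- which(c_start != w_start | c_end != w_end)
  if (length(clipped) > 0) {
    warning(length(clipped), " window(s) clipped at chromosome bounds")
  }
  seqs <- Biostrings::subseq(genome[peaks$chrom], start = c_start + 1L,
                             end = c_end)
  signal <- if ("signal" %in% names(peaks)) peaks$signal else NA_real_
  names(seqs) <- sprintf("%s:%d-%d;signal=%s", peaks$chrom, c_start, c_end,
                         ifelse(is.na(signal), "NA", format(signal)))
  seqs
}
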
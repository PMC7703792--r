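test_that("JASPAR parsing normalizes counts and validates structure", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 TFA",
               "A [ 10  0 ]",
               "C [  0 10 ]",
               "G [  0  0 ]",
               "T [  0  0 ]",
               ">M2",
               "1 1 1 1",
               "1 1 1 1",
               "1 1 1 1",
               "1 1 1 1"), f)
  got <- read_motifs(f, "jaspar")
  expect_length(got, 2)
  expect_equal(got[[1]]$id, "M1")
  expect_equal(got[[1]]$name, "TFA")
  expect_equal(got[[1]]$matrix[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(got[[1]]$matrix[, 2], c(A = 0, C = 1, G = 0, T = 0))
  expect_equal(unname(colSums(got[[2]]$matrix)), rep(1, 4))

  # empty file -> empty list
  f2 <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(character(), f2)
  expect_length(read_motifs(f2, "jaspar"), 0)

  # malformed row names the line
  f3 <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M3", "A [ 1 2 ]", "C [ x 2 ]", "G [ 1 2 ]", "T [ 1 2 ]"), f3)
  expect_error(read_motifs(f3, "jaspar"), "line 3")

  # zero-sum column is a validation error, not silently fixed
  f4 <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M4", "A [ 1 0 ]", "C [ 1 0 ]", "G [ 1 0 ]", "T [ 1 0 ]"), f4)
  expect_error(read_motifs(f4, "jaspar"), "zero")
  # ... unless a pseudo-count makes it proper
  expect_length(read_motifs(f4, "jaspar", pseudo_count = 1), 1)
})

test_that("TRANSFAC and MEME dialects parse", {
  f <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("AC MX01", "XX", "ID someTF", "XX", "PO A C G T",
               "01 8 0 0 0", "02 0 8 0 0", "XX", "//"), f)
  got <- read_motifs(f, "transfac")
  expect_length(got, 1)
  expect_equal(got[[1]]$id, "MX01")
  expect_equal(unname(got[[1]]$matrix[1:2, 1:2]),
               matrix(c(1, 0, 0, 1), 2))

  f2 <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF MM1 tf1",
               "letter-probability matrix: alength= 4 w= 2 nsites= 20",
               " 0.5 0.5 0.0 0.0",
               " 0.0 0.0 0.5 0.5", ""), f2)
  got2 <- read_motifs(f2, "meme")
  expect_length(got2, 1)
  expect_equal(unname(got2[[1]]$matrix["A", 1]), 0.5)
  expect_equal(unname(got2[[1]]$matrix["T", 2]), 0.5)
})

test_that("write/read round trip preserves frequencies in every dialect", {
  set.seed(11)
  motifs <- lapply(1:4, function(i) rand_pfm(sample(3:9, 1), paste0("R", i)))
  for (fmt in c("jaspar", "transfac", "meme")) {
    f <- withr::local_tempfile()
    write_motifs(motifs, f, fmt)
    back <- read_motifs(f, fmt)
    expect_length(back, length(motifs))
    for (i in seq_along(motifs)) {
      expect_equal(back[[i]]$id, motifs[[i]]$id)
      expect_lt(max(abs(back[[i]]$matrix - motifs[[i]]$matrix)), 1e-6)
    }
  }
})

test_that("reverse complement is the strand involution", {
  expect_equal(unname(reverse_complement(det_pfm("A"))$matrix[, 1]),
               c(0, 0, 0, 1))
  p <- det_pfm(c("A", "C"))
  rc <- reverse_complement(p)
  expect_equal(unname(rc$matrix), unname(det_pfm(c("G", "T"))$matrix))
  set.seed(4)
  q <- rand_pfm(7)
  rr <- reverse_complement(reverse_complement(q))
  expect_equal(rr$matrix, q$matrix)
  expect_equal(rr$id, q$id)
  # column sums and information content are preserved (mirrored)
  expect_equal(unname(colSums(reverse_complement(q)$matrix)), rep(1, 7))
  expect_equal(column_entropy(reverse_complement(q)), rev(column_entropy(q)))
})

test_that("BED peaks expose signalValue from column 7, else column 5", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t1100\tpk1\t17\t.\t42.5\t-1\t-1\t500",
               "chr1\t0\t10\tpk2\t3"), f)
  peaks <- read_bed_peaks(f)
  expect_equal(peaks$signal, c(42.5, 3))
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t50\t40", f2)
  expect_error(read_bed_peaks(f2), "start >= end")
})

test_that("peak-centered extraction centers, clips, and labels sequences", {
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep("ACGT", 500), collapse = ""), # 2000 bp
    tiny = paste(rep("A", 50), collapse = "")))
  peaks <- data.frame(chrom = "chr1", start = 100, end = 1100, signal = 42.5)
  seqs <- extract_centered_sequences(peaks, genome, 500)
  # center floor((100+1100)/2) = 600 -> window [350, 850)
  expect_equal(names(seqs), "chr1:350-850;signal=42.5")
  expect_equal(unname(Biostrings::width(seqs)), 500)
  expect_equal(as.character(seqs[[1]]),
               as.character(Biostrings::subseq(genome$chr1, 351, 850)))

  clip <- data.frame(chrom = "tiny", start = 0, end = 10, signal = 1)
  expect_warning(s2 <- extract_centered_sequences(clip, genome, 100),
                 "clipped")
  expect_equal(unname(Biostrings::width(s2)), 50)
  expect_equal(names(s2), "tiny:0-50;signal=1")

  bad <- data.frame(chrom = "chrX", start = 5, end = 10, signal = 1)
  expect_error(extract_centered_sequences(bad, genome, 10), "chrX")
})
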
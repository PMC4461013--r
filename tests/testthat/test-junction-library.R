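# Brute-force oracle: all exon pairs (i, j) in transcript order, classified
# by adjacency. Independent of the per-transcript enumeration code path.
oracle_pairs <- function(k) {
  pairs <- expand.grid(i = seq_len(k), j = seq_len(k))
  pairs <- pairs[pairs$j > pairs$i, ]
  list(known = sum(pairs$j == pairs$i + 1L),
       novel = sum(pairs$j >= pairs$i + 2L),
       single_skip = sum(pairs$j == pairs$i + 2L))
}

test_that("junction combinatorics match the exhaustive pair oracle", {
  withr::local_seed(11)
  for (k in 2:12) {
    exon_len <- sample(30:200, k, replace = TRUE)
    strand <- sample(c("+", "-"), 1L)
    ann <- make_transcript_ann(k, exon_len = exon_len, strand = strand)
    oracle <- oracle_pairs(k)
    known <- known_junctions(ann)
    novel <- novel_junctions(ann)
    expect_equal(nrow(known), k - 1L)
    expect_equal(nrow(known), oracle$known)
    expect_equal(nrow(novel), (k - 1L) * (k - 2L) / 2L)
    expect_equal(nrow(novel), oracle$novel)
    expect_equal(sum(novel$n_skipped == 1L), max(0L, k - 2L))
    expect_equal(sum(novel$n_skipped == 1L), oracle$single_skip)
    # total = k(k-1)/2, and every junction key unique within a transcript
    expect_equal(nrow(known) + nrow(novel), k * (k - 1L) / 2L)
    keys <- paste(c(known$donor, novel$donor), c(known$acceptor,
                                                 novel$acceptor))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("flanks truncate at short exons and sequences match the genome", {
  genome <- make_toy_genome()
  ann <- make_transcript_ann(3, exon_len = c(100L, 80L, 30L))
  lib <- build_junction_library(ann, genome, L = 50L)
  ord <- ann[order(ann$rank), ]

  # known junction exon2 -> exon3: up flank 50 of 80, down flank all 30
  rec <- lib[lib$category == "known" & lib$donor == ord$end[2L] - 1L, ]
  expect_equal(rec$up_len, 50L)
  expect_equal(rec$down_len, 30L)
  expect_equal(nchar(rec$sequence), rec$up_len + rec$down_len)
  expect_equal(nchar(rec$sequence), 80L)

  # base-by-base: sequence is the spliced concatenation of the two flanks
  chr <- as.character(genome[["chr1"]])
  for (i in seq_len(nrow(lib))) {
    up <- substr(chr, lib$donor[i] + 1L - lib$up_len[i] + 1L,
                 lib$donor[i] + 1L)
    dn <- substr(chr, lib$acceptor[i] + 1L,
                 lib$acceptor[i] + lib$down_len[i])
    expect_equal(lib$sequence[i], paste0(up, dn))
  }
})

test_that("minus-strand records carry reverse-complemented sense sequence", {
  genome <- make_toy_genome()
  ann <- make_transcript_ann(2, exon_len = c(60L, 40L), strand = "-")
  lib <- build_junction_library(ann, genome, L = 50L)
  chr <- as.character(genome[["chr1"]])
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # upstream flank: first up_len genomic bases of the right (5'-most) exon
  up <- substr(chr, lib$donor + 1L, lib$donor + lib$up_len)
  dn <- substr(chr, lib$acceptor + 1L - lib$down_len + 1L, lib$acceptor + 1L)
  expect_equal(lib$sequence, paste0(rc(up), rc(dn)))
})

test_that("shared junctions deduplicate and known beats novel", {
  genome <- make_toy_genome()
  # T1: exons A,B,C ; T2: exons A,C (the A->C junction is a skip in T1 but
  # adjacent in T2); both transcripts share the A exon
  starts <- c(1000L, 1200L, 1400L)
  ends <- starts + 100L
  ann <- make_annotation(
    transcript_id = c("T1", "T1", "T1", "T2", "T2"),
    gene_id = rep("G1", 5L), chrom = rep("chr1", 5L),
    strand = rep("+", 5L),
    start = c(starts, starts[c(1L, 3L)]),
    end = c(ends, ends[c(1L, 3L)]))
  lib <- build_junction_library(ann, genome, L = 50L)
  ac <- lib[lib$donor == ends[1L] - 1L & lib$acceptor == starts[3L], ]
  expect_equal(nrow(ac), 1L)
  expect_equal(ac$category, "known")
  expect_equal(ac$n_skipped, 0L)
  expect_setequal(ac$source_transcripts[[1L]], c("T1", "T2"))
  # A->B junction is unique to T1
  ab <- lib[lib$acceptor == starts[2L], ]
  expect_equal(ab$source_transcripts[[1L]], "T1")
  # known and novel key sets are disjoint
  keys <- paste(lib$donor, lib$acceptor)
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("truncating an L=150 library to 50 bp flanks equals the L=50 build", {
  genome <- make_toy_genome()
  withr::local_seed(21)
  ann <- make_transcript_ann(6, exon_len = sample(30:200, 6), strand = "-")
  lib150 <- build_junction_library(ann, genome, L = 150L)
  lib50 <- build_junction_library(ann, genome, L = 50L)
  # truncate: keep the last 50 sense bases of the up flank, first 50 of down
  trunc <- lib150 |>
    dplyr::mutate(
      new_up = pmin(up_len, 50L), new_down = pmin(down_len, 50L),
      sequence = paste0(
        substr(sequence, up_len - new_up + 1L, up_len),
        substr(sequence, up_len + 1L, up_len + new_down)),
      up_len = new_up, down_len = new_down) |>
    dplyr::select(-new_up, -new_down)
  key <- function(x) x[order(x$donor, x$acceptor),
                       c("donor", "acceptor", "up_len", "down_len",
                         "sequence")]
  expect_equal(as.data.frame(key(trunc)), as.data.frame(key(lib50)),
               ignore_attr = TRUE)
})

test_that("library FASTA round trip reconstructs every header field", {
  genome <- make_toy_genome()
  ann <- make_transcript_ann(4, exon_len = c(100L, 30L, 120L, 45L))
  lib <- build_junction_library(ann, genome, L = 50L)
  path <- tempfile(fileext = ".fa")
  write_junction_fasta(lib, path)
  back <- read_junction_fasta(path)
  cols <- c("junction_id", "chrom", "strand", "donor", "acceptor",
            "category", "n_skipped", "up_len", "down_len", "sequence")
  expect_equal(as.data.frame(back[, cols]), as.data.frame(lib[, cols]),
               ignore_attr = TRUE)
  expect_equal(nchar(back$sequence), back$up_len + back$down_len)
})

test_that("unsupported boundary length and missing chromosome error", {
  genome <- make_toy_genome()
  ann <- make_transcript_ann(3)
  expect_error(build_junction_library(ann, genome, L = 60L),
               class = "spliceops_input_error")
  ann2 <- make_transcript_ann(3, chrom = "chrMissing")
  expect_error(build_junction_library(ann2, genome, L = 50L),
               class = "spliceops_sequence_error")
})
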
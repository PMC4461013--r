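toy_reads <- function(seqs, ids = paste0("r", seq_along(seqs))) {
  tibble::tibble(read_id = ids, seq = seqs,
                 qual = strrep("I", nchar(seqs)))
}

test_that("tag extraction follows the terminal-A-run rule exactly", {
  reads <- toy_reads(c(
    "ACGTACGTACAAAAAAAA",    # tail 8, trimmed 10 -> tag
    "ACGTACGTACGT",          # no terminal run >= 6 -> not a tag
    "AAAAAAAAAAAA",          # all A: trimmed length 0 -> rejected
    "CCGGTTACGTACGTAAAAA"))  # tail 5 < 6 -> not a tag
  tags <- extract_polya_tags(reads, min_tail = 6L, min_trimmed = 10L)
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$tail_len, 8L)
  expect_equal(tags$seq, "ACGTACGTAC")
  expect_equal(nchar(tags$qual), 10L)
  g <- glance(tags)
  expect_equal(g$tags + g$rejected_no_tail + g$rejected_short_prefix,
               g$input_reads)
  expect_equal(g$rejected_no_tail, 2L)    # run of 0 and run of 5
  expect_equal(g$rejected_short_prefix, 1L)
})

test_that("trimmed sequence plus its tail reconstructs every original read", {
  withr::local_seed(5)
  seqs <- vapply(1:50, function(i) {
    body <- paste0(sample(c("A", "C", "G", "T"), sample(10:40, 1L),
                          replace = TRUE), collapse = "")
    paste0(body, strrep("A", sample(0:12, 1L)))
  }, character(1))
  reads <- toy_reads(seqs)
  tags <- extract_polya_tags(reads, min_tail = 6L, min_trimmed = 10L)
  expect_true(nrow(tags) > 0L)
  expect_equal(paste0(tags$seq, strrep("A", tags$tail_len)),
               reads$seq[match(tags$read_id, reads$read_id)])
})

test_that("FASTQ round trip and malformed records", {
  reads <- toy_reads(c("ACGTACGTAC", "GGGCCCATAT"))
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  tags_in <- extract_polya_tags(path, min_tail = 1L, min_trimmed = 1L)
  expect_equal(glance(tags_in)$input_reads, 2L)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
  expect_error(extract_polya_tags(bad), class = "spliceops_format_error")
})

test_that("site calling clusters to the modal position with 3' tie-break", {
  # 3 tags ending at 1000, 1001, 1000 (+): one site at the mode, 1000
  aln <- dplyr::bind_rows(
    make_aln("t1", "chr1", 981L, "20M"),   # end - 1 = 1000
    make_aln("t2", "chr1", 982L, "20M"),   # 1001
    make_aln("t3", "chr1", 981L, "20M"))
  sites <- call_polya_sites(aln, cluster_window = 5L)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$cleavage_pos, 1000L)
  expect_equal(sites$n_tags, 3L)

  # beyond the window: two sites
  far <- dplyr::bind_rows(make_aln("a", "chr1", 981L, "20M"),
                          make_aln("b", "chr1", 1031L, "20M"))
  expect_equal(nrow(call_polya_sites(far, cluster_window = 5L)), 2L)

  # tie: equal multiplicity resolves to the 3'-most position (+ strand)
  tie <- dplyr::bind_rows(make_aln("a", "chr1", 981L, "20M"),
                          make_aln("b", "chr1", 983L, "20M"))
  expect_equal(call_polya_sites(tie, cluster_window = 5L)$cleavage_pos, 1002L)

  # minus strand: 3'-most aligned base is the leftmost
  minus <- make_aln("m", "chr1", 200L, "50M", flag = 16L)
  sm <- call_polya_sites(minus)
  expect_equal(sm$strand, "-")
  expect_equal(sm$cleavage_pos, 200L)

  # sum of n_tags equals the number of aligned tags
  all_aln <- dplyr::bind_rows(aln, far, tie, minus,
                              make_aln("u", "*", 0L, "*", flag = 4L))
  expect_equal(sum(call_polya_sites(all_aln)$n_tags), 8L)

  # unmapped-only input gives an empty result, not an error
  expect_equal(nrow(call_polya_sites(make_aln("u", "*", 0L, "*", flag = 4L))),
               0L)
})

test_that("PAS search honors rank order over proximity", {
  tab <- pas_table()
  # cleavage at local 100 (0-based); window 40 upstream = [60,100)
  base <- strrep("C", 200L)
  plant <- function(seq, hex, genomic_start) {
    substr(seq, genomic_start + 1L, genomic_start + 6L) <- hex
    seq
  }
  # ATTAAA at offset -12 (closer) and AATAAA at -30: canonical must win
  s <- plant(plant(base, "ATTAAA", 100L - 12L), "AATAAA", 100L - 30L)
  genome <- Biostrings::DNAStringSet(s); names(genome) <- "chr1"
  sites <- tibble::tibble(chrom = "chr1", strand = "+",
                          cleavage_pos = 100L, n_tags = 1L)
  ann <- annotate_pas(sites, genome, search_window = 40L, table = tab)
  expect_equal(ann$pas_hexamer, "AATAAA")
  expect_equal(ann$pas_offset, 30L)

  # single canonical hit at -16
  s2 <- plant(base, "AATAAA", 100L - 16L)
  genome2 <- Biostrings::DNAStringSet(s2); names(genome2) <- "chr1"
  ann2 <- annotate_pas(sites, genome2, search_window = 40L, table = tab)
  expect_equal(ann2$pas_hexamer, "AATAAA")
  expect_equal(ann2$pas_offset, 16L)

  # duplicate canonical: the cleavage-proximal occurrence is reported
  s3 <- plant(plant(base, "AATAAA", 100L - 35L), "AATAAA", 100L - 14L)
  genome3 <- Biostrings::DNAStringSet(s3); names(genome3) <- "chr1"
  ann3 <- annotate_pas(sites, genome3, search_window = 40L, table = tab)
  expect_equal(ann3$pas_offset, 14L)

  # no hexamer at all
  genome4 <- Biostrings::DNAStringSet(base); names(genome4) <- "chr1"
  ann4 <- annotate_pas(sites, genome4, search_window = 40L, table = tab)
  expect_true(is.na(ann4$pas_hexamer))
  expect_true(is.na(ann4$pas_offset))
})

test_that("minus-strand PAS search reads the transcribed strand", {
  # cleavage at 100 on -, hexamer start 20 bases upstream (transcribed):
  # genome carries the reverse complement at [114,120)
  base <- strrep("C", 200L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("AATAAA")))
  substr(base, 100L + 20L - 5L + 1L, 100L + 20L + 1L) <- rc
  genome <- Biostrings::DNAStringSet(base); names(genome) <- "chr1"
  sites <- tibble::tibble(chrom = "chr1", strand = "-",
                          cleavage_pos = 100L, n_tags = 1L)
  ann <- annotate_pas(sites, genome, search_window = 40L)
  expect_equal(ann$pas_hexamer, "AATAAA")
  expect_equal(ann$pas_offset, 20L)
})

test_that("window truncation at the chromosome edge warns and A-rich flags", {
  genome <- Biostrings::DNAStringSet(paste0(strrep("C", 20L),
                                            strrep("A", 20L)))
  names(genome) <- "chr1"
  sites <- tibble::tibble(chrom = "chr1", strand = "+",
                          cleavage_pos = 25L, n_tags = 1L)
  expect_warning(ann <- annotate_pas(sites, genome, search_window = 40L),
                 "truncated")
  expect_true(is.na(ann$pas_hexamer))
  # downstream bases [26,36) are all A -> flagged A-rich
  expect_true(ann$a_rich)
})

test_that("the default PAS table is canonical + 10 variants, unique hexamers", {
  tab <- pas_table()
  expect_equal(nrow(tab), 11L)
  expect_equal(tab$hexamer[1L], "AATAAA")
  expect_equal(tab$rank, 1:11)
  expect_true(all(nchar(tab$hexamer) == 6L))
  expect_equal(anyDuplicated(tab$hexamer), 0L)
})

test_that("pas_frequency_table keeps rank order with canonical first", {
  sites <- tibble::tibble(
    chrom = "chr1", strand = "+", cleavage_pos = c(1L, 2L, 3L),
    n_tags = 1L, pas_hexamer = c("ATTAAA", "AATAAA", NA), pas_offset = 20L,
    a_rich = FALSE)
  freq <- pas_frequency_table(sites)
  expect_equal(freq$rank, 1:11)
  expect_equal(freq$hexamer[1L], "AATAAA")
  expect_equal(freq$n_sites[freq$hexamer == "AATAAA"], 1L)
  expect_equal(sum(freq$n_sites), 2L)
  expect_equal(sum(freq$frequency), 1)
})
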
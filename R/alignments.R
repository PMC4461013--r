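#' Read alignments from SAM or BAM into a tibble
#'
#' SAM text files are parsed directly; BAM files are read through Rsamtools
#' when available. Positions are converted to the package's 0-based half-open
#' convention: `pos` is the 0-based leftmost aligned reference position and
#' `end` the exclusive end of the aligned reference span (from the CIGAR).
#'
#' @param path SAM or BAM file path.
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, and derived logicals `unmapped`, `secondary`, `reverse`,
#'   plus `end`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) {
    stop_spliceops(paste0("alignment file not found: ", path),
                   "spliceops_input_error")
  }
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop_spliceops("Rsamtools is required to read BAM input",
                     "spliceops_input_error")
    }
    b <- Rsamtools::scanBam(path)[[1L]]
    aln <- tibble(
      qname = b$qname, flag = as.integer(b$flag),
      rname = as.character(b$rname), pos = as.integer(b$pos) - 1L,
      mapq = as.integer(b$mapq), cigar = as.character(b$cigar),
      seq = as.character(b$seq)
    )
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[!grepl("^@", lines) & nzchar(lines)]
    f <- stringr::str_split_fixed(lines, "\t", 12L)
    if (length(lines) && ncol(f) < 11L) {
      stop_spliceops("SAM records must have >= 11 tab-separated fields",
                     "spliceops_format_error")
    }
    aln <- tibble(
      qname = f[, 1L], flag = as.integer(f[, 2L]), rname = f[, 3L],
      pos = as.integer(f[, 4L]) - 1L, mapq = as.integer(f[, 5L]),
      cigar = f[, 6L], seq = f[, 10L]
    )
  }
  aln |>
    mutate(
      unmapped = bitwAnd(.data$flag, 4L) > 0L,
      secondary = bitwAnd(.data$flag, 256L) > 0L |
        bitwAnd(.data$flag, 2048L) > 0L,
      reverse = bitwAnd(.data$flag, 16L) > 0L,
      end = .data$pos + cigar_ref_width(.data$cigar, .data$unmapped)
    )
}

# Reference-space width consumed by a CIGAR (0 for unmapped records).
cigar_ref_width <- function(cigar, unmapped) {
  w <- integer(length(cigar))
  ok <- !unmapped & !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    w[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  }
  w
}

# Aligned reference blocks (M/=/X runs; D splits nothing, N splits) for one
# alignment, as a 0-based half-open start/end matrix. `split_indels` also
# splits at D and I so the fusion-point crossing test can see indels.
alignment_blocks <- function(pos, cigar, drop_d = FALSE) {
  ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, ops = if (drop_d) c("M", "=", "X") else c("M", "=", "X", "D"),
    reduce.ranges = TRUE)[[1L]]
  cbind(start = pos + IRanges::start(ir) - 1L,
        end = pos + IRanges::end(ir))
}

#' Write alignments as SAM text
#'
#' Minimal SAM writer used by the simulator: emits an @SQ header for every
#' reference and one 11-field record per row.
#'
#' @param aln Tibble with `qname`, `flag`, `rname`, `pos` (0-based), `mapq`,
#'   `cigar`, `seq`; optional `qual`.
#' @param refs Named integer vector of reference lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
  qual <- if ("qual" %in% names(aln)) aln$qual
          else strrep("I", nchar(aln$seq))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 aln$qname, aln$flag, aln$rname, aln$pos + 1L, aln$mapq,
                 aln$cigar, aln$seq, qual)
  rec[aln$rname == "*"] <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                                   aln$qname[aln$rname == "*"],
                                   aln$seq[aln$rname == "*"],
                                   qual[aln$rname == "*"])
  readr::write_lines(c(hdr, rec), path)
  invisible(path)
}
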
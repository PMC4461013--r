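#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_spliceops <- function(msg, class) {
  rlang::abort(msg, class = c(class, "spliceops_error"))
}

#' Load a genome as a DNAStringSet
#'
#' Accepts either a `Biostrings::DNAStringSet` (returned unchanged) or a path
#' to a FASTA file. Sequence names are truncated at the first whitespace, as
#' alignment tools do.
#'
#' @param genome A `DNAStringSet` or a FASTA file path.
#' @return A named `DNAStringSet`.
#' @export
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (!is.character(genome) || length(genome) != 1L) {
    stop_spliceops("`genome` must be a DNAStringSet or a FASTA path",
                   "spliceops_input_error")
  }
  if (!file.exists(genome)) {
    stop_spliceops(paste0("genome FASTA not found: ", genome),
                   "spliceops_input_error")
  }
  seqs <- Biostrings::readDNAStringSet(genome)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

# Fetch genome substring [start, end) (0-based half-open), optionally
# reverse-complemented. Errors if chrom missing or coordinates out of bounds.
genome_seq <- function(genome, chrom, start, end, revcomp = FALSE) {
  if (!chrom %in% names(genome)) {
    stop_spliceops(paste0("chromosome not in sequence source: ", chrom),
                   "spliceops_sequence_error")
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end) {
    stop_spliceops(
      sprintf("interval [%d,%d) out of bounds for %s (length %d)",
              start, end, chrom, len),
      "spliceops_consistency_error")
  }
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (revcomp) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
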
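#' Enumerate novel (exon-skipping) splice junctions
#'
#' By selectively skipping one or more sequential inner exons of each
#' transcript, every exon pair (i, j) with j >= i + 2 in transcript order
#' defines a candidate novel junction. A transcript with k exons therefore
#' yields (k-1)(k-2)/2 novel junctions, of which the single-skip subset
#' (j = i + 2) has size k - 2. Enumeration is strictly per transcript: exons
#' of different isoforms are never mixed.
#'
#' @param ann Annotation tibble from [read_gtf()].
#' @return A tibble with the same columns as [known_junctions()];
#'   `n_skipped` >= 1 counts the skipped inner exons and `category` is
#'   `"novel"`.
#' @export
novel_junctions <- function(ann) {
  exon_pair_junctions(ann, gap = 2L) |>
    mutate(category = "novel")
}

#' Build a splice-junction library with flanking sequences
#'
#' Generates known (adjacent) and novel (exon-skipping) junctions for every
#' transcript, extracts up to `L` exonic bases on each side of every junction
#' — the 3' end of the upstream exon and the 5' start of the downstream exon,
#' spliced together — and deduplicates by genomic identity
#' (chrom, strand, donor, acceptor). When a flanking exon is shorter than
#' `L`, a truncated flank of the full exon is extracted, and the per-record
#' flank lengths `up_len`/`down_len` retain the information needed to locate
#' the fusion point. A junction that is adjacent in any transcript is
#' categorised `known` even if it also arises as a skip elsewhere. Sequences
#' are in transcript (sense) orientation; minus-strand records are
#' reverse-complemented.
#'
#' @param ann Annotation tibble from [read_gtf()].
#' @param genome A `DNAStringSet` or FASTA path covering every chromosome
#'   referenced by `ann`.
#' @param L Boundary length in bp; must be one of `boundaries`.
#' @param boundaries Supported boundary lengths (default 50/75/100/150 bp).
#' @return A tibble of class `spliceops_junction_library` with one row per
#'   unique junction: `junction_id`, `chrom`, `strand`, `donor`, `acceptor`,
#'   `category`, `n_skipped`, `up_len`, `down_len`, `sequence`, and a
#'   list-column `source_transcripts`. Attribute `L` records the boundary.
#' @export
build_junction_library <- function(ann, genome, L = 75L,
                                   boundaries = c(50L, 75L, 100L, 150L)) {
  if (!L %in% boundaries) {
    stop_spliceops(
      sprintf("boundary length L=%d not in supported set {%s}",
              L, paste(boundaries, collapse = ", ")),
      "spliceops_input_error")
  }
  genome <- load_genome(genome)
  jx <- bind_rows(known_junctions(ann), novel_junctions(ann))
  if (!nrow(jx)) {
    stop_spliceops("annotation yields no junctions", "spliceops_input_error")
  }
  lib <- jx |>
    mutate(
      up_exon_len = .data$up_end - .data$up_start,
      down_exon_len = .data$down_end - .data$down_start,
      up_len = pmin(L, .data$up_exon_len),
      down_len = pmin(L, .data$down_exon_len)
    ) |>
    group_by(.data$chrom, .data$strand, .data$donor, .data$acceptor) |>
    summarise(
      # adjacency in any transcript wins over a skip in another
      category = if (any(.data$category == "known")) "known" else "novel",
      n_skipped = if (any(.data$category == "known")) 0L
                  else min(.data$n_skipped),
      up_len = max(.data$up_len),
      down_len = max(.data$down_len),
      source_transcripts = list(sort(unique(.data$transcript_id))),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$donor, .data$acceptor, .data$strand)
  fl <- junction_flanks(lib)
  lib$sequence <- vapply(seq_len(nrow(lib)), function(i) {
    minus <- lib$strand[i] == "-"
    up <- genome_seq(genome, lib$chrom[i], fl$up_start[i], fl$up_end[i],
                     revcomp = minus)
    dn <- genome_seq(genome, lib$chrom[i], fl$down_start[i], fl$down_end[i],
                     revcomp = minus)
    paste0(up, dn)
  }, character(1))
  lib <- lib |>
    mutate(junction_id = sprintf("JX%06d", dplyr::row_number())) |>
    select("junction_id", "chrom", "strand", "donor", "acceptor", "category",
           "n_skipped", "up_len", "down_len", "sequence",
           "source_transcripts")
  attr(lib, "L") <- as.integer(L)
  class(lib) <- c("spliceops_junction_library", class(lib))
  lib
}

# Genomic intervals (0-based half-open) of the two flanks of each record,
# derivable from donor/acceptor + flank lengths + strand.
junction_flanks <- function(lib) {
  plus <- lib$strand == "+"
  tibble(
    up_start = ifelse(plus, lib$donor + 1L - lib$up_len, lib$donor),
    up_end = ifelse(plus, lib$donor + 1L, lib$donor + lib$up_len),
    down_start = ifelse(plus, lib$acceptor, lib$acceptor + 1L - lib$down_len),
    down_end = ifelse(plus, lib$acceptor + lib$down_len, lib$acceptor + 1L)
  )
}

#' Write a junction library to FASTA
#'
#' One entry per record; the header encodes
#' `junction_id|chrom|strand|donor|acceptor|up_len|down_len|category|n_skipped`
#' so that [read_junction_fasta()] reconstructs every field.
#'
#' @param lib Junction library from [build_junction_library()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(lib, path) {
  if (!nrow(lib)) {
    stop_spliceops("junction library is empty", "spliceops_input_error")
  }
  headers <- sprintf("%s|%s|%s|%d|%d|%d|%d|%s|%d",
                     lib$junction_id, lib$chrom, lib$strand, lib$donor,
                     lib$acceptor, lib$up_len, lib$down_len, lib$category,
                     lib$n_skipped)
  seqs <- Biostrings::DNAStringSet(lib$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a junction library FASTA written by [write_junction_fasta()]
#'
#' @param path FASTA path.
#' @return A `spliceops_junction_library` tibble (without
#'   `source_transcripts`, which the FASTA does not carry).
#' @export
read_junction_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  f <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 9L)
  lib <- tibble(
    junction_id = f[, 1L], chrom = f[, 2L], strand = f[, 3L],
    donor = as.integer(f[, 4L]), acceptor = as.integer(f[, 5L]),
    up_len = as.integer(f[, 6L]), down_len = as.integer(f[, 7L]),
    category = f[, 8L], n_skipped = as.integer(f[, 9L]),
    sequence = unname(as.character(seqs))
  )
  class(lib) <- c("spliceops_junction_library", class(lib))
  lib
}

#' Tabular manifest of a junction library
#'
#' @param lib Junction library.
#' @return A tibble (key, category, n_skipped, up_len, down_len,
#'   n_source_transcripts) suitable for TSV export.
#' @export
junction_manifest <- function(lib) {
  lib |>
    mutate(
      key = paste(.data$chrom, .data$strand, .data$donor, .data$acceptor,
                  sep = ":"),
      n_source_transcripts = if ("source_transcripts" %in% names(lib))
        lengths(.data$source_transcripts) else NA_integer_
    ) |>
    select("junction_id", "key", "category", "n_skipped", "up_len",
           "down_len", "n_source_transcripts") |>
    as_tibble()
}

#' Write junctions as a BED12-style track
#'
#' One line per junction with two blocks, one per flank, for genome-browser
#' inspection. Coordinates are 0-based half-open as BED requires.
#'
#' @param lib Junction library.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(lib, path) {
  fl <- junction_flanks(lib)
  chrom_start <- pmin(fl$up_start, fl$down_start)
  chrom_end <- pmax(fl$up_end, fl$down_end)
  left_first <- fl$up_start <= fl$down_start
  b1s <- ifelse(left_first, fl$up_start, fl$down_start)
  b1e <- ifelse(left_first, fl$up_end, fl$down_end)
  b2s <- ifelse(left_first, fl$down_start, fl$up_start)
  b2e <- ifelse(left_first, fl$down_end, fl$up_end)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t2\t%d,%d\t%d,%d",
                   lib$chrom, chrom_start, chrom_end, lib$junction_id,
                   lib$strand, chrom_start, chrom_end,
                   b1e - b1s, b2e - b2s, 0L, b2s - chrom_start)
  readr::write_lines(lines, path)
  invisible(path)
}
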
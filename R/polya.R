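#' Default polyadenylation-signal (PAS) hexamer table
#'
#' The canonical signal AATAAA plus ten variants, ordered by published human
#' frequency (most common first). During annotation the table is searched in
#' rank order, so the canonical signal always beats a variant regardless of
#' proximity to the cleavage site. Supplied as a packaged TSV
#' (`extdata/pas_hexamers.tsv`); users may pass their own table anywhere a
#' `pas_table` argument appears.
#'
#' @param path Optional TSV with columns `hexamer` and `rank`.
#' @return A tibble with columns `hexamer` (read-strand DNA alphabet) and
#'   `rank` (1 = canonical).
#' @export
pas_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pas_hexamers.tsv",
                                package = "spliceops")
  tab <- readr::read_tsv(path, col_types = "ci") |> arrange(.data$rank)
  if (any(nchar(tab$hexamer) != 6L) || anyDuplicated(tab$hexamer) ||
      tab$hexamer[1L] != "AATAAA") {
    stop_spliceops(
      "PAS table must hold unique hexamers with canonical AATAAA at rank 1",
      "spliceops_input_error")
  }
  tab
}

#' Extract poly(A) tags from a FASTQ stream
#'
#' A read qualifies as a poly(A) tag when its maximal uninterrupted terminal
#' run of A has length >= `min_tail` and the remaining prefix is at least
#' `min_trimmed` bases. Qualifying reads are emitted with the run removed and
#' quality strings truncated in lockstep; appending `A` x `tail_len` to the
#' trimmed sequence reconstructs the original read exactly.
#'
#' @param fastq Path to a FASTQ file, or a tibble with columns `read_id`,
#'   `seq`, `qual`.
#' @param min_tail Minimum terminal A-run length (default 6).
#' @param min_trimmed Minimum trimmed-read length (default 15).
#' @return A tibble of class `spliceops_polya_tags`: `read_id`, `seq`
#'   (trimmed), `qual` (trimmed), `tail_len`. `glance()` reports the
#'   conservation tallies (input reads, tags, rejected by reason).
#' @export
extract_polya_tags <- function(fastq, min_tail = 6L, min_trimmed = 15L) {
  if (min_tail < 1L || min_trimmed < 1L) {
    stop_spliceops("min_tail and min_trimmed must be >= 1",
                   "spliceops_input_error")
  }
  reads <- if (is.character(fastq)) read_fastq(fastq) else as_tibble(fastq)
  tail_len <- nchar(stringr::str_extract(reads$seq, "A*$"))
  trimmed_len <- nchar(reads$seq) - tail_len
  ok_tail <- tail_len >= min_tail
  ok_prefix <- trimmed_len >= min_trimmed
  tags <- reads[ok_tail & ok_prefix, ] |>
    mutate(tail_len = tail_len[ok_tail & ok_prefix],
           seq = substr(.data$seq, 1L, nchar(.data$seq) - .data$tail_len),
           qual = substr(.data$qual, 1L, nchar(.data$seq)))
  attr(tags, "tallies") <- list(
    input_reads = nrow(reads), tags = nrow(tags),
    rejected_no_tail = sum(!ok_tail),
    rejected_short_prefix = sum(ok_tail & !ok_prefix))
  class(tags) <- c("spliceops_polya_tags", class(tags))
  tags
}

#' @exportS3Method generics::glance
glance.spliceops_polya_tags <- function(x, ...) {
  as_tibble(attr(x, "tallies"))
}

read_fastq <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) %% 4L != 0L) {
    stop_spliceops(
      sprintf("malformed FASTQ: %d lines is not a multiple of 4",
              length(lines)),
      "spliceops_format_error")
  }
  n <- length(lines) / 4L
  ids <- lines[seq(1L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop_spliceops(sprintf("malformed FASTQ record %d", bad[1L]),
                   "spliceops_format_error")
  }
  tibble(read_id = sub("\\s.*$", "", sub("^@", "", ids)),
         seq = lines[seq(2L, by = 4L, length.out = n)],
         qual = lines[seq(4L, by = 4L, length.out = n)])
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  readr::write_lines(
    as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)),
    path)
  invisible(path)
}

#' Call polyadenylation sites from aligned poly(A) tags
#'
#' The cleavage position of a tag is the genomic position of its 3'-most
#' aligned base (the rightmost base on `+`, the leftmost on `-`). Cleavage
#' positions on the same chromosome and strand are clustered by
#' single-linkage within `cluster_window` bp; each cluster becomes one site at
#' its modal cleavage position (ties resolved toward the 3' direction), with
#' `n_tags` the cluster size.
#'
#' @param tag_alignments Alignment tibble from [read_alignments()] (or a
#'   SAM/BAM path) of trimmed tags against the genome.
#' @param cluster_window Merge radius in bp (default 10).
#' @return A tibble of class `spliceops_polya_sites`: `chrom`, `strand`,
#'   `cleavage_pos`, `n_tags` (unannotated; see [annotate_pas()]).
#' @export
call_polya_sites <- function(tag_alignments, cluster_window = 10L) {
  if (is.character(tag_alignments)) {
    tag_alignments <- read_alignments(tag_alignments)
  }
  if (cluster_window < 0L) {
    stop_spliceops("cluster_window must be >= 0", "spliceops_input_error")
  }
  a <- tag_alignments |> filter(!.data$unmapped, !.data$secondary)
  if (!nrow(a)) {
    res <- tibble(chrom = character(), strand = character(),
                  cleavage_pos = integer(), n_tags = integer())
    class(res) <- c("spliceops_polya_sites", class(res))
    return(res)
  }
  cl <- a |>
    mutate(strand = ifelse(.data$reverse, "-", "+"),
           cleavage_pos = ifelse(.data$reverse, .data$pos, .data$end - 1L)) |>
    group_by(.data$rname, .data$strand) |>
    arrange(.data$cleavage_pos, .by_group = TRUE) |>
    mutate(cluster = cumsum(
      c(1L, as.integer(diff(.data$cleavage_pos) > cluster_window)))) |>
    group_by(.data$rname, .data$strand, .data$cluster) |>
    summarise(cleavage_pos = mode_position(.data$cleavage_pos,
                                           .data$strand[1L]),
              n_tags = dplyr::n(), .groups = "drop") |>
    select(chrom = "rname", "strand", "cleavage_pos", "n_tags") |>
    arrange(.data$chrom, .data$strand, .data$cleavage_pos)
  class(cl) <- c("spliceops_polya_sites", class(cl))
  cl
}

# Modal value; ties broken toward the 3' end of the transcribed strand.
mode_position <- function(x, strand) {
  tab <- table(x)
  cand <- as.integer(names(tab)[tab == max(tab)])
  if (strand == "+") max(cand) else min(cand)
}

#' Annotate poly(A) sites with PAS hexamers
#'
#' Scans the transcribed-strand genomic sequence of the `search_window` bases
#' immediately upstream of each cleavage position for the hexamers of
#' `table`, in rank (frequency) order: the highest-ranked hexamer present
#' anywhere in the window is reported even if a lower-ranked one lies closer
#' to the cleavage site. When the winning hexamer occurs several times, the
#' occurrence closest to the cleavage site is reported. `pas_offset` is the
#' distance from the hexamer start to the cleavage position. An A-richness
#' flag (`a_rich`) marks sites whose 10 transcribed-strand genomic bases
#' downstream of the cleavage position are more than 70% A — the classical
#' internal-priming artifact signature; flagged sites are reported, not
#' removed.
#'
#' @param sites Sites from [call_polya_sites()].
#' @param genome `DNAStringSet` or FASTA path.
#' @param search_window Upstream window in bp (default 40; must be >= 6).
#' @param table PAS table from [pas_table()].
#' @return `sites` with `pas_hexamer` (NA if none), `pas_offset` (NA if
#'   none) and `a_rich` columns added.
#' @export
annotate_pas <- function(sites, genome, search_window = 40L,
                         table = pas_table()) {
  if (search_window < 6L) {
    stop_spliceops("search_window must be >= 6", "spliceops_input_error")
  }
  genome <- load_genome(genome)
  res <- sites |>
    mutate(pas_hexamer = NA_character_, pas_offset = NA_integer_,
           a_rich = FALSE)
  for (i in seq_len(nrow(res))) {
    win <- pas_window(genome, res$chrom[i], res$strand[i],
                      res$cleavage_pos[i], search_window)
    hit <- scan_pas(win$seq, table)
    if (!is.null(hit)) {
      res$pas_hexamer[i] <- hit$hexamer
      # window index is 0-based from the window 5' end; offset counts back
      # from the cleavage base to the hexamer start
      res$pas_offset[i] <- win$len - hit$start
    }
    down <- downstream_seq(genome, res$chrom[i], res$strand[i],
                           res$cleavage_pos[i], 10L)
    if (nchar(down) > 0L) {
      res$a_rich[i] <-
        stringr::str_count(down, "A") / nchar(down) > 0.7
    }
  }
  res
}

# Transcribed-strand sequence of the `window` bases upstream of (excluding)
# the cleavage base; truncated with a warning at the chromosome edge.
pas_window <- function(genome, chrom, strand, cleavage_pos, window) {
  chrom_len <- length(genome[[chrom]])
  if (strand == "+") {
    s <- cleavage_pos - window
    if (s < 0L) {
      rlang::warn("PAS window truncated at chromosome start")
      s <- 0L
    }
    e <- cleavage_pos
  } else {
    s <- cleavage_pos + 1L
    e <- cleavage_pos + 1L + window
    if (e > chrom_len) {
      rlang::warn("PAS window truncated at chromosome end")
      e <- chrom_len
    }
  }
  if (s >= e) return(list(seq = "", len = 0L))
  list(seq = genome_seq(genome, chrom, s, e, revcomp = strand == "-"),
       len = e - s)
}

downstream_seq <- function(genome, chrom, strand, cleavage_pos, n) {
  chrom_len <- length(genome[[chrom]])
  if (strand == "+") {
    s <- cleavage_pos + 1L
    e <- min(chrom_len, s + n)
  } else {
    e <- cleavage_pos
    s <- max(0L, e - n)
  }
  if (s >= e) return("")
  genome_seq(genome, chrom, s, e, revcomp = strand == "-")
}

# Highest-ranked hexamer present; among its occurrences, the one closest to
# the window 3' end (= cleavage-proximal). Returns NULL when nothing hits.
scan_pas <- function(window_seq, table) {
  if (nchar(window_seq) < 6L) return(NULL)
  for (r in seq_len(nrow(table))) {
    hex <- table$hexamer[r]
    occ <- stringr::str_locate_all(window_seq, stringr::fixed(hex))[[1L]]
    if (nrow(occ)) {
      return(list(hexamer = hex, start = max(occ[, "start"]) - 1L))
    }
  }
  NULL
}

#' PAS hexamer frequency summary across annotated sites
#'
#' @param sites Annotated sites from [annotate_pas()].
#' @param table PAS table (defines the row order).
#' @return A tibble `hexamer`, `rank`, `n_sites`, `frequency` — the package's
#'   PAS frequency table, with the canonical signal always at rank 1.
#' @export
pas_frequency_table <- function(sites, table = pas_table()) {
  counts <- sites |>
    filter(!is.na(.data$pas_hexamer)) |>
    count(hexamer = .data$pas_hexamer, name = "n_sites")
  table |>
    left_join(counts, by = "hexamer") |>
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
           frequency = if (sum(.data$n_sites) > 0)
             .data$n_sites / sum(.data$n_sites) else 0) |>
    arrange(.data$rank)
}

#' Write poly(A) sites as TSV and BED6
#'
#' @param sites Annotated sites.
#' @param tsv_path,bed_path Output paths (NULL skips).
#' @return Invisibly, the paths written.
#' @export
write_polya_sites <- function(sites, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(as_tibble(sites), tsv_path)
  if (!is.null(bed_path)) {
    readr::write_lines(
      sprintf("%s\t%d\t%d\tpA\t%d\t%s", sites$chrom, sites$cleavage_pos,
              sites$cleavage_pos + 1L, sites$n_tags, sites$strand),
      bed_path)
  }
  invisible(c(tsv_path, bed_path))
}
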
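#' Read a GTF gene model into an exon annotation table
#'
#' Parses exon features from a GTF file into a tibble with one row per exon.
#' GTF 1-based inclusive coordinates are converted to the package's internal
#' 0-based half-open convention at this boundary, and exons are ranked 1..k in
#' transcript 5'-to-3' order (ascending genomic order on `+`, descending on
#' `-`). Non-exon feature lines are ignored. Both common attribute dialects,
#' `key "value";` and `key=value`, are accepted.
#'
#' @param path Path to a GTF file.
#' @return A tibble of class `spliceops_annotation` with columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end` (0-based
#'   half-open) and `rank` (1-based, 5'→3').
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", "101", "200", ".", "+", ".",
#'                  'gene_id "G1"; transcript_id "T1";', sep = "\t"), gtf)
#' read_gtf(gtf)
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) {
    stop_spliceops(paste0("GTF file not found: ", path),
                   "spliceops_input_error")
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- stringr::str_split_fixed(lines, "\t", 9L)
  if (length(lines) && ncol(fields) < 9L) {
    stop_spliceops("GTF lines must have 9 tab-separated fields",
                   "spliceops_format_error")
  }
  is_exon <- fields[, 3L] == "exon"
  if (!any(is_exon)) {
    stop_spliceops("no exon features found in GTF (empty annotation)",
                   "spliceops_empty_annotation")
  }
  fields <- fields[is_exon, , drop = FALSE]
  line_no <- line_no[is_exon]

  tid <- gtf_attr(fields[, 9L], "transcript_id")
  gid <- gtf_attr(fields[, 9L], "gene_id")
  if (anyNA(tid)) {
    bad <- line_no[which(is.na(tid))[1L]]
    stop_spliceops(
      sprintf("exon line %d lacks a transcript_id attribute", bad),
      "spliceops_format_error")
  }
  if (anyNA(gid)) gid[is.na(gid)] <- tid[is.na(gid)]

  strand <- fields[, 7L]
  if (!all(strand %in% c("+", "-"))) {
    stop_spliceops("exon strand must be '+' or '-'", "spliceops_format_error")
  }
  ann <- tibble(
    transcript_id = tid,
    gene_id = gid,
    chrom = fields[, 1L],
    strand = strand,
    start = as.integer(fields[, 4L]) - 1L,  # to 0-based half-open
    end = as.integer(fields[, 5L])
  )
  if (any(is.na(ann$start)) || any(is.na(ann$end)) ||
      any(ann$start < 0) || any(ann$start >= ann$end)) {
    stop_spliceops("invalid exon coordinates in GTF",
                   "spliceops_format_error")
  }
  new_annotation(ann)
}

gtf_attr <- function(attrs, key) {
  # `key "value";` dialect first, then `key=value`
  m <- stringr::str_match(attrs, paste0(key, '\\s+"([^"]*)"'))[, 2L]
  alt <- stringr::str_match(attrs, paste0(key, '=\\s*"?([^;"\\s]+)"?'))[, 2L]
  ifelse(is.na(m), alt, m)
}

# Rank exons 5'->3' within each transcript and validate the model.
new_annotation <- function(ann) {
  chk <- ann |>
    group_by(.data$transcript_id) |>
    summarise(
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand),
      n_gene = dplyr::n_distinct(.data$gene_id),
      overlap = {
        o <- order(.data$start)
        any(.data$start[o][-1] < .data$end[o][-length(o)])
      },
      .groups = "drop"
    )
  if (any(chk$n_chrom > 1L) || any(chk$n_strand > 1L) || any(chk$n_gene > 1L)) {
    stop_spliceops("transcript spans multiple chroms/strands/genes",
                   "spliceops_format_error")
  }
  if (any(chk$overlap)) {
    bad <- chk$transcript_id[chk$overlap][1L]
    stop_spliceops(
      paste0("transcript has overlapping exons: ", bad),
      "spliceops_overlapping_exons")
  }
  ann <- ann |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(rank = if (.data$strand[1L] == "+") seq_len(dplyr::n())
           else rev(seq_len(dplyr::n()))) |>
    ungroup() |>
    arrange(.data$transcript_id, .data$rank)
  class(ann) <- c("spliceops_annotation", class(ann))
  ann
}

#' Write an exon annotation table back to GTF
#'
#' Inverse of [read_gtf()]: internal 0-based half-open coordinates are written
#' as 1-based inclusive GTF exon lines with `gene_id`/`transcript_id`
#' attributes. A read/write round trip reconstructs the annotation exactly.
#'
#' @param ann Annotation tibble from [read_gtf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  out <- ann |> arrange(.data$transcript_id, .data$rank)
  lines <- sprintf(
    "%s\tspliceops\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    out$chrom, out$start + 1L, out$end, out$strand, out$gene_id,
    out$transcript_id)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Summarise an annotation at transcript level
#'
#' @param ann Annotation tibble from [read_gtf()].
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand` and exon count `k`.
#' @export
annotation_summary <- function(ann) {
  ann |>
    group_by(.data$transcript_id) |>
    summarise(gene_id = .data$gene_id[1L], chrom = .data$chrom[1L],
              strand = .data$strand[1L], k = dplyr::n(), .groups = "drop")
}

#' Enumerate known (adjacent-exon) splice junctions
#'
#' For every transcript with k exons, reports the k-1 junctions joining the 3'
#' end of exon i to the 5' start of exon i+1 in transcript order. `donor` is
#' the 0-based genomic position of the exonic base 3'-adjacent to the intron
#' and `acceptor` the first exonic base after the intron, both strand-aware.
#' Single-exon transcripts contribute nothing.
#'
#' @param ann Annotation tibble from [read_gtf()].
#' @return A tibble: `transcript_id`, `gene_id`, `chrom`, `strand`, `donor`,
#'   `acceptor`, `category` (`"known"`), `n_skipped` (0), plus the flanking
#'   exon intervals (`up_start`, `up_end`, `down_start`, `down_end`).
#' @export
known_junctions <- function(ann) {
  exon_pair_junctions(ann, gap = 1L, max_gap = 1L) |>
    mutate(category = "known")
}

# Junctions joining exon rank i to rank i + gap .. i + max_gap.
exon_pair_junctions <- function(ann, gap = 1L, max_gap = NULL) {
  ann |>
    group_by(.data$transcript_id) |>
    arrange(.data$rank, .by_group = TRUE) |>
    reframe(
      gene_id = .data$gene_id[1L], chrom = .data$chrom[1L],
      strand = .data$strand[1L],
      {
        k <- dplyr::n()
        st <- .data$start
        en <- .data$end
        hi <- if (is.null(max_gap)) k - 1L else max_gap
        pairs <- if (k >= 1L + gap) {
          do.call(rbind, lapply(seq_len(k - gap), function(i) {
            js <- seq.int(i + gap, min(k, i + hi))
            cbind(i = i, j = js)
          }))
        }
        if (is.null(pairs)) {
          tibble(up_start = integer(), up_end = integer(),
                 down_start = integer(), down_end = integer(),
                 n_inner = integer())
        } else {
          tibble(
            up_start = st[pairs[, 1L]],
            up_end = en[pairs[, 1L]],
            down_start = st[pairs[, 2L]],
            down_end = en[pairs[, 2L]],
            n_inner = pairs[, 2L] - pairs[, 1L] - 1L
          )
        }
      }
    ) |>
    mutate(
      donor = ifelse(.data$strand == "+", .data$up_end - 1L, .data$up_start),
      acceptor = ifelse(.data$strand == "+", .data$down_start,
                        .data$down_end - 1L)
    ) |>
    select("transcript_id", "gene_id", "chrom", "strand", "donor", "acceptor",
           n_skipped = "n_inner", "up_start", "up_end", "down_start",
           "down_end")
}
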
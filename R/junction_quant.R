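#' Count junction-spanning reads aligned to a junction library
#'
#' An alignment against a library record supports its junction when the
#' aligned span crosses the record's fusion point (local position `up_len`)
#' with at least `min_anchor` aligned bases on each side, and no insertion or
#' deletion interrupts the alignment at the fusion point itself. Secondary and
#' supplementary alignments are ignored (reported in a separate tally);
#' each read is counted at most once per junction. In `unique_only` mode a
#' read aligned to several records is discarded instead of counted for each.
#'
#' @param alignments Alignment tibble from [read_alignments()] (or a SAM/BAM
#'   path), aligned against the library FASTA: reference names are
#'   `junction_id`s or full [write_junction_fasta()] headers.
#' @param lib Junction library.
#' @param min_anchor Minimum aligned bases on each side of the fusion point
#'   (default 8).
#' @param unique_only Drop reads hitting more than one record (default FALSE:
#'   multi-hit reads count once per record they span).
#' @param sample_id Label stored in the result attributes.
#' @return A tibble of class `spliceops_junction_counts` with one row per
#'   library record: `junction_id`, `chrom`, `strand`, `donor`, `acceptor`,
#'   `category`, `n_skipped`, `count`. `glance()` returns the tallies
#'   (total examined, counted, rejected by reason, unmapped, multi-hit
#'   fraction).
#' @export
count_junction_hits <- function(alignments, lib, min_anchor = 8L,
                                unique_only = FALSE, sample_id = "sample") {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  if (min_anchor < 1L) {
    stop_spliceops("min_anchor must be >= 1", "spliceops_input_error")
  }
  # accept either bare junction ids or the structured FASTA header
  ref_id <- sub("\\|.*$", "", alignments$rname)
  known_ids <- lib$junction_id
  mapped <- !alignments$unmapped
  bad <- mapped & !ref_id %in% known_ids
  if (any(bad)) {
    stop_spliceops(
      paste0("alignment references unknown library record: ",
             ref_id[bad][1L]),
      "spliceops_consistency_error")
  }
  rec_len <- stats::setNames(lib$up_len + lib$down_len, lib$junction_id)
  up_len <- stats::setNames(lib$up_len, lib$junction_id)

  primary <- !alignments$secondary
  n_secondary <- sum(!primary)
  a <- alignments[primary, ]
  ref_id <- ref_id[primary]
  total <- nrow(a)
  n_unmapped <- sum(a$unmapped)

  status <- character(total)
  status[a$unmapped] <- "unmapped"
  idx <- which(!a$unmapped)
  for (i in idx) {
    fp <- up_len[[ref_id[i]]]
    if (a$end[i] > rec_len[[ref_id[i]]]) {
      stop_spliceops(
        paste0("alignment extends past library record ", ref_id[i]),
        "spliceops_consistency_error")
    }
    if (!(a$pos[i] < fp && a$end[i] > fp)) {
      status[i] <- "non_spanning"
      next
    }
    blocks <- alignment_blocks(a$pos[i], a$cigar[i], drop_d = TRUE)
    crosses <- any(blocks[, "start"] < fp & blocks[, "end"] > fp)
    if (!crosses) {            # indel or gap lands on the fusion point
      status[i] <- "non_spanning"
    } else if (fp - a$pos[i] < min_anchor || a$end[i] - fp < min_anchor) {
      status[i] <- "short_anchor"
    } else {
      status[i] <- "counted"
    }
  }

  hits <- tibble(qname = a$qname[status == "counted"],
                 junction_id = ref_id[status == "counted"]) |>
    distinct()  # a read counts at most once per junction
  multi <- hits |> count(.data$qname) |> filter(.data$n > 1L)
  multi_frac <- if (nrow(hits)) {
    length(unique(multi$qname)) / length(unique(hits$qname))
  } else 0
  if (unique_only && nrow(multi)) {
    hits <- hits |> filter(!.data$qname %in% multi$qname)
  }
  per_jx <- hits |> count(.data$junction_id, name = "count")
  res <- lib |>
    select("junction_id", "chrom", "strand", "donor", "acceptor", "category",
           "n_skipped") |>
    as_tibble() |>
    left_join(per_jx, by = "junction_id") |>
    mutate(count = as.integer(dplyr::coalesce(.data$count, 0L)))
  attr(res, "tallies") <- list(
    sample_id = sample_id, total_examined = total,
    counted = sum(status == "counted"),
    rejected_non_spanning = sum(status == "non_spanning"),
    rejected_short_anchor = sum(status == "short_anchor"),
    unmapped = n_unmapped, secondary_ignored = n_secondary,
    multi_hit_fraction = multi_frac)
  class(res) <- c("spliceops_junction_counts", class(res))
  res
}

#' @exportS3Method generics::glance
glance.spliceops_junction_counts <- function(x, ...) {
  as_tibble(attr(x, "tallies"))
}

#' Map a record-local position back to the genome
#'
#' Local positions `< up_len` fall in the upstream flank ending at the donor;
#' positions `>= up_len` fall in the downstream flank starting at the
#' acceptor. Truncated flanks shift the local origin accordingly, which is
#' why flank lengths are carried in the record. Strand-aware: on the minus
#' strand local coordinates run against the genome.
#'
#' @param rec One junction record (a single-row tibble or list with `strand`,
#'   `donor`, `acceptor`, `up_len`, `down_len`).
#' @param local_pos 0-based position(s) within the record sequence.
#' @return Genomic position(s), 0-based.
#' @export
junction_breakpoint <- function(rec, local_pos) {
  total <- rec$up_len + rec$down_len
  if (any(local_pos < 0L | local_pos >= total)) {
    stop_spliceops(
      sprintf("local position out of range [0,%d)", total),
      "spliceops_bounds_error")
  }
  up <- local_pos < rec$up_len
  if (rec$strand == "+") {
    ifelse(up,
           rec$donor + 1L - rec$up_len + local_pos,
           rec$acceptor + (local_pos - rec$up_len))
  } else {
    ifelse(up,
           rec$donor + rec$up_len - 1L - local_pos,
           rec$acceptor - (local_pos - rec$up_len))
  }
}

#' Write per-junction counts as TSV and a genomic BED6 track
#'
#' @param counts Result of [count_junction_hits()].
#' @param tsv_path,bed_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_junction_counts <- function(counts, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    counts |>
      mutate(key = paste(.data$chrom, .data$strand, .data$donor,
                         .data$acceptor, sep = ":")) |>
      select("junction_id", "key", "category", "n_skipped", "count") |>
      readr::write_tsv(tsv_path)
  }
  if (!is.null(bed_path)) {
    lo <- pmin(counts$donor, counts$acceptor)
    hi <- pmax(counts$donor, counts$acceptor) + 1L
    readr::write_lines(
      sprintf("%s\t%d\t%d\t%s\t%d\t%s", counts$chrom, lo, hi,
              counts$junction_id, counts$count, counts$strand),
      bed_path)
  }
  invisible(c(tsv_path, bed_path))
}
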
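#' Build an exon-trio database (TXdb) from an annotation
#'
#' Breaks every transcript into all consecutive exon trios (ranks i, i+1,
#' i+2). Each trio defines two isoforms: an inclusion isoform splicing all
#' three exons and a skipping isoform splicing only the two flanking exons,
#' so `len_inc = len_skip + middle exon length` always. A transcript with k
#' exons contributes max(0, k-2) trios; trios with identical exon intervals
#' arising from different transcripts are merged.
#'
#' @param ann Annotation tibble from [read_gtf()].
#' @return A tibble of class `spliceops_txdb`: `trio_id`, `chrom`, `strand`,
#'   the three exon intervals (`up_start`..`down_end`), `middle_len`,
#'   `len_inc`, `len_skip` and a `source_transcripts` list-column.
#' @export
build_txdb <- function(ann) {
  if (!nrow(ann)) {
    stop_spliceops("annotation is empty", "spliceops_input_error")
  }
  trios <- ann |>
    group_by(.data$transcript_id) |>
    arrange(.data$rank, .by_group = TRUE) |>
    reframe(
      chrom = .data$chrom[1L], strand = .data$strand[1L],
      {
        k <- dplyr::n()
        st <- .data$start
        en <- .data$end
        if (k < 3L) {
          tibble(up_start = integer(), up_end = integer(),
                 mid_start = integer(), mid_end = integer(),
                 down_start = integer(), down_end = integer())
        } else {
          i <- seq_len(k - 2L)
          tibble(up_start = st[i], up_end = en[i],
                 mid_start = st[i + 1L], mid_end = en[i + 1L],
                 down_start = st[i + 2L], down_end = en[i + 2L])
        }
      }
    ) |>
    group_by(.data$chrom, .data$strand, .data$up_start, .data$up_end,
             .data$mid_start, .data$mid_end, .data$down_start,
             .data$down_end) |>
    summarise(source_transcripts = list(sort(unique(.data$transcript_id))),
              .groups = "drop") |>
    mutate(
      middle_len = .data$mid_end - .data$mid_start,
      len_skip = (.data$up_end - .data$up_start) +
        (.data$down_end - .data$down_start),
      len_inc = .data$len_skip + .data$middle_len,
      trio_id = sprintf("TRIO%05d", dplyr::row_number())
    ) |>
    select("trio_id", "chrom", "strand", "up_start", "up_end", "mid_start",
           "mid_end", "down_start", "down_end", "middle_len", "len_inc",
           "len_skip", "source_transcripts")
  class(trios) <- c("spliceops_txdb", class(trios))
  trios
}

#' Estimate the exon inclusion ratio of a trio
#'
#' The inclusion ratio is the expression of the inclusion isoform divided by
#' the summed expression of both isoforms, with read counts normalised by
#' isoform length: IR = (n_inc/len_inc) / (n_inc/len_inc + n_skip/len_skip).
#' A binomial-derived standard error on the effective counts is attached via
#' the delta method. With zero total support, IR is undefined (NA).
#'
#' Vectorised over its arguments.
#'
#' @param n_inc,n_skip Supporting read counts (inclusion / skipping isoform).
#' @param len_inc,len_skip Isoform lengths in bp.
#' @return A tibble: `n_inc`, `n_skip`, `ir`, `se`, `defined`.
#' @export
estimate_inclusion <- function(n_inc, n_skip, len_inc, len_skip) {
  if (any(n_inc < 0) || any(n_skip < 0)) {
    stop_spliceops("counts must be non-negative", "spliceops_domain_error")
  }
  if (any(len_inc <= 0) || any(len_skip <= 0)) {
    stop_spliceops("isoform lengths must be positive",
                   "spliceops_domain_error")
  }
  n <- n_inc + n_skip
  dens_inc <- n_inc / len_inc
  dens_skip <- n_skip / len_skip
  ir <- ifelse(n > 0, dens_inc / (dens_inc + dens_skip), NA_real_)
  # IR as a function of the binomial fraction p = n_inc / n:
  # IR(p) = p*ls / (p*ls + (1-p)*li), dIR/dp = ls*li / (p*ls + (1-p)*li)^2
  p <- ifelse(n > 0, n_inc / n, NA_real_)
  denom <- p * len_skip + (1 - p) * len_inc
  se <- ifelse(n > 0,
               (len_skip * len_inc / denom^2) * sqrt(p * (1 - p) / n),
               NA_real_)
  tibble(n_inc = n_inc, n_skip = n_skip, ir = ir, se = se, defined = n > 0)
}

#' Apply the exon-size-dependent coverage cutoff
#'
#' Poorly covered trios are flagged with a dynamic cutoff that grows with the
#' middle exon: a trio passes when its total support reaches
#' `max(n_min, ceiling(rho * middle_exon_len / read_len))`. Estimates that
#' fail keep their IR but are flagged unreliable.
#'
#' @param est Estimates from [estimate_inclusion()] (any tibble with `n_inc`,
#'   `n_skip`).
#' @param middle_exon_len Middle exon length(s) in bp.
#' @param read_len Read length in bp.
#' @param n_min Absolute floor on supporting reads (default 4).
#' @param rho Coverage factor (default 2): required middle-exon coverage in
#'   read equivalents.
#' @return `est` with `cutoff` and `passes_cutoff` columns added.
#' @export
apply_coverage_cutoff <- function(est, middle_exon_len, read_len,
                                  n_min = 4L, rho = 2) {
  if (any(read_len <= 0)) {
    stop_spliceops("read_len must be positive", "spliceops_domain_error")
  }
  cutoff <- pmax(n_min, ceiling(rho * middle_exon_len / read_len))
  est |>
    mutate(cutoff = as.integer(cutoff),
           passes_cutoff = (.data$n_inc + .data$n_skip) >= cutoff)
}

#' Quantify inclusion over a TXdb from per-trio support counts
#'
#' Convenience wrapper joining a TXdb with support counts and applying
#' [estimate_inclusion()] and [apply_coverage_cutoff()]. Read-to-isoform
#' support counting is the caller's: a read supports inclusion when it
#' overlaps the middle exon body or either inclusion-only junction, and
#' supports skipping when it spans the skip junction.
#'
#' @param txdb TXdb from [build_txdb()].
#' @param support Tibble with `trio_id`, `n_inc`, `n_skip`.
#' @param read_len,n_min,rho Cutoff parameters, see
#'   [apply_coverage_cutoff()].
#' @return A tibble: trio metadata plus `n_inc`, `n_skip`, `ir`, `se`,
#'   `defined`, `cutoff`, `passes_cutoff`.
#' @export
quantify_inclusion <- function(txdb, support, read_len, n_min = 4L,
                               rho = 2) {
  joined <- txdb |>
    as_tibble() |>
    inner_join(support, by = "trio_id")
  est <- estimate_inclusion(joined$n_inc, joined$n_skip, joined$len_inc,
                            joined$len_skip)
  joined |>
    select("trio_id", "chrom", "strand", "mid_start", "mid_end",
           "middle_len", "len_inc", "len_skip") |>
    bind_cols(est) |>
    apply_coverage_cutoff(middle_exon_len = joined$middle_len,
                          read_len = read_len, n_min = n_min, rho = rho)
}
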
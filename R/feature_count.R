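#' Per-gene exon-union intervals
#'
#' Merges each gene's exons into a disjoint set of intervals — the feature
#' space used by [assign_read()] and [count_genes()].
#'
#' @param ann Annotation tibble from [read_gtf()].
#' @return A tibble: `gene_id`, `chrom`, `strand`, `start`, `end` (0-based
#'   half-open, disjoint within gene).
#' @export
gene_features <- function(ann) {
  ann |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    reframe({
      ir <- IRanges::reduce(IRanges::IRanges(.data$start + 1L, .data$end))
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    ungroup()
}

#' Assign one read to a gene under the intersection-nonempty rule
#'
#' Over the read's aligned positions, the gene set at each position is
#' computed; the assignment is the intersection of the non-empty per-position
#' sets. A singleton intersection assigns the read to that gene — so a read
#' completely inside gene A and only partially overlapping gene B goes to A,
#' and partial overlap of a single gene still assigns. An empty intersection
#' of non-empty sets is ambiguous; a read touching no feature at all is
#' unassigned. Implemented on interval arithmetic: a gene survives iff its
#' overlap with the read covers every read position covered by any gene.
#'
#' @param blocks Matrix or data frame with `start`/`end` columns: the read's
#'   aligned genomic blocks, 0-based half-open, sorted, non-overlapping.
#' @param features Gene features from [gene_features()], already restricted
#'   to the read's chromosome (and strand, if counting stranded).
#' @return A list with `status` (`"assigned"`, `"ambiguous"`,
#'   `"no_feature"`) and `gene_id` (NA unless assigned).
#' @export
assign_read <- function(blocks, features) {
  blocks <- as.matrix(blocks[, c("start", "end"), drop = FALSE])
  if (!nrow(blocks) || any(blocks[, "start"] >= blocks[, "end"]) ||
      is.unsorted(blocks[, "start"])) {
    stop_spliceops("read blocks must be non-empty, sorted, non-overlapping",
                   "spliceops_domain_error")
  }
  read_ir <- IRanges::IRanges(blocks[, "start"] + 1L, blocks[, "end"])
  feat_ir <- IRanges::IRanges(features$start + 1L, features$end)
  ov <- IRanges::findOverlaps(feat_ir, read_ir)
  if (!length(ov)) return(list(status = "no_feature", gene_id = NA_character_))
  # per-gene intersection with the read
  hit_rows <- unique(S4Vectors::queryHits(ov))
  per_gene <- lapply(split(hit_rows, features$gene_id[hit_rows]), function(r) {
    IRanges::reduce(IRanges::intersect(
      IRanges::reduce(feat_ir[r]), read_ir))
  })
  covered <- IRanges::reduce(do.call(c, unname(per_gene)))
  full_w <- sum(IRanges::width(covered))
  winners <- names(per_gene)[
    vapply(per_gene, function(x) sum(IRanges::width(x)) == full_w,
           logical(1))]
  if (length(winners) == 1L) {
    list(status = "assigned", gene_id = winners)
  } else {
    # empty pairwise intersection, or several genes covering identically
    list(status = "ambiguous", gene_id = NA_character_)
  }
}

#' Count aligned fragments per gene (intersection-nonempty)
#'
#' Applies [assign_read()] to every primary alignment; paired mates sharing a
#' read name are combined into one fragment whose block set is the union of
#' both mates' blocks, counted once. Secondary/supplementary alignments go to
#' a `multi_mapped` tally and are excluded from gene counts. Strandedness
#' restricts candidate genes to the compatible strand (`forward`: read strand
#' equals gene strand; `reverse`: opposite).
#'
#' @param alignments Alignment tibble from [read_alignments()] or a SAM/BAM
#'   path, aligned to the genome.
#' @param ann Annotation tibble from [read_gtf()].
#' @param strandedness One of `"none"`, `"forward"`, `"reverse"`.
#' @return A tibble of class `spliceops_gene_counts` with `gene_id`, `count`
#'   for every gene in `ann`; `glance()` returns the tallies (`no_feature`,
#'   `ambiguous`, `not_aligned`, `multi_mapped`, `total_fragments`).
#' @export
count_genes <- function(alignments, ann,
                        strandedness = c("none", "forward", "reverse")) {
  strandedness <- match.arg(strandedness)
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  feats <- gene_features(ann)
  known_chroms <- unique(feats$chrom)
  a <- alignments |> filter(!.data$secondary)
  multi_mapped <- sum(alignments$secondary)
  bad <- !a$unmapped & !a$rname %in% known_chroms
  if (any(bad)) {
    stop_spliceops(
      paste0("alignment chromosome absent from annotation: ",
             a$rname[bad][1L]),
      "spliceops_consistency_error")
  }

  frags <- a |>
    group_by(.data$qname) |>
    summarise(
      unmapped = all(.data$unmapped),
      chrom = .data$rname[!.data$unmapped][1L] %||% NA_character_,
      read_strand = ifelse(any(.data$reverse[!.data$unmapped]), "-", "+"),
      blocks = list({
        m <- .data$unmapped
        if (all(m)) NULL else {
          bl <- do.call(rbind, Map(alignment_blocks,
                                   .data$pos[!m], .data$cigar[!m]))
          ir <- IRanges::reduce(IRanges::IRanges(bl[, "start"] + 1L,
                                                 bl[, "end"]))
          cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
        }
      }),
      .groups = "drop"
    )

  tall <- c(no_feature = 0L, ambiguous = 0L, not_aligned = 0L)
  counts <- stats::setNames(integer(length(unique(ann$gene_id))),
                            sort(unique(ann$gene_id)))
  for (i in seq_len(nrow(frags))) {
    if (frags$unmapped[i]) {
      tall["not_aligned"] <- tall["not_aligned"] + 1L
      next
    }
    fs <- feats |> filter(.data$chrom == frags$chrom[i])
    if (strandedness == "forward") {
      fs <- fs |> filter(.data$strand == frags$read_strand[i])
    } else if (strandedness == "reverse") {
      fs <- fs |> filter(.data$strand != frags$read_strand[i])
    }
    res <- assign_read(frags$blocks[[i]], fs)
    if (res$status == "assigned") {
      counts[res$gene_id] <- counts[res$gene_id] + 1L
    } else if (res$status == "ambiguous") {
      tall["ambiguous"] <- tall["ambiguous"] + 1L
    } else {
      tall["no_feature"] <- tall["no_feature"] + 1L
    }
  }
  out <- tibble(gene_id = names(counts), count = unname(counts))
  attr(out, "tallies") <- list(
    no_feature = unname(tall["no_feature"]),
    ambiguous = unname(tall["ambiguous"]),
    not_aligned = unname(tall["not_aligned"]),
    multi_mapped = multi_mapped,
    total_fragments = nrow(frags))
  class(out) <- c("spliceops_gene_counts", class(out))
  out
}

#' @exportS3Method generics::glance
glance.spliceops_gene_counts <- function(x, ...) {
  as_tibble(attr(x, "tallies"))
}

#' Write gene counts (plus special tallies) as TSV
#'
#' Output is format-compatible with common count-matrix consumers: gene rows
#' first, then `__no_feature`, `__ambiguous`, `__not_aligned`,
#' `__multi_mapped` tallies.
#'
#' @param counts Result of [count_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_counts <- function(counts, path) {
  t <- attr(counts, "tallies")
  extra <- tibble(
    gene_id = c("__no_feature", "__ambiguous", "__not_aligned",
                "__multi_mapped"),
    count = as.integer(c(t$no_feature, t$ambiguous, t$not_aligned,
                         t$multi_mapped)))
  readr::write_tsv(bind_rows(as_tibble(counts), extra), path,
                   col_names = FALSE)
  invisible(path)
}
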
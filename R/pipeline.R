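#' Run the in-scope analysis stages end to end
#'
#' Orchestrates junction-library construction, junction quantification,
#' poly(A) site detection, TXdb construction + inclusion estimation, gene
#' counting, and differential testing over a declarative configuration.
#' Stages run in dependency order; each records a status — `completed`,
#' `skipped` or `error` — in a JSON-lines manifest, and a failing stage never
#' removes the outputs of stages that already completed.
#'
#' @param config A named list. Paths: `gtf`, `genome`, `library_aln`
#'   (SAM/BAM vs junction library), `tag_aln` (SAM/BAM of trimmed tags vs
#'   genome), `genome_aln` (SAM/BAM vs genome), `reads` (FASTQ), `outdir`.
#'   Stage flags (logical): `junctions`, `quant`, `polya`, `trios`, `counts`,
#'   `diff`. Parameters: `L`, `min_anchor`, `min_tail`, `min_trimmed`,
#'   `search_window`, `cluster_window`, `n_min`, `rho`, `strandedness`,
#'   `read_len`; for `diff`: `counts_tsv` (features x samples TSV, first
#'   column feature id) and `condition` (vector of labels).
#' @return Invisibly, a tibble manifest (`stage`, `status`, `detail`),
#'   also written to `<outdir>/manifest.jsonl`.
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  state <- new.env(parent = emptyenv())

  note <- function(stage, status, detail = "") {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, status = status, detail = detail)
  }
  run_stage <- function(stage, enabled, fn) {
    if (!isTRUE(enabled)) {
      note(stage, "skipped")
      return(invisible())
    }
    tryCatch({
      detail <- fn()
      note(stage, "completed", detail %||% "")
    }, error = function(e) note(stage, "error", conditionMessage(e)))
  }
  need_ann <- function() {
    if (is.null(state$ann)) state$ann <- read_gtf(config$gtf)
    state$ann
  }

  run_stage("junctions", config$junctions, function() {
    lib <- build_junction_library(need_ann(), config$genome,
                                  L = config$L %||% 75L)
    state$lib <- lib
    write_junction_fasta(lib, file.path(outdir, "junction_library.fa"))
    readr::write_tsv(junction_manifest(lib),
                     file.path(outdir, "junction_manifest.tsv"))
    sprintf("%d junctions", nrow(lib))
  })
  run_stage("quant", config$quant, function() {
    lib <- state$lib %||% build_junction_library(need_ann(), config$genome,
                                                 L = config$L %||% 75L)
    jc <- count_junction_hits(config$library_aln, lib,
                              min_anchor = config$min_anchor %||% 8L)
    state$junction_counts <- jc
    write_junction_counts(jc, file.path(outdir, "junction_counts.tsv"),
                          file.path(outdir, "junction_counts.bed"))
    sprintf("%d reads counted", sum(jc$count))
  })
  run_stage("polya", config$polya, function() {
    if (!is.null(config$reads)) {
      tags <- extract_polya_tags(config$reads,
                                 min_tail = config$min_tail %||% 6L,
                                 min_trimmed = config$min_trimmed %||% 15L)
      write_fastq(tags, file.path(outdir, "polya_tags.fastq"))
    }
    sites <- call_polya_sites(config$tag_aln,
                              cluster_window = config$cluster_window %||%
                                10L)
    sites <- annotate_pas(sites, config$genome,
                          search_window = config$search_window %||% 40L)
    state$polya_sites <- sites
    write_polya_sites(sites, file.path(outdir, "polya_sites.tsv"),
                      file.path(outdir, "polya_sites.bed"))
    readr::write_tsv(pas_frequency_table(sites),
                     file.path(outdir, "pas_frequency.tsv"))
    sprintf("%d sites", nrow(sites))
  })
  run_stage("trios", config$trios, function() {
    txdb <- build_txdb(need_ann())
    state$txdb <- txdb
    readr::write_tsv(txdb |> select(-"source_transcripts") |> as_tibble(),
                     file.path(outdir, "txdb.tsv"))
    readr::write_lines(
      sprintf("%s\t%d\t%d\t%s\t0\t%s", txdb$chrom, txdb$mid_start,
              txdb$mid_end, txdb$trio_id, txdb$strand),
      file.path(outdir, "txdb_middle_exons.bed"))
    sprintf("%d trios", nrow(txdb))
  })
  run_stage("counts", config$counts, function() {
    gc <- count_genes(config$genome_aln, need_ann(),
                      strandedness = config$strandedness %||% "none")
    state$gene_counts <- gc
    write_gene_counts(gc, file.path(outdir, "gene_counts.tsv"))
    sprintf("%d fragments assigned", sum(gc$count))
  })
  run_stage("diff", config$diff, function() {
    cm <- readr::read_tsv(config$counts_tsv, show_col_types = FALSE)
    mat <- as.matrix(cm[, -1L])
    rownames(mat) <- cm[[1L]]
    res <- diff_counts(mat, config$condition)
    readr::write_tsv(tidy(res), file.path(outdir, "diff_results.tsv"))
    sprintf("%d features tested", nrow(res))
  })

  manifest <- bind_rows(manifest)
  readr::write_lines(
    vapply(seq_len(nrow(manifest)), function(i) {
      jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE)
    }, character(1)),
    file.path(outdir, "manifest.jsonl"))
  invisible(manifest)
}
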
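#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The generator emulates
#' a small multi-exon annotation with spliced, unspliced and poly(A)-tailed
#' short reads whose placements are known exactly, so each analysis stage can
#' be validated against planted ground truth. All randomness flows from
#' `seed`; identical configs give byte-identical outputs.
#'
#' @param seed Integer seed fixing every random draw.
#' @param n_genes Number of genes (one transcript each).
#' @param exons_per_transcript Integer range `c(min, max)` for k.
#' @param exon_len,intron_len Length ranges in bp.
#' @param read_len Read length in bp.
#' @param reads_per_gene Mean unspliced (exonic) reads per gene.
#' @param junction_read_range Range of planted spanning-read counts per
#'   junction.
#' @param frac_junction Fraction of known junctions that receive planted
#'   spanning reads.
#' @param frac_polya Fraction of genes with a planted polyadenylation site.
#' @param polya_tags_per_site Planted tag count per poly(A) site.
#' @param tail_len A-tail length appended to poly(A) reads.
#' @param pas_hexamer Planted PAS hexamer.
#' @param pas_offset_range Range (bp upstream of the cleavage base) for the
#'   planted hexamer start.
#' @param min_anchor Minimum anchor guaranteed for planted junction reads.
#' @param error_rate Per-base substitution rate (0 = error-free).
#' @return A list of class `spliceops_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L,
                       exons_per_transcript = c(2L, 6L),
                       exon_len = c(90L, 300L), intron_len = c(60L, 200L),
                       read_len = 75L, reads_per_gene = 30L,
                       junction_read_range = c(5L, 20L),
                       frac_junction = 1, frac_polya = 0.5,
                       polya_tags_per_site = 6L, tail_len = 12L,
                       pas_hexamer = "AATAAA",
                       pas_offset_range = c(15L, 30L),
                       min_anchor = 8L, error_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_transcript = as.integer(exons_per_transcript),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              read_len = as.integer(read_len),
              reads_per_gene = as.integer(reads_per_gene),
              junction_read_range = as.integer(junction_read_range),
              frac_junction = frac_junction, frac_polya = frac_polya,
              polya_tags_per_site = as.integer(polya_tags_per_site),
              tail_len = as.integer(tail_len), pas_hexamer = pas_hexamer,
              pas_offset_range = as.integer(pas_offset_range),
              min_anchor = as.integer(min_anchor), error_rate = error_rate)
  if (any(c(cfg$frac_junction, cfg$frac_polya, cfg$error_rate) < 0) ||
      any(c(cfg$frac_junction, cfg$frac_polya, cfg$error_rate) > 1)) {
    stop_spliceops("fractions must lie in [0, 1]", "spliceops_config_error")
  }
  if (cfg$exon_len[1L] < cfg$read_len) {
    stop_spliceops(
      "minimum exon length must be >= read_len (reads are planted within single exons)",
      "spliceops_config_error")
  }
  if (cfg$pas_offset_range[1L] < 7L) {
    stop_spliceops("PAS offset must leave the hexamer upstream of cleavage",
                   "spliceops_config_error")
  }
  class(cfg) <- "spliceops_sim_config"
  cfg
}

#' Simulate a toy genome and annotation
#'
#' Generates random-sequence chromosomes carrying `n_genes` single-transcript
#' genes with k exons drawn from the configured range, on alternating
#' strands. Homopolymer A/T runs of five or more bases are broken during
#' genome generation so that untemplated poly(A) tails are the only long
#' terminal A-runs reads can carry. For genes designated to carry a
#' polyadenylation site, the configured PAS hexamer is planted in the genome
#' at a drawn offset upstream of the transcript's 3' end.
#'
#' @param cfg A [sim_config()].
#' @return A list: `genome` (DNAStringSet), `annotation` (tibble as from
#'   [read_gtf()]), and `polya_truth` (tibble of planted sites: `gene_id`,
#'   `chrom`, `strand`, `cleavage_pos`, `pas_hexamer`, `pas_offset`).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  gap <- 300L
  exon_rows <- list()
  chrom_seqs <- character()
  chrom <- "chrS1"
  cursor <- gap
  pieces <- list(random_dna(gap))
  polya_truth <- list()
  n_polya <- round(cfg$frac_polya * cfg$n_genes)

  for (g in seq_len(cfg$n_genes)) {
    k <- sample(seq(cfg$exons_per_transcript[1L],
                    cfg$exons_per_transcript[2L]), 1L)
    strand <- if (g %% 2L == 0L) "-" else "+"
    ex_lens <- sample(seq(cfg$exon_len[1L], cfg$exon_len[2L]), k,
                      replace = TRUE)
    in_lens <- if (k > 1L) {
      sample(seq(cfg$intron_len[1L], cfg$intron_len[2L]), k - 1L,
             replace = TRUE)
    } else integer()
    starts <- integer(k)
    pos <- cursor
    for (e in seq_len(k)) {
      starts[e] <- pos
      pos <- pos + ex_lens[e] + if (e < k) in_lens[e] else 0L
    }
    gene_end <- starts[k] + ex_lens[k]
    gene_seq <- random_dna(gene_end - cursor)
    gid <- sprintf("G%03d", g)
    tid <- sprintf("T%03d", g)
    exon_rows[[g]] <- tibble(
      transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
      start = starts, end = starts + ex_lens)

    if (g <= n_polya) {
      # plant a PAS upstream of the transcript 3' end (strand-aware); pin the
      # cleavage base to C so the untemplated tail is the whole terminal run
      off <- sample(seq(cfg$pas_offset_range[1L], cfg$pas_offset_range[2L]),
                    1L)
      if (strand == "+") {
        cleav <- gene_end - 1L
        substr(gene_seq, cleav - cursor + 1L, cleav - cursor + 1L) <- "C"
        hex_start <- cleav - off
        local <- hex_start - cursor
        substr(gene_seq, local + 1L, local + 6L) <- cfg$pas_hexamer
      } else {
        cleav <- starts[1L]
        substr(gene_seq, cleav - cursor + 1L, cleav - cursor + 1L) <- "G"
        hex_start_ts <- cleav + off   # transcribed 5'->3' runs rightward
        local <- hex_start_ts - cursor
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cfg$pas_hexamer)))
        substr(gene_seq, local - 5L + 1L, local + 1L) <- rc
      }
      polya_truth[[g]] <- tibble(
        gene_id = gid, chrom = chrom, strand = strand,
        cleavage_pos = cleav, pas_hexamer = cfg$pas_hexamer,
        pas_offset = off)
    }
    pieces[[length(pieces) + 1L]] <- gene_seq
    pieces[[length(pieces) + 1L]] <- random_dna(gap)
    cursor <- gene_end + gap
  }
  chrom_seqs[chrom] <- paste0(unlist(pieces), collapse = "")
  genome <- Biostrings::DNAStringSet(chrom_seqs)
  ann <- new_annotation(bind_rows(exon_rows))
  list(genome = genome, annotation = ann,
       polya_truth = bind_rows(polya_truth))
}

# Random DNA without A/T homopolymer runs >= 3 (every 3rd base is C or G), so
# only appended tails can form poly(A) stretches — even across a junction
# fusion point the terminal A-run of a read stays below the tag threshold.
random_dna <- function(n) {
  if (n <= 0L) return("")
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  brk <- seq(3L, n, by = 3L)
  base[brk] <- sample(c("C", "G"), length(brk), replace = TRUE)
  paste0(base, collapse = "")
}

#' Simulate reads and alignments with known ground truth
#'
#' Emits three read classes with exactly known placements: unspliced exonic
#' reads (one exon, aligned to the genome), junction-spanning reads (drawn
#' from the junction-library record sequence with both anchors >=
#' `min_anchor`, aligned to the library), and poly(A) reads (the last
#' transcribed bases before each planted cleavage site plus an untemplated
#' A-tail; trimmed-tag alignments to the genome are emitted from the known
#' placement). No aligner runs: SAM records are synthesised directly.
#'
#' @param sim Output of [simulate_annotation()].
#' @param cfg The same [sim_config()].
#' @param lib Junction library built from `sim` (default: built at L = 150).
#' @return A list with `reads` (tibble `read_id`, `seq`, `qual`),
#'   `genome_aln` / `library_aln` / `tag_aln` (alignment tibbles in
#'   [read_alignments()] layout), and `truth` (list of tibbles:
#'   `junction_counts`, `gene_counts`, `polya_sites`).
#' @export
simulate_reads <- function(sim, cfg,
                           lib = build_junction_library(sim$annotation,
                                                        sim$genome,
                                                        L = 150L)) {
  set.seed(cfg$seed + 1L)
  genome <- sim$genome
  ann <- sim$annotation
  rl <- cfg$read_len
  reads <- list(); gen_aln <- list(); lib_aln <- list(); tag_aln <- list()
  rid <- 0L
  next_id <- function(prefix) {
    rid <<- rid + 1L
    sprintf("%s_%06d", prefix, rid)
  }

  ## unspliced exonic reads: whole read inside one exon
  gene_counts <- stats::setNames(integer(length(unique(ann$gene_id))),
                                 sort(unique(ann$gene_id)))
  big_exons <- ann |> filter(.data$end - .data$start >= rl)
  for (g in names(gene_counts)) {
    ex <- big_exons |> filter(.data$gene_id == g)
    if (!nrow(ex)) next
    n <- stats::rpois(1L, cfg$reads_per_gene)
    gene_counts[g] <- n
    if (n == 0L) next
    pick <- sample(nrow(ex), n, replace = TRUE)
    offs <- vapply(pick, function(i) {
      sample(0:(ex$end[i] - ex$start[i] - rl), 1L)
    }, integer(1))
    for (j in seq_len(n)) {
      s <- ex$start[pick[j]] + offs[j]
      minus <- ex$strand[pick[j]] == "-"
      seq <- apply_errors(
        genome_seq(genome, ex$chrom[pick[j]], s, s + rl, revcomp = minus),
        cfg$error_rate)
      id <- next_id("exonic")
      reads[[id]] <- tibble(read_id = id, seq = seq, qual = strrep("I", rl))
      gen_aln[[id]] <- tibble(
        qname = id, flag = if (minus) 16L else 0L, rname = ex$chrom[pick[j]],
        pos = s, mapq = 60L, cigar = paste0(rl, "M"),
        seq = if (minus) revcomp_chr(seq) else seq)
    }
  }

  ## junction-spanning reads aligned to the library
  known <- lib |> filter(.data$category == "known",
                         .data$up_len >= cfg$min_anchor,
                         .data$down_len >= cfg$min_anchor,
                         .data$up_len + .data$down_len >= rl)
  n_jx <- round(cfg$frac_junction * nrow(known))
  jx_counts <- tibble(junction_id = character(), count = integer())
  if (n_jx > 0L) {
    sel <- known[sample(nrow(known), n_jx), ]
    planted <- sample(seq(cfg$junction_read_range[1L],
                          cfg$junction_read_range[2L]),
                      n_jx, replace = TRUE)
    for (j in seq_len(n_jx)) {
      fp <- sel$up_len[j]
      tot <- sel$up_len[j] + sel$down_len[j]
      lo <- max(0L, fp + cfg$min_anchor - rl)
      hi <- min(fp - cfg$min_anchor, tot - rl)
      for (r in seq_len(planted[j])) {
        s <- if (hi > lo) sample(lo:hi, 1L) else lo
        seq <- apply_errors(substr(sel$sequence[j], s + 1L, s + rl),
                            cfg$error_rate)
        id <- next_id("jx")
        reads[[id]] <- tibble(read_id = id, seq = seq,
                              qual = strrep("I", rl))
        lib_aln[[id]] <- tibble(
          qname = id, flag = 0L, rname = sel$junction_id[j], pos = s,
          mapq = 60L, cigar = paste0(rl, "M"), seq = seq)
      }
    }
    jx_counts <- tibble(junction_id = sel$junction_id, count = planted)
  }

  ## poly(A) reads: last (rl - tail_len) transcribed bases + A-tail
  polya_truth <- sim$polya_truth
  if (!is.null(polya_truth) && nrow(polya_truth)) {
    body_len <- rl - cfg$tail_len
    for (i in seq_len(nrow(polya_truth))) {
      st <- polya_truth$strand[i]
      cp <- polya_truth$cleavage_pos[i]
      if (st == "+") { s <- cp + 1L - body_len; e <- cp + 1L }
      else { s <- cp; e <- cp + body_len }
      body <- genome_seq(genome, polya_truth$chrom[i], s, e,
                         revcomp = st == "-")
      for (r in seq_len(cfg$polya_tags_per_site)) {
        id <- next_id("polyA")
        seq <- paste0(apply_errors(body, cfg$error_rate),
                      strrep("A", cfg$tail_len))
        reads[[id]] <- tibble(read_id = id, seq = seq,
                              qual = strrep("I", rl))
        # alignment of the *trimmed* tag, from the known placement
        tag_aln[[id]] <- tibble(
          qname = id, flag = if (st == "-") 16L else 0L,
          rname = polya_truth$chrom[i], pos = s, mapq = 60L,
          cigar = paste0(body_len, "M"),
          seq = if (st == "-") revcomp_chr(substr(seq, 1L, body_len))
                else substr(seq, 1L, body_len))
      }
    }
  }

  finish <- function(x) {
    if (!length(x)) {
      return(tibble(qname = character(), flag = integer(),
                    rname = character(), pos = integer(), mapq = integer(),
                    cigar = character(), seq = character(),
                    unmapped = logical(), secondary = logical(),
                    reverse = logical(), end = integer()))
    }
    bind_rows(x) |>
      mutate(unmapped = FALSE, secondary = FALSE,
             reverse = bitwAnd(.data$flag, 16L) > 0L,
             end = .data$pos + cigar_ref_width(.data$cigar, .data$unmapped))
  }
  truth_sites <- if (!is.null(polya_truth) && nrow(polya_truth)) {
    polya_truth |> mutate(n_tags = cfg$polya_tags_per_site)
  } else {
    tibble(gene_id = character(), chrom = character(), strand = character(),
           cleavage_pos = integer(), pas_hexamer = character(),
           pas_offset = integer(), n_tags = integer())
  }
  list(
    reads = bind_rows(reads),
    genome_aln = finish(gen_aln),
    library_aln = finish(lib_aln),
    tag_aln = finish(tag_aln),
    truth = list(
      junction_counts = jx_counts,
      gene_counts = tibble(gene_id = names(gene_counts),
                           count = unname(gene_counts)),
      polya_sites = truth_sites)
  )
}

apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste0(ch, collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate per-trio isoform support counts at a true inclusion fraction
#'
#' Draws `n` reads from a two-isoform mixture with length-proportional
#' sampling: a read originates from the inclusion isoform with probability
#' `psi * len_inc / (psi * len_inc + (1 - psi) * len_skip)`, so the
#' length-normalised estimator of [estimate_inclusion()] is consistent for
#' `psi`.
#'
#' @param psi True inclusion fraction in \[0, 1\].
#' @param n Total supporting reads.
#' @param len_inc,len_skip Isoform lengths in bp.
#' @return A one-row tibble `n_inc`, `n_skip`.
#' @export
simulate_trio_counts <- function(psi, n, len_inc, len_skip) {
  p <- psi * len_inc / (psi * len_inc + (1 - psi) * len_skip)
  n_inc <- stats::rbinom(1L, n, p)
  tibble(n_inc = n_inc, n_skip = n - n_inc)
}

#' Write a full simulated fixture set to disk
#'
#' Convenience wrapper emitting genome FASTA, annotation GTF, reads FASTQ,
#' the three SAM files and the ground-truth TSV bundle under `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param L Junction-library boundary length.
#' @return Invisibly, a named list of the paths written.
#' @export
write_simulation <- function(cfg, dir, L = 150L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_annotation(cfg)
  lib <- build_junction_library(sim$annotation, sim$genome, L = L)
  rd <- simulate_reads(sim, cfg, lib = lib)
  p <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    library = file.path(dir, "junctions.fa"),
    fastq = file.path(dir, "reads.fastq"),
    genome_sam = file.path(dir, "genome.sam"),
    library_sam = file.path(dir, "library.sam"),
    tags_sam = file.path(dir, "tags.sam"),
    truth_junctions = file.path(dir, "truth_junctions.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_polya = file.path(dir, "truth_polya.tsv"))
  Biostrings::writeXStringSet(sim$genome, p$genome)
  write_gtf(sim$annotation, p$gtf)
  write_junction_fasta(lib, p$library)
  write_fastq(rd$reads, p$fastq)
  refs_g <- stats::setNames(Biostrings::width(sim$genome),
                            names(sim$genome))
  refs_l <- stats::setNames(nchar(lib$sequence), lib$junction_id)
  write_sam(rd$genome_aln, refs_g, p$genome_sam)
  write_sam(rd$library_aln, refs_l, p$library_sam)
  write_sam(rd$tag_aln, refs_g, p$tags_sam)
  readr::write_tsv(rd$truth$junction_counts, p$truth_junctions)
  readr::write_tsv(rd$truth$gene_counts, p$truth_genes)
  readr::write_tsv(rd$truth$polya_sites, p$truth_polya)
  invisible(p)
}
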
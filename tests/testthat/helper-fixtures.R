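# Shared fixture builders. Everything is generated in code; nothing binary.

# Write a GTF from exon rows (1-based inclusive coords as GTF requires).
write_toy_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    rows$chrom, rows$start1, rows$end1, rows$strand, rows$gene_id,
    rows$transcript_id)
  writeLines(lines, path)
  path
}

# Annotation tibble from 0-based half-open exon coordinates.
make_annotation <- function(transcript_id, gene_id, chrom, strand, start,
                            end) {
  rows <- tibble::tibble(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, start1 = start + 1L, end1 = end)
  read_gtf(write_toy_gtf(rows))
}

# A transcript with k exons of the given lengths separated by fixed introns.
make_transcript_ann <- function(k, exon_len = 100L, intron_len = 50L,
                                strand = "+", chrom = "chr1", offset = 1000L,
                                tid = "T1", gid = "G1") {
  exon_len <- rep_len(exon_len, k)
  starts <- integer(k)
  pos <- offset
  for (i in seq_len(k)) {
    starts[i] <- pos
    pos <- pos + exon_len[i] + intron_len
  }
  make_annotation(rep(tid, k), rep(gid, k), rep(chrom, k), rep(strand, k),
                  starts, starts + exon_len)
}

# Deterministic toy genome long enough for the default fixtures.
make_toy_genome <- function(len = 10000L, chrom = "chr1", seed = 99L) {
  withr::with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  })
  g <- Biostrings::DNAStringSet(paste0(bases, collapse = ""))
  names(g) <- chrom
  g
}

# Minimal alignment tibble in read_alignments() layout.
make_aln <- function(qname, rname, pos, cigar, flag = 0L,
                     seq = strrep("N", 10L)) {
  tibble::tibble(
    qname = qname, flag = flag, rname = rname, pos = as.integer(pos),
    mapq = 60L, cigar = cigar, seq = seq,
    unmapped = bitwAnd(flag, 4L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    end = as.integer(pos) + ifelse(bitwAnd(flag, 4L) > 0L, 0L,
      GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)))
}

# Brute-force per-position oracle for the intersection-nonempty rule.
oracle_assign <- function(blocks, features) {
  pos <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    seq.int(blocks$start[i], blocks$end[i] - 1L)
  }))
  sets <- lapply(pos, function(p) {
    features$gene_id[features$start <= p & p < features$end]
  })
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets)) return(list(status = "no_feature",
                                 gene_id = NA_character_))
  inter <- Reduce(intersect, sets)
  if (length(inter) == 1L) list(status = "assigned", gene_id = inter)
  else list(status = "ambiguous", gene_id = NA_character_)
}
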
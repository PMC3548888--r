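# Shared synthetic fixtures, built in code at test time.

# Two-isoform locus: TXa has a private middle exon, TXb skips it.
fx_two_isoforms <- function(seed = 101L) {
  gen <- generate_genome(c(chr1 = 400L), seed = seed)
  txs <- generate_transcriptome(list(list(
    gene_id = "G1", chrom = "chr1", start = 50L, strand = "+",
    exon_lengths = c(40L, 30L, 40L), intron_lengths = c(20L, 20L),
    isoforms = list(TXa = 1:3, TXb = c(1L, 3L)))))
  list(genome = gen$sequences, transcripts = txs)
}

# Two byte-identical single-exon transcripts annotated at one locus.
fx_identical_isoforms <- function(seed = 202L) {
  gen <- generate_genome(c(chr1 = 300L), seed = seed)
  txs <- generate_transcriptome(list(list(
    gene_id = "G1", chrom = "chr1", start = 80L, strand = "+",
    exon_lengths = 60L,
    isoforms = list(TX1 = 1L, TX2 = 1L))))
  list(genome = gen$sequences, transcripts = txs)
}

# Two identical paralogs: a 150 bp segment present at two loci, each
# wrapped in a single-exon transcript with 60 bp of unique flank on
# both sides. A mate anchored in a flank rescues fragments whose other
# mate lies inside the shared segment.
fx_paralogs <- function(seed = 303L, copy_len = 150L, flank = 60L) {
  u1 <- random_seq(250, seed * 7L + 1L)
  rep_seg <- random_seq(copy_len, seed * 7L + 2L)
  u2 <- random_seq(250, seed * 7L + 3L)
  u3 <- random_seq(250, seed * 7L + 4L)
  chr <- paste0(u1, rep_seg, u2, rep_seg, u3)
  c1 <- 250L
  c2 <- 250L + copy_len + 250L
  txs <- list(
    P1 = transcript_model("P1", "geneA", "chr1", "+",
                          data.frame(start = c1 - flank,
                                     end = c1 + copy_len + flank)),
    P2 = transcript_model("P2", "geneB", "chr1", "+",
                          data.frame(start = c2 - flank,
                                     end = c2 + copy_len + flank)))
  list(genome = c(chr1 = chr),
       repeat_map = data.frame(family = 1L, chrom = "chr1",
                               start = c(c1, c2),
                               end = c(c1, c2) + copy_len),
       transcripts = txs)
}

make_mul_set <- function(arrays, value_width = 1L) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_mul_files(arrays, dir, value_width = value_width)
}

# Expression panel: three single-exon genes with planted unique
# proportions ~1.0 / ~0.5 / ~0.2 (the trailing part of genes 2 and 3 is
# duplicated in an intergenic region). `read_txs` extend each gene by
# read_length - 1 bases so that uniform read starts cover exactly the
# gene body.
fx_expression_panel <- function(read_length = 20L, seed = 404L) {
  blk <- function(n, k) random_seq(n, seed * 13L + k)
  dup2 <- blk(250L, 5L)
  dup3 <- blk(400L, 6L)
  parts <- list(junk1 = blk(300L, 1L),
                g1 = blk(500L, 2L),
                sp1 = blk(100L, 3L),
                g2 = paste0(blk(250L, 4L), dup2),
                sp2 = blk(100L, 7L),
                g3 = paste0(blk(100L, 8L), dup3),
                sp3 = blk(100L, 9L),
                copy2 = dup2,
                sp4 = blk(100L, 10L),
                copy3 = dup3,
                junk2 = blk(200L, 11L))
  lens <- vapply(parts, nchar, 0L)
  offs <- cumsum(c(0L, utils::head(lens, -1L)))
  names(offs) <- names(parts)
  chr <- paste(unlist(parts), collapse = "")
  gene_txs <- list()
  read_txs <- list()
  for (g in c("g1", "g2", "g3")) {
    id <- toupper(g)
    s <- offs[[g]]
    e <- s + lens[[g]]
    gene_txs[[id]] <- transcript_model(id, id, "chr1", "+",
                                       data.frame(start = s, end = e))
    read_txs[[paste0(id, "r")]] <- transcript_model(
      paste0(id, "r"), id, "chr1", "+",
      data.frame(start = s, end = e + read_length - 1L))
  }
  list(genome = c(chr1 = chr), gene_txs = gene_txs, read_txs = read_txs,
       read_length = read_length)
}
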
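test_that("refFlat and BED12 parse to equivalent half-open exon models", {
  rf <- withr::local_tempfile(fileext = ".refflat")
  writeLines(paste("G1", "TX1", "chrA", "+", 10, 19, 10, 19, 2,
                   "10,16,", "13,19,", sep = "\t"), rf)
  m1 <- parse_annotation(rf, "refFlat")$TX1
  expect_equal(m1$exons, data.frame(start = c(10L, 16L), end = c(13L, 19L)))
  expect_equal(m1$spliced_length, 6L)
  expect_equal(m1$gene_id, "G1")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chrA", 10, 19, "TX1", 0, "+", 10, 19, "0", 2,
                   "3,3,", "0,6,", sep = "\t"), bed)
  m2 <- parse_annotation(bed, "BED12")$TX1
  expect_equal(m2$exons, m1$exons)

  # single-exon refFlat
  rf2 <- withr::local_tempfile()
  writeLines(paste("G2", "TX2", "chrA", "-", 5, 9, 5, 9, 1,
                   "5,", "9,", sep = "\t"), rf2)
  expect_equal(parse_annotation(rf2, "refFlat")$TX2$spliced_length, 4L)
})

test_that("malformed annotation lines fail with the offending line number", {
  bad <- withr::local_tempfile()
  writeLines(c(paste("G1", "TX1", "c", "+", 0, 4, 0, 4, 1, "0,", "4,",
                     sep = "\t"),
               paste("G2", "TX2", "c", "+", 0, 9, 0, 9, 2, "0,6,", "4,",
                     sep = "\t")), bad)
  expect_error(parse_annotation(bad, "refFlat"), "line 2")

  unsorted <- withr::local_tempfile()
  writeLines(paste("G1", "TX1", "c", "+", 0, 20, 0, 20, 2,
                   "10,0,", "15,4,", sep = "\t"), unsorted)
  expect_error(parse_annotation(unsorted, "refFlat"), "sorted")

  overlapping <- withr::local_tempfile()
  writeLines(paste("c", 0, 20, "TX", 0, "+", 0, 20, "0", 2,
                   "10,10,", "0,5,", sep = "\t"), overlapping)
  expect_error(parse_annotation(overlapping, "BED12"), "line 1")
})

test_that("BED12 reader agrees with rtracklayer on generated annotations", {
  skip_if_not_installed("rtracklayer")
  fx <- fx_two_isoforms()
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed12(fx$transcripts, bed)
  ours <- parse_annotation(bed, "BED12")
  ref <- rtracklayer::import(bed, format = "bed")
  for (i in seq_along(ref)) {
    id <- ref$name[i]
    blocks <- ref$blocks[[i]]
    # rtracklayer reports 1-based block coordinates
    expect_equal(ours[[id]]$exons$start,
                 BiocGenerics::start(blocks) +
                   BiocGenerics::start(ref)[i] - 2L)
    expect_equal(ours[[id]]$exons$end - ours[[id]]$exons$start,
                 BiocGenerics::width(blocks))
  }
})

test_that("spliced sequences concatenate exons in transcript orientation", {
  g <- c(chr = "AAACCCGGGTTT")
  plus <- transcript_model("t", "g", "chr", "+",
                           data.frame(start = c(0, 9), end = c(3, 12)))
  expect_equal(extract_spliced_sequence(g, plus), "AAATTT")
  minus <- transcript_model("t", "g", "chr", "-",
                            data.frame(start = 0, end = 3))
  expect_equal(extract_spliced_sequence(g, minus), "TTT")
  out <- transcript_model("t", "g", "chr", "+",
                          data.frame(start = 6, end = 13))
  expect_error(extract_spliced_sequence(g, out), "bounds")
  expect_error(transcript_model("t", "g", "chr", "+",
                                data.frame(start = integer(),
                                           end = integer())),
               "at least one exon")
})

test_that("transcript-to-genome collapsing handles junctions and strand", {
  tx <- transcript_model("T1", "G1", "chr", "+",
                         data.frame(start = c(10, 16), end = c(13, 19)))
  j <- transcript_to_genomic(tx, 2, 2)  # spans the junction
  expect_equal(c(j$genomic_start, j$genomic_end), c(12L, 17L))
  expect_equal(unlist(transcript_to_genomic(tx, 0, 1)[2:3],
                      use.names = FALSE), c(10L, 11L))

  txm <- transcript_model("T1", "G1", "chr", "-",
                          data.frame(start = c(10, 16), end = c(13, 19)))
  r <- transcript_to_genomic(txm, 0, 1)  # 5' end of a minus transcript
  expect_equal(c(r$genomic_start, r$genomic_end), c(18L, 19L))
  expect_error(transcript_to_genomic(tx, 5, 2), "outside")
})

test_that("read classification applies the start/end locus rules", {
  same <- data.frame(genomic_start = 100L, genomic_end = 125L,
                     source = c("T1", "T2", "genome"))
  expect_equal(classify_read(same), "transcript_unique")
  expect_equal(classify_read(same, "single_source"), "gene_unique")

  expect_equal(classify_read(data.frame(genomic_start = c(100L, 300L),
                                        genomic_end = c(125L, 325L),
                                        source = c("T1", "T3"))),
               "multimapping")
  expect_equal(classify_read(data.frame(genomic_start = c(100L, 100L),
                                        genomic_end = c(125L, 140L),
                                        source = c("T1", "T2"))),
               "gene_unique")
  expect_equal(classify_read(data.frame(genomic_start = integer(),
                                        genomic_end = integer(),
                                        source = character())),
               "unmapped")
  # same coordinates on different chromosomes are different loci
  expect_equal(classify_read(data.frame(chrom = c("c1", "c2"),
                                        genomic_start = 100L,
                                        genomic_end = 125L,
                                        source = "genome")),
               "multimapping")
})

test_that("identical isoforms are gene-unique but not single-source unique", {
  fx <- fx_identical_isoforms()
  gene <- compute_transcript_mul(fx$genome, fx$transcripts, "TX1",
                                 level = "gene", kmin = 10, kmax = 30)
  expect_true(any(gene$values > 0L))
  ss <- compute_transcript_mul(fx$genome, fx$transcripts, "TX1",
                               level = "transcript", kmin = 10, kmax = 30,
                               transcript_rule = "single_source")
  expect_true(all(ss$values == 0L))
  # under the coordinate rule the copies collapse to one locus
  coord <- compute_transcript_mul(fx$genome, fx$transcripts, "TX1",
                                  level = "transcript", kmin = 10, kmax = 30)
  expect_equal(coord$values, gene$values)
})

test_that("private exons give transcript-level uniqueness, shared exons do not", {
  fx <- fx_two_isoforms()
  txa <- compute_transcript_mul(fx$genome, fx$transcripts, "TXa",
                                level = "transcript", kmin = 8, kmax = 30,
                                transcript_rule = "single_source")
  # TXa exons: 40 shared + 30 private + 40 shared; windows inside the
  # private exon identify TXa alone
  private <- 41:60  # deep inside the private exon (transcript coords)
  expect_true(any(txa$values[private] > 0L))
  # windows confined to the first shared exon also occur in TXb
  shared <- 1:10
  expect_true(all(txa$values[shared] == 0L))
})

test_that("duplicated loci destroy both uniqueness levels", {
  fx <- fx_paralogs()
  res <- compute_transcript_mul(fx$genome, fx$transcripts, "P1",
                                level = "gene", kmin = 10, kmax = 25)
  # transcript coords 60..209 sit inside the duplicated segment; windows
  # whose kmax-reach stays inside it can never be unique
  interior <- 61:(210 - 25)
  expect_true(all(res$values[interior] == 0L))
  # flanks are unique background
  expect_true(any(res$values[1:40] > 0L))
})

test_that("junction-spanning windows can be unique without a genomic match", {
  fx <- fx_two_isoforms()
  # TXb skips the middle exon: its junction sequence exon1|exon3 is
  # absent from the genome as a contiguous string
  txb <- compute_transcript_mul(fx$genome, fx$transcripts, "TXb",
                                level = "transcript", kmin = 8, kmax = 30,
                                transcript_rule = "single_source")
  junction <- 36:40  # windows starting here span the exon1/exon3 junction
  expect_true(any(txb$values[junction] > 0L))
  idx <- occurrence_index(fx$genome)
  comb <- occurrence_index(c(fx$genome,
    TXa = extract_spliced_sequence(fx$genome, fx$transcripts$TXa),
    TXb = extract_spliced_sequence(fx$genome, fx$transcripts$TXb)))
  spliced_b <- extract_spliced_sequence(fx$genome, fx$transcripts$TXb)
  p <- junction[which(txb$values[junction] > 0L)[1]]
  w <- substr(spliced_b, p, p + txb$values[p] - 1L)
  expect_equal(count_occurrences(idx, w), 0L)    # not in the genome
  expect_equal(count_occurrences(comb, w), 1L)   # once, in TXb itself
})

test_that("gene-level uniqueness dominates transcript-level uniqueness", {
  for (fx in list(fx_two_isoforms(), fx_identical_isoforms())) {
    for (id in names(fx$transcripts)) {
      g <- compute_transcript_mul(fx$genome, fx$transcripts, id,
                                  level = "gene", kmin = 8, kmax = 25)$values
      t <- compute_transcript_mul(fx$genome, fx$transcripts, id,
                                  level = "transcript", kmin = 8, kmax = 25,
                                  transcript_rule = "single_source")$values
      expect_true(all(which(t > 0L) %in% which(g > 0L)))
      both <- t > 0L & g > 0L
      expect_true(all(g[both] <= t[both]))
    }
  }
})

test_that("a lone single-exon transcript reproduces the genomic MUL over its exon", {
  gen <- generate_genome(c(chr1 = 300L), seed = 7L)
  txs <- generate_transcriptome(list(list(
    gene_id = "G", chrom = "chr1", start = 100L, strand = "+",
    exon_lengths = 80L, isoforms = list(TX = 1L))))
  gmul <- compute_mul_array(occurrence_index(gen$sequences), "chr1",
                            kmin = 10, kmax = 40)
  tmul <- compute_transcript_mul(gen$sequences, txs, "TX", level = "gene",
                                 kmin = 10, kmax = 40)
  # positions whose windows stay inside the exon must agree
  inside <- 1:(80 - 40)
  expect_equal(tmul$values[inside], gmul$values[100L + inside])
})

test_that("transcript overlap counts reflect locus sharing", {
  shared <- generate_transcriptome(list(list(
    gene_id = "G", chrom = "c", start = 0L, strand = "+",
    exon_lengths = c(10L, 10L), intron_lengths = 5L,
    isoforms = list(A = 1:2, B = 1L))))
  expect_equal(count_overlaps(shared), c(A = 1L, B = 1L))

  disjoint <- list(
    X = transcript_model("X", "gx", "c", "+", data.frame(start = 0, end = 10)),
    Y = transcript_model("Y", "gy", "c", "+", data.frame(start = 50, end = 60)))
  expect_equal(count_overlaps(disjoint), c(X = 0L, Y = 0L))

  nested <- generate_transcriptome(list(list(
    gene_id = "G", chrom = "c", start = 0L, strand = "+",
    exon_lengths = c(10L, 10L, 10L), intron_lengths = c(5L, 5L),
    isoforms = list(A = 1:3, B = 1:2, C = 1L))))
  expect_equal(count_overlaps(nested), c(A = 2L, B = 2L, C = 2L))
})
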
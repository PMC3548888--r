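# MUL-corrected RPKM quantification. Only uniquely mapped reads are
# counted; the lost coverage over non-unique positions is compensated
# by replacing the gene-model length with its effective length (the
# number of uniquely mappable positions at the read length).

#' Build gene models from transcript annotations
#'
#' Merges each gene's exons into a disjoint interval union. With
#' `rmnameoverlap = TRUE` (default), bases belonging to the exon union
#' of more than one gene id are removed from every gene, so reads from
#' shared exons are not attributed ambiguously.
#'
#' @param transcripts List of [transcript_model()]s.
#' @param rmnameoverlap Remove exon-union bases shared between
#'   different genes?
#' @return Named list of `GeneModel` objects (gene_id, chrom, strand,
#'   `intervals` data frame of half-open 0-based intervals,
#'   `raw_length`).
#' @export
gene_models <- function(transcripts, rmnameoverlap = TRUE) {
  gene_ids <- vapply(transcripts, `[[`, "", "gene_id")
  gr <- GenomicRanges::GRanges(
    seqnames = rep(vapply(transcripts, `[[`, "", "chrom"),
                   vapply(transcripts, function(t) nrow(t$exons), 0L)),
    ranges = IRanges::IRanges(
      start = unlist(lapply(transcripts, function(t) t$exons$start)) + 1L,
      end = unlist(lapply(transcripts, function(t) t$exons$end))),
    gene = rep(gene_ids, vapply(transcripts, function(t) nrow(t$exons), 0L)))
  out <- list()
  for (g in unique(gene_ids)) {
    own <- GenomicRanges::reduce(gr[gr$gene == g])
    if (rmnameoverlap) {
      other <- GenomicRanges::reduce(gr[gr$gene != g])
      own <- GenomicRanges::setdiff(own, other, ignore.strand = TRUE)
    }
    if (length(own) == 0L) {
      warning("gene ", g, " has no private exonic bases left; dropped")
      next
    }
    strand <- unique(vapply(transcripts[gene_ids == g], `[[`, "", "strand"))
    out[[g]] <- structure(
      list(gene_id = g,
           chrom = as.character(GenomicRanges::seqnames(own))[1],
           strand = if (length(strand) == 1L) strand else "*",
           intervals = data.frame(start = GenomicRanges::start(own) - 1L,
                                  end = GenomicRanges::end(own)),
           raw_length = sum(GenomicRanges::width(own))),
      class = "GeneModel")
  }
  out
}

cigar_ref_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1L) stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^\\d+", "", toks)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Read uniquely-mapped single-end alignments (SAM or BED6)
#'
#' Returns one row per mapped read with the 0-based coordinate of its
#' 5'-most aligned base (for minus-strand reads, the rightmost aligned
#' reference base, CIGAR-aware for SAM). Unmapped SAM records (flag
#' 0x4) are skipped and counted in the `skipped_unmapped` attribute.
#'
#' @param path Path to the alignment file.
#' @param format `"SAM"` or `"BED"` (BED6).
#' @return Data frame with `chrom`, `pos5` (0-based), `strand`.
#' @export
read_alignments <- function(path, format = c("SAM", "BED")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "SAM") {
    lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
    chrom <- character(length(lines))
    pos5 <- integer(length(lines))
    strand <- character(length(lines))
    keep <- logical(length(lines))
    skipped <- 0L
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 11L) {
        stop("malformed SAM record ", i, ": expected >= 11 fields")
      }
      flag <- as.integer(f[2])
      if (is.na(flag)) stop("malformed SAM record ", i, ": bad FLAG")
      if (bitwAnd(flag, 4L) > 0L) { skipped <- skipped + 1L; next }
      rev <- bitwAnd(flag, 16L) > 0L
      pos0 <- as.integer(f[4]) - 1L
      chrom[i] <- f[3]
      strand[i] <- if (rev) "-" else "+"
      pos5[i] <- if (rev) pos0 + cigar_ref_width(f[6]) - 1L else pos0
      keep[i] <- TRUE
    }
    out <- data.frame(chrom = chrom[keep], pos5 = pos5[keep],
                      strand = strand[keep])
    attr(out, "skipped_unmapped") <- skipped
    out
  } else {
    lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                     !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 6L)
    if (length(bad)) stop("malformed BED6 record ", bad[1])
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.integer(vapply(fields, `[[`, "", 2L))
    end <- as.integer(vapply(fields, `[[`, "", 3L))
    strand <- vapply(fields, `[[`, "", 6L)
    out <- data.frame(chrom = chrom,
                      pos5 = ifelse(strand == "-", end - 1L, start),
                      strand = strand)
    attr(out, "skipped_unmapped") <- 0L
    out
  }
}

#' Count uniquely mapped reads per gene
#'
#' A read is assigned to a gene iff its 5'-most aligned base falls
#' inside the gene's exon union; `total_mapped` counts every mapped
#' read in the file whether or not it was assigned (so sequencing depth
#' is normalized against all mapped reads).
#'
#' @param alignments Data frame from [read_alignments()].
#' @param models Gene models from [gene_models()].
#' @return List with `counts` (named integer vector) and
#'   `total_mapped`.
#' @export
count_unique_reads <- function(alignments, models) {
  counts <- setNames(integer(length(models)), names(models))
  for (g in names(models)) {
    m <- models[[g]]
    on_chrom <- alignments$chrom == m$chrom
    if (!any(on_chrom)) next
    p <- alignments$pos5[on_chrom]
    inside <- rep(FALSE, length(p))
    for (k in seq_len(nrow(m$intervals))) {
      inside <- inside |
        (p >= m$intervals$start[k] & p < m$intervals$end[k])
    }
    counts[g] <- sum(inside)
  }
  list(counts = counts, total_mapped = nrow(alignments))
}

#' Effective length of a gene model at a read length
#'
#' Counts the exon-union positions whose stored MUL value is nonzero
#' and at most `read_length` — the positions where a read of that
#' length maps uniquely. Read lengths above the stored `kmax` are
#' computed at `kmax` with a warning.
#'
#' @param model A `GeneModel` from [gene_models()].
#' @param mul_files A [mul_file_set()] covering the gene's chromosome
#'   (gene-level transcriptome uniqueness superimposed on genomic
#'   uniqueness, or plain genomic uniqueness).
#' @param read_length Read length in nt.
#' @return Effective length in nt (0 means unquantifiable).
#' @export
effective_length <- function(model, mul_files, read_length) {
  arr <- set_array(mul_files, model$chrom)
  if (read_length > arr$kmax) {
    warning("read_length ", read_length, " above stored kmax ", arr$kmax,
            "; effective length computed at ", arr$kmax)
    read_length <- arr$kmax
  }
  if (read_length < arr$kmin) {
    stop("read_length ", read_length, " below stored kmin ", arr$kmin)
  }
  total <- 0L
  for (k in seq_len(nrow(model$intervals))) {
    v <- arr$values[(model$intervals$start[k] + 1L):model$intervals$end[k]]
    total <- total + sum(v > 0L & v <= read_length)
  }
  total
}

#' Reads per kilobase of model per million mapped reads
#'
#' `rpkm = read_count * 1e9 / (length_nt * total_mapped)`.
#'
#' @param read_count Reads assigned to the gene.
#' @param length_nt Gene-model length (raw or effective).
#' @param total_mapped Total mapped reads in the library.
#' @return RPKM value.
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
#' @export
rpkm <- function(read_count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop("length_nt must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  read_count * 1e9 / (length_nt * total_mapped)
}

#' Quantify gene expression with and without MUL correction
#'
#' Combines read counting, raw length and effective length into per-gene
#' expression records: `raw_rpkm` uses the raw exon-union length,
#' `norm_rpkm` the effective (uniquely mappable) length. Genes with
#' effective length 0 get `NA` for `norm_rpkm` and `ratio`.
#'
#' @param alignments Data frame from [read_alignments()].
#' @param models Gene models from [gene_models()].
#' @param mul_files A [mul_file_set()].
#' @param read_length Read length of the library.
#' @return Data frame with `gene_id`, `read_count`, `raw_length`,
#'   `effective_length`, `raw_rpkm`, `norm_rpkm`, `ratio`
#'   (= norm/raw = raw_length/effective_length).
#' @export
quantify_expression <- function(alignments, models, mul_files, read_length) {
  cu <- count_unique_reads(alignments, models)
  if (cu$total_mapped == 0L) stop("no mapped reads; RPKM undefined")
  eff <- vapply(models, effective_length, 0L, mul_files = mul_files,
                read_length = read_length)
  raw_len <- vapply(models, `[[`, 0L, "raw_length")
  raw <- rpkm(cu$counts, raw_len, cu$total_mapped)
  norm <- ifelse(eff > 0L,
                 cu$counts * 1e9 / (eff * cu$total_mapped), NA_real_)
  data.frame(gene_id = names(models), read_count = as.integer(cu$counts),
             raw_length = raw_len, effective_length = as.integer(eff),
             raw_rpkm = raw, norm_rpkm = norm,
             ratio = ifelse(eff > 0L, raw_len / eff, NA_real_),
             row.names = NULL)
}

#' Summarize the effect of uniqueness compensation
#'
#' Per-gene norm/raw RPKM ratio (algebraically `raw_length /
#' effective_length`, so the ratio-versus-unique-proportion relation is
#' exactly `y = 1/x` for this estimator) plus an optional log2-binned
#' histogram of the ratios. Genes with no uniquely mappable position
#' are reported separately.
#'
#' @param records Data frame from [quantify_expression()].
#' @param bins Histogram breaks on log2(ratio); `NULL` for none.
#' @return List with `ratios` (gene_id, ratio, unique_proportion),
#'   `unquantifiable` (gene ids with effective length 0), and
#'   `histogram` (data frame of bin mid and count, or `NULL`).
#' @export
compare_raw_norm <- function(records, bins = NULL) {
  quant <- records[records$effective_length > 0L, , drop = FALSE]
  ratios <- data.frame(gene_id = quant$gene_id,
                       ratio = quant$raw_length / quant$effective_length,
                       unique_proportion =
                         quant$effective_length / quant$raw_length)
  hist_df <- NULL
  if (!is.null(bins)) {
    h <- hist(log2(ratios$ratio), breaks = bins, plot = FALSE)
    hist_df <- data.frame(log2_ratio_mid = h$mids, count = h$counts)
  }
  list(ratios = ratios,
       unquantifiable = records$gene_id[records$effective_length == 0L],
       histogram = hist_df)
}
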
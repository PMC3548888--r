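# Spliced-transcript handling: annotation parsing, spliced sequence
# extraction, transcript <-> genome coordinate maps, and gene-level /
# transcript-level uniqueness of transcriptome reads. Coordinates are
# 0-based half-open internally (refFlat and BED12 both store 0-based
# starts, so both parse without shifting).

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame (or 2-column matrix) of genomic `start`,
#'   `end` half-open intervals, non-overlapping, sorted by start.
#' @return An object of class `TranscriptModel`, with the spliced
#'   length in `$spliced_length`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  exons <- as.data.frame(exons)
  if (ncol(exons) < 2L) stop("exons need start and end columns")
  names(exons)[1:2] <- c("start", "end")
  if (nrow(exons) == 0L) stop("transcript must have at least one exon")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(exons$end <= exons$start)) stop("empty or inverted exon interval")
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("exons must be sorted by start and non-overlapping")
  }
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 chrom = as.character(chrom), strand = strand,
                 exons = exons[, c("start", "end")],
                 spliced_length = sum(exons$end - exons$start)),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%s %d exon(s), %d bp spliced\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$spliced_length))
  invisible(x)
}

parse_int_list <- function(x) {
  as.integer(strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1]])
}

#' Parse transcript annotations (refFlat or BED12)
#'
#' refFlat rows carry `geneName`, `name`, `chrom`, `strand`, tx/cds
#' bounds, and comma-separated `exonStarts`/`exonEnds` (0-based starts,
#' exclusive ends). BED12 rows carry `chromStart` plus block sizes and
#' block starts relative to `chromStart`; the `name` field is used as
#' both transcript and gene identifier (BED12 has no gene field).
#'
#' @param path Path to the annotation file.
#' @param format `"refFlat"` or `"BED12"`.
#' @return A named list of [transcript_model()]s keyed by transcript id.
#' @export
parse_annotation <- function(path, format = c("refFlat", "BED12")) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  models <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    m <- tryCatch({
      if (format == "refFlat") {
        if (length(f) < 11L) stop("expected 11 fields, got ", length(f))
        starts <- parse_int_list(f[10])
        ends <- parse_int_list(f[11])
        n <- as.integer(f[9])
        if (length(starts) != n || length(ends) != n) {
          stop("exonStarts/exonEnds length does not match exonCount")
        }
        transcript_model(f[2], f[1], f[3], f[4],
                         data.frame(start = starts, end = ends))
      } else {
        if (length(f) < 12L) stop("expected 12 fields, got ", length(f))
        chrom_start <- as.integer(f[2])
        n <- as.integer(f[10])
        sizes <- parse_int_list(f[11])
        offs <- parse_int_list(f[12])
        if (length(sizes) != n || length(offs) != n) {
          stop("blockSizes/blockStarts length does not match blockCount")
        }
        transcript_model(f[4], f[4], f[1], f[6],
                         data.frame(start = chrom_start + offs,
                                    end = chrom_start + offs + sizes))
      }
    }, error = function(e) {
      stop("malformed ", format, " line ", i, ": ", conditionMessage(e),
           call. = FALSE)
    })
    models[[m$transcript_id]] <- m
  }
  models
}

#' Extract the spliced sequence of a transcript
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' the result for minus-strand transcripts, so the returned string reads
#' 5' to 3' in transcript orientation.
#'
#' @param genome Named sequences (as for [occurrence_index()]).
#' @param transcript A [transcript_model()].
#' @return A DNA string of length `transcript$spliced_length`.
#' @export
extract_spliced_sequence <- function(genome, transcript) {
  seqs <- as_sequences(genome)
  if (!transcript$chrom %in% names(seqs)) {
    stop("chromosome not in genome: ", transcript$chrom)
  }
  chrom <- seqs[[transcript$chrom]]
  if (any(transcript$exons$end > nchar(chrom)) ||
      any(transcript$exons$start < 0L)) {
    stop("exon outside chromosome bounds for ", transcript$transcript_id)
  }
  pieces <- substring(chrom, transcript$exons$start + 1L, transcript$exons$end)
  s <- paste(pieces, collapse = "")
  if (transcript$strand == "-") revcomp(s) else s
}

# Genomic coordinate (0-based) of each transcript position, in
# transcript orientation.
transcript_coord_map <- function(transcript) {
  g <- unlist(mapply(function(s, e) s:(e - 1L),
                     transcript$exons$start, transcript$exons$end,
                     SIMPLIFY = FALSE))
  if (transcript$strand == "-") rev(g) else g
}

#' Map a transcript-coordinate read to its genomic span
#'
#' Collapses a read placed at 0-based transcript `offset` with the given
#' `length` to the genomic interval from its first to its last aligned
#' base (half-open, reported with start < end regardless of strand).
#' Introns inside the span are not represented: only the outer
#' coordinates matter for locus identity.
#'
#' @param transcript A [transcript_model()].
#' @param offset 0-based transcript coordinate of the read start.
#' @param length Read length; `offset + length` must not exceed the
#'   spliced length.
#' @return A list with `chrom`, `genomic_start`, `genomic_end`,
#'   `source` (the transcript id).
#' @export
transcript_to_genomic <- function(transcript, offset, length) {
  if (offset < 0L || length < 1L ||
      offset + length > transcript$spliced_length) {
    stop("read [", offset, ", ", offset + length,
         ") outside spliced length ", transcript$spliced_length)
  }
  map <- transcript_coord_map(transcript)
  g1 <- map[offset + 1L]
  g2 <- map[offset + length]
  list(chrom = transcript$chrom,
       genomic_start = min(g1, g2),
       genomic_end = max(g1, g2) + 1L,
       source = transcript$transcript_id)
}

#' Classify a read from its collapsed alignments
#'
#' Given all alignments of one read, each collapsed to genomic
#' coordinates, decides its uniqueness class. With `S` the set of
#' distinct (chrom, start) values, `E` the distinct (chrom, end) values
#' and `T` the distinct transcript sources (excluding `"genome"`): the
#' read is gene-level unique iff all alignments share a start or all
#' share an end (|S| == 1 or |E| == 1); transcript-level unique under
#' the default `"coordinate"` rule iff |S| == 1 and |E| == 1, and under
#' the stricter `"single_source"` rule additionally |T| <= 1.
#' Transcript-level uniqueness implies gene-level uniqueness.
#'
#' @param alignments Data frame with columns `genomic_start`,
#'   `genomic_end`, `source`, and optionally `chrom` (assumed equal when
#'   absent).
#' @param transcript_rule `"coordinate"` (default) or `"single_source"`.
#' @return One of `"transcript_unique"`, `"gene_unique"`,
#'   `"multimapping"`, `"unmapped"` (the most specific class that
#'   applies).
#' @export
classify_read <- function(alignments,
                          transcript_rule = c("coordinate", "single_source")) {
  transcript_rule <- match.arg(transcript_rule)
  alignments <- as.data.frame(alignments)
  if (nrow(alignments) == 0L) return("unmapped")
  chrom <- if ("chrom" %in% names(alignments)) alignments$chrom else ""
  s_keys <- unique(paste(chrom, alignments$genomic_start))
  e_keys <- unique(paste(chrom, alignments$genomic_end))
  sources <- unique(setdiff(alignments$source, "genome"))
  gene_unique <- length(s_keys) == 1L || length(e_keys) == 1L
  transcript_unique <- length(s_keys) == 1L && length(e_keys) == 1L
  if (transcript_rule == "single_source") {
    transcript_unique <- transcript_unique && length(sources) <= 1L
  }
  if (transcript_unique) "transcript_unique"
  else if (gene_unique) "gene_unique"
  else "multimapping"
}

# Combined alignment target: genome chromosomes plus every spliced
# transcript as an extra named sequence.
combined_index <- function(genome, transcripts) {
  seqs <- as_sequences(genome)
  tx_ids <- vapply(transcripts, `[[`, "", "transcript_id")
  clash <- intersect(tx_ids, names(seqs))
  if (length(clash)) {
    stop("transcript id(s) clash with chromosome names: ",
         paste(clash, collapse = ", "))
  }
  spliced <- vapply(transcripts, function(tx)
    extract_spliced_sequence(seqs, tx), "")
  names(spliced) <- tx_ids
  list(index = occurrence_index(c(seqs, spliced)),
       transcripts = setNames(transcripts, tx_ids),
       chroms = names(seqs))
}

# Collapse occurrences of a length-L read in a combined index to
# genomic spans. Transcript hits are mapped through the exon structure;
# genomic hits (either strand) use their own coordinates.
collapse_occurrences <- function(occ, L, combined) {
  if (nrow(occ) == 0L) {
    return(data.frame(chrom = character(), genomic_start = integer(),
                      genomic_end = integer(), source = character()))
  }
  rows <- lapply(seq_len(nrow(occ)), function(i) {
    nm <- occ$seq_name[i]
    if (nm %in% combined$chroms) {
      list(chrom = nm, genomic_start = occ$position[i],
           genomic_end = occ$position[i] + L, source = "genome")
    } else {
      transcript_to_genomic(combined$transcripts[[nm]], occ$position[i], L)
    }
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Compute a transcript's MUL array at gene or transcript level
#'
#' Profiles a spliced transcript against the combined genome +
#' transcriptome target: for every transcript position, the smallest
#' read length whose window — after finding all its exact occurrences
#' on both strands of every chromosome and every spliced transcript,
#' and collapsing each occurrence to genomic coordinates — classifies
#' as gene-level or transcript-level unique ([classify_read()]).
#' Windows spanning exon junctions are evaluated on the spliced
#' sequence, so junction reads absent from the genome can still be
#' unique. Lengths are scanned linearly from `kmin` upward: collapsing
#' through differing exon structures does not guarantee the
#' monotonicity that justifies bracketing.
#'
#' @param genome Named sequences.
#' @param transcripts List of all annotated [transcript_model()]s (the
#'   whole annotation, not just the target).
#' @param transcript_id Which transcript to profile.
#' @param level `"gene"` or `"transcript"`.
#' @param kmin,kmax Read-length range (defaults 20 and 255).
#' @param transcript_rule Passed to [classify_read()].
#' @return A [mul_array()] in transcript coordinates.
#' @export
compute_transcript_mul <- function(genome, transcripts, transcript_id,
                                   level = c("gene", "transcript"),
                                   kmin = 20L, kmax = 255L,
                                   transcript_rule = c("coordinate",
                                                       "single_source")) {
  level <- match.arg(level)
  transcript_rule <- match.arg(transcript_rule)
  comb <- combined_index(genome, transcripts)
  if (!transcript_id %in% names(comb$transcripts)) {
    stop("unknown transcript: ", transcript_id)
  }
  spliced <- comb$index$sequences[[transcript_id]]
  n <- nchar(spliced)
  target <- if (level == "gene") "gene_unique" else "transcript_unique"
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  values <- integer(n)
  for (p in seq_len(n) - 1L) {
    lmax <- min(kmax, valid_run_length(spliced, p))
    L <- kmin
    while (L <= lmax) {
      occ <- find_occurrences(comb$index, substr(spliced, p + 1L, p + L))
      cls <- classify_read(collapse_occurrences(occ, L, comb),
                           transcript_rule)
      ok <- cls == "transcript_unique" ||
        (target == "gene_unique" && cls == "gene_unique")
      if (ok) { values[p + 1L] <- L; break }
      L <- L + 1L
    }
  }
  mul_array(transcript_id, values, kmin, kmax,
            mode = if (level == "gene") "transcript_gene_level"
                   else "transcript_level")
}

#' Count overlapping transcripts per transcript
#'
#' For each transcript, the number of other annotated transcripts whose
#' exon-union interval set intersects it on the same chromosome
#' (either strand). A diagnostic mirroring how transcriptome uniqueness
#' work is commonly batched by locus complexity; the occurrence engine
#' here enumerates all matches, so no multimapping cap is derived from
#' it.
#'
#' @param transcripts List of [transcript_model()]s.
#' @return Named integer vector keyed by transcript id.
#' @export
count_overlaps <- function(transcripts) {
  tx_ids <- vapply(transcripts, `[[`, "", "transcript_id")
  gr <- GenomicRanges::GRanges(
    seqnames = rep(vapply(transcripts, `[[`, "", "chrom"),
                   vapply(transcripts, function(t) nrow(t$exons), 0L)),
    ranges = IRanges::IRanges(
      start = unlist(lapply(transcripts, function(t) t$exons$start)) + 1L,
      end = unlist(lapply(transcripts, function(t) t$exons$end))),
    tx = rep(tx_ids, vapply(transcripts, function(t) nrow(t$exons), 0L)))
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  pairs <- unique(data.frame(
    a = gr$tx[S4Vectors::queryHits(hits)],
    b = gr$tx[S4Vectors::subjectHits(hits)]))
  pairs <- pairs[pairs$a != pairs$b, ]
  counts <- setNames(integer(length(tx_ids)), tx_ids)
  if (nrow(pairs)) {
    tab <- table(pairs$a)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
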
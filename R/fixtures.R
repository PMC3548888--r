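# Seeded synthetic-data generation: genomes with planted repeat
# families, multi-isoform transcript layouts, and uniform read
# placements over transcripts, together with the planted ground truth.
# Everything is a pure function of its arguments, so the same seed
# reproduces the same FASTA/annotation/alignment files.

#' Generate a random genome with planted exact repeats
#'
#' Chromosomes are i.i.d. uniform A/C/G/T background. Each repeat family
#' copies one randomly chosen segment to additional non-overlapping
#' locations (within the same chromosome), making those segments
#' exactly multi-copy; the returned `repeat_map` lists every planted
#' copy so tests know where mappability must break down.
#'
#' @param lengths Named integer vector of chromosome lengths.
#' @param repeats List of repeat families, each a list with `chrom`,
#'   `length` (segment length) and `copies` (total copy count >= 2).
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector) and
#'   `repeat_map` (data frame: family, chrom, start, end).
#' @export
generate_genome <- function(lengths, repeats = list(), seed = 1L) {
  stopifnot(!is.null(names(lengths)), all(lengths >= 1L))
  with_preserved_rng({
    set.seed(derive_seed(seed, "genome", 0L))
    seqs <- vapply(lengths, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, "")
    map <- data.frame(family = integer(), chrom = character(),
                      start = integer(), end = integer())
    for (fi in seq_along(repeats)) {
      rp <- repeats[[fi]]
      n <- lengths[[rp$chrom]]
      if (rp$length > n) {
        stop("repeat family ", fi, " longer than chromosome ", rp$chrom)
      }
      # place copies without overlap, first copy is the template
      placed <- integer(0)
      tries <- 0L
      while (length(placed) < rp$copies) {
        cand <- sample.int(n - rp$length + 1L, 1L) - 1L
        if (!any(abs(cand - placed) < rp$length)) {
          placed <- c(placed, cand)
        }
        tries <- tries + 1L
        if (tries > 10000L) stop("cannot place repeat copies without overlap")
      }
      template <- substr(seqs[[rp$chrom]], placed[1] + 1L,
                         placed[1] + rp$length)
      s <- seqs[[rp$chrom]]
      for (pos in placed[-1]) {
        substr(s, pos + 1L, pos + rp$length) <- template
      }
      seqs[[rp$chrom]] <- s
      map <- rbind(map, data.frame(family = fi, chrom = rp$chrom,
                                   start = sort(placed),
                                   end = sort(placed) + rp$length))
    }
    list(sequences = seqs, repeat_map = map)
  })
}

#' Build a transcript annotation from explicit locus layouts
#'
#' Each locus lays a chain of exon blocks (alternating exon and intron
#' lengths from `start`) on a chromosome and defines isoforms as
#' subsets of those blocks, giving precise control over shared and
#' private exons.
#'
#' @param loci List of locus specs: `gene_id`, `chrom`, `start`
#'   (0-based), `strand`, `exon_lengths`, `intron_lengths` (one fewer
#'   than exons), and `isoforms`, a named list mapping transcript ids
#'   to integer vectors of exon-block indices.
#' @return Named list of [transcript_model()]s.
#' @export
generate_transcriptome <- function(loci) {
  out <- list()
  for (lc in loci) {
    ne <- length(lc$exon_lengths)
    introns <- if (is.null(lc$intron_lengths)) integer(0) else lc$intron_lengths
    if (ne > 1L && length(introns) != ne - 1L) {
      stop("locus ", lc$gene_id, ": need ", ne - 1L, " intron lengths")
    }
    starts <- lc$start + cumsum(c(0L, utils::head(lc$exon_lengths, -1L) +
                                    introns))
    ends <- starts + lc$exon_lengths
    for (tx in names(lc$isoforms)) {
      idx <- sort(lc$isoforms[[tx]])
      out[[tx]] <- transcript_model(
        tx, lc$gene_id, lc$chrom,
        if (is.null(lc$strand)) "+" else lc$strand,
        data.frame(start = starts[idx], end = ends[idx]))
    }
  }
  out
}

#' Draw uniform read placements over transcripts
#'
#' Places `reads_per_transcript[[id]]` read start offsets uniformly over
#' the positions of each transcript where a read of `max_read_length`
#' fits. Placements are length-agnostic: trimming reads to any shorter
#' length reuses the same offsets, mirroring how real reads are trimmed
#' in place.
#'
#' @param transcripts Named list of [transcript_model()]s.
#' @param reads_per_transcript Named integer vector (true expression in
#'   read counts).
#' @param max_read_length Longest read length the placements must
#'   support.
#' @param seed Integer seed.
#' @return Data frame with `transcript_id` and 0-based `offset`.
#' @export
simulate_read_placements <- function(transcripts, reads_per_transcript,
                                     max_read_length, seed = 1L) {
  rows <- list()
  with_preserved_rng({
    for (id in names(reads_per_transcript)) {
      tx <- transcripts[[id]]
      if (is.null(tx)) stop("unknown transcript: ", id)
      nfit <- tx$spliced_length - max_read_length + 1L
      if (nfit < 1L) stop("transcript ", id, " shorter than the read length")
      n <- reads_per_transcript[[id]]
      if (n == 0L) next
      set.seed(derive_seed(seed, id, 0L))
      rows[[id]] <- data.frame(
        transcript_id = id,
        offset = sample.int(nfit, n, replace = TRUE) - 1L)
    }
  })
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), offset = integer()))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Realize read placements as genomic alignments at a read length
#'
#' Converts transcript placements to genomic alignments (collapsed
#' coordinates, transcript strand) at the requested read length, and
#' checks each read's sequence for uniqueness against `genome_index`
#' (exactly one occurrence over both strands). With `unique_only =
#' TRUE` the multimapping reads are dropped, emulating an alignment
#' file of uniquely mapped reads.
#'
#' @param placements From [simulate_read_placements()].
#' @param transcripts Named list of [transcript_model()]s.
#' @param genome Named genome sequences.
#' @param read_length Read length to realize (at most the
#'   `max_read_length` the placements were drawn for).
#' @param genome_index Optional prebuilt [occurrence_index()] over
#'   `genome` (rebuilt if omitted).
#' @param unique_only Drop reads whose sequence is not unique?
#' @return Data frame with `read_id`, `transcript_id`, `offset`,
#'   `chrom`, `gstart`, `gend` (0-based half-open outer span),
#'   `strand`, `seq`, `unique`.
#' @export
placements_to_alignments <- function(placements, transcripts, genome,
                                     read_length, genome_index = NULL,
                                     unique_only = FALSE) {
  seqs <- as_sequences(genome)
  if (is.null(genome_index)) genome_index <- occurrence_index(seqs)
  spliced <- vapply(transcripts, function(tx)
    extract_spliced_sequence(seqs, tx), "")
  maps <- lapply(transcripts, transcript_coord_map)
  n <- nrow(placements)
  if (n == 0L) {
    return(data.frame(read_id = character(), transcript_id = character(),
                      offset = integer(), chrom = character(),
                      gstart = integer(), gend = integer(),
                      strand = character(), seq = character(),
                      unique = logical()))
  }
  id <- placements$transcript_id
  off <- placements$offset
  read <- substring(spliced[id], off + 1L, off + read_length)
  g1 <- mapply(function(i, o) maps[[i]][o + 1L], id, off)
  g2 <- mapply(function(i, o) maps[[i]][o + read_length], id, off)
  out <- data.frame(
    read_id = sprintf("read_%06d", seq_len(n)), transcript_id = id,
    offset = off,
    chrom = vapply(transcripts[id], `[[`, "", "chrom"),
    gstart = pmin(g1, g2), gend = pmax(g1, g2) + 1L,
    strand = vapply(transcripts[id], `[[`, "", "strand"),
    seq = read,
    unique = vapply(read, function(r)
      count_occurrences(genome_index, r) == 1L, NA, USE.NAMES = FALSE))
  if (unique_only) out <- out[out$unique, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write transcript models as refFlat
#' @param transcripts Named list of [transcript_model()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(transcripts, path) {
  lines <- vapply(transcripts, function(tx) {
    paste(tx$gene_id, tx$transcript_id, tx$chrom, tx$strand,
          min(tx$exons$start), max(tx$exons$end),
          min(tx$exons$start), max(tx$exons$end), nrow(tx$exons),
          paste0(paste(tx$exons$start, collapse = ","), ","),
          paste0(paste(tx$exons$end, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write transcript models as BED12
#' @inheritParams write_refflat
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(transcripts, path) {
  lines <- vapply(transcripts, function(tx) {
    cs <- min(tx$exons$start)
    paste(tx$chrom, cs, max(tx$exons$end), tx$transcript_id, 0, tx$strand,
          cs, max(tx$exons$end), "0", nrow(tx$exons),
          paste0(paste(tx$exons$end - tx$exons$start, collapse = ","), ","),
          paste0(paste(tx$exons$start - cs, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# CIGAR for a read whose aligned genomic base coordinates are `coords`
# (ascending): runs of consecutive bases are M blocks, gaps are N.
alignment_cigar <- function(coords) {
  breaks <- which(diff(coords) > 1L)
  run_starts <- c(1L, breaks + 1L)
  run_ends <- c(breaks, length(coords))
  cig <- ""
  for (k in seq_along(run_starts)) {
    if (k > 1L) {
      gap <- coords[run_starts[k]] - coords[run_ends[k - 1L]] - 1L
      cig <- paste0(cig, gap, "N")
    }
    cig <- paste0(cig, run_ends[k] - run_starts[k] + 1L, "M")
  }
  cig
}

#' Write alignments as a SAM file
#'
#' Emits a minimal, valid single-end SAM: header `@SQ` lines from the
#' genome, flag 0/16 by strand, 1-based POS of the leftmost aligned
#' base, and a junction-aware CIGAR (`M`/`N`).
#'
#' @param alignments From [placements_to_alignments()].
#' @param transcripts Named list of [transcript_model()]s (for
#'   junction-aware CIGARs).
#' @param genome Named genome sequences (for header lengths).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, transcripts, genome, path) {
  seqs <- as_sequences(genome)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(seqs), "\tLN:", nchar(seqs)))
  body <- vapply(seq_len(nrow(alignments)), function(i) {
    a <- alignments[i, ]
    tx <- transcripts[[a$transcript_id]]
    map <- transcript_coord_map(tx)
    coords <- sort(map[(a$offset + 1L):(a$offset + nchar(a$seq))])
    flag <- if (a$strand == "-") 16L else 0L
    seq_out <- if (a$strand == "-") revcomp(a$seq) else a$seq
    paste(a$read_id, flag, a$chrom, coords[1] + 1L, 255,
          alignment_cigar(coords), "*", 0, 0, seq_out, "*", sep = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write alignments as BED6
#' @param alignments From [placements_to_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(alignments, path) {
  lines <- paste(alignments$chrom, alignments$gstart, alignments$gend,
                 alignments$read_id, 0, alignments$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
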
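# Minimum unique length (MUL) computation. MUL at a position is the
# shortest read starting there that matches exactly one location in the
# index; 0 means no read length in [kmin, kmax] is ever unique there.

#' Construct a MUL array
#'
#' Container for per-position minimum-unique-length values of one
#' sequence. Normally produced by [compute_mul_array()],
#' [compute_bisulfite_mul()] or [compute_transcript_mul()].
#'
#' @param seq_name Sequence identifier.
#' @param values Integer vector, one value per base: 0 or in
#'   `[kmin, kmax]`.
#' @param kmin,kmax Queried read-length range (defaults 20 and 255; a
#'   one-byte track can hold values up to 255, a two-byte track up to
#'   65535).
#' @param mode One of `"genome"`, `"bisulfite_fw"`, `"bisulfite_rv"`,
#'   `"transcript_gene_level"`, `"transcript_level"`.
#' @return An object of class `MULArray`.
#' @export
mul_array <- function(seq_name, values, kmin = 20L, kmax = 255L,
                      mode = "genome") {
  mode <- match.arg(mode, c("genome", "bisulfite_fw", "bisulfite_rv",
                            "transcript_gene_level", "transcript_level"))
  values <- as.integer(values)
  stopifnot(kmin >= 1L, kmax >= kmin)
  bad <- values != 0L & (values < kmin | values > kmax)
  if (any(bad)) {
    stop("MUL values must be 0 or within [kmin, kmax]; offending position ",
         which(bad)[1] - 1L)
  }
  structure(list(seq_name = as.character(seq_name), values = values,
                 kmin = as.integer(kmin), kmax = as.integer(kmax),
                 mode = mode),
            class = "MULArray")
}

#' @export
print.MULArray <- function(x, ...) {
  nz <- sum(x$values > 0L)
  cat(sprintf("MULArray '%s' (%s): %d positions, %d mappable within [%d, %d]\n",
              x$seq_name, x$mode, length(x$values), nz, x$kmin, x$kmax))
  invisible(x)
}

#' Compute the minimum unique length at every position of a sequence
#'
#' For each position `p` of `seq_name`, finds the smallest read length
#' `L` in `[kmin, min(kmax, remaining sequence)]` such that the window
#' starting at `p` occurs exactly once in the whole index; positions
#' with no such length get 0. The search brackets the answer: the
#' longest fitting window is probed first (non-unique there means 0),
#' then `kmin`, then lengths ascending in steps of `step` until a unique
#' length bounds the answer from above, and the bracket is scanned
#' linearly. Because exact-match uniqueness is monotone in read length,
#' the result is identical to exhaustive scanning over all lengths.
#'
#' @param index An [occurrence_index()] (the full set of sequences reads
#'   could map to).
#' @param seq_name Which sequence of the index to profile.
#' @param kmin,kmax Read-length range to query (defaults 20 and 255).
#' @param strand_mode `"both"` (default; reads may match either strand)
#'   or `"forward_only"`.
#' @param step Increment of the bracketing ascent (default 25).
#' @param chunk_size Positions processed per batch; a memory/progress
#'   knob with no effect on the result.
#' @return A [mul_array()] with `mode = "genome"`.
#' @examples
#' idx <- occurrence_index(c(chr = "AACCGG"))
#' compute_mul_array(idx, "chr", kmin = 2, kmax = 3)$values  # 2 2 0 0 0 0
#' @export
compute_mul_array <- function(index, seq_name, kmin = 20L, kmax = 255L,
                              strand_mode = "both", step = 25L,
                              chunk_size = 1000000L) {
  stopifnot(inherits(index, "OccurrenceIndex"))
  strand_mode <- check_strand_mode(strand_mode)
  target <- match(seq_name, names(index$sequences))
  if (is.na(target)) stop("unknown sequence name: ", seq_name)
  stopifnot(kmin >= 1L, kmax >= kmin, step >= 1L, chunk_size >= 1L)
  n <- nchar(index$sequences[[target]])
  values <- integer(n)
  starts <- seq(0L, n - 1L, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size, n)
    values[(s + 1L):e] <- cpp_mul_array(unname(index$sequences), target,
                                        as.integer(kmin), as.integer(kmax),
                                        strand_mode == "both",
                                        as.integer(step), s, e)
  }
  mul_array(seq_name, values, kmin, kmax, mode = "genome")
}

# Shared bracketing search over an arbitrary monotone uniqueness
# predicate. lmax is the longest admissible window at this position.
mul_search <- function(is_unique, kmin, lmax, step) {
  if (lmax < kmin) return(0L)
  if (!is_unique(lmax)) return(0L)
  if (is_unique(kmin)) return(kmin)
  klow <- kmin
  khigh <- lmax
  k <- kmin + step
  while (k < lmax) {
    if (is_unique(k)) { khigh <- k; break }
    klow <- k
    k <- k + step
  }
  for (k in seq(klow + 1L, khigh)) {
    if (is_unique(k)) return(as.integer(k))
  }
  as.integer(khigh)  # unreachable for monotone predicates; defensive
}

# Longest run of A/C/G/T starting at 0-based position p.
valid_run_length <- function(seq, p) {
  n <- nchar(seq)
  v <- 0L
  while (p + v < n &&
         substr(seq, p + v + 1L, p + v + 1L) %in% c("A", "C", "G", "T")) {
    v <- v + 1L
  }
  v
}

#' Bisulfite-convert a DNA strand
#'
#' Models complete bisulfite conversion of an unmethylated reference:
#' on the forward strand every C reads as T; on the reverse strand the
#' converted sequence, expressed on the forward representation, has
#' every G replaced by A (reverse-complement, C-to-T, reverse-complement
#' back). After conversion the two strands are no longer reverse
#' complements of each other.
#'
#' @param sequence A DNA string.
#' @param strand `"fw"` or `"rv"`.
#' @return The converted uppercase string.
#' @examples
#' convert_bisulfite("ACGTCC", "fw")  # "ATGTTT"
#' convert_bisulfite("ACGTCC", "rv")  # "ACATCC"
#' @export
convert_bisulfite <- function(sequence, strand = c("fw", "rv")) {
  strand <- match.arg(strand)
  s <- toupper(sequence)
  if (strand == "fw") chartr("C", "T", s) else chartr("G", "A", s)
}

#' Compute bisulfite-converted MUL arrays
#'
#' Mappability of bisulfite reads against per-strand converted
#' references. A read drawn from the forward strand at position `p` with
#' length `L` is unique iff (a) its C-to-T converted sequence occurs
#' exactly once, forward orientation only, in the fully C-to-T converted
#' genome, and (b) it does not occur in the G-to-A converted genome
#' (the reverse-strand reference). The reverse-strand file is the
#' symmetric construction. Because conversion collapses C/T (or G/A),
#' bisulfite MUL values are never smaller than plain forward-only
#' genome MUL values.
#'
#' @param genome Named sequences (as for [occurrence_index()]).
#' @param strand `"fw"` or `"rv"`: which strand's reads are profiled.
#' @param kmin,kmax Read-length range.
#' @param step Bracketing increment.
#' @param crosscheck_orientation `"both"` (default, conservative: the
#'   read may not match the other-strand reference in either
#'   orientation) or `"forward"`.
#' @return A named list of [mul_array()]s (mode `bisulfite_fw` or
#'   `bisulfite_rv`), one per input sequence.
#' @examples
#' compute_bisulfite_mul(c(c1 = "CT"), "fw", kmin = 1, kmax = 2)$c1$values
#' @export
compute_bisulfite_mul <- function(genome, strand = c("fw", "rv"),
                                  kmin = 20L, kmax = 255L, step = 25L,
                                  crosscheck_orientation = c("both", "forward")) {
  strand <- match.arg(strand)
  crosscheck_orientation <- match.arg(crosscheck_orientation)
  seqs <- as_sequences(genome)
  own <- vapply(seqs, convert_bisulfite,
                strand = if (strand == "fw") "fw" else "rv", "")
  other <- vapply(seqs, convert_bisulfite,
                  strand = if (strand == "fw") "rv" else "fw", "")
  own_idx <- occurrence_index(own)
  other_idx <- occurrence_index(other)
  mode <- if (strand == "fw") "bisulfite_fw" else "bisulfite_rv"
  kmin <- as.integer(kmin); kmax <- as.integer(kmax); step <- as.integer(step)
  out <- lapply(names(seqs), function(nm) {
    conv <- own[[nm]]
    n <- nchar(conv)
    values <- integer(n)
    for (p in seq_len(n) - 1L) {
      lmax <- min(kmax, valid_run_length(conv, p))
      is_unique <- function(L) {
        read <- substr(conv, p + 1L, p + L)
        count_occurrences(own_idx, read, "forward_only") == 1L &&
          count_occurrences(other_idx, read,
                            if (crosscheck_orientation == "both") "both"
                            else "forward_only") == 0L
      }
      values[p + 1L] <- mul_search(is_unique, kmin, lmax, step)
    }
    mul_array(nm, values, kmin, kmax, mode = mode)
  })
  setNames(out, names(seqs))
}
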
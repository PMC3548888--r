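#' Build an exact-match occurrence index over named DNA sequences
#'
#' The index is the package's alignment target: every uniqueness query
#' ("how many places does this read map to?") is answered by exact,
#' mismatch-free matching against it, on the forward strand and
#' (optionally) the reverse strand. Soft-masked lowercase input is
#' uppercased at build time; queries are therefore case-insensitive.
#' `N` and other ambiguity codes are retained but never match anything,
#' so any window containing one is unmappable.
#'
#' @param sequences Named character vector of DNA sequences, a
#'   [Biostrings::DNAStringSet], or the path to a (multi-record,
#'   possibly line-wrapped) FASTA file.
#' @return An object of class `OccurrenceIndex` with elements
#'   `sequences` (named uppercase character vector) and `total_length`.
#' @examples
#' idx <- occurrence_index(c(chr1 = "ACGTACGT"))
#' count_occurrences(idx, "ACGTA")
#' @seealso [count_occurrences()], [find_occurrences()]
#' @export
occurrence_index <- function(sequences) {
  seqs <- as_sequences(sequences)
  if (length(seqs) == 0L || any(nchar(seqs) == 0L)) {
    stop("at least one non-empty sequence is required")
  }
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) {
    stop("duplicate sequence names: ", paste(unique(dup), collapse = ", "))
  }
  chars <- unique(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]])
  iupac <- strsplit("ACGTNRYSWKMBDHV", "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, iupac)
  if (length(bad)) {
    stop("sequence contains non-IUPAC character(s): ",
         paste(sQuote(bad), collapse = ", "))
  }
  structure(list(sequences = seqs,
                 total_length = sum(nchar(seqs))),
            class = "OccurrenceIndex")
}

#' @export
print.OccurrenceIndex <- function(x, ...) {
  cat("OccurrenceIndex:", length(x$sequences), "sequence(s),",
      x$total_length, "bp total\n")
  invisible(x)
}

check_strand_mode <- function(strand_mode) {
  match.arg(strand_mode, c("both", "forward_only"))
}

#' Count exact occurrences of a query in an index
#'
#' Counts distinct (sequence, position, strand) exact matches of `query`.
#' Under `strand_mode = "both"` a minus-strand match means the reverse
#' complement of the query occurs on the forward representation; a
#' palindromic query matching one locus on both strands counts twice,
#' mirroring per-strand alignment reporting. Queries containing any
#' character outside A/C/G/T return 0.
#'
#' @param index An [occurrence_index()].
#' @param query A single non-empty DNA string.
#' @param strand_mode `"both"` (default) or `"forward_only"`.
#' @return A non-negative integer count.
#' @examples
#' idx <- occurrence_index(c(chr1 = "ACGTACGT"))
#' count_occurrences(idx, "ACGTA")              # 2: forward + revcomp hit
#' count_occurrences(idx, "ACGT", "forward_only")
#' @export
count_occurrences <- function(index, query, strand_mode = "both") {
  stopifnot(inherits(index, "OccurrenceIndex"),
            is.character(query), length(query) == 1L)
  if (nchar(query) == 0L) stop("query must be non-empty")
  strand_mode <- check_strand_mode(strand_mode)
  cpp_count_occurrences(unname(index$sequences), toupper(query),
                        strand_mode == "both")
}

#' Locate exact occurrences of a query in an index
#'
#' @inheritParams count_occurrences
#' @return A data frame with columns `seq_name`, `position` (0-based
#'   offset of the match start on the forward representation) and
#'   `strand` (`"+"`/`"-"`), sorted by (seq_name, position, strand).
#'   The number of rows equals [count_occurrences()].
#' @examples
#' idx <- occurrence_index(c(chr = "AACCAAGG"))
#' find_occurrences(idx, "CC")   # forward at 2, minus-strand at 6
#' @export
find_occurrences <- function(index, query, strand_mode = "both") {
  stopifnot(inherits(index, "OccurrenceIndex"),
            is.character(query), length(query) == 1L)
  if (nchar(query) == 0L) stop("query must be non-empty")
  strand_mode <- check_strand_mode(strand_mode)
  hits <- cpp_find_occurrences(unname(index$sequences), toupper(query),
                               strand_mode == "both")
  out <- data.frame(
    seq_name = names(index$sequences)[hits$seq_idx],
    position = hits$position,
    strand = ifelse(hits$forward, "+", "-"),
    stringsAsFactors = FALSE
  )
  out[order(out$seq_name, out$position, out$strand), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}
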
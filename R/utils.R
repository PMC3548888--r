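# Internal helpers shared across modules. All coordinates are 0-based,
# half-open unless a function documents otherwise.

#' Reverse complement of a DNA string
#'
#' Complements A/C/G/T (case-insensitively, returning uppercase) and
#' reverses. `N` and other IUPAC codes are preserved as `N`-like
#' characters via [Biostrings::reverseComplement()].
#'
#' @param x A single character string over the DNA alphabet.
#' @return A single uppercase character string.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# Coerce genome input (named character vector, list, DNAStringSet, or a
# FASTA file path) to a named uppercase character vector.
as_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    # FASTA description lines: keep the first token as the record name
    names(out) <- sub("\\s.*$", "", names(out))
    x <- out
  }
  if (is.list(x)) x <- unlist(x)
  if (length(x) == 0L) stop("sequences must be non-empty")
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("sequences must be a named character vector, DNAStringSet or FASTA path")
  }
  toupper(x)
}

# Reversible sanitization of sequence names for use as file names:
# every character outside [A-Za-z0-9._-] is percent-encoded.
sanitize_name <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- !grepl("^[A-Za-z0-9._-]$", chars)
    chars[bad] <- vapply(chars[bad],
                         function(ch) sprintf("%%%02X", utf8ToInt(ch)), "")
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
}

unsanitize_name <- function(x) {
  vapply(x, function(s) utils::URLdecode(s), "", USE.NAMES = FALSE)
}

# Deterministic 31-bit stream seed derived from (seed, label, position),
# independent of iteration order and chunking.
derive_seed <- function(seed, label, position) {
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h * 1103515245 + as.double(position) * 12820163 + 12345) %%
               2147483647)
}
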
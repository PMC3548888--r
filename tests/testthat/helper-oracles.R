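# Independent brute-force oracles. These deliberately share no code
# with the package internals: matching is done by R string equality on
# enumerated windows (hash-table counting), not by scanning, and the
# paired-end oracle enumerates candidate spans rather than pairing
# occurrences.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", x), "")[[1]]),
        collapse = "")
}

# Occurrence count of `query` over named sequences by naive window
# enumeration. Queries or windows containing non-ACGT never match.
oracle_count <- function(seqs, query, both = TRUE) {
  if (grepl("[^ACGT]", query)) return(0L)
  L <- nchar(query)
  total <- 0L
  for (s in seqs) {
    n <- nchar(s)
    if (n < L) next
    w <- substring(s, 1:(n - L + 1L), L:n)
    total <- total + sum(w == query)
    if (both) total <- total + sum(w == oracle_revcomp(query))
  }
  total
}

# Per-position minimum unique length by exhaustive per-length window
# tabulation (smallest L in [kmin, kmax] with total occurrence count 1).
oracle_mul <- function(seqs, target, kmin, kmax, both = TRUE) {
  s <- seqs[[target]]
  n <- nchar(s)
  vals <- integer(n)
  open <- rep(TRUE, n)
  for (L in kmin:kmax) {
    if (n < L) break
    db <- unlist(lapply(seqs, function(x) {
      m <- nchar(x)
      if (m >= L) substring(x, 1:(m - L + 1L), L:m) else character(0)
    }), use.names = FALSE)
    db <- db[!grepl("[^ACGT]", db)]
    tab <- table(db)
    tw <- substring(s, 1:(n - L + 1L), L:n)
    cnt <- as.integer(tab[tw])
    cnt[is.na(cnt)] <- 0L
    if (both) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(tw)))
      extra <- as.integer(tab[rc])
      extra[is.na(extra)] <- 0L
      cnt <- cnt + extra
    }
    hit <- which(open[seq_along(tw)] & cnt == 1L)
    vals[hit] <- L
    open[hit] <- FALSE
  }
  vals
}

# Exhaustive paired-end uniqueness: enumerate every candidate span
# (sequence, start, width) with width in [imin, imax], keep those whose
# span (or its reverse complement) starts with mate1 and ends with the
# sense sequence of mate2, and require the surviving spans to agree on
# a start or an end.
oracle_pair_unique <- function(seqs, source, fstart, flen, rl, imin, imax) {
  if (flen <= rl) return(FALSE)
  frag <- substr(seqs[[source]], fstart + 1L, fstart + flen)
  m1 <- substr(frag, 1L, rl)
  m2 <- substr(frag, flen - rl + 1L, flen)
  rc_m1 <- oracle_revcomp(m1)
  rc_m2 <- oracle_revcomp(m2)
  spans <- NULL
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    n <- nchar(s)
    for (w in max(imin, rl):min(imax, n)) {
      starts <- 0:(n - w)
      head_ <- substring(s, starts + 1L, starts + rl)
      tail_ <- substring(s, starts + w - rl + 1L, starts + w)
      # span matches the fragment forward, or its reverse complement does
      hit <- (head_ == m1 & tail_ == m2) | (head_ == rc_m2 & tail_ == rc_m1)
      if (any(hit)) {
        spans <- rbind(spans, data.frame(chrom = nm, start = starts[hit],
                                         end = starts[hit] + w))
      }
    }
  }
  if (is.null(spans)) return(FALSE)
  spans <- unique(spans)
  length(unique(paste(spans$chrom, spans$start))) == 1L ||
    length(unique(paste(spans$chrom, spans$end))) == 1L
}

random_seq <- function(n, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Bisulfite MUL oracle: per-strand converted genomes, own-genome
# forward count must be 1 and the other strand's converted genome must
# contain neither the window nor (when cross_both) its reverse
# complement.
oracle_bisulfite_mul <- function(seqs, target, strand, kmin, kmax,
                                 cross_both = TRUE) {
  conv_fw <- vapply(seqs, function(s) chartr("C", "T", s), "")
  conv_rv <- vapply(seqs, function(s) chartr("G", "A", s), "")
  own <- if (strand == "fw") conv_fw else conv_rv
  oth <- if (strand == "fw") conv_rv else conv_fw
  s <- own[[target]]
  n <- nchar(s)
  vals <- integer(n)
  for (p in 0:(n - 1L)) {
    for (L in kmin:kmax) {
      if (p + L > n) break
      w <- substr(s, p + 1L, p + L)
      if (grepl("[^ACGT]", w)) break
      if (oracle_count(own, w, both = FALSE) == 1L &&
          oracle_count(oth, w, both = cross_both) == 0L) {
        vals[p + 1L] <- L
        break
      }
    }
  }
  vals
}
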
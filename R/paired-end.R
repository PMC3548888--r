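# Paired-end uniqueness. A single minimum unique length is not defined
# for read pairs (fragment lengths vary between and within libraries);
# instead fragments are simulated from a Gaussian length model and the
# uniquely mappable proportion is turned into an effective length per
# transcript and read length.

#' Gaussian fragment-length configuration
#'
#' @param mean Mean fragment (insert) length in nt (default 250).
#' @param sd Standard deviation in nt (default 25).
#' @param draws_per_position Simulated fragment lengths drawn per
#'   transcript position (default 5).
#' @param seed Integer seed; all fragment simulation derives from it.
#' @param insert_min,insert_max Accepted fragment-span bounds when
#'   pairing mates; default `mean - 3*sd` and `mean + 3*sd`, which
#'   cover 99.7% of the Gaussian mass.
#' @return An object of class `FragmentConfig`.
#' @examples
#' cfg <- fragment_config()
#' c(cfg$insert_min, cfg$insert_max)  # 175 325
#' @export
fragment_config <- function(mean = 250, sd = 25, draws_per_position = 5L,
                            seed = 1L, insert_min = NULL, insert_max = NULL) {
  stopifnot(sd > 0, draws_per_position >= 1L)
  if (is.null(insert_min)) insert_min <- mean - 3 * sd
  if (is.null(insert_max)) insert_max <- mean + 3 * sd
  structure(list(mean = mean, sd = sd,
                 draws_per_position = as.integer(draws_per_position),
                 seed = as.integer(seed),
                 insert_min = insert_min, insert_max = insert_max),
            class = "FragmentConfig")
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  expr
}

#' Simulate paired-end fragments over a transcript
#'
#' From every 0-based start position, `draws_per_position` lengths are
#' drawn from Normal(mean, sd) and rounded to the nearest integer;
#' fragments whose end falls outside the transcript (or whose length is
#' below 1) are discarded. Each position uses its own RNG stream derived
#' from `(seed, transcript_id, position)`, so results are independent of
#' iteration order.
#'
#' @param transcript_length Spliced transcript length in nt.
#' @param config A [fragment_config()].
#' @param transcript_id Label entering the per-position stream seed.
#' @return Data frame with 0-based `start` and integer `length`.
#' @export
simulate_fragments <- function(transcript_length, config,
                               transcript_id = "") {
  stopifnot(inherits(config, "FragmentConfig"), transcript_length >= 1L)
  with_preserved_rng({
    res <- lapply(seq_len(transcript_length) - 1L, function(p) {
      set.seed(derive_seed(config$seed, transcript_id, p))
      len <- round(rnorm(config$draws_per_position, config$mean, config$sd))
      len <- len[len >= 1 & p + len <= transcript_length]
      if (length(len)) data.frame(start = p, length = as.integer(len))
    })
    res <- res[!vapply(res, is.null, TRUE)]
    if (!length(res)) {
      data.frame(start = integer(), length = integer())
    } else {
      do.call(rbind, res)
    }
  })
}

# Collapse a fragment span occurrence to genomic coordinates.
collapse_span <- function(seq_name, pos, span_len, transcripts) {
  if (!is.null(transcripts) && seq_name %in% names(transcripts)) {
    g <- transcript_to_genomic(transcripts[[seq_name]], pos, span_len)
    data.frame(chrom = g$chrom, start = g$genomic_start,
               end = g$genomic_end)
  } else {
    data.frame(chrom = seq_name, start = pos, end = pos + span_len)
  }
}

#' Decide whether a mate pair maps uniquely
#'
#' Mate 1 is the first `read_length` bases of the fragment; mate 2 is
#' the reverse complement of its last `read_length` bases. Candidate
#' mappings are pairs of exact occurrences on the same target sequence
#' in forward-reverse orientation (on either strand) whose implied
#' fragment span lies within `[insert_min, insert_max]`. Candidate
#' spans are collapsed to genomic coordinates (through the exon
#' structure for transcript hits) and the pair is unique iff the
#' surviving spans agree on a single locus under the gene-level rule
#' (all share a span start or all share a span end). Fragments no
#' longer than the read length are completely overlapping mates and
#' count as non-mappable.
#'
#' @param index An [occurrence_index()] over the genome (optionally
#'   plus spliced transcripts).
#' @param source Name of the sequence in `index` the fragment is taken
#'   from.
#' @param fragment_start 0-based start of the fragment on `source`.
#' @param fragment_length Fragment length in nt.
#' @param read_length Mate length in nt.
#' @param config A [fragment_config()] (supplies the insert bounds).
#' @param transcripts Optional named list of [transcript_model()]s for
#'   sequences in the index that are spliced transcripts.
#' @return `TRUE` iff the pair maps uniquely.
#' @export
pair_is_unique <- function(index, source, fragment_start, fragment_length,
                           read_length, config, transcripts = NULL) {
  stopifnot(inherits(index, "OccurrenceIndex"),
            inherits(config, "FragmentConfig"))
  if (!source %in% names(index$sequences)) {
    stop("unknown sequence in index: ", source)
  }
  if (fragment_length <= read_length) return(FALSE)
  seq <- index$sequences[[source]]
  frag <- substr(seq, fragment_start + 1L, fragment_start + fragment_length)
  if (nchar(frag) < fragment_length) stop("fragment outside sequence bounds")
  mate1 <- substr(frag, 1L, read_length)
  mate2_sense <- substr(frag, fragment_length - read_length + 1L,
                        fragment_length)
  o1 <- find_occurrences(index, mate1)
  o2 <- find_occurrences(index, mate2_sense)
  if (nrow(o1) == 0L || nrow(o2) == 0L) return(FALSE)
  spans <- list()
  for (i in seq_len(nrow(o1))) {
    js <- which(o2$seq_name == o1$seq_name[i] & o2$strand == o1$strand[i])
    for (j in js) {
      if (o1$strand[i] == "+") {
        span_start <- o1$position[i]
        span_len <- o2$position[j] + read_length - o1$position[i]
      } else {
        span_start <- o2$position[j]
        span_len <- o1$position[i] + read_length - o2$position[j]
      }
      if (span_len >= read_length && span_len >= config$insert_min &&
          span_len <= config$insert_max) {
        spans[[length(spans) + 1L]] <-
          collapse_span(o1$seq_name[i], span_start, span_len, transcripts)
      }
    }
  }
  if (!length(spans)) return(FALSE)
  spans <- unique(do.call(rbind, spans))
  length(unique(paste(spans$chrom, spans$start))) == 1L ||
    length(unique(paste(spans$chrom, spans$end))) == 1L
}

#' Estimate paired-end effective lengths for transcripts
#'
#' Simulates one fragment set per transcript ([simulate_fragments()])
#' and, for each requested mate length, counts the fragments whose mate
#' pair maps uniquely ([pair_is_unique()]). The effective length is
#' `transcript length * (uniquely mapped fragments / all fragments)`,
#' where "all fragments" are those that fit inside the transcript.
#' Fragments shorter than or equal to the mate length stay in the
#' denominator but cannot map. Transcripts where no fragment fits get
#' an effective length of 0 with a warning.
#'
#' @param index An [occurrence_index()] containing (at least) the
#'   sequences named in `sources`.
#' @param sources Character vector of sequence names in `index` to
#'   profile (e.g. spliced transcript ids of a combined index).
#' @param read_lengths Integer vector of mate lengths; each must be
#'   below `config$insert_max`.
#' @param config A [fragment_config()].
#' @param transcripts Optional named list of [transcript_model()]s for
#'   collapsing transcript hits to the genome.
#' @return Data frame with columns `transcript_id`, `read_length`,
#'   `fragments_total`, `fragments_unique`, `unique_proportion`,
#'   `effective_length`.
#' @export
estimate_effective_lengths <- function(index, sources, read_lengths, config,
                                       transcripts = NULL) {
  stopifnot(length(read_lengths) >= 1L)
  if (any(read_lengths >= config$insert_max)) {
    stop("read lengths must be below insert_max (complete-overlap regime)")
  }
  rows <- list()
  for (src in sources) {
    n <- nchar(index$sequences[[src]])
    frags <- simulate_fragments(n, config, transcript_id = src)
    total <- nrow(frags)
    if (total == 0L) {
      warning("no simulated fragment fits inside ", src,
              " (length ", n, "); reporting proportion 0")
    }
    for (rl in read_lengths) {
      uniq <- 0L
      if (total > 0L) {
        uniq <- sum(vapply(seq_len(total), function(i) {
          pair_is_unique(index, src, frags$start[i], frags$length[i], rl,
                         config, transcripts)
        }, NA))
      }
      prop <- if (total > 0L) uniq / total else 0
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = src, read_length = rl, fragments_total = total,
        fragments_unique = uniq, unique_proportion = prop,
        effective_length = n * prop)
    }
  }
  do.call(rbind, rows)
}
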
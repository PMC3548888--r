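test_that("fragment configuration derives insert bounds from mean and sd", {
  cfg <- fragment_config()
  expect_equal(cfg$mean, 250)
  expect_equal(cfg$sd, 25)
  expect_equal(cfg$draws_per_position, 5L)
  expect_equal(cfg$insert_min, 175)
  expect_equal(cfg$insert_max, 325)
  over <- fragment_config(mean = 100, sd = 10, insert_min = 60,
                          insert_max = 140)
  expect_equal(c(over$insert_min, over$insert_max), c(60, 140))
  expect_error(fragment_config(sd = 0))
})

test_that("fragment simulation discards ill-fitting fragments deterministically", {
  cfg <- fragment_config(seed = 5L)
  # nothing near 250 nt fits in 100 nt
  expect_equal(nrow(simulate_fragments(100L, cfg)), 0L)
  expect_lte(nrow(simulate_fragments(1L, cfg)), cfg$draws_per_position)

  short_cfg <- fragment_config(mean = 50, sd = 5, seed = 9L)
  a <- simulate_fragments(400L, short_cfg, "tx")
  b <- simulate_fragments(400L, short_cfg, "tx")
  expect_identical(a, b)
  expect_true(all(a$start + a$length <= 400L))
  expect_true(all(a$length >= 1L))
  # per-position streams: truncating the transcript keeps the shared
  # positions' draws identical
  c200 <- simulate_fragments(200L, short_cfg, "tx")
  expect_identical(c200, a[a$start < 200L & a$start + a$length <= 200L, ],
                   ignore_attr = TRUE)
  expect_false(identical(a, simulate_fragments(400L, short_cfg, "other")))
})

test_that("sampled fragment lengths follow the configured Gaussian", {
  cfg <- fragment_config(mean = 250, sd = 25, seed = 3L,
                         draws_per_position = 5L)
  fr <- simulate_fragments(2000L, cfg, "big")
  # fragments that fit are an unbiased sample at interior positions
  inner <- fr$length[fr$start < 1500L]
  expect_gt(length(inner), 5000L)
  expect_equal(mean(inner), 250, tolerance = 0.01)
  expect_equal(sd(inner), 25, tolerance = 0.05)
  cover <- mean(inner >= 175 & inner <= 325)
  expect_gte(cover, 0.995)  # ~99.7% within +/- 3 sd
})

test_that("pair uniqueness matches hand-enumerated pairings", {
  cfg <- fragment_config(insert_min = 4, insert_max = 4)
  idx1 <- occurrence_index(c(chr = "AACCAAGG"))
  expect_true(pair_is_unique(idx1, "chr", 0, 4, 2, cfg))
  idx2 <- occurrence_index(c(chr = "AACCAACC"))
  expect_false(pair_is_unique(idx2, "chr", 0, 4, 2, cfg))
  # complete mate overlap is non-mappable
  expect_false(pair_is_unique(idx1, "chr", 0, 2, 2, cfg))
})

test_that("pair uniqueness agrees with exhaustive span enumeration", {
  for (seed in 1:6) {
    n <- 150L + 40L * seed
    alpha <- if (seed %% 2 == 0) c("A", "C", "G", "T") else c("A", "C", "G")
    seqs <- c(chr = random_seq(n, seed * 17L, alpha))
    idx <- occurrence_index(seqs)
    cfg <- fragment_config(mean = 40, sd = 5, seed = seed,
                           insert_min = 25, insert_max = 55)
    set.seed(seed)
    for (rep in 1:15) {
      flen <- sample(25:55, 1)
      fstart <- sample(n - flen, 1) - 1L
      rl <- sample(5:12, 1)
      expect_equal(
        pair_is_unique(idx, "chr", fstart, flen, rl, cfg),
        oracle_pair_unique(seqs, "chr", fstart, flen, rl,
                           cfg$insert_min, cfg$insert_max),
        info = sprintf("seed %d fstart %d flen %d rl %d",
                       seed, fstart, flen, rl))
    }
  }
})

test_that("effective lengths follow the unique-fraction formula", {
  fx <- fx_paralogs()
  idx <- occurrence_index(fx$genome)
  cfg <- fragment_config(mean = 80, sd = 8, seed = 11L,
                         draws_per_position = 2L)
  tab <- estimate_effective_lengths(idx, "chr1", read_lengths = c(15L, 20L),
                                    config = cfg)
  expect_equal(tab$effective_length,
               nchar(fx$genome[["chr1"]]) *
                 tab$fragments_unique / tab$fragments_total)
  expect_true(all(tab$effective_length >= 0 &
                    tab$effective_length <= nchar(fx$genome[["chr1"]])))
  # recount one row against pair_is_unique directly
  fr <- simulate_fragments(nchar(fx$genome[["chr1"]]), cfg, "chr1")
  uniq <- sum(vapply(seq_len(nrow(fr)), function(i)
    pair_is_unique(idx, "chr1", fr$start[i], fr$length[i], 15L, cfg), NA))
  expect_equal(tab$fragments_unique[tab$read_length == 15L], uniq)
})

test_that("a repeat-free sequence is fully unique; a transcript too short warns", {
  seqs <- c(u = random_seq(300L, 99L))
  idx <- occurrence_index(seqs)
  # insert bounds wide enough that every simulated fragment is eligible
  # (under the default mean +/- 3 sd bounds the ~0.3% of draws outside
  # them are non-mappable by definition)
  cfg <- fragment_config(mean = 60, sd = 6, seed = 2L,
                         insert_min = 25, insert_max = 150)
  tab <- estimate_effective_lengths(idx, "u", 20L, cfg)
  expect_equal(tab$unique_proportion, 1)
  expect_equal(tab$effective_length, 300)

  idx2 <- occurrence_index(c(u = seqs[["u"]], tiny = substr(seqs[["u"]], 1, 20)))
  expect_warning(
    tab2 <- estimate_effective_lengths(idx2, "tiny", 10L,
                                       fragment_config(mean = 250, sd = 25)),
    "no simulated fragment")
  expect_equal(tab2$effective_length, 0)
})

test_that("seeds reproduce exactly and only perturb within sampling error", {
  fx <- fx_paralogs()
  idx <- occurrence_index(fx$genome)
  spliced <- vapply(fx$transcripts, function(tx)
    extract_spliced_sequence(fx$genome, tx), "")
  comb <- occurrence_index(c(fx$genome, spliced))
  run <- function(seed) {
    cfg <- fragment_config(mean = 120, sd = 12, seed = seed,
                           draws_per_position = 2L)
    estimate_effective_lengths(comb, "P1", 20L, cfg,
                               transcripts = fx$transcripts)
  }
  expect_identical(run(4L), run(4L))
  p1 <- run(4L)$unique_proportion
  p2 <- run(5L)$unique_proportion
  n <- run(4L)$fragments_total
  se <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  expect_lt(abs(p1 - p2), 6 * se + 1e-9)
})

test_that("longer inserts rescue paralog fragments (monotone trend)", {
  fx <- fx_paralogs()
  spliced <- vapply(fx$transcripts, function(tx)
    extract_spliced_sequence(fx$genome, tx), "")
  comb <- occurrence_index(c(fx$genome, spliced))
  props <- vapply(c(60, 120, 200), function(mu) {
    cfg <- fragment_config(mean = mu, sd = mu / 10, seed = 8L,
                           draws_per_position = 2L)
    tab <- estimate_effective_lengths(comb, "P1", 20L, cfg,
                                      transcripts = fx$transcripts)
    tab$unique_proportion
  }, 0)
  expect_true(all(diff(props) >= 0))
  expect_gt(props[3], props[1])
})
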
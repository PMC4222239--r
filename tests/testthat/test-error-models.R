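test_that("base substitution is seeded, length-preserving and calibrated", {
  s <- random_dna(200, seed = 1)
  expect_identical(substitute_bases(s, 0, seed = 5), s)
  # forced substitution never keeps the original base
  out <- substitute_bases(strrep("A", 500), 1, seed = 6)
  expect_false(grepl("A", out, fixed = TRUE))
  expect_equal(nchar(out), 500L)
  # determinism
  expect_identical(substitute_bases(s, 0.1, seed = 9),
                   substitute_bases(s, 0.1, seed = 9))
  expect_false(identical(substitute_bases(s, 0.1, seed = 9),
                         substitute_bases(s, 0.1, seed = 10)))
  # realized substitution fraction is Binomial(L, p): 3 sigma band at L=1e5
  L <- 100000L
  long <- random_dna(L, seed = 2)
  noisy <- substitute_bases(long, 0.1, seed = 3)
  frac <- mean(strsplit(long, "")[[1]] != strsplit(noisy, "")[[1]])
  sigma <- sqrt(0.1 * 0.9 / L)
  expect_lt(abs(frac - 0.1), 3 * sigma)
})

test_that("error-free read pairs are exact substrings with the stated count", {
  ref <- random_dna(720, seed = 4)
  spec <- read_sim_spec(read_len = 76, insert_size = 200, coverage = 90,
                        seed = 12)
  reads <- simulate_read_pairs(ref, spec, error_profile(0, 0, 0))
  # ceil(90 * 720 / (2 * 76)) = 427 pairs
  expect_equal(nrow(reads), 2L * 427L)
  expect_equal(sum(reads$mate == 1), 427L)
  joined <- paste0(ref, "|", revcomp(ref))
  expect_true(all(vapply(reads$bases[1:50], grepl, logical(1), x = joined,
                         fixed = TRUE)))
  # determinism of the whole read set
  again <- simulate_read_pairs(ref, spec, error_profile(0, 0, 0))
  expect_identical(reads$bases, again$bases)
  expect_error(simulate_read_pairs(random_dna(100, 1), spec, error_profile()),
               "insert")
})

test_that("realized error-event rates match the profile within 3 sigma", {
  ref <- random_dna(4000, seed = 5)
  profile <- error_profile()  # 0.19% sub, 0.01% ins, 0.38% del
  spec <- read_sim_spec(coverage = 250, seed = 13)
  reads <- simulate_read_pairs(ref, spec, profile)
  ev <- attr(reads, "event_counts")
  n <- ev[["template_bases"]]
  expect_gte(n, 1e6)
  for (nm in c("sub", "ins", "del")) {
    p <- switch(nm, sub = profile$p_sub, ins = profile$p_ins,
                del = profile$p_del)
    sigma <- sqrt(p * (1 - p) / n)
    expect_lt(abs(ev[[nm]] / n - p), 3 * sigma)
  }
  # deletions shorten reads; with ins << del mean length drops below 76
  expect_lt(mean(nchar(reads$bases)), 76)
})

test_that("substituted bases get sub-Q40 qualities so trimming can see them", {
  ref <- random_dna(720, seed = 6)
  reads <- simulate_read_pairs(
    ref, read_sim_spec(coverage = 30, seed = 14),
    error_profile(p_sub = 0.05, p_ins = 0, p_del = 0))
  q <- unlist(lapply(reads$quals, function(x) utf8ToInt(x) - 33L))
  expect_true(all(q %in% c(20:39, 40L)))
  expect_gt(sum(q < 40), 0)
  # trimming at Q32 removes every 3'-tail that starts at a substitution
  trimmed <- quality_trim(reads, min_q = 32)
  qt <- unlist(lapply(trimmed$quals, function(x) utf8ToInt(x) - 33L))
  expect_true(all(qt >= 32L))
})

test_that("down-sampling keeps mates together and hits the requested size", {
  ref <- random_dna(2000, seed = 7)
  reads <- simulate_read_pairs(ref, read_sim_spec(coverage = 76, seed = 15),
                               error_profile(0, 0, 0))
  n_pairs <- length(unique(reads$pair_id))
  expect_equal(n_pairs, 1000L)
  half <- downsample_reads(reads, fraction = 0.5, seed = 16)
  expect_equal(length(unique(half$pair_id)), 500L)
  expect_true(all(table(half$pair_id) == 2L))
  # target-coverage mode
  ds <- downsample_reads(reads, target_coverage = 19, reference_len = 2000,
                         seed = 17)
  expect_equal(length(unique(ds$pair_id)), 250L)
  expect_identical(downsample_reads(reads, fraction = 1, seed = 18)$id,
                   reads$id)
  expect_equal(nrow(downsample_reads(reads, fraction = 0, seed = 19)), 0L)
  expect_error(downsample_reads(reads, target_coverage = 200,
                                reference_len = 2000, seed = 20),
               "exceeds")
  # determinism
  expect_identical(downsample_reads(reads, fraction = 0.3, seed = 21)$id,
                   downsample_reads(reads, fraction = 0.3, seed = 21)$id)
})
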
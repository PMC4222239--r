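reads_df <- function(bases, quals = NULL, ids = NULL) {
  n <- length(bases)
  if (is.null(quals)) quals <- strrep("I", nchar(bases))  # Q40
  if (is.null(ids)) ids <- sprintf("r%02d", seq_len(n))
  data.frame(id = ids, bases = bases, quals = quals,
             mate = rep(NA_integer_, n), pair_id = ids,
             stringsAsFactors = FALSE)
}

phred_string <- function(q) intToUtf8(q + 33L)

test_that("quality trimming keeps the longest high-quality prefix", {
  r <- reads_df(c("ACGTACGTACGTACGTACGTACGTACGT"))
  expect_identical(quality_trim(r, min_q = 32)$bases, r$bases)  # all Q40

  # quality dip at position 3 truncates there; the 2-base rest is discarded
  r <- reads_df("ACGT", quals = phred_string(c(40, 40, 30, 40)))
  trimmed <- quality_trim(r, min_q = 32, min_keep_len = 2)
  expect_identical(trimmed$bases, "AC")
  expect_identical(trimmed$quals, phred_string(c(40, 40)))
  expect_equal(nrow(quality_trim(r, min_q = 32, min_keep_len = 25)), 0L)

  # hopeless reads vanish entirely
  r <- reads_df(strrep("A", 30), quals = strrep(phred_string(10), 30))
  expect_equal(nrow(quality_trim(r, min_q = 32)), 0L)

  # N bases are not usable by the two-bit alphabet
  r <- reads_df(paste0(strrep("A", 20), "N", strrep("C", 10)))
  expect_equal(nrow(quality_trim(r, min_q = 32)), 0L)
})

test_that("the prefix index finds overlaps in both orientations", {
  ref <- random_dna(120, seed = 42)
  reads <- reads_df(c(substr(ref, 1, 40), revcomp(substr(ref, 21, 60))))
  idx <- build_prefix_index(reads, min_overlap = 16L)
  # forward read and the RC of the reverse read are both indexed
  expect_equal(length(idx$seqs), 4L)
  expect_true(substr(ref, 21, 60) %in% idx$seqs)
  hits <- dnastore:::overlap_hits(substr(ref, 1, 30), 30L, idx)
  expect_gt(length(hits$seq), 0L)
  # queries against an empty index come back empty
  empty <- build_prefix_index(reads_df(character(0)), min_overlap = 16L)
  expect_equal(length(dnastore:::overlap_hits("ACGTACGTACGTACGTACGT", 20L,
                                              empty)$seq), 0L)
})

test_that("a seed with no matching reads is returned unchanged", {
  idx <- build_prefix_index(reads_df(character(0)), min_overlap = 16L)
  seed <- random_dna(30, seed = 8)
  ctg <- extend_seed(seed, idx, seed_id = "lonely")
  expect_identical(ctg$consensus, seed)
  expect_equal(ctg$n_reads, 0L)
})

test_that("error-free tiling reads reconstruct the reference exactly", {
  enc <- fixture_encoding()
  ref <- enc$blocks[[1]]$bases
  for (s in 1:5) {
    reads <- quality_trim(make_tiling_reads(ref, step = 6L, seed = s))
    idx <- build_prefix_index(reads, min_overlap = 50L)
    ctg <- extend_seed(enc$blocks[[1]]$header_bases, idx)
    expect_identical(ctg$consensus, ref)
    expect_true(all(ctg$coverage >= 1L))
  }
})

test_that("majority vote overcomes scattered substitution errors at depth", {
  enc <- fixture_encoding()
  ref <- enc$blocks[[2]]$bases
  reads <- simulate_read_pairs(
    ref, read_sim_spec(coverage = 100, seed = 17),
    error_profile(p_sub = 0.005, p_ins = 0, p_del = 0))
  reads <- quality_trim(reads)
  idx <- build_prefix_index(reads, min_overlap = 50L)
  ctg <- extend_seed(enc$blocks[[2]]$header_bases, idx)
  # interior must be error-free; terminal coverage decay may shorten the
  # contig by a few bases, which is not an assembly error
  expect_gte(nchar(ctg$consensus), 700L)
  expect_identical(substr(ref, 1, nchar(ctg$consensus)), ctg$consensus)
})

test_that("assembly is invariant under read-order shuffling", {
  enc <- fixture_encoding()
  ref <- enc$blocks[[3]]$bases
  reads <- quality_trim(simulate_read_pairs(
    ref, read_sim_spec(coverage = 60, seed = 23), error_profile()))
  base_ctg <- NULL
  for (s in 1:3) {
    shuffled <- withr::with_seed(s, reads[sample(nrow(reads)), ])
    idx <- build_prefix_index(shuffled, min_overlap = 50L)
    ctg <- extend_seed(enc$blocks[[3]]$header_bases, idx)
    if (is.null(base_ctg)) base_ctg <- ctg$consensus
    expect_identical(ctg$consensus, base_ctg)
  }
})

test_that("one contig is produced per header, flagged when underbuilt", {
  enc <- fixture_encoding()
  headers <- vapply(enc$blocks, `[[`, character(1), "header_bases")
  # no reads at all: seeds come back as short contigs, flagged
  ctgs <- assemble_blocks(reads_df(character(0)), headers, expected_len = 720)
  expect_length(ctgs, 6L)
  expect_true(all(vapply(ctgs, function(c) c$flagged_short, logical(1))))
  expect_true(all(vapply(ctgs, function(c) nchar(c$consensus), integer(1)) == 24L))
  rep <- contig_report(ctgs)
  expect_equal(nrow(rep), 6L)
  expect_true(all(rep$flagged_short))
  expect_error(assemble_blocks(reads_df(character(0)), headers[c(1, 1)]),
               "duplicate")
})

test_that("two blocks assemble from a pooled read set", {
  enc <- fixture_encoding()
  refs <- vapply(enc$blocks[1:2], `[[`, character(1), "bases")
  pool <- do.call(rbind, lapply(1:2, function(i) {
    r <- simulate_read_pairs(refs[i], read_sim_spec(coverage = 80, seed = 30 + i),
                             error_profile())
    r$id <- paste0("b", i, "_", r$id); r$pair_id <- paste0("b", i, "_", r$pair_id)
    r
  }))
  pool <- quality_trim(pool)
  headers <- vapply(enc$blocks[1:2], `[[`, character(1), "header_bases")
  ctgs <- assemble_blocks(pool, headers, expected_len = 720)
  for (i in 1:2) {
    expect_gte(percent_identity(ctgs[[i]]$consensus, refs[i]), 99)
  }
})

test_that("consensus base always carries the maximal tally", {
  enc <- fixture_encoding()
  ref <- enc$blocks[[1]]$bases
  reads <- quality_trim(simulate_read_pairs(
    ref, read_sim_spec(coverage = 50, seed = 77), error_profile()))
  idx <- build_prefix_index(reads, min_overlap = 50L)
  ctg <- extend_seed(enc$blocks[[1]]$header_bases, idx)
  cons <- strsplit(ctg$consensus, "")[[1]]
  covered <- which(ctg$coverage > 0L)
  ok <- vapply(covered, function(p) {
    ctg$counts[cons[p], p] == max(ctg$counts[, p])
  }, logical(1))
  expect_true(all(ok))
  expect_equal(ctg$coverage, as.integer(colSums(ctg$counts)))
})
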
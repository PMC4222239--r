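test_that("LZMA compression round-trips arbitrary payloads", {
  expect_identical(decompress_payload(compress_payload(raw(0))), raw(0))
  img <- make_fixture_image()
  expect_identical(decompress_payload(compress_payload(img)), img)
  # degenerate highly redundant input compresses strictly
  blob <- as.raw(rep(7L, 1024))
  expect_lt(length(compress_payload(blob)), length(blob))
  payload <- as.raw(withr::with_seed(5, sample(0:255, 200, replace = TRUE)))
  expect_identical(decompress_payload(compress_payload(payload)), payload)
})

test_that("bit/base mapping follows the quaternary table and inverts exactly", {
  expect_equal(bits_to_bases(c(0, 0, 0, 1, 1, 0, 1, 1)), "ATCG")
  expect_equal(bits_to_bases(integer(0)), "")
  expect_equal(bases_to_bits("GATC"), c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L))
  expect_equal(bases_to_bits(strrep("A", 10)), rep(0L, 20))
  expect_error(bits_to_bases(c(0, 1, 0)), "even")
  expect_error(bases_to_bits("ACGNA"), "position 4")
  withr::with_seed(11, {
    for (i in 1:10) {
      x <- sample(0:1, 2 * sample(1:50, 1), replace = TRUE)
      expect_equal(bases_to_bits(bits_to_bases(x)), x)
    }
  })
})

test_that("fragmentation partitions the bit stream with recorded padding", {
  # exact division: 12 bytes over 6 fragments of 16 bits
  frags <- fragment_payload(as.raw(1:12), 6, 16)
  expect_length(frags, 6L)
  expect_true(all(vapply(frags, `[[`, integer(1), "pad_len") == 0L))
  expect_equal(vapply(frags, `[[`, integer(1), "address"), 0:5)
  # 11 bytes = 88 bits into 6 x 16: last fragment padded by 8
  frags <- fragment_payload(as.raw(1:11), 6, 16)
  expect_equal(vapply(frags, `[[`, integer(1), "pad_len"),
               c(0L, 0L, 0L, 0L, 0L, 8L))
  # reassembly in shuffled order restores the bytes
  expect_identical(defragment_payload(rev(frags)), as.raw(1:11))
  expect_error(fragment_payload(as.raw(1:13), 6, 16), "capacity")
})

test_that("address headers are repetition-protected and parse back", {
  hs <- header_candidates(6)
  expect_true(all(nchar(hs) == 24L))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_gte(dnastore:::hamming_dist(hs[i], hs[j]), 3)
  }
  for (a in 0:5) {
    expect_identical(make_header(a, 6), make_header(a, 6))
    got <- parse_header(make_header(a, 6))
    expect_equal(got$address, a)
    expect_equal(got$total, 6L)
  }
  # single-base damage within one repetition triple is corrected
  h <- make_header(3, 6)
  damaged <- paste0("G", substr(h, 2, 24))
  expect_equal(parse_header(damaged)$address, 3L)
  expect_error(make_header(6, 6), "address")
})

test_that("the fixture encodes to six 720-base blocks and round-trips", {
  enc <- fixture_encoding()
  img <- make_fixture_image()
  expect_length(enc$blocks, 6L)
  for (b in enc$blocks) {
    expect_equal(nchar(b$bases), 720L)
    expect_equal(nchar(b$header_bases), 24L)
    expect_equal(nchar(b$payload_bases), 696L)
    expect_false(grepl("[^ACGT]", b$bases))
  }
  headers <- vapply(enc$blocks, `[[`, character(1), "header_bases")
  expect_equal(anyDuplicated(headers), 0L)
  blocks <- vapply(enc$blocks, `[[`, character(1), "bases")
  expect_identical(decode_message(blocks, enc$container, channel_spec(0)), img)
})

test_that("decoding is invariant to contig order and survives 2% substitution", {
  enc <- fixture_encoding()
  img <- make_fixture_image()
  blocks <- vapply(enc$blocks, `[[`, character(1), "bases")
  withr::with_seed(3, {
    for (rep in 1:3) {
      expect_identical(
        decode_message(sample(blocks), enc$container, channel_spec(0)), img)
    }
  })
  noisy <- vapply(seq_along(blocks), function(b) {
    substitute_bases(blocks[b], 0.02, seed = 400 + b)
  }, character(1))
  expect_identical(decode_message(noisy, enc$container, channel_spec(0.02)),
                   img)
})

test_that("decode failures carry distinct, named condition classes", {
  enc <- fixture_encoding()
  blocks <- vapply(enc$blocks, `[[`, character(1), "bases")
  expect_error(decode_message(blocks[-3], enc$container, channel_spec(0)),
               "missing address 2", class = "dnastore_missing_address")
  expect_error(decode_message(c(blocks, blocks[1]), enc$container,
                              channel_spec(0)),
               class = "dnastore_duplicate_address")
  expect_error(decode_message(blocks[c(1, 1, 2, 3, 4, 5)], enc$container,
                              channel_spec(0)),
               "indistinguishable", class = "dnastore_duplicate_address")
  # a block scrambled beyond repair must surface as non-convergence
  hopeless <- blocks
  hopeless[2] <- paste0(substr(hopeless[2], 1, 24),
                        substitute_bases(substr(hopeless[2], 25, 720),
                                         0.45, seed = 99))
  expect_error(decode_message(hopeless, enc$container, channel_spec(0.1)),
               class = "dnastore_nonconvergence")
})

test_that("round trip at zero noise is bit-exact for random payloads", {
  code <- build_regular_code(144, 72, 3, seed = 7)
  withr::with_seed(21, {
    for (i in 1:5) {
      # capacity must absorb the fixed xz container overhead (~60 bytes)
      n_frag <- sample(9:12, 1)
      payload <- as.raw(sample(0:255, sample(2:12, 1), replace = TRUE))
      enc <- encode_message(payload, n_fragments = n_frag, code = code)
      got <- decode_message(
        vapply(enc$blocks, `[[`, character(1), "bases"),
        enc$container, channel_spec(0))
      expect_identical(got, payload)
    }
  })
})
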
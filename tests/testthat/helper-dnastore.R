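# Shared fixtures and independent oracles for the test suite.

# small reference code used throughout; cheap to rebuild but cached anyway
tiny_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- build_regular_code(12, 6, 3, seed = 1)
    code
  }
})

# the production-layout encoding of the fixture image, built once
fixture_encoding <- local({
  enc <- NULL
  function() {
    if (is.null(enc)) enc <<- encode_message(make_fixture_image(),
                                             name = "fixture")
    enc
  }
})

# all 2^k codewords of a small code, one per row
enumerate_codewords <- function(code) {
  k <- code$k
  msgs <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  t(apply(msgs, 1, ldpc_encode, code = code))
}

# brute-force maximum-likelihood decoding: indices of all nearest codewords
ml_nearest <- function(received, codewords) {
  d <- rowSums(codewords != rep(received, each = nrow(codewords)))
  which(d == min(d))
}

# independent Needleman-Wunsch oracle: global alignment with match +1,
# mismatch -1, gap -2; returns 100 * matches / alignment_length via a full
# DP + traceback, written without reference to the package implementation
nw_identity_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -2 * (0:n); S[1, ] <- -2 * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + ifelse(A[i] == B[j], 1, -1),
                           S[i, j + 1] - 2,
                           S[i + 1, j] - 2)
  }
  # traceback counting matched columns and total columns
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    cols <- cols + 1
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(A[i] == B[j], 1, -1)) {
      if (A[i] == B[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  100 * matches / cols
}

# error-free reads laid out to tile the whole reference (every position
# covered by construction, unlike random fragment draws whose terminal
# coverage decays); both orientations per start, order shuffled per seed
make_tiling_reads <- function(ref, step = 6L, read_len = 76L, seed = 1L) {
  L <- nchar(ref)
  starts <- seq(1L, L - read_len + 1L, by = step)
  if (starts[length(starts)] != L - read_len + 1L) {
    starts <- c(starts, L - read_len + 1L)
  }
  fwd <- substr(rep(ref, length(starts)), starts, starts + read_len - 1L)
  bases <- c(fwd, revcomp(fwd))
  n <- length(bases)
  withr::with_seed(seed, {
    ord <- sample(n)
    data.frame(id = sprintf("r%04d", seq_len(n)),
               bases = bases,
               quals = strrep(rawToChar(as.raw(40L + 33L)), nchar(bases)),
               mate = NA_integer_,
               pair_id = sprintf("r%04d", seq_len(n)),
               stringsAsFactors = FALSE)[ord, ]
  })
}

random_dna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}
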
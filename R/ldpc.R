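#' Regular low-density parity-check codes
#'
#' Construction, systematic encoding and sum-product decoding of regular
#' (Gallager-style) binary LDPC codes. The storage pipeline protects each
#' message fragment with one codeword of such a code; the default production
#' code has n = 1392 bits (696 bases) so that a 24-base address header plus
#' the codeword payload totals exactly 720 bases per DNA information block.
#'
#' @name ldpc
NULL

# ---- GF(2) linear algebra (internal) ----------------------------------------

# Reduced row echelon form over GF(2). Returns list(mat, pivots, rank).
gf2_rref <- function(H) {
  m <- nrow(H); n <- ncol(H)
  H <- H %% 2L
  pivots <- integer(0)
  r <- 1L
  for (col in seq_len(n)) {
    if (r > m) break
    hit <- which(H[r:m, col] == 1L)
    if (length(hit) == 0L) next
    p <- r + hit[1] - 1L
    if (p != r) H[c(r, p), ] <- H[c(p, r), ]
    others <- which(H[, col] == 1L)
    others <- others[others != r]
    if (length(others)) {
      H[others, ] <- (H[others, , drop = FALSE] +
                        rep(H[r, ], each = length(others))) %% 2L
    }
    pivots <- c(pivots, col)
    r <- r + 1L
  }
  list(mat = H, pivots = pivots, rank = length(pivots))
}

gf2_rank <- function(H) gf2_rref(H)$rank

# ---- construction -----------------------------------------------------------

# One seeded draw of a column-regular parity-check matrix: every column gets
# `col_weight` distinct rows, chosen to keep row weights as even as possible;
# duplicate columns are re-drawn (they would force minimum distance 2).
draw_regular_H <- function(n, m, col_weight, max_tries = 1000L) {
  H <- matrix(0L, nrow = m, ncol = n)
  fill <- integer(m)
  seen <- new.env(parent = emptyenv())
  for (j in seq_len(n)) {
    for (tries in seq_len(max_tries)) {
      rows <- integer(0)
      f <- fill
      for (w in seq_len(col_weight)) {
        avail <- setdiff(seq_len(m), rows)
        cand <- avail[f[avail] == min(f[avail])]
        pick <- cand[sample.int(length(cand), 1L)]
        rows <- c(rows, pick)
        f[pick] <- f[pick] + 1L
      }
      key <- paste(sort(rows), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        H[rows, j] <- 1L
        fill <- f
        break
      }
      if (tries == max_tries) stop("cannot draw distinct columns; m too small for n at this column weight")
    }
  }
  H
}

#' Construct a regular LDPC code
#'
#' Builds a column-regular Gallager-style parity-check matrix with `n - k`
#' rows and derives a systematic encoder by Gauss-Jordan elimination over
#' GF(2). Construction is deterministic given `seed`: if a draw is rank
#' deficient (or contains duplicate columns), further columns/matrices are
#' re-drawn from the same seeded stream until the parity-check matrix has
#' full row rank.
#'
#' @param n Codeword length in bits.
#' @param k Information length in bits (`0 < k < n`).
#' @param col_weight Number of checks per bit (column weight, >= 2).
#' @param seed Integer seed controlling the construction.
#' @param max_attempts Number of seeded re-draws allowed before giving up.
#' @return An object of class `ldpc_code`: a list with elements `n`, `k`,
#'   `m`, `H` (0/1 integer matrix), `col_weight`, `seed`, `rate`,
#'   `info_idx` (systematic bit positions), `parity_idx` (pivot positions)
#'   and `B` (the m-by-k GF(2) map from information bits to parity bits).
#' @export
#' @examples
#' code <- build_regular_code(n = 12, k = 6, col_weight = 3, seed = 1)
#' code$rate
build_regular_code <- function(n, k, col_weight = 3L, seed = 1L,
                               max_attempts = 50L) {
  stopifnot(n > k, k > 0, col_weight >= 2, col_weight <= n - k)
  m <- n - k
  res <- withr::with_seed(as.integer(seed), {
    out <- NULL
    for (attempt in seq_len(max_attempts)) {
      H <- draw_regular_H(n, m, col_weight)
      rr <- gf2_rref(H)
      if (rr$rank == m) { out <- list(H = H, rr = rr); break }
    }
    out
  })
  if (is.null(res)) {
    stop("could not reach a full-row-rank parity-check matrix for n=", n,
         ", k=", k, ", col_weight=", col_weight,
         " after ", max_attempts, " attempts")
  }
  H <- res$H
  rr <- res$rr
  parity_idx <- rr$pivots
  info_idx <- setdiff(seq_len(n), parity_idx)
  # In RREF, columns at pivots form I_m, so for codewords H c = 0:
  #   c[parity_idx] = B %*% c[info_idx]  (mod 2)
  B <- rr$mat[, info_idx, drop = FALSE]
  edges <- which(H == 1L, arr.ind = TRUE)
  structure(
    list(n = as.integer(n), k = as.integer(k), m = as.integer(m),
         H = H, col_weight = as.integer(col_weight),
         seed = as.integer(seed), rate = k / n,
         info_idx = info_idx, parity_idx = parity_idx, B = B,
         edge_row = as.integer(edges[, 1] - 1L),
         edge_col = as.integer(edges[, 2] - 1L)),
    class = "ldpc_code")
}

#' @export
print.ldpc_code <- function(x, ...) {
  cat(sprintf("Regular LDPC code: n = %d, k = %d (rate %.3f), column weight %d, seed %d\n",
              x$n, x$k, x$rate, x$col_weight, x$seed))
  invisible(x)
}

#' The production storage code
#'
#' The default code used for 720-base DNA information blocks: n = 1392,
#' k = 640, column weight 3 (rate ~ 0.46, comfortably below binary-symmetric
#' channel capacity at a 4% base-substitution rate). The constructed code is
#' cached for the session.
#'
#' @param n,k,col_weight,seed Code parameters; the defaults are the
#'   production block layout.
#' @return An `ldpc_code`.
#' @export
default_code <- function(n = 1392L, k = 640L, col_weight = 3L, seed = 101L) {
  key <- paste(n, k, col_weight, seed, sep = "_")
  if (is.null(.dnastore_cache[[key]])) {
    .dnastore_cache[[key]] <- build_regular_code(n, k, col_weight, seed)
  }
  .dnastore_cache[[key]]
}

# ---- channel ----------------------------------------------------------------

#' Describe the substitution channel seen by the decoder
#'
#' Base substitutions are quaternary-symmetric: a substituted base is uniform
#' over the other three. Each base carries two bits, and under that model a
#' substitution flips each of its bits with probability 2/3, so the induced
#' bit-level crossover used for decoder LLRs is `p_bit = (2/3) * p_base`.
#'
#' @param p_base Per-base substitution probability in `[0, 1)`.
#' @return An object of class `channel_spec` with `p_base` and `p_bit`.
#' @export
channel_spec <- function(p_base) {
  stopifnot(is.numeric(p_base), length(p_base) == 1L, p_base >= 0, p_base < 1)
  structure(list(p_base = p_base, p_bit = (2 / 3) * p_base),
            class = "channel_spec")
}

# ---- encode / syndrome / decode --------------------------------------------

#' Systematically encode information bits
#'
#' @param info_bits 0/1 vector of length `code$k`; returned unchanged at the
#'   systematic positions of the codeword.
#' @param code An [`ldpc_code`][build_regular_code].
#' @return 0/1 integer vector of length `code$n` with zero syndrome.
#' @export
ldpc_encode <- function(info_bits, code) {
  stopifnot(inherits(code, "ldpc_code"))
  check_bits(info_bits)
  if (length(info_bits) != code$k) {
    stop("info_bits must have length k = ", code$k, ", got ", length(info_bits))
  }
  u <- as.integer(info_bits)
  cw <- integer(code$n)
  cw[code$info_idx] <- u
  cw[code$parity_idx] <- as.integer((code$B %*% u) %% 2L)
  cw
}

#' Parity-check syndrome
#'
#' @param bits 0/1 vector of length `code$n`.
#' @param code An `ldpc_code`.
#' @return `H %*% bits mod 2`, an integer vector of length `code$m`
#'   (all zero exactly for codewords).
#' @export
syndrome <- function(bits, code) {
  stopifnot(inherits(code, "ldpc_code"))
  check_bits(bits)
  if (length(bits) != code$n) {
    stop("bits must have length n = ", code$n, ", got ", length(bits))
  }
  as.integer((code$H %*% as.integer(bits)) %% 2L)
}

#' Decode received bits by sum-product belief propagation
#'
#' Message passing on the Tanner graph of `H` with hard-decision channel
#' LLRs of magnitude `log((1 - p_bit) / p_bit)`. Iteration stops as soon as
#' the running hard decision satisfies every parity check, or after
#' `max_iter` iterations. Non-convergence is reported in the returned flag,
#' never as an error. With `p_bit = 0` the channel is noiseless and decoding
#' reduces to a syndrome check on the received word.
#'
#' @param received_bits 0/1 vector of length `code$n`.
#' @param code An `ldpc_code`.
#' @param channel A [channel_spec()].
#' @param max_iter Maximum belief-propagation iterations (default 100).
#' @return List with `info_bits` (length `code$k`), `converged` (logical:
#'   the final hard decision is a codeword), `iterations`, and `codeword`
#'   (the full length-n hard decision).
#' @export
ldpc_decode <- function(received_bits, code, channel = channel_spec(0.01),
                        max_iter = 100L) {
  stopifnot(inherits(code, "ldpc_code"), inherits(channel, "channel_spec"))
  check_bits(received_bits)
  if (length(received_bits) != code$n) {
    stop("received_bits must have length n = ", code$n,
         ", got ", length(received_bits))
  }
  y <- as.integer(received_bits)
  if (channel$p_bit <= 0) {
    conv <- all(syndrome(y, code) == 0L)
    return(list(info_bits = y[code$info_idx], converged = conv,
                iterations = 0L, codeword = y))
  }
  stopifnot(channel$p_bit < 0.5)
  llr <- log((1 - channel$p_bit) / channel$p_bit)
  res <- .bp_decode_cpp(y, code$edge_row, code$edge_col,
                        code$m, code$n, llr, as.integer(max_iter))
  bits <- as.integer(res$bits)
  list(info_bits = bits[code$info_idx],
       converged = isTRUE(res$converged),
       iterations = as.integer(res$iterations),
       codeword = bits)
}

# ---- alist interchange ------------------------------------------------------

#' Write a parity-check matrix in alist format
#'
#' The alist sparse text format is the de facto interchange format for LDPC
#' parity-check matrices (columns first, then rows, 1-based indices, zero
#' padding for irregular degrees).
#'
#' @param code An `ldpc_code` (or a 0/1 matrix).
#' @param path Output file path.
#' @export
write_alist <- function(code, path) {
  H <- if (inherits(code, "ldpc_code")) code$H else code
  m <- nrow(H); n <- ncol(H)
  col_lists <- lapply(seq_len(n), function(j) which(H[, j] == 1L))
  row_lists <- lapply(seq_len(m), function(i) which(H[i, ] == 1L))
  cw <- lengths(col_lists); rw <- lengths(row_lists)
  pad <- function(v, len) c(v, rep(0L, len - length(v)))
  lines <- c(
    paste(n, m),
    paste(max(cw), max(rw)),
    paste(cw, collapse = " "),
    paste(rw, collapse = " "),
    vapply(col_lists, function(v) paste(pad(v, max(cw)), collapse = " "), character(1)),
    vapply(row_lists, function(v) paste(pad(v, max(rw)), collapse = " "), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a parity-check matrix from alist format
#'
#' @param path Path to an alist file.
#' @return A 0/1 integer matrix.
#' @export
read_alist <- function(path) {
  toks <- lapply(readLines(path), function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  n <- toks[[1]][1]; m <- toks[[1]][2]
  H <- matrix(0L, nrow = m, ncol = n)
  for (j in seq_len(n)) {
    rows <- toks[[4L + j]]
    rows <- rows[rows > 0L]
    H[rows, j] <- 1L
  }
  H
}
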
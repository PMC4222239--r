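#' Bit-level and base-level conversions
#'
#' The codec represents data as integer vectors of 0/1 bits. Bytes are
#' traversed most-significant bit first, and consecutive bit pairs map onto
#' the quaternary DNA alphabet with A=0, T=1, C=2, G=3 (most-significant bit
#' first within each pair).
#'
#' @name bit-conversions
NULL

#' Convert raw bytes to a bit vector
#'
#' Each byte contributes eight bits, most-significant first.
#'
#' @param bytes A `raw` vector.
#' @return Integer vector of 0/1 of length `8 * length(bytes)`.
#' @export
#' @examples
#' bytes_to_bits(as.raw(c(0xB4)))  # 1 0 1 1 0 1 0 0
bytes_to_bits <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (length(bytes) == 0L) return(integer(0))
  m <- matrix(as.integer(rawToBits(bytes)), nrow = 8L)  # row 1 = LSB
  as.vector(m[8:1, , drop = FALSE])
}

#' Convert a bit vector back to raw bytes
#'
#' Inverse of [bytes_to_bits()]; length must be a multiple of 8.
#'
#' @param bits Integer vector of 0/1.
#' @return A `raw` vector.
#' @export
bits_to_bytes <- function(bits) {
  check_bits(bits)
  if (length(bits) %% 8L != 0L) {
    stop("bit vector length must be a multiple of 8, got ", length(bits))
  }
  if (length(bits) == 0L) return(raw(0))
  m <- matrix(as.integer(bits), nrow = 8L)
  packBits(as.vector(m[8:1, , drop = FALSE]) == 1L, type = "raw")
}

check_bits <- function(bits) {
  if (!is.numeric(bits) && !is.logical(bits)) {
    stop("bits must be a numeric or logical vector of 0/1")
  }
  if (length(bits) && !all(bits %in% c(0L, 1L))) {
    stop("bits must contain only 0 and 1")
  }
  invisible(TRUE)
}

.base_alphabet <- c("A", "T", "C", "G")  # digit order 0,1,2,3

#' Map a bit vector onto DNA bases
#'
#' Consecutive bit pairs (most-significant bit first) become quaternary
#' digits which map onto bases as A=0, T=1, C=2, G=3.
#'
#' @param bits Integer vector of 0/1, of even length.
#' @return A DNA string of `length(bits)/2` bases.
#' @export
#' @examples
#' bits_to_bases(c(0,0, 0,1, 1,0, 1,1))  # "ATCG"
bits_to_bases <- function(bits) {
  check_bits(bits)
  if (length(bits) %% 2L != 0L) {
    stop("bit vector length must be even, got ", length(bits))
  }
  if (length(bits) == 0L) return("")
  b <- as.integer(bits)
  digit <- 2L * b[c(TRUE, FALSE)] + b[c(FALSE, TRUE)]
  paste(.base_alphabet[digit + 1L], collapse = "")
}

#' Map DNA bases back to bits
#'
#' Exact inverse of [bits_to_bases()]. Non-ACGT symbols are an error that
#' reports the offending position.
#'
#' @param seq A DNA string over A/C/G/T.
#' @return Integer vector of 0/1 of length `2 * nchar(seq)`.
#' @export
bases_to_bits <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(integer(0))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  digit <- match(ch, .base_alphabet) - 1L
  if (anyNA(digit)) {
    pos <- which(is.na(digit))[1]
    stop("invalid DNA symbol '", ch[pos], "' at position ", pos)
  }
  bits <- integer(2L * length(digit))
  bits[c(TRUE, FALSE)] <- digit %/% 2L
  bits[c(FALSE, TRUE)] <- digit %% 2L
  bits
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (A/C/G/T/N).
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# CRC-32 (IEEE 802.3, reflected, poly 0xEDB88320) of a raw vector.
# Used as the end-to-end payload checksum recorded in the storage container.
.crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    crc <- i
    for (j in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L) {
        bitwXor(bitwShiftR(crc, 1L), -306674912L)  # 0xEDB88320 as signed int
      } else {
        bitwShiftR(crc, 1L)
      }
    }
    tab[i + 1L] <- crc
  }
  tab
})

#' CRC-32 checksum of raw bytes
#'
#' Standard IEEE CRC-32, returned as an 8-character uppercase hex string.
#'
#' @param bytes A `raw` vector.
#' @return Character scalar, e.g. `"CBF43926"`.
#' @export
crc32 <- function(bytes) {
  stopifnot(is.raw(bytes))
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8L), .crc32_table[idx + 1L])
  }
  crc <- bitwXor(crc, -1L)
  sprintf("%04X%04X", bitwAnd(bitwShiftR(crc, 16L), 65535L), bitwAnd(crc, 65535L))
}
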
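#' The DNA storage codec pipeline
#'
#' Binary payloads are LZMA-compressed, split into non-overlapping
#' fragments, each fragment is LDPC-encoded, prefixed with an address
#' header, and mapped two bits per base onto DNA. With the production code
#' every DNA information block is exactly 720 bases: a 24-base header plus
#' 696 payload bases (1392 codeword bits).
#'
#' @name codec
NULL

.container_version <- "1.0"
.default_header_len <- 24L

# ---- compression -------------------------------------------------------------

#' Lossless LZMA compression of a payload
#'
#' Dictionary (Lempel-Ziv-Markov chain) compression via the xz/LZMA stream
#' coder. The compression id is recorded in the storage container so the
#' decoder never relies on defaults.
#'
#' @param raw A `raw` vector (may be empty).
#' @return Compressed `raw` vector.
#' @export
compress_payload <- function(raw) {
  stopifnot(is.raw(raw))
  memCompress(raw, type = "xz")
}

#' @rdname compress_payload
#' @param compressed A `raw` vector produced by [compress_payload()].
#' @export
decompress_payload <- function(compressed) {
  stopifnot(is.raw(compressed))
  memDecompress(compressed, type = "xz")
}

# ---- fragmentation -----------------------------------------------------------

#' Split a compressed payload into equal, non-overlapping fragments
#'
#' The bit stream of `compressed` is cut into `n_fragments` disjoint slices
#' of `k` bits each, addressed 0 to `n_fragments - 1`. Slices beyond the end
#' of the stream are zero padded and the padding length per fragment is
#' recorded so reassembly is exact.
#'
#' @param compressed Non-empty `raw` vector.
#' @param n_fragments Number of fragments (>= 1).
#' @param k Information bits per fragment.
#' @return List of fragments, each a list with `address`, `total`,
#'   `info_bits` (length `k`) and `pad_len`.
#' @export
fragment_payload <- function(compressed, n_fragments, k) {
  stopifnot(is.raw(compressed), length(compressed) > 0,
            n_fragments >= 1, k >= 1)
  bits <- bytes_to_bits(compressed)
  capacity <- n_fragments * k
  if (length(bits) > capacity) {
    stop("compressed payload of ", length(bits), " bits exceeds capacity ",
         capacity, " (", n_fragments, " fragments x ", k, " bits)")
  }
  lapply(seq_len(n_fragments) - 1L, function(a) {
    lo <- a * k + 1L
    hi <- min((a + 1L) * k, length(bits))
    slice <- if (lo <= length(bits)) bits[lo:hi] else integer(0)
    pad <- k - length(slice)
    list(address = a, total = as.integer(n_fragments),
         info_bits = c(slice, integer(pad)), pad_len = as.integer(pad))
  })
}

#' Reassemble fragments into the compressed byte stream
#'
#' @param fragments List of fragments as produced by [fragment_payload()]
#'   (any order; sorted by address).
#' @return The original compressed `raw` vector, padding stripped.
#' @export
defragment_payload <- function(fragments) {
  ord <- order(vapply(fragments, `[[`, integer(1), "address"))
  fragments <- fragments[ord]
  bits <- unlist(lapply(fragments, function(f) {
    keep <- length(f$info_bits) - f$pad_len
    f$info_bits[seq_len(keep)]
  }))
  bits_to_bytes(bits)
}

# ---- address headers ---------------------------------------------------------

# header layout: 4 quaternary digits of the address then 4 of the total,
# most-significant digit first, every digit repeated 3x -> 24 bases.
.header_digits <- 4L
.header_rep <- 3L

value_to_quaternary <- function(x, n_digits) {
  (x %/% 4L^((n_digits - 1L):0)) %% 4L
}

#' Build the address header of a DNA information block
#'
#' Encodes `(address, total)` as quaternary digits with threefold base
#' repetition, giving a fixed 24-base header whose pairwise Hamming distance
#' between distinct addresses is at least the repetition factor. Headers are
#' deliberately not LDPC protected; they are short, heavily repeated, and
#' the decoder can enumerate every candidate header, so nearest-match
#' assignment is robust. The header doubles as the assembly seed.
#'
#' @param address Fragment address, `0 <= address < total`.
#' @param total Number of fragments (at most 256 with the 4-digit layout).
#' @return A 24-base DNA string.
#' @export
make_header <- function(address, total) {
  stopifnot(address >= 0, total >= 1, address < total,
            total <= 4L^.header_digits)
  digits <- c(value_to_quaternary(as.integer(address), .header_digits),
              value_to_quaternary(as.integer(total), .header_digits))
  paste(.base_alphabet[rep(digits, each = .header_rep) + 1L], collapse = "")
}

#' Parse an address header
#'
#' Majority vote within each repeated digit triple (ties broken toward the
#' smaller digit), then digits are reassembled into `(address, total)`.
#'
#' @param header A 24-base DNA string (possibly error-bearing).
#' @return List with `address` and `total`.
#' @export
parse_header <- function(header) {
  stopifnot(is.character(header), nchar(header) == 2L * .header_digits * .header_rep)
  ch <- strsplit(header, "", fixed = TRUE)[[1]]
  digit_of <- match(ch, .base_alphabet) - 1L
  if (anyNA(digit_of)) stop("header contains a non-ACGT symbol")
  groups <- matrix(digit_of, nrow = .header_rep)
  digits <- apply(groups, 2, function(g) {
    tab <- tabulate(g + 1L, nbins = 4L)
    which.max(tab) - 1L  # which.max takes the first maximum: smaller digit
  })
  n <- .header_digits
  list(address = sum(digits[1:n] * 4L^((n - 1L):0)),
       total = sum(digits[(n + 1L):(2L * n)] * 4L^((n - 1L):0)))
}

#' All candidate headers for a message of `total` fragments
#'
#' @param total Number of fragments.
#' @return Character vector of headers, in address order (names = address).
#' @export
header_candidates <- function(total) {
  h <- vapply(seq_len(total) - 1L, make_header, character(1), total = total)
  names(h) <- as.character(seq_len(total) - 1L)
  h
}

hamming_dist <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# ---- container object --------------------------------------------------------

#' Construct a storage container
#'
#' The container is the codec's interchange metadata: everything the decoder
#' needs with no side channel. Serialized to XML by [write_container()].
#'
#' @param name Message name.
#' @param raw_len Length in bytes of the uncompressed payload.
#' @param crc32 CRC-32 of the uncompressed payload (8 hex characters).
#' @param compression Compression id (currently `"xz"`).
#' @param n_fragments Number of fragments / DNA blocks.
#' @param code_n,code_k,code_col_weight,code_seed LDPC code parameters.
#' @param header_len Header length in bases.
#' @param pad_len Integer vector of padding bits per fragment.
#' @param extra List of verbatim XML child nodes (character) preserved for
#'   forward compatibility.
#' @return An object of class `storage_container`.
#' @export
storage_container <- function(name, raw_len, crc32, compression = "xz",
                              n_fragments, code_n, code_k, code_col_weight,
                              code_seed, header_len = .default_header_len,
                              pad_len, extra = list()) {
  stopifnot(length(pad_len) == n_fragments)
  structure(list(
    version = .container_version,
    name = as.character(name),
    raw_len = as.integer(raw_len),
    crc32 = toupper(as.character(crc32)),
    compression = compression,
    n_fragments = as.integer(n_fragments),
    code_n = as.integer(code_n), code_k = as.integer(code_k),
    code_col_weight = as.integer(code_col_weight),
    code_seed = as.integer(code_seed),
    header_len = as.integer(header_len),
    pad_len = as.integer(pad_len),
    extra = extra
  ), class = "storage_container")
}

#' @export
print.storage_container <- function(x, ...) {
  cat(sprintf("DNA storage container '%s' (v%s)\n", x$name, x$version))
  cat(sprintf("  payload: %d bytes, CRC-32 %s, compression %s\n",
              x$raw_len, x$crc32, x$compression))
  cat(sprintf("  layout: %d fragments, header %d bases, LDPC n=%d k=%d w=%d seed=%d\n",
              x$n_fragments, x$header_len, x$code_n, x$code_k,
              x$code_col_weight, x$code_seed))
  invisible(x)
}

container_code <- function(container) {
  default_code(container$code_n, container$code_k,
               container$code_col_weight, container$code_seed)
}

# ---- failure conditions ------------------------------------------------------

decode_failure <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dnastore_decode_error", "error")))
}

# Globally assign contigs to addresses by minimum total header Hamming
# distance (bijective matching). Each contig alone would pick its nearest
# header; resolving the assignment globally keeps one corrupted header from
# colliding with the block that legitimately owns that address. Identical
# header regions are genuinely ambiguous and raise the duplicate-address
# failure. Brute force over permutations for the small block counts this
# codec uses; greedy fallback beyond that.
assign_addresses <- function(dmat) {
  nc <- nrow(dmat); na <- ncol(dmat)
  if (nc >= 2L) {
    for (i in 1:(nc - 1L)) for (j in (i + 1L):nc) {
      if (all(dmat[i, ] == dmat[j, ])) {
        decode_failure(paste0("sequences ", i, " and ", j,
                              " have indistinguishable headers"),
                       "dnastore_duplicate_address")
      }
    }
  }
  if (na <= 8L) {
    pkey <- paste0("perms_", na)
    if (is.null(.dnastore_cache[[pkey]])) {
      .dnastore_cache[[pkey]] <- perms_of(seq_len(na))
    }
    perms <- .dnastore_cache[[pkey]]
    best <- NULL; best_cost <- Inf
    for (p in perms) {
      cost <- sum(dmat[cbind(seq_len(nc), p[seq_len(nc)])])
      if (cost < best_cost) { best_cost <- cost; best <- p[seq_len(nc)] }
    }
    return(best - 1L)
  }
  # greedy: repeatedly take the smallest remaining (contig, address) distance
  assigned <- rep(NA_integer_, nc)
  free_c <- seq_len(nc); free_a <- seq_len(na)
  while (length(free_c)) {
    sub <- dmat[free_c, free_a, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    assigned[free_c[ij[1]]] <- free_a[ij[2]] - 1L
    free_c <- free_c[-ij[1]]
    free_a <- free_a[-ij[2]]
  }
  assigned
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# ---- message encode / decode -------------------------------------------------

#' Encode a binary payload into DNA information blocks
#'
#' Runs the full storage pipeline: LZMA compression, non-overlapping
#' fragmentation into `n_fragments` slices of `code$k` bits, systematic
#' LDPC encoding of each slice, then address header plus two-bits-per-base
#' DNA mapping. With default parameters each block is exactly 720 bases.
#'
#' @param raw Payload bytes (`raw` vector).
#' @param n_fragments Number of DNA blocks (default 6).
#' @param code An [`ldpc_code`][build_regular_code]; default the production
#'   code of [default_code()].
#' @param name Message name recorded in the container.
#' @return List with `blocks` (list of `dna_block`: `address`,
#'   `header_bases`, `payload_bases`, `bases`) and `container`
#'   (a [storage_container()]).
#' @export
#' @examples
#' enc <- encode_message(as.raw(1:32), n_fragments = 2,
#'                       code = build_regular_code(144, 72, 3, seed = 7))
#' nchar(enc$blocks[[1]]$bases)
encode_message <- function(raw, n_fragments = 6L, code = default_code(),
                           name = "message") {
  stopifnot(is.raw(raw), length(raw) > 0)
  compressed <- compress_payload(raw)
  frags <- fragment_payload(compressed, n_fragments, code$k)
  blocks <- lapply(frags, function(f) {
    header <- make_header(f$address, f$total)
    payload <- bits_to_bases(ldpc_encode(f$info_bits, code))
    structure(list(address = f$address,
                   header_bases = header,
                   payload_bases = payload,
                   bases = paste0(header, payload)),
              class = "dna_block")
  })
  container <- storage_container(
    name = name, raw_len = length(raw), crc32 = crc32(raw),
    compression = "xz", n_fragments = n_fragments,
    code_n = code$n, code_k = code$k, code_col_weight = code$col_weight,
    code_seed = code$seed, header_len = .default_header_len,
    pad_len = vapply(frags, `[[`, integer(1), "pad_len"))
  list(blocks = blocks, container = container)
}

#' Decode DNA sequences back into the original payload
#'
#' The reverse pipeline: each input sequence (a recovered block or an
#' assembled contig) is assigned to an address by minimum Hamming distance
#' between its leading bases and the enumerable candidate headers; the
#' payload bases are mapped back to bits and LDPC-decoded by belief
#' propagation; fragments are concatenated in address order, padding is
#' stripped, the stream is decompressed and the CRC-32 verified.
#'
#' Failures raise classed conditions: `dnastore_missing_address`,
#' `dnastore_duplicate_address`, `dnastore_nonconvergence`,
#' `dnastore_checksum_mismatch`.
#'
#' @param contigs Character vector (or list) of DNA strings, any order.
#' @param container The [storage_container()] of the message.
#' @param channel A [channel_spec()] describing the assumed substitution
#'   rate (drives decoder LLRs).
#' @param max_iter Belief-propagation iteration cap.
#' @return The recovered payload as a `raw` vector.
#' @export
decode_message <- function(contigs, container, channel = channel_spec(0.01),
                           max_iter = 100L) {
  stopifnot(inherits(container, "storage_container"))
  contigs <- as.character(unlist(contigs))
  code <- container_code(container)
  hl <- container$header_len
  need <- hl + code$n %/% 2L
  cands <- header_candidates(container$n_fragments)

  if (length(contigs) > container$n_fragments) {
    decode_failure(paste0(length(contigs), " sequences for ",
                          container$n_fragments,
                          " addresses: at least one address is duplicated"),
                   "dnastore_duplicate_address")
  }
  dmat <- matrix(0, nrow = length(contigs), ncol = length(cands))
  for (i in seq_along(contigs)) {
    s <- contigs[[i]]
    if (nchar(s) < need) s <- paste0(s, strrep("A", need - nchar(s)))
    contigs[[i]] <- s
    head_bases <- substr(s, 1L, hl)
    dmat[i, ] <- vapply(cands, hamming_dist, numeric(1), a = head_bases)
  }
  assigned <- assign_addresses(dmat)  # 0-based addresses, pairwise distinct
  missing <- setdiff(seq_len(container$n_fragments) - 1L, assigned)
  if (length(missing)) {
    decode_failure(paste0("missing address ", paste(missing, collapse = ", ")),
                   "dnastore_missing_address")
  }

  frags <- vector("list", container$n_fragments)
  for (i in seq_along(contigs)) {
    a <- assigned[i]
    payload <- substr(contigs[[i]], hl + 1L, need)
    dec <- ldpc_decode(bases_to_bits(payload), code, channel, max_iter)
    if (!dec$converged) {
      decode_failure(paste0("LDPC decoding did not converge for block address ", a),
                     "dnastore_nonconvergence")
    }
    frags[[a + 1L]] <- list(address = a, total = container$n_fragments,
                            info_bits = dec$info_bits,
                            pad_len = container$pad_len[a + 1L])
  }
  compressed <- defragment_payload(frags)
  raw <- tryCatch(decompress_payload(compressed), error = function(e) {
    decode_failure(paste0("decompression failed: ", conditionMessage(e)),
                   "dnastore_checksum_mismatch")
  })
  if (!identical(crc32(raw), container$crc32)) {
    decode_failure(paste0("checksum mismatch: expected ", container$crc32,
                          ", got ", crc32(raw)),
                   "dnastore_checksum_mismatch")
  }
  raw
}
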
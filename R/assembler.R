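#' Greedy overlay-consensus assembly
#'
#' Recovers DNA information blocks from short reads in the SSAKE style:
#' reads are quality trimmed, indexed by prefix in both orientations, and a
#' contig is grown from a known seed (the block's address header) by
#' repeatedly appending the majority next base among reads that overlap the
#' contig 3' end by at least a minimum overlap. After both ends have been
#' extended, the consensus is re-called per position by majority vote over
#' every placed read.
#'
#' @name assembler
NULL

phred_ints <- function(quals) utf8ToInt(quals) - 33L

#' Quality-trim reads
#'
#' Keeps, for each read, the longest prefix whose bases all have quality at
#' least `min_q` (3' trimming). Reads shorter than `min_keep_len` after
#' trimming, and reads whose kept prefix contains an N, are discarded: the
#' two-bit codec alphabet has no N channel.
#'
#' @param reads Read `data.frame` (columns `id`, `bases`, `quals` in
#'   Phred+33, optionally `mate`, `pair_id`).
#' @param min_q Minimum Phred quality (default 32).
#' @param min_keep_len Minimum post-trim length to retain a read
#'   (default 25).
#' @return The trimmed read `data.frame` (possibly with fewer rows).
#' @export
quality_trim <- function(reads, min_q = 32L, min_keep_len = 25L) {
  stopifnot(is.data.frame(reads), min_q >= 0)
  if (nrow(reads) == 0L) return(reads)
  keep_len <- vapply(reads$quals, function(q) {
    qi <- phred_ints(q)
    bad <- which(qi < min_q)
    if (length(bad)) bad[1] - 1L else length(qi)
  }, integer(1), USE.NAMES = FALSE)
  reads$bases <- substr(reads$bases, 1L, keep_len)
  reads$quals <- substr(reads$quals, 1L, keep_len)
  ok <- keep_len >= min_keep_len & !grepl("N", reads$bases, fixed = TRUE)
  out <- reads[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Index reads by prefix for overlap queries
#'
#' Both each read and its reverse complement are indexed by their leading
#' `min_overlap` bases. The index answers: which reads have a prefix of
#' length `>= min_overlap` matching a given contig suffix, which is the
#' candidate set for greedy extension.
#'
#' @param reads Trimmed read `data.frame`.
#' @param min_overlap Prefix length used as the hash key (default 50).
#' @return An object of class `read_index`.
#' @export
build_prefix_index <- function(reads, min_overlap = 50L) {
  stopifnot(is.data.frame(reads), min_overlap >= 16L)
  fwd <- reads$bases[nchar(reads$bases) > min_overlap]
  seqs <- c(fwd, revcomp(fwd))
  env <- new.env(parent = emptyenv(), size = max(16L, 2L * length(seqs)))
  keys <- substr(seqs, 1L, min_overlap)
  for (i in seq_along(seqs)) {
    k <- keys[i]
    env[[k]] <- c(env[[k]], i)
  }
  structure(list(seqs = seqs, lens = nchar(seqs), env = env,
                 min_overlap = as.integer(min_overlap),
                 max_len = if (length(seqs)) max(nchar(seqs)) else 0L),
            class = "read_index")
}

# candidate (seq index, overlap L) hits for the current contig 3' end.
# While the contig is shorter than one read length the seed neighborhood
# cannot contain full qualifying overlaps (the 24-base header seed is much
# shorter than a 50-base overlap), so a bootstrap phase scans read prefixes
# directly with the overlap floor relaxed to 16 bases; once the contig is at
# least one read long the hash index enforces the full overlap requirement.
overlap_hits <- function(contig, clen, index) {
  mo <- index$min_overlap
  bootstrap <- clen < index$max_len
  lo <- if (bootstrap) min(16L, clen) else mo
  hi <- min(index$max_len - 1L, clen)
  if (hi < lo) return(list(seq = integer(0), L = integer(0)))
  hits_seq <- integer(0); hits_L <- integer(0)
  for (L in seq.int(lo, hi)) {
    suf <- substr(contig, clen - L + 1L, clen)
    if (bootstrap || L < mo) {
      ok <- which(index$lens > L & substr(index$seqs, 1L, L) == suf)
    } else {
      key <- substr(suf, 1L, mo)
      cand <- index$env[[key]]
      if (is.null(cand)) next
      if (L > mo) {
        ok <- cand[index$lens[cand] > L &
                     substr(index$seqs[cand], 1L, L) == suf]
      } else {
        ok <- cand[index$lens[cand] > L]
      }
    }
    if (length(ok)) {
      hits_seq <- c(hits_seq, ok)
      hits_L <- c(hits_L, rep.int(L, length(ok)))
    }
  }
  list(seq = hits_seq, L = hits_L)
}

# extend one direction; returns list(contig, placements data.frame)
extend_3prime <- function(contig, index, min_depth, max_len) {
  placed_key <- new.env(parent = emptyenv())
  pl_seq <- integer(0); pl_start <- integer(0)
  clen <- nchar(contig)
  if (length(index$seqs) == 0L) {
    return(list(contig = contig, seq = pl_seq, start = pl_start))
  }
  lex <- c("A", "C", "G", "T")
  repeat {
    if (clen >= max_len) break
    h <- overlap_hits(contig, clen, index)
    if (length(h$seq) == 0L) break
    nxt <- substr(index$seqs[h$seq], h$L + 1L, h$L + 1L)
    # majority vote on the next base; ties broken lexicographically A<C<G<T
    vlex <- tabulate(match(nxt, lex), nbins = 4L)
    if (max(vlex) < min_depth) break
    base <- lex[which.max(vlex)]
    # record placements of the supporting reads (start in contig coords)
    sup <- which(nxt == base)
    for (t in sup) {
      key <- paste0(h$seq[t], "@", clen - h$L[t] + 1L)
      if (is.null(placed_key[[key]])) {
        placed_key[[key]] <- TRUE
        pl_seq <- c(pl_seq, h$seq[t])
        pl_start <- c(pl_start, clen - h$L[t] + 1L)
      }
    }
    contig <- paste0(contig, base)
    clen <- clen + 1L
  }
  list(contig = contig, seq = pl_seq, start = pl_start)
}

#' Extend a seed into a contig by greedy overlap-consensus
#'
#' Starting from `seed`, reads overlapping the contig 3' end by at least
#' `min_overlap` bases vote on the next base; the majority base (ties broken
#' A<C<G<T) is appended when supported by at least `min_depth` reads. When
#' no further extension is possible the contig is reverse complemented and
#' the other end extended the same way. Finally all placed reads are piled
#' up and the consensus re-called per position by majority vote.
#'
#' @param seed Seed DNA string (typically a block's address header).
#' @param index A [build_prefix_index()] over the trimmed reads.
#' @param min_overlap Minimum overlap in bases (default 50; must equal the
#'   index's key length).
#' @param min_depth Minimum read support to accept an extension (default 1).
#' @param max_len Safety cap on contig length.
#' @param seed_id Identifier recorded on the contig.
#' @return An object of class `contig`: list with `consensus`, `counts`
#'   (4 x L matrix, rows A/C/G/T), `coverage` (integer vector), `seed_id`,
#'   `n_reads` (placed read count).
#' @export
extend_seed <- function(seed, index, min_overlap = index$min_overlap,
                        min_depth = 1L, max_len = 100000L, seed_id = "seed") {
  stopifnot(inherits(index, "read_index"), nchar(seed) >= 1L,
            min_depth >= 1L)
  if (min_overlap != index$min_overlap) {
    stop("min_overlap (", min_overlap, ") must match the index key length (",
         index$min_overlap, "); rebuild the index")
  }
  # phase 1: extend rightwards
  e1 <- extend_3prime(seed, index, min_depth, max_len)
  # phase 2: reverse complement and extend the other end
  rc <- revcomp(e1$contig)
  e2 <- extend_3prime(rc, index, min_depth, max_len)
  final <- revcomp(e2$contig)
  N <- nchar(final)
  grew <- nchar(e2$contig) - nchar(e1$contig)  # bases prepended in final coords

  # collect placements in final coordinates
  p_seq <- integer(0); p_start <- integer(0); p_rc <- logical(0)
  if (length(e1$seq)) {
    p_seq <- c(p_seq, e1$seq)
    p_start <- c(p_start, e1$start + grew)
    p_rc <- c(p_rc, rep(FALSE, length(e1$seq)))
  }
  if (length(e2$seq)) {
    # placement at start s, length l on the RC contig maps to final
    # start N - (s + l - 1) + 1 with the read reverse complemented
    l2 <- index$lens[e2$seq]
    p_seq <- c(p_seq, e2$seq)
    p_start <- c(p_start, N - (e2$start + l2 - 1L) + 1L)
    p_rc <- c(p_rc, rep(TRUE, length(e2$seq)))
  }

  counts <- matrix(0L, nrow = 4L, ncol = N,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  if (length(p_seq)) {
    pos_all <- integer(0); base_all <- integer(0)
    for (t in seq_along(p_seq)) {
      s <- index$seqs[p_seq[t]]
      if (p_rc[t]) s <- revcomp(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      pos <- p_start[t]:(p_start[t] + length(ch) - 1L)
      inside <- pos >= 1L & pos <= N
      b <- match(ch[inside], c("A", "C", "G", "T"))
      good <- !is.na(b)
      pos_all <- c(pos_all, pos[inside][good])
      base_all <- c(base_all, b[good])
    }
    tab <- tabulate((pos_all - 1L) * 4L + base_all, nbins = 4L * N)
    counts <- matrix(as.integer(tab), nrow = 4L,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
  }
  coverage <- as.integer(colSums(counts))
  greedy <- strsplit(final, "", fixed = TRUE)[[1]]
  consensus <- greedy
  has_cov <- coverage > 0L
  if (any(has_cov)) {
    maj <- c("A", "C", "G", "T")[apply(counts[, has_cov, drop = FALSE], 2, which.max)]
    consensus[has_cov] <- maj
  }
  structure(list(consensus = paste(consensus, collapse = ""),
                 counts = counts, coverage = coverage,
                 seed_id = seed_id, n_reads = length(p_seq)),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("contig '%s': %d bases, mean coverage %.1f, %d reads placed\n",
              x$seed_id, nchar(x$consensus), mean(x$coverage), x$n_reads))
  invisible(x)
}

#' Assemble one contig per expected block
#'
#' Builds the prefix index once and runs [extend_seed()] from every block
#' header. Reads may support more than one contig; no read claiming is
#' performed across blocks.
#'
#' @param reads Trimmed read `data.frame`.
#' @param headers Character vector of block header sequences (the assembly
#'   seeds); must be pairwise distinct.
#' @param min_overlap,min_depth,max_len Passed to [extend_seed()].
#' @param expected_len If given, contigs shorter than this are flagged
#'   (`flagged_short` attribute on each contig).
#' @return List of `contig` objects, in header order.
#' @export
assemble_blocks <- function(reads, headers, min_overlap = 50L, min_depth = 1L,
                            max_len = 100000L, expected_len = NULL) {
  headers <- as.character(headers)
  if (anyDuplicated(headers)) {
    stop("duplicate header seeds: seeds must be unambiguous")
  }
  index <- build_prefix_index(reads, min_overlap)
  out <- lapply(seq_along(headers), function(i) {
    ctg <- extend_seed(headers[i], index, min_overlap, min_depth, max_len,
                       seed_id = paste0("block_", i - 1L))
    ctg$flagged_short <- !is.null(expected_len) &&
      nchar(ctg$consensus) < expected_len
    ctg
  })
  out
}

#' Per-contig assembly report
#'
#' @param contigs List of `contig` objects.
#' @return A `data.frame` with one row per contig: `seed_id`, `length`,
#'   `mean_coverage`, `n_reads`, `flagged_short`.
#' @export
contig_report <- function(contigs) {
  data.frame(
    seed_id = vapply(contigs, `[[`, character(1), "seed_id"),
    length = vapply(contigs, function(c) nchar(c$consensus), integer(1)),
    mean_coverage = vapply(contigs, function(c) mean(c$coverage), numeric(1)),
    n_reads = vapply(contigs, `[[`, integer(1), "n_reads"),
    flagged_short = vapply(contigs, function(c) isTRUE(c$flagged_short), logical(1)),
    stringsAsFactors = FALSE
  )
}
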
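#' Seeded stochastic error channels
#'
#' Two channels are modelled: (i) a quaternary-symmetric base-substitution
#' channel used by the error-tolerance sweep, and (ii) an Illumina-like
#' paired-end read simulator with a substitution/insertion/deletion profile,
#' used by the assembly experiments. All channels are pure functions of
#' (input, parameters, seed).
#'
#' @name error-models
NULL

#' Per-base sequencing/synthesis error profile
#'
#' Defaults are the observed per-base error rates of the storage
#' experiment's real sequencing library: 0.19% substitutions, 0.01%
#' insertions, 0.38% deletions.
#'
#' @param p_sub,p_ins,p_del Per-base probabilities, each in `[0, 1)` and
#'   summing to less than 1.
#' @return An object of class `error_profile`.
#' @export
error_profile <- function(p_sub = 0.0019, p_ins = 0.0001, p_del = 0.0038) {
  stopifnot(p_sub >= 0, p_ins >= 0, p_del >= 0, p_sub < 1, p_ins < 1,
            p_del < 1, p_sub + p_ins + p_del < 1)
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del),
            class = "error_profile")
}

#' Read-simulation geometry
#'
#' Defaults mirror the sequencing library of the storage experiment:
#' 76-base read pairs with a 200-base insert.
#'
#' @param read_len Read length in bases.
#' @param insert_size Insert (fragment) size in bases; `>= read_len`.
#' @param coverage Target fold coverage (> 0).
#' @param seed Integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(read_len = 76L, insert_size = 200L, coverage = 90,
                          seed = 1L) {
  stopifnot(read_len >= 1, insert_size >= read_len, coverage > 0)
  structure(list(read_len = as.integer(read_len),
                 insert_size = as.integer(insert_size),
                 coverage = coverage, seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Substitute bases at random (quaternary symmetric channel)
#'
#' Each position is independently substituted with probability `p_base`;
#' the substitute is uniform over the other three bases. Length preserving
#' and deterministic given `seed`.
#'
#' @param seq DNA string.
#' @param p_base Substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return DNA string of the same length.
#' @export
substitute_bases <- function(seq, p_base, seed) {
  stopifnot(is.character(seq), length(seq) == 1L, p_base >= 0, p_base <= 1)
  L <- nchar(seq)
  if (L == 0L) return(seq)
  withr::with_seed(as.integer(seed), {
    # position uniforms and replacement offsets are drawn for every
    # position regardless of p_base, so runs at the same seed and different
    # rates are coupled: the error set grows with p and agrees on shared
    # positions (common random numbers for monotonicity studies)
    u <- runif(L)
    off <- sample.int(3L, L, replace = TRUE)
    hit <- which(u < p_base)
    if (length(hit) == 0L) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    cur <- match(ch[hit], .base_alphabet)
    # offset 1..3 from the current base, cyclically: uniform over the others
    ch[hit] <- .base_alphabet[((cur - 1L + off[hit]) %% 4L) + 1L]
    paste(ch, collapse = "")
  })
}

# apply an error profile to one error-free read; returns list(bases, quals)
# qualities: Q40 at correct (and inserted) bases, uniform Q20-39 at
# substituted bases, so a Q32 trimming threshold is exercised.
apply_profile_to_read <- function(bases_vec, profile) {
  l <- length(bases_vec)
  u <- runif(l)
  p1 <- profile$p_sub
  p2 <- p1 + profile$p_ins
  p3 <- p2 + profile$p_del
  if (all(u >= p3)) {
    return(list(bases = bases_vec, quals = rep(40L, l),
                events = c(sub = 0L, ins = 0L, del = 0L)))
  }
  pieces_b <- vector("list", l)
  pieces_q <- vector("list", l)
  ev <- c(sub = 0L, ins = 0L, del = 0L)
  for (i in seq_len(l)) {
    if (u[i] < p1) {                       # substitution
      cur <- match(bases_vec[i], .base_alphabet)
      nb <- .base_alphabet[((cur - 1L + sample.int(3L, 1L)) %% 4L) + 1L]
      pieces_b[[i]] <- nb
      pieces_q[[i]] <- sample(20:39, 1L)
      ev["sub"] <- ev["sub"] + 1L
    } else if (u[i] < p2) {                # insertion of a uniform base
      pieces_b[[i]] <- c(.base_alphabet[sample.int(4L, 1L)], bases_vec[i])
      pieces_q[[i]] <- c(40L, 40L)
      ev["ins"] <- ev["ins"] + 1L
    } else if (u[i] < p3) {                # deletion
      pieces_b[[i]] <- character(0)
      pieces_q[[i]] <- integer(0)
      ev["del"] <- ev["del"] + 1L
    } else {
      pieces_b[[i]] <- bases_vec[i]
      pieces_q[[i]] <- 40L
    }
  }
  list(bases = unlist(pieces_b), quals = unlist(pieces_q), events = ev)
}

#' Simulate paired-end short reads from a reference
#'
#' Fragments of `insert_size` bases are drawn uniformly over valid start
#' positions of the reference; mate 1 is the 5' read of the fragment, mate 2
#' the reverse complement of its 3' end. Per-base errors follow `profile`
#' (substitution, insertion of a uniform base, deletion; at most one event
#' per template position). The number of pairs is
#' `ceiling(coverage * len / (2 * read_len))`. Deterministic given
#' `spec$seed`.
#'
#' @param reference DNA string, at least `insert_size` bases.
#' @param spec A [read_sim_spec()].
#' @param profile An [error_profile()]; `error_profile(0, 0, 0)` gives
#'   error-free reads.
#' @return A `data.frame` of reads with columns `id`, `bases`, `quals`
#'   (Phred+33 string), `mate` and `pair_id`. The realized error-event
#'   tallies are attached as attribute `event_counts`
#'   (`sub`/`ins`/`del`/`template_bases`), for provenance and calibration
#'   checks.
#' @export
simulate_read_pairs <- function(reference, spec = read_sim_spec(),
                                profile = error_profile()) {
  stopifnot(is.character(reference), length(reference) == 1L,
            inherits(spec, "read_sim_spec"), inherits(profile, "error_profile"))
  L <- nchar(reference)
  if (L < spec$insert_size) {
    stop("reference (", L, " bases) is shorter than the insert size (",
         spec$insert_size, ")")
  }
  n_pairs <- as.integer(ceiling(spec$coverage * L / (2 * spec$read_len)))
  rl <- spec$read_len
  withr::with_seed(spec$seed, {
    starts <- sample.int(L - spec$insert_size + 1L, n_pairs, replace = TRUE)
    ids <- sprintf("pair%06d", seq_len(n_pairs))
    rows <- vector("list", 2L * n_pairs)
    events <- c(sub = 0L, ins = 0L, del = 0L)
    for (i in seq_len(n_pairs)) {
      s <- starts[i]
      m1 <- substr(reference, s, s + rl - 1L)
      m2 <- revcomp(substr(reference, s + spec$insert_size - rl,
                           s + spec$insert_size - 1L))
      r1 <- apply_profile_to_read(strsplit(m1, "", fixed = TRUE)[[1]], profile)
      r2 <- apply_profile_to_read(strsplit(m2, "", fixed = TRUE)[[1]], profile)
      rows[[2L * i - 1L]] <- list(id = paste0(ids[i], "/1"),
                                  bases = paste(r1$bases, collapse = ""),
                                  quals = intToUtf8(r1$quals + 33L),
                                  mate = 1L, pair_id = ids[i])
      rows[[2L * i]] <- list(id = paste0(ids[i], "/2"),
                             bases = paste(r2$bases, collapse = ""),
                             quals = intToUtf8(r2$quals + 33L),
                             mate = 2L, pair_id = ids[i])
      events <- events + r1$events + r2$events
    }
    out <- do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
    attr(out, "event_counts") <- c(events,
                                   template_bases = 2L * n_pairs * rl)
    out
  })
}

#' Randomly down-sample reads, keeping mates together
#'
#' A uniform subset of read pairs without replacement. Exactly one of
#' `fraction` and `target_coverage` must be given; with `target_coverage`
#' the number of retained pairs is computed from the mean per-pair base
#' yield and the reference length.
#'
#' @param reads Read `data.frame` as from [simulate_read_pairs()].
#' @param fraction Fraction of pairs to keep, in `[0, 1]`.
#' @param target_coverage Desired fold coverage after down-sampling.
#' @param reference_len Reference length in bases (required with
#'   `target_coverage`).
#' @param seed Integer seed.
#' @return Subset of `reads` (pairs kept or dropped together).
#' @export
downsample_reads <- function(reads, fraction = NULL, target_coverage = NULL,
                             reference_len = NULL, seed = 1L) {
  stopifnot(is.data.frame(reads), xor(is.null(fraction), is.null(target_coverage)))
  pair_ids <- unique(reads$pair_id)
  n_pairs <- length(pair_ids)
  if (!is.null(fraction)) {
    stopifnot(fraction >= 0, fraction <= 1)
    n_keep <- round(fraction * n_pairs)
  } else {
    stopifnot(!is.null(reference_len), target_coverage >= 0)
    per_pair <- sum(nchar(reads$bases)) / n_pairs
    n_keep <- round(target_coverage * reference_len / per_pair)
    if (n_keep > n_pairs) {
      stop("requested coverage ", target_coverage,
           "x exceeds the available ~",
           round(sum(nchar(reads$bases)) / reference_len, 1), "x")
    }
  }
  if (n_keep == 0L) return(reads[0, , drop = FALSE])
  keep <- withr::with_seed(as.integer(seed),
                           sample(pair_ids, n_keep, replace = FALSE))
  out <- reads[reads$pair_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
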
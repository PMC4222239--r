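#' In-silico characterization experiments
#'
#' Two seeded Monte-Carlo studies characterize the storage system: an
#' error-tolerance sweep that substitutes bases in every encoded block at a
#' grid of rates and records the fraction of replicates whose payload is
#' recovered bit-exactly, and a coverage down-sampling study that assembles
#' one block from simulated read pairs at decreasing coverage and scores the
#' consensus against the truth by global-alignment percent identity.
#'
#' @name experiments
NULL

pid_submat <- function() {
  if (is.null(.dnastore_cache[["pid_submat"]])) {
    .dnastore_cache[["pid_submat"]] <-
      Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                               baseOnly = FALSE)
  }
  .dnastore_cache[["pid_submat"]]
}

#' Global-alignment percent identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a
#' linear gap cost of 2 per gapped position; identity is
#' `100 * matches / alignment_length`, where the alignment length counts
#' every column including gaps. A global (end-to-end) alignment is used so
#' that terminal truncation of a contig lowers the score rather than being
#' silently ignored.
#'
#' @param a,b Non-empty DNA strings.
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' percent_identity("ACGTACGT", "ACGTACGT")  # 100
percent_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), nchar(a) > 0, nchar(b) > 0)
  ali <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = pid_submat(),
    gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(ali)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(ali)), "")[[1]]
  100 * sum(p == s & p != "-") / length(p)
}

#' Gap columns of the global alignment
#'
#' Returns the number of gapped columns in the global alignment of `a` and
#' `b`, split into internal gaps and terminal gaps (leading/trailing runs of
#' gap columns). Internal gaps are the indel signal: a consensus that is
#' merely truncated at one end has terminal but no internal gaps.
#'
#' @param a,b Non-empty DNA strings.
#' @return List with `internal` and `terminal` gap-column counts.
#' @export
alignment_gaps <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  ali <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = pid_submat(),
    gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(ali)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(ali)), "")[[1]]
  gap <- p == "-" | s == "-"
  if (!any(gap)) return(list(internal = 0L, terminal = 0L))
  nongap <- which(!gap)
  if (length(nongap) == 0L) {
    return(list(internal = 0L, terminal = length(gap)))
  }
  inner <- seq(min(nongap), max(nongap))
  internal <- sum(gap[inner])
  list(internal = as.integer(internal),
       terminal = as.integer(sum(gap) - internal))
}

#' Error-tolerance sweep of the full codec
#'
#' Encodes `raw` once, then for every grid substitution rate `p` and every
#' replicate substitutes each base of every block independently with
#' probability `p` and attempts full decoding (header matching, belief
#' propagation, reassembly, decompression, checksum). A replicate succeeds
#' only on bit-exact payload recovery. Replicates reuse the same seeds
#' across grid points (common random numbers), so the realized error sets
#' grow monotonically with `p`.
#'
#' @param raw Payload bytes.
#' @param grid Ascending vector of base-substitution probabilities,
#'   starting at 0.
#' @param reps Replicates per grid point (default 20).
#' @param n_fragments,code Codec parameters (defaults: production layout).
#' @param seed Master seed.
#' @param max_iter Belief-propagation iteration cap.
#' @return An object of class `sweep_result`: list with `grid`, `successes`
#'   (per grid point), `reps`, and `threshold` (largest grid `p` with full
#'   recovery in all replicates, `NA` if none).
#' @export
error_tolerance_sweep <- function(raw, grid = seq(0, 0.08, by = 0.005),
                                  reps = 20L, n_fragments = 6L,
                                  code = default_code(), seed = 1L,
                                  max_iter = 100L) {
  stopifnot(is.raw(raw), !is.unsorted(grid), grid[1] == 0, reps >= 1)
  enc <- encode_message(raw, n_fragments = n_fragments, code = code)
  blocks <- vapply(enc$blocks, `[[`, character(1), "bases")
  successes <- integer(length(grid))
  for (gi in seq_along(grid)) {
    p <- grid[gi]
    ok <- 0L
    for (r in seq_len(reps)) {
      noisy <- vapply(seq_along(blocks), function(b) {
        substitute_bases(blocks[b], p, seed = seed * 1000L + r * 10L + b)
      }, character(1))
      res <- tryCatch(
        decode_message(noisy, enc$container,
                       channel = channel_spec(max(p, 1e-3)),
                       max_iter = max_iter),
        dnastore_decode_error = function(e) NULL)
      if (!is.null(res) && identical(res, raw)) ok <- ok + 1L
    }
    successes[gi] <- ok
  }
  full <- which(successes == reps)
  structure(list(grid = grid, successes = successes, reps = as.integer(reps),
                 threshold = if (length(full)) max(grid[full]) else NA_real_),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Error-tolerance sweep: %d grid points, %d replicates each\n",
              length(x$grid), x$reps))
  cat(sprintf("  100%% recovery up to p = %s\n",
              if (is.na(x$threshold)) "never" else
                sprintf("%.1f%%", 100 * x$threshold)))
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  data.frame(p_base = x$grid, successes = x$successes, reps = x$reps)
}

#' Coverage down-sampling study of de novo block recovery
#'
#' For each replicate, paired reads are simulated once from the reference
#' block at the maximum requested coverage and then down-sampled to each
#' grid coverage (pairs kept together), mirroring the down-sampling design
#' of the original experiment and coupling the replicates across coverages.
#' Reads are quality trimmed, the block is assembled from its header seed,
#' and the consensus scored by [percent_identity()] against the reference.
#'
#' @param reference The true DNA information block (720 bases by default
#'   layout).
#' @param coverages Vector of fold coverages to evaluate.
#' @param reps Replicates per coverage (default 20).
#' @param profile An [error_profile()] (defaults: the observed sequencing
#'   error rates).
#' @param read_len,insert_size Read geometry.
#' @param min_q Quality-trimming threshold.
#' @param min_overlap,min_depth Assembly parameters.
#' @param header_len Bases of `reference` used as the assembly seed.
#' @param seed Master seed.
#' @return An object of class `coverage_curve`: list with `coverages`,
#'   `mean_identity`, `identity` (reps x coverages matrix), `reps`.
#' @export
coverage_sweep <- function(reference, coverages = c(1, 5, 10, 30, 60, 90, 120),
                           reps = 20L, profile = error_profile(),
                           read_len = 76L, insert_size = 200L, min_q = 32L,
                           min_overlap = 50L, min_depth = 1L,
                           header_len = 24L, seed = 1L) {
  stopifnot(nchar(reference) >= insert_size, reps >= 1, all(coverages > 0))
  coverages <- sort(coverages)
  cmax <- max(coverages)
  L <- nchar(reference)
  seed_seq <- substr(reference, 1L, header_len)
  identity <- matrix(NA_real_, nrow = reps, ncol = length(coverages))
  for (r in seq_len(reps)) {
    # oversample so that down-sampling to cmax is always feasible
    spec <- read_sim_spec(read_len = read_len, insert_size = insert_size,
                          coverage = cmax * 1.1 + 2,
                          seed = seed * 1000L + r)
    pool <- simulate_read_pairs(reference, spec, profile)
    # one permutation of pairs per replicate; each coverage keeps a prefix,
    # so subsets are nested across coverages (monotone coupling)
    pair_ids <- unique(pool$pair_id)
    perm <- withr::with_seed(seed * 1000L + r + 7L, sample(pair_ids))
    per_pair <- sum(nchar(pool$bases)) / length(pair_ids)
    for (ci in seq_along(coverages)) {
      n_keep <- min(length(perm), round(coverages[ci] * L / per_pair))
      reads <- pool[pool$pair_id %in% perm[seq_len(n_keep)], , drop = FALSE]
      reads <- quality_trim(reads, min_q = min_q)
      idx <- build_prefix_index(reads, min_overlap)
      ctg <- extend_seed(seed_seq, idx, min_overlap, min_depth,
                         max_len = 4L * L, seed_id = "block")
      identity[r, ci] <- percent_identity(ctg$consensus, reference)
    }
  }
  structure(list(coverages = coverages,
                 mean_identity = colMeans(identity),
                 identity = identity, reps = as.integer(reps)),
            class = "coverage_curve")
}

#' @export
print.coverage_curve <- function(x, ...) {
  cat(sprintf("Coverage curve: %d coverages, %d replicates each\n",
              length(x$coverages), x$reps))
  for (i in seq_along(x$coverages)) {
    cat(sprintf("  %5gx  mean identity %.2f%%\n",
                x$coverages[i], x$mean_identity[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.coverage_curve <- function(x, ...) {
  data.frame(coverage = x$coverages, mean_identity = x$mean_identity,
             reps = x$reps)
}

#' Write experiment results as CSV with a JSON run manifest
#'
#' @param result A `sweep_result` or `coverage_curve`.
#' @param path Output CSV path; the manifest is written alongside with
#'   extension `.manifest.json`.
#' @param params Named list of run parameters (seeds included) recorded in
#'   the manifest.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(result, path, params = list()) {
  df <- as.data.frame(result)
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- list(class = class(result)[1],
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   params = params)
  jsonlite::write_json(manifest, paste0(tools::file_path_sans_ext(path),
                                        ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
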
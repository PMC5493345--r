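#' Bootstrap minimum sample size for a stable length-frequency distribution
#'
#' For each candidate subsample size n, draws `reps` subsamples without
#' replacement from the pooled length records and computes the
#' Kolmogorov-Smirnov distance between the subsample and the full empirical
#' length distribution. The minimum sample size is the smallest candidate
#' whose mean KS distance is at or below `criterion_eps`. The reliability
#' criterion (mean KS distance <= 0.05 by default) is one explicit
#' operationalization of "reliable size-frequency distribution"; both the
#' threshold and the candidate grid are configurable.
#'
#' @param lengths Numeric lengths in mm, or a data frame with `length_mm`.
#' @param criterion_eps Mean-KS-distance threshold (default 0.05).
#' @param n_grid Candidate subsample sizes; default `seq(25, n, by = 25)`.
#' @param reps Bootstrap replicates per candidate (default 500).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return A list with `n_min` (smallest qualifying candidate, or `NA` when
#'   the criterion is never met), `attained` (logical), and `profile` (data
#'   frame of candidate `n` and `mean_ks`).
#' @examples
#' x <- rlnorm(400, log(80), 0.2)
#' minimum_sample_size(x, reps = 50, seed = 1)$n_min
#' @export
minimum_sample_size <- function(lengths, criterion_eps = 0.05,
                                n_grid = NULL, reps = 500L, seed = 1L) {
  if (is.data.frame(lengths)) lengths <- lengths$length_mm
  stopifnot(is.numeric(lengths), length(lengths) >= 2L, reps >= 1L)
  n <- length(lengths)
  if (is.null(n_grid)) n_grid <- seq(25L, n, by = 25L)
  n_grid <- sort(unique(as.integer(n_grid)))
  if (max(n_grid) > n) stop("candidate sizes exceed the number of records",
                            call. = FALSE)
  sorted <- sort(lengths)
  mean_ks <- with_seed(seed, vapply(n_grid, function(m) {
    d <- numeric(reps)
    for (r in seq_len(reps)) {
      sub <- sample(lengths, m, replace = FALSE)
      d[r] <- ks_distance(sub, sorted)
    }
    mean(d)
  }, numeric(1)))
  ok <- which(mean_ks <= criterion_eps)
  list(n_min = if (length(ok)) n_grid[ok[1L]] else NA_integer_,
       attained = length(ok) > 0L,
       profile = data.frame(n = n_grid, mean_ks = mean_ks))
}

# KS distance of `sub` against the full empirical distribution: the sup of
# |F_sub - F_full| is attained at a subsample jump point, approaching from
# the right (both ECDFs evaluated at s_i) or from the left (full ECDF's left
# limit against the pre-jump subsample value).
ks_distance <- function(sub, full_sorted) {
  s <- sort(sub)
  m <- length(s)
  n <- length(full_sorted)
  fs_hi <- findInterval(s, full_sorted) / n                    # P(full <= s)
  fs_lo <- findInterval(s, full_sorted, left.open = TRUE) / n  # P(full <  s)
  ss_hi <- findInterval(s, s) / m                              # P(sub  <= s)
  ss_lo <- findInterval(s, s, left.open = TRUE) / m            # P(sub  <  s)
  max(abs(fs_hi - ss_hi), abs(fs_lo - ss_lo))
}

# Run `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
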
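#' Bin lengths into 1-mm intervals
#'
#' Organises raw length measurements into a length-frequency table on
#' half-open 1-mm intervals `[i, i+1)`. This mirrors the field convention of
#' recording shell length to the nearest mm before any age conversion.
#'
#' @param lengths Numeric vector of lengths in mm; all must be positive.
#' @return A data frame with columns `length_mm` (lower bin edge) and `count`;
#'   empty input gives a zero-row table. Total count is conserved.
#' @examples
#' bin_lengths(c(10.0, 10.4, 11.0))
#' @export
bin_lengths <- function(lengths) {
  stopifnot(is.numeric(lengths))
  if (length(lengths) == 0L) {
    return(data.frame(length_mm = integer(0), count = integer(0)))
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all lengths must be positive and finite", call. = FALSE)
  }
  idx <- floor(lengths)
  rng <- seq.int(min(idx), max(idx))
  cnt <- tabulate(idx - min(idx) + 1L, nbins = length(rng))
  data.frame(length_mm = rng, count = cnt)
}

#' Construct an age-frequency distribution
#'
#' Low-level constructor for the catch-curve substrate: counts per age class
#' on a regular grid of midpoints. Classes are half-open on the right,
#' `[m - w/2, m + w/2)`, so an age on a class boundary belongs to the upper
#' class. Counts may be non-integer (e.g. exact exponential frequencies used
#' in calibration work); the builder [age_frequency()] always produces
#' integers.
#'
#' @param midpoints Strictly increasing, equally spaced class midpoints (yr).
#' @param counts Non-negative counts, one per class.
#' @param class_width Class width in yr (default 0.2).
#' @param n_dropped_over_linf Number of input records dropped as
#'   over-asymptote before binning.
#' @return An object of class `age_frequency`.
#' @export
as_age_frequency <- function(midpoints, counts, class_width = 0.2,
                             n_dropped_over_linf = 0L) {
  stopifnot(is.numeric(midpoints), is.numeric(counts),
            length(midpoints) == length(counts), length(midpoints) >= 1L,
            is.numeric(class_width), class_width > 0)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(midpoints) > 1L) {
    d <- diff(midpoints)
    if (any(d <= 0) || any(abs(d - class_width) > 1e-8 * class_width)) {
      stop("midpoints must be strictly increasing with spacing = class_width",
           call. = FALSE)
    }
  }
  structure(list(class_width = class_width,
                 midpoints = as.numeric(midpoints),
                 counts = as.numeric(counts),
                 n_dropped_over_linf = as.integer(n_dropped_over_linf)),
            class = "age_frequency")
}

#' Build an age-frequency distribution from length records
#'
#' Ages every length with the inverse von Bertalanffy transform and bins the
#' ages into half-open classes of `class_width` yr (0.2 yr by default; wider
#' classes can mask the onset of the descending limb). The conservation
#' invariant `sum(counts) + n_dropped_over_linf == n records` always holds.
#'
#' @param lengths Numeric vector of lengths in mm, or a data frame with a
#'   `length_mm` column (the length-record table).
#' @param p A [growth_params()] object.
#' @param class_width Age class width in yr.
#' @param over_linf Over-asymptote policy passed to [vb_age()].
#' @return An [as_age_frequency()] object.
#' @examples
#' gp <- growth_params(150, 0.433)
#' af <- age_frequency(runif(200, 40, 140), gp)
#' sum(af$counts)
#' @export
age_frequency <- function(lengths, p, class_width = 0.2,
                          over_linf = c("drop", "clamp")) {
  if (is.data.frame(lengths)) lengths <- lengths$length_mm
  over_linf <- match.arg(over_linf)
  stopifnot(is.numeric(lengths), length(lengths) >= 1L)
  ages <- suppressWarnings(vb_age(lengths, p, over_linf = over_linf))
  n_drop <- attr(ages, "n_dropped")
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0L) stop("no ageable records", call. = FALSE)
  idx <- age_class_index(ages, class_width)
  rng <- seq.int(min(idx), max(idx))
  cnt <- tabulate(idx - min(idx) + 1L, nbins = length(rng))
  as_age_frequency((rng + 0.5) * class_width, cnt, class_width,
                   n_dropped_over_linf = n_drop)
}

# Index of the half-open class [i*w, (i+1)*w) containing age a. The small
# epsilon enforces the boundary-goes-up convention under floating point
# (e.g. 1.2/0.2 evaluates just below 6).
age_class_index <- function(a, w) {
  floor(a / w + 1e-9)
}

#' @export
print.age_frequency <- function(x, ...) {
  cat(sprintf("Age-frequency distribution: %d classes of %.2g yr on [%.2f, %.2f] yr\n",
              length(x$midpoints), x$class_width,
              x$midpoints[1] - x$class_width / 2,
              x$midpoints[length(x$midpoints)] + x$class_width / 2))
  cat(sprintf("  %g individuals aged; %d dropped (length >= Linf)\n",
              sum(x$counts), x$n_dropped_over_linf))
  invisible(x)
}

#' @export
plot.age_frequency <- function(x, log = FALSE, ...) {
  y <- if (log) ifelse(x$counts > 0, log(x$counts), NA) else x$counts
  graphics::plot(x$midpoints, y, type = "h",
                 xlab = "Age (yr)",
                 ylab = if (log) "ln frequency" else "Frequency", ...)
  invisible(x)
}

#' Truncate the sparse right tail of an age-frequency distribution
#'
#' Removes every class at (and beyond) the first run of `gap` or more
#' consecutive zero-count classes situated beyond the modal class.
#' Observations isolated at the right end behind such a gap would otherwise
#' bias the catch-curve regression. Interior structure left of the first
#' qualifying gap is untouched, and gaps on the ascending side of the
#' distribution (e.g. behind a stray young record) never trigger truncation
#' — the rule is about the right tail.
#'
#' @param af An [as_age_frequency()] object.
#' @param gap Minimum run length of zero-count classes that triggers
#'   truncation (default 4).
#' @return The truncated `age_frequency`.
#' @examples
#' af <- as_age_frequency(seq(0.1, 1.5, by = 0.2), c(5, 3, 2, 0, 0, 0, 0, 1))
#' truncate_right_tail(af)$counts
#' @export
truncate_right_tail <- function(af, gap = 4L) {
  stopifnot(inherits(af, "age_frequency"), gap >= 1)
  r <- rle(af$counts == 0)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  peak <- which.max(af$counts)
  q <- which(r$values & r$lengths >= gap & starts > peak)
  if (length(q) > 0L) {
    cut <- starts[q[1L]]
    af$midpoints <- af$midpoints[seq_len(cut - 1L)]
    af$counts <- af$counts[seq_len(cut - 1L)]
  }
  af
}

#' Age of full recruitment from a spline fit to the catch curve
#'
#' Fits a cubic smoothing spline (smoothing chosen by generalized
#' cross-validation) to the class counts against class midpoints and returns
#' the age maximising the fitted spline on a dense grid (step
#' `class_width / 20`), restricted to the observed age range. The maximum
#' frequency age is taken as the age of full recruitment to the fishery,
#' i.e. the onset of the descending limb.
#'
#' @param af An [as_age_frequency()] object with at least 4 nonzero classes.
#' @param scale Fit the spline to raw counts (default) or to `log(count + 1)`.
#' @param spar Optional smoothing parameter forwarded to
#'   [stats::smooth.spline()]; `NULL` (default) selects by GCV.
#' @return The full-recruitment age in yr.
#' @examples
#' af <- as_age_frequency(seq(0.5, 3.1, by = 0.2),
#'                        c(2, 8, 20, 40, 55, 60, 55, 40, 25, 14, 8, 4, 2, 1))
#' full_recruitment_age(af)
#' @export
full_recruitment_age <- function(af, scale = c("counts", "log"), spar = NULL) {
  stopifnot(inherits(af, "age_frequency"))
  scale <- match.arg(scale)
  if (sum(af$counts > 0) < 4L) stop("too few classes for spline", call. = FALSE)
  y <- if (scale == "log") log(af$counts + 1) else af$counts
  sp <- if (is.null(spar)) {
    stats::smooth.spline(af$midpoints, y, cv = FALSE)
  } else {
    stats::smooth.spline(af$midpoints, y, spar = spar)
  }
  grid <- seq(af$midpoints[1L], af$midpoints[length(af$midpoints)],
              by = af$class_width / 20)
  grid[which.max(stats::predict(sp, grid)$y)]
}
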
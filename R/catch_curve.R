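#' Estimate total instantaneous mortality from a catch curve
#'
#' Fits the catch-curve regression
#' \deqn{\log C = -Z \cdot A + B}
#' by ordinary least squares of the natural log of the class counts on the
#' class midpoints over the descending limb. The limb starts at the class
#' containing `recruit_age` (so the peak class is included) and runs to the
#' truncated right end; zero-count classes inside the limb are skipped, since
#' their log frequency is undefined. The slope magnitude estimates total
#' instantaneous mortality Z (1/yr), the sum of natural and fishing
#' mortality; the intercept B estimates the log catch of age-0 animals had
#' they been fully vulnerable.
#'
#' @param af An [as_age_frequency()] object, already right-truncated (see
#'   [truncate_right_tail()]); [catch_curve()] does the full pipeline.
#' @param recruit_age Age of full recruitment (yr); the descending limb uses
#'   classes whose interval lies at or beyond it.
#' @return An object of class `catch_curve` with components `z` (positive
#'   magnitude, 1/yr), `intercept_b`, `se_z`, `ci95` (on Z), `r2`,
#'   `recruit_age`, `ages_used`, `n_classes`, `limb` (data frame with `age`,
#'   `log_count`), the underlying `lm` fit, and the input `af`.
#' @examples
#' mids <- seq(1.1, 4.1, by = 0.2)
#' af <- as_age_frequency(mids, exp(8 - 1.5 * mids))
#' fit <- estimate_z(af, recruit_age = 1.1)
#' coef(fit)
#' @seealso [catch_curve()] for the record-to-fit convenience wrapper.
#' @export
estimate_z <- function(af, recruit_age) {
  stopifnot(inherits(af, "age_frequency"),
            is.numeric(recruit_age), length(recruit_age) == 1L)
  w <- af$class_width
  use <- af$midpoints >= recruit_age - w / 2 & af$counts > 0
  ages <- af$midpoints[use]
  cnts <- af$counts[use]
  if (length(ages) < 3L) stop("insufficient descending limb", call. = FALSE)
  limb <- data.frame(age = ages, log_count = log(cnts))
  fit <- stats::lm(log_count ~ age, data = limb)
  # a perfect fit is legitimate here (noiseless calibration curves)
  sm <- suppressWarnings(summary(fit))
  slope <- stats::coef(fit)[["age"]]
  se <- sm$coefficients["age", "Std. Error"]
  tcrit <- stats::qt(0.975, fit$df.residual)
  ci_slope <- slope + c(-1, 1) * tcrit * se
  structure(list(z = -slope,
                 intercept_b = stats::coef(fit)[["(Intercept)"]],
                 se_z = se,
                 ci95 = sort(-ci_slope),
                 r2 = sm$r.squared,
                 recruit_age = recruit_age,
                 ages_used = ages,
                 n_classes = length(ages),
                 n_records = sum(af$counts),
                 n_dropped = af$n_dropped_over_linf,
                 limb = limb,
                 lm = fit,
                 af = af),
            class = "catch_curve")
}

#' Length records to mortality estimate in one call
#'
#' Convenience pipeline: ages the lengths ([age_frequency()]), truncates the
#' sparse right tail ([truncate_right_tail()]), locates the age of full
#' recruitment by the spline rule ([full_recruitment_age()]) unless supplied,
#' and fits the catch-curve regression ([estimate_z()]).
#'
#' @param lengths Numeric lengths in mm, a length-record data frame with a
#'   `length_mm` column, or a ready-made `age_frequency` object.
#' @param p A [growth_params()] object (ignored when `lengths` is already an
#'   `age_frequency`).
#' @param class_width Age class width in yr.
#' @param gap Zero-run length triggering right truncation.
#' @param recruit_age Optional known full-recruitment age; `NULL` (default)
#'   locates it with the spline rule.
#' @param spline_scale,spar Forwarded to [full_recruitment_age()].
#' @param over_linf Over-asymptote policy, see [vb_age()].
#' @return A `catch_curve` object; see [estimate_z()].
#' @examples
#' gp <- growth_params(150, 0.433)
#' cfg <- sim_config(m = 1, f = 0, n = 2000, growth = gp, seed = 1)
#' fit <- catch_curve(simulate_cohort(cfg), gp)
#' fit
#' @export
catch_curve <- function(lengths, p = NULL, class_width = 0.2, gap = 4L,
                        recruit_age = NULL, spline_scale = "counts",
                        spar = NULL, over_linf = "drop") {
  af <- if (inherits(lengths, "age_frequency")) {
    lengths
  } else {
    stopifnot(inherits(p, "growth_params"))
    age_frequency(lengths, p, class_width = class_width,
                  over_linf = over_linf)
  }
  af <- truncate_right_tail(af, gap = gap)
  if (is.null(recruit_age)) {
    recruit_age <- full_recruitment_age(af, scale = spline_scale, spar = spar)
  }
  estimate_z(af, recruit_age)
}

#' @export
print.catch_curve <- function(x, ...) {
  cat("Catch-curve fit (log C = -Z A + B)\n")
  cat(sprintf("  Z = %.3f /yr (SE %.3f, 95%% CI %.3f-%.3f), R2 = %.3f\n",
              x$z, x$se_z, x$ci95[1], x$ci95[2], x$r2))
  cat(sprintf("  full recruitment at %.2f yr; %d limb classes; %g records (%d dropped)\n",
              x$recruit_age, x$n_classes, x$n_records, x$n_dropped))
  invisible(x)
}

#' @export
summary.catch_curve <- function(object, ...) {
  out <- c(z = object$z, se_z = object$se_z,
           ci_lo = object$ci95[1], ci_hi = object$ci95[2],
           r2 = object$r2, recruit_age = object$recruit_age,
           n_classes = object$n_classes, n_records = object$n_records,
           n_dropped = object$n_dropped)
  class(out) <- "summary.catch_curve"
  out
}

#' @export
print.summary.catch_curve <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
coef.catch_curve <- function(object, ...) {
  c(z = object$z, intercept_b = object$intercept_b)
}

#' @export
confint.catch_curve <- function(object, parm = "z", level = 0.95, ...) {
  slope <- -object$z
  tcrit <- stats::qt(1 - (1 - level) / 2, object$lm$df.residual)
  sort(-(slope + c(-1, 1) * tcrit * object$se_z))
}

#' Predicted log frequency at age from a catch-curve fit
#'
#' @param object A `catch_curve` fit.
#' @param newdata Optional data frame with an `age` column; defaults to the
#'   limb ages used in the fit.
#' @param ... Unused.
#' @return Predicted `log_count` values.
#' @export
predict.catch_curve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$limb
  object$intercept_b - object$z * newdata$age
}

#' @export
residuals.catch_curve <- function(object, ...) {
  stats::residuals(object$lm)
}

#' Plot a catch curve with its fitted descending limb
#'
#' Log frequencies against age-class midpoints; limb classes entering the
#' regression are filled, the fitted line is drawn over the limb, and the
#' full-recruitment age is marked.
#'
#' @param x A `catch_curve` fit.
#' @param ... Forwarded to [graphics::plot()].
#' @export
plot.catch_curve <- function(x, ...) {
  af <- x$af
  pos <- af$counts > 0
  graphics::plot(af$midpoints[pos], log(af$counts[pos]),
                 pch = ifelse(af$midpoints[pos] %in% x$ages_used, 19, 1),
                 xlab = "Age (yr)", ylab = "ln frequency", ...)
  graphics::abline(a = x$intercept_b, b = -x$z)
  graphics::abline(v = x$recruit_age, lty = 3)
  invisible(x)
}
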
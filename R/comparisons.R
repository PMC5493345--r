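#' Compare catch-curve slopes across groups by ANCOVA
#'
#' Stacks the descending-limb data of several catch-curve fits and fits the
#' full-interaction linear model `log_count ~ level * age`. The reported F
#' statistic tests equality of the age slopes (total mortality Z) across
#' levels, i.e. the `level:age` interaction, with Type II sums of squares for
#' unbalanced limbs. Per-level slopes from the interaction model reproduce
#' the separate per-level OLS slopes exactly.
#'
#' @param fits Named list (>= 2 elements) of `catch_curve` fits, one per
#'   factor level; each must have at least 3 usable limb classes.
#' @param design Label describing the factor design (e.g. `"regime"`,
#'   `"site-nested-regime"`, `"year"`); bookkeeping only.
#' @return An object of class `slope_comparison`: `design`, `f_stat`,
#'   `df_num`, `df_den`, `p`, `group_fits` (the input fits), `anova_table`
#'   (Type II), and the stacked-model `lm`.
#' @examples
#' mids <- seq(1.1, 4.1, by = 0.2)
#' af1 <- as_age_frequency(mids, exp(8 - 1.0 * mids))
#' af2 <- as_age_frequency(mids, exp(8 - 2.0 * mids))
#' cmp <- ancova_slopes(list(A = estimate_z(af1, 1.1),
#'                           B = estimate_z(af2, 1.1)))
#' cmp$f_stat
#' @export
ancova_slopes <- function(fits, design = "regime") {
  stopifnot(is.list(fits), length(fits) >= 2L)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    stop("`fits` must be a fully named list", call. = FALSE)
  }
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (!inherits(f, "catch_curve")) {
      stop(sprintf("level '%s' is not a catch_curve fit", nm), call. = FALSE)
    }
    if (nrow(f$limb) < 3L) {
      stop(sprintf("level '%s' has fewer than 3 usable classes", nm),
           call. = FALSE)
    }
  }
  stacked <- do.call(rbind, lapply(names(fits), function(nm) {
    cbind(fits[[nm]]$limb, level = nm)
  }))
  stacked$level <- factor(stacked$level, levels = names(fits))
  fit <- stats::lm(log_count ~ level * age, data = stacked)
  red <- stats::lm(log_count ~ level + age, data = stacked)
  rss_full <- sum(stats::residuals(fit)^2)
  rss_red <- sum(stats::residuals(red)^2)
  df_num <- length(fits) - 1L
  df_den <- fit$df.residual
  extra <- rss_red - rss_full
  # Extra sum of squares for the slope heterogeneity term; identical to the
  # Type II (and Type III) test for the highest-order interaction. Guard the
  # degenerate perfect-fit cases where both sums vanish to rounding error.
  ss_tot <- sum((stacked$log_count - mean(stacked$log_count))^2)
  eps <- 1e-12 * max(ss_tot, 1)
  if (extra <= eps) {
    f_stat <- 0
    p <- 1
  } else if (rss_full <= eps) {
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- (extra / df_num) / (rss_full / df_den)
    p <- stats::pf(f_stat, df_num, df_den, lower.tail = FALSE)
  }
  tab <- if (rss_full > eps) {
    tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  }
  structure(list(design = design,
                 f_stat = f_stat,
                 df_num = df_num,
                 df_den = as.integer(df_den),
                 p = p,
                 group_fits = fits,
                 anova_table = tab,
                 lm = fit,
                 data = stacked),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("Slope comparison (%s): interaction F = %.4g on (%d, %d) df, p = %.4g\n",
              x$design, x$f_stat, x$df_num, x$df_den, x$p))
  z <- vapply(x$group_fits, function(f) f$z, numeric(1))
  cat("  per-level Z:",
      paste(sprintf("%s = %.3f", names(z), z), collapse = ", "), "\n")
  invisible(x)
}

#' Nested ANCOVA: management regime within site
#'
#' Pools the limb data per (site, regime) cell — length data from all
#' management areas (or open-access grounds) within a site are pooled before
#' fitting, so each cell contributes one catch curve — and tests homogeneity
#' of the cell slopes. With S sites and R regimes the interaction carries
#' `S * R - 1` numerator df.
#'
#' @param fits Named list of `catch_curve` fits, one per (site, regime) cell.
#' @param site,regime Character vectors parallel to `fits` giving each cell's
#'   site and management regime.
#' @return A `slope_comparison` with design `"site-nested-regime"` and a
#'   `cells` data frame attached.
#' @export
nested_ancova <- function(fits, site, regime) {
  stopifnot(length(fits) == length(site), length(site) == length(regime))
  if (anyDuplicated(paste(site, regime))) {
    stop("duplicate (site, regime) cells", call. = FALSE)
  }
  names(fits) <- paste(site, regime, sep = ":")
  out <- ancova_slopes(fits, design = "site-nested-regime")
  out$cells <- data.frame(site = site, regime = regime,
                          level = names(fits),
                          z = vapply(fits, function(f) f$z, numeric(1)),
                          row.names = NULL)
  out
}

#' Post-hoc pairwise slope contrasts
#'
#' Tests each requested pair of levels by the single-df contrast on the
#' difference of their age slopes within the full interaction model (the
#' squared t of the slope-difference estimate over its standard error,
#' reported as F on (1, df_den)). Unbalanced cells are handled naturally
#' because the contrast variance comes from the full-model coefficient
#' covariance. P-values are unadjusted by default; Holm adjustment by flag.
#'
#' @param cmp A [ancova_slopes()] result.
#' @param pairs List of length-2 character vectors of level names; default
#'   all pairs.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame with `level_1`, `level_2`, `estimate` (slope
#'   difference, on the Z scale), `f_stat`, `df_num`, `df_den`, `p`.
#' @export
posthoc_pairs <- function(cmp, pairs = NULL, adjust = c("none", "holm")) {
  stopifnot(inherits(cmp, "slope_comparison"))
  adjust <- match.arg(adjust)
  lev <- levels(cmp$data$level)
  if (is.null(pairs)) {
    pairs <- utils::combn(lev, 2, simplify = FALSE)
  }
  beta <- stats::coef(cmp$lm)
  V <- suppressWarnings(stats::vcov(cmp$lm))
  rss <- sum(stats::residuals(cmp$lm)^2)
  ss_tot <- sum((cmp$data$log_count - mean(cmp$data$log_count))^2)
  degenerate <- rss <= 1e-12 * max(ss_tot, 1)
  slope_vec <- function(l) {
    v <- numeric(length(beta))
    names(v) <- names(beta)
    v["age"] <- 1
    term <- paste0("level", l, ":age")
    if (term %in% names(beta)) v[term] <- 1
    v
  }
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% lev)) {
      stop(sprintf("unknown level(s): %s",
                   paste(setdiff(pr, lev), collapse = ", ")), call. = FALSE)
    }
    cvec <- slope_vec(pr[1]) - slope_vec(pr[2])
    est <- sum(cvec * beta)
    if (degenerate) {
      # exact-fit input: the contrast is either exactly null or exactly not
      null_diff <- abs(est) <= 1e-8 * max(abs(beta[["age"]]), 1)
      f <- if (null_diff) 0 else Inf
      pval <- if (null_diff) 1 else 0
    } else {
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      f <- (est / se)^2
      pval <- stats::pf(f, 1, cmp$lm$df.residual, lower.tail = FALSE)
    }
    data.frame(level_1 = pr[1], level_2 = pr[2],
               estimate = -est,  # on the Z (positive mortality) scale
               f_stat = f, df_num = 1L, df_den = cmp$lm$df.residual,
               p = pval)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Temporal trend in annual mortality estimates
#'
#' Regresses management-area-level annual Z estimates on calendar year as a
#' continuous single-df predictor and reports the slope test (F on
#' (1, n - 2) df). This is the regional consistency check that mortality in
#' co-managed areas did not drift over the study period.
#'
#' @param z Numeric vector of Z estimates (1/yr), or a data frame with
#'   columns `ma`, `year`, `z`.
#' @param year Calendar years parallel to `z` (ignored for data-frame input).
#' @return List with `f_stat`, `df_num` (1), `df_den` (n - 2), `p`, `slope`
#'   (1/yr per yr), `r2`, `n`.
#' @export
temporal_trend <- function(z, year = NULL) {
  if (is.data.frame(z)) {
    year <- z$year
    z <- z$z
  }
  stopifnot(is.numeric(z), is.numeric(year), length(z) == length(year))
  if (length(z) < 3L) stop("need at least 3 annual estimates", call. = FALSE)
  if (stats::var(z) == 0) {
    # flat response: no trend, by construction
    return(list(f_stat = 0, df_num = 1L, df_den = length(z) - 2L, p = 1,
                slope = 0, r2 = 0, n = length(z)))
  }
  fit <- stats::lm(z ~ year)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(f_stat = unname(fstat[1]), df_num = 1L,
       df_den = as.integer(unname(fstat[3])),
       p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       slope = stats::coef(fit)[["year"]],
       r2 = sm$r.squared, n = length(z))
}

#' Pooled-variance Student's t-test between two sets of mortality estimates
#'
#' Compares the mean annual Z of two species across management-area-by-year
#' cells with the classical pooled-variance form, df = n1 + n2 - 2.
#'
#' @param z1,z2 Numeric vectors of Z estimates (each length >= 2).
#' @return List with `t`, `df`, `p`, and the two means.
#' @export
species_ttest <- function(z1, z2) {
  stopifnot(is.numeric(z1), is.numeric(z2),
            length(z1) >= 2L, length(z2) >= 2L)
  if (stats::var(z1) == 0 && stats::var(z2) == 0) {
    stop("both samples are degenerate (zero variance)", call. = FALSE)
  }
  ht <- stats::t.test(z1, z2, var.equal = TRUE)
  list(t = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
       p = ht$p.value, mean_1 = mean(z1), mean_2 = mean(z2))
}

#' Frequency-matched subsampling of length records
#'
#' Downsamples a stratum to `n_target` records while forcing the subsample's
#' age-class frequency distribution to match the source's own distribution.
#' Per-class quotas are `n_target` times the class proportions, rounded by
#' largest remainder so they sum exactly to `n_target`; individuals are then
#' drawn without replacement within each class. Used to equalize open-access
#' strata of unequal size before a regional comparison.
#'
#' @param records Data frame of length records with a `length_mm` column.
#' @param n_target Subsample size (<= `nrow(records)`).
#' @param p A [growth_params()] object used to age the records.
#' @param class_width Age class width in yr.
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @param over_linf Over-asymptote policy; dropped records cannot be sampled.
#' @return A subset of `records` with exactly `n_target` rows.
#' @export
frequency_matched_subsample <- function(records, n_target, p,
                                        class_width = 0.2, seed = 1L,
                                        over_linf = "drop") {
  stopifnot(is.data.frame(records), "length_mm" %in% names(records),
            n_target >= 1L)
  ages <- suppressWarnings(vb_age(records$length_mm, p,
                                  over_linf = over_linf))
  keep <- !is.na(ages)
  pool <- records[keep, , drop = FALSE]
  cls <- age_class_index(ages[keep], class_width)
  if (n_target > nrow(pool)) {
    stop("n_target exceeds the number of ageable records", call. = FALSE)
  }
  tab <- table(cls)
  props <- as.numeric(tab) / nrow(pool)
  raw <- n_target * props
  quota <- floor(raw)
  rem <- n_target - sum(quota)
  if (rem > 0) {
    frac <- raw - quota
    # largest remainder; ties broken by class order for determinism
    bump <- order(-frac, seq_along(frac))[seq_len(rem)]
    quota[bump] <- quota[bump] + 1L
  }
  if (any(quota > as.numeric(tab))) {
    stop("a class quota exceeds its class count", call. = FALSE)
  }
  cls_levels <- names(tab)
  idx <- with_seed(seed, {
    unlist(lapply(seq_along(cls_levels), function(i) {
      members <- which(cls == as.numeric(cls_levels[i]))
      if (quota[i] == 0L) return(integer(0))
      members[sample.int(length(members), quota[i])]
    }))
  })
  pool[sort(idx), , drop = FALSE]
}
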
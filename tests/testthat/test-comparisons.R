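make_group_fits <- function(slopes, b = 8, ages = seq(1.1, 5.1, by = 0.2),
                            sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(slopes, function(z) {
    limb_fit(ages, b - z * ages + rnorm(length(ages), 0, sd))
  })
  names(fits) <- names(slopes)
  fits
}

test_that("identical groups give a null interaction and equal slopes", {
  fits <- make_group_fits(c(A = 1, B = 1))
  cmp <- ancova_slopes(fits)
  expect_lt(cmp$f_stat, 1e-6)
  expect_equal(cmp$group_fits$A$z, 1)
  expect_equal(cmp$group_fits$B$z, 1)
})

test_that("noiseless distinct slopes are recovered exactly and separated", {
  fits <- make_group_fits(c(A = 1, B = 2))
  cmp <- ancova_slopes(fits)
  expect_equal(cmp$group_fits$A$z, 1, tolerance = 1e-9)
  expect_equal(cmp$group_fits$B$z, 2, tolerance = 1e-9)
  expect_lt(cmp$p, 1e-12)
})

test_that("interaction F and p match the design-matrix oracle", {
  set.seed(33)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    slopes <- runif(k, 0.5, 2)
    names(slopes) <- LETTERS[seq_len(k)]
    ages <- seq(1.1, by = 0.2, length.out = sample(8:25, 1))
    fits <- make_group_fits(slopes, ages = ages, sd = 0.1)
    cmp <- ancova_slopes(fits)
    d <- do.call(rbind, lapply(names(fits), function(nm) {
      data.frame(g = nm, age = fits[[nm]]$limb$age,
                 y = fits[[nm]]$limb$log_count)
    }))
    o <- f_oracle(interaction_design(d$g, d$age),
                  reduced_design(d$g, d$age), d$y)
    expect_equal(cmp$f_stat, o$f, tolerance = 1e-9)
    expect_equal(cmp$p, o$p, tolerance = 1e-9)
    expect_identical(c(cmp$df_num, cmp$df_den), c(o$df1, o$df2))
    # per-level slopes equal the separate per-level OLS slopes
    for (nm in names(fits)) {
      sep <- ols_oracle(fits[[nm]]$limb$age, fits[[nm]]$limb$log_count)
      expect_lt(abs(fits[[nm]]$z + sep$slope), 1e-9)
    }
  }
})

test_that("ancova input contracts are enforced", {
  fits <- make_group_fits(c(A = 1, B = 1))
  expect_error(ancova_slopes(fits["A"]))
  expect_error(ancova_slopes(unname(fits)), "named")
  short <- limb_fit(c(1.1, 1.3, 1.5), c(5, 4, 3))
  short$limb <- short$limb[1:2, ]
  expect_error(ancova_slopes(list(A = fits$A, B = short)), "'B'")
})

test_that("nested ANCOVA pools (site, regime) cells and tests their slopes jointly", {
  cells <- expand.grid(site = c("S1", "S2"), regime = c("MA", "OAA"),
                       stringsAsFactors = FALSE)
  # all four cells from one generating line
  fits <- make_group_fits(setNames(rep(1.2, 4), paste(cells$site, cells$regime)))
  cmp <- nested_ancova(fits, cells$site, cells$regime)
  expect_lt(cmp$f_stat, 1e-6)
  expect_equal(cmp$df_num, 3L)
  expect_equal(nrow(cmp$cells), 4)
  # one cell's slope doubled: reflected exactly in its group fit
  fits2 <- make_group_fits(setNames(c(1.2, 1.2, 1.2, 2.4),
                                    paste(cells$site, cells$regime)))
  cmp2 <- nested_ancova(fits2, cells$site, cells$regime)
  expect_equal(cmp2$group_fits[[4]]$z, 2.4, tolerance = 1e-9)
  expect_lt(cmp2$p, 1e-10)
  # seeded noisy 2x2 agrees with the oracle
  fits3 <- make_group_fits(setNames(c(0.8, 1.0, 1.3, 1.6),
                                    paste(cells$site, cells$regime)),
                           sd = 0.1, seed = 5)
  cmp3 <- nested_ancova(fits3, cells$site, cells$regime)
  d <- cmp3$data
  o <- f_oracle(interaction_design(d$level, d$age),
                reduced_design(d$level, d$age), d$log_count)
  expect_equal(cmp3$f_stat, o$f, tolerance = 1e-9)
  expect_error(nested_ancova(fits3, rep("S1", 4), rep("MA", 4)), "duplicate")
})

test_that("post-hoc pairs are slope-difference contrasts within the full model", {
  fits <- make_group_fits(c(A = 1.0, B = 1.4, C = 0.7), sd = 0.1, seed = 9)
  cmp <- ancova_slopes(fits)
  ph <- posthoc_pairs(cmp)
  expect_equal(nrow(ph), 3)
  # oracle: contrast t^2 from the full-model coefficient covariance
  d <- cmp$data
  X <- interaction_design(d$level, d$age)
  y <- d$log_count
  b <- solve(crossprod(X), crossprod(X, y))
  df2 <- length(y) - ncol(X)
  s2 <- sum((y - X %*% b)^2) / df2
  V <- s2 * solve(crossprod(X))
  # columns: 1, age, dB, dB*age, dC, dC*age; slope diffs A-B: -b4; A-C: -b6; B-C: b4-b6
  cons <- list(c(0, 0, 0, -1, 0, 0), c(0, 0, 0, 0, 0, -1),
               c(0, 0, 0, 1, 0, -1))
  for (i in 1:3) {
    est <- sum(cons[[i]] * b)
    f_or <- est^2 / drop(t(cons[[i]]) %*% V %*% cons[[i]])
    expect_equal(ph$f_stat[i], f_or, tolerance = 1e-9)
    expect_equal(ph$p[i], pf(f_or, 1, df2, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
  # identical pair ~ p near 1; separated pair below machine threshold
  fits2 <- make_group_fits(c(A = 1, B = 1, C = 2))
  cmp2 <- ancova_slopes(fits2)
  ph2 <- posthoc_pairs(cmp2, pairs = list(c("A", "B"), c("A", "C")))
  expect_gt(ph2$p[1], 0.99)
  expect_lt(ph2$p[2], 1e-12)
  expect_error(posthoc_pairs(cmp2, pairs = list(c("A", "Z"))), "unknown")
  # Holm adjustment is monotone above the raw p-values
  ph_h <- posthoc_pairs(cmp, adjust = "holm")
  expect_true(all(ph_h$p >= ph$p - 1e-12))
})

test_that("temporal trend is a single-df year regression", {
  years <- rep(1999:2016, each = 3)
  expect_equal(temporal_trend(rep(1.5, length(years)), years)$f_stat, 0)
  tt <- temporal_trend(0.1 * (years - 1999) + 2, years)
  expect_equal(tt$r2, 1, tolerance = 1e-9)
  expect_error(temporal_trend(c(1, 2), c(1999, 2000)), "at least 3")
  # 54 seeded noisy points: df (1, 52) and F equal to the hand OLS
  set.seed(21)
  z <- rnorm(54, 1.8, 0.3)
  yr <- rep(1999:2016, each = 3)
  tt <- temporal_trend(z, yr)
  o <- ols_oracle(yr, z)
  expect_identical(c(tt$df_num, tt$df_den), c(1L, 52L))
  expect_equal(tt$f_stat, (o$slope / o$se_slope)^2, tolerance = 1e-9)
  expect_equal(tt$slope, o$slope, tolerance = 1e-8)
})

test_that("species comparison is the pooled-variance Student t-test", {
  z1 <- c(1.9, 2.1, 2.4, 1.7, 2.0)
  z2 <- c(0.5, 0.7, 0.6, 0.4)
  st <- species_ttest(z1, z2)
  # frozen from the textbook pooled-variance formula
  expect_equal(st$t, 10.281264636013, tolerance = 1e-9)
  expect_identical(st$df, 7L)
  expect_equal(st$p, 1.78137498237e-05, tolerance = 1e-6)
  # symmetry up to sign
  st2 <- species_ttest(z2, z1)
  expect_equal(st2$t, -st$t)
  expect_equal(st2$p, st$p)
  # identical non-degenerate samples: t = 0
  expect_equal(species_ttest(z1, z1)$t, 0)
  expect_error(species_ttest(c(1, 1), c(2, 2)), "degenerate")
})

test_that("frequency-matched subsampling preserves the source age composition", {
  gp <- loco_growth()
  # two age classes: 100 records near age 0.5, 300 near age 1.5
  recs <- data.frame(length_mm = c(vb_length(runif(100, 0.42, 0.58), gp),
                                   vb_length(runif(300, 1.42, 1.58), gp)))
  sub <- frequency_matched_subsample(recs, 100, gp, seed = 4)
  expect_equal(nrow(sub), 100)
  cls <- floor(as.numeric(vb_age(sub$length_mm, gp)) / 0.2)
  expect_equal(as.numeric(table(cls)), c(25, 75))
  # n_target = source size returns a permutation of the full set
  all_sub <- frequency_matched_subsample(recs, 400, gp, seed = 4)
  expect_equal(sort(all_sub$length_mm), sort(recs$length_mm))
  # largest-remainder bound on every class proportion
  set.seed(12)
  recs2 <- data.frame(length_mm = vb_length(rgamma(800, 5, 2), gp))
  n_t <- 173
  sub2 <- frequency_matched_subsample(recs2, n_t, gp, seed = 8)
  src_cls <- table(floor(as.numeric(vb_age(recs2$length_mm, gp)) / 0.2))
  sub_cls <- table(floor(as.numeric(vb_age(sub2$length_mm, gp)) / 0.2))
  for (k in names(sub_cls)) {
    expect_lt(abs(sub_cls[[k]] / n_t - src_cls[[k]] / 800), 1 / n_t + 1e-12)
  }
  # determinism given seed
  expect_identical(frequency_matched_subsample(recs2, n_t, gp, seed = 8),
                   sub2)
  expect_error(frequency_matched_subsample(recs2, 1e4, gp), "exceeds")
})
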
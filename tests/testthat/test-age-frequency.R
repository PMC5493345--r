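test_that("length binning uses half-open 1-mm intervals and conserves counts", {
  tab <- bin_lengths(c(10.0, 10.4, 11.0))
  expect_equal(tab$count[tab$length_mm == 10], 2)
  expect_equal(tab$count[tab$length_mm == 11], 1)
  expect_equal(nrow(bin_lengths(numeric(0))), 0)
  set.seed(1)
  x <- runif(1000, 10, 20)
  tab <- bin_lengths(x)
  expect_equal(sum(tab$count), 1000)
  expect_equal(nrow(tab), 10)
  expect_true(all(abs(tab$count - 100) < 50))
  expect_error(bin_lengths(c(1, -2)), "positive")
})

test_that("age binning is half-open with boundary ages going up", {
  gp <- loco_growth()
  # a record whose age is exactly on the 1.2-yr class boundary
  af <- age_frequency(vb_length(1.2, gp), gp)
  expect_equal(af$midpoints, 1.3)
  expect_equal(af$counts, 1)
  # interior age lands in its containing class
  af <- age_frequency(vb_length(1.05, gp), gp)
  expect_equal(af$midpoints, 1.1)
})

test_that("record conservation: counts plus over-asymptote drops equal input size", {
  gp <- loco_growth()
  cfg <- sim_config(m = 0.8, f = 0.4, n = 5000, growth = gp, seed = 42)
  recs <- simulate_cohort(cfg)
  af <- age_frequency(recs$length_mm, gp)
  expect_equal(sum(af$counts) + af$n_dropped_over_linf, 5000)
  expect_true(all(diff(af$midpoints) - af$class_width < 1e-8))
  # all-over-asymptote input errors
  expect_error(suppressWarnings(age_frequency(c(151, 160), gp)), "no ageable")
})

test_that("right-tail truncation removes only what lies beyond the first long zero gap", {
  mids <- function(k) seq(0.1, by = 0.2, length.out = k)
  af <- as_age_frequency(mids(8), c(5, 3, 2, 0, 0, 0, 0, 1))
  expect_equal(truncate_right_tail(af)$counts, c(5, 3, 2))
  af <- as_age_frequency(mids(6), c(5, 3, 0, 0, 0, 2))
  expect_equal(truncate_right_tail(af)$counts, c(5, 3, 0, 0, 0, 2))
  # two qualifying gaps: cut at the first
  af <- as_age_frequency(mids(15), c(5, 3, 0, 0, 0, 0, 2, 1, 0, 0, 0, 0, 1, 0, 1))
  expect_equal(truncate_right_tail(af)$counts, c(5, 3))
  # gap parameter is honoured
  expect_equal(truncate_right_tail(af, gap = 2)$counts, c(5, 3))
  expect_error(truncate_right_tail(af, gap = 0))
})

test_that("full-recruitment age is the spline maximum", {
  # symmetric unimodal counts peaking at 1.5
  mids <- seq(0.7, 2.3, by = 0.2)
  cnts <- c(5, 20, 50, 80, 95, 80, 50, 20, 5)
  af <- as_age_frequency(mids, cnts)
  expect_lt(abs(full_recruitment_age(af) - 1.5), 0.1)
  # strictly decreasing counts: boundary maximum at the first midpoint
  af <- as_age_frequency(mids, 90 * exp(-1.2 * seq_along(mids)))
  expect_equal(full_recruitment_age(af), mids[1])
  # too few classes
  expect_error(full_recruitment_age(as_age_frequency(mids[1:3], c(3, 2, 1))),
               "too few")
})

test_that("spline maximum matches a brute-force dense evaluation (gamma-shaped curve)", {
  mids <- seq(0.5, 6.3, by = 0.2)
  cnts <- round(500 * dgamma(mids, shape = 4, rate = 2))
  af <- as_age_frequency(mids, cnts)
  got <- full_recruitment_age(af)
  # same spline, much finer grid
  sp <- smooth.spline(af$midpoints, af$counts, cv = FALSE)
  grid <- seq(min(mids), max(mids), by = 0.2 / 200)
  oracle <- grid[which.max(predict(sp, grid)$y)]
  expect_lt(abs(got - oracle), 0.2 / 20 + 1e-9)
})

test_that("manual age-frequency construction validates its invariants", {
  expect_error(as_age_frequency(c(0.1, 0.5), c(1, 2)), "spacing")
  expect_error(as_age_frequency(c(0.1, 0.3), c(1, -2)), "non-negative")
})

test_that("zero gaps on the ascending side never trigger truncation", {
  mids <- seq(0.1, by = 0.2, length.out = 12)
  cnts <- c(1, 0, 0, 0, 0, 30, 22, 15, 9, 5, 2, 1)
  expect_equal(truncate_right_tail(as_age_frequency(mids, cnts))$counts, cnts)
})
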
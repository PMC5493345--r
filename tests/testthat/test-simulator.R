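test_that("simulation is deterministic given the seed and respects n", {
  gp <- loco_growth()
  cfg <- sim_config(m = 1, f = 0.5, n = 500, growth = gp, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 500)
  expect_true(all(s1$length_mm > 0))
  cfg0 <- sim_config(m = 1, f = 0.5, n = 0, growth = gp)
  expect_equal(nrow(simulate_cohort(cfg0)), 0)
})

test_that("simulator seed does not leak into the caller's RNG stream", {
  gp <- loco_growth()
  set.seed(5)
  before <- runif(1)
  set.seed(5)
  invisible(simulate_cohort(sim_config(m = 1, f = 0, n = 100, growth = gp,
                                       seed = 1)))
  expect_identical(runif(1), before)
})

test_that("knife-edge mean age sits at recruit age plus mean residence time", {
  gp <- loco_growth()
  cfg <- sim_config(m = 1, f = 0, n = 5000, growth = gp, recruit_age = 1,
                    selectivity_steepness = Inf, max_age = 15, seed = 17)
  ages <- simulate_cohort(cfg)$age
  expect_true(all(ages >= 1))
  # truncated-exponential mean: 1 + 1/z up to a negligible truncation term
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - 2), 3 * se)
})

test_that("age histogram of a large knife-edge cohort decays log-linearly at rate z", {
  gp <- loco_growth()
  z <- 0.8
  cfg <- sim_config(m = z, f = 0, n = 50000, growth = gp, recruit_age = 1,
                    selectivity_steepness = Inf, max_age = 15, seed = 23)
  ages <- simulate_cohort(cfg)$age
  idx <- floor(ages / 0.2)
  tab <- table(idx)
  mid <- (as.numeric(names(tab)) + 0.5) * 0.2
  keep <- mid > 1.2 & tab >= 10  # fully recruited, counts dense enough
  o <- ols_oracle(mid[keep], log(as.numeric(tab[keep])))
  expect_lt(abs(-o$slope - z) / z, 0.05)
})

test_that("length at age is unbiased around the growth curve", {
  gp <- loco_growth()
  cfg <- sim_config(m = 0.5, f = 0, n = 20000, growth = gp, recruit_age = 1,
                    selectivity_steepness = Inf, seed = 31)
  s <- simulate_cohort(cfg)
  band <- s$age >= 2 & s$age < 2.2
  dev <- s$length_mm[band] / vb_length(s$age[band], gp) - 1
  expect_lt(abs(mean(dev)), 2 * sd(dev) / sqrt(length(dev)) + 1e-12)
})

test_that("the study fixture mirrors its design table cell by cell", {
  des <- study_design()
  # design bookkeeping: regimes, generating mortalities, cell counts
  expect_equal(sum(des$species == "loco" & des$regime == "MA"), 54)
  expect_equal(sum(des$species == "limpet" & des$regime == "MA"), 53)
  expect_true(all(des$f[des$regime == "NT"] == 0))
  expect_equal(unique(des$m[des$species == "loco"]), 0.98)
  expect_equal(unique(des$f[des$species == "loco" & des$regime == "OAA"]),
               0.90)
  sub <- des[des$species == "loco" & des$year == 2013, ]
  spec <- study_fixture_spec(sub, seed = 11, n_per_cell = 50)
  recs <- make_study_fixture(spec)
  expect_equal(nrow(recs), 50 * nrow(sub))
  got <- as.data.frame(table(recs$regime))
  expect_equal(sort(got$Freq), sort(as.numeric(table(sub$regime)) * 50))
  # reproducible bit-for-bit
  expect_identical(make_study_fixture(spec), recs)
  # duplicate cells rejected
  expect_error(study_fixture_spec(rbind(sub, sub[1, ])), "duplicate")
})

test_that("fixture records validate as length records", {
  des <- study_design("limpet")
  des <- des[des$year == 2013, ]
  recs <- make_study_fixture(study_fixture_spec(des, seed = 2, n_per_cell = 40))
  expect_silent(catchcurve:::validate_length_records(recs))
  expect_true(all(is.na(recs$ma_id[recs$regime == "NT"])))
})

test_that("invalid simulator configurations are rejected", {
  gp <- loco_growth()
  expect_error(sim_config(m = 0, f = 0, n = 10, growth = gp), "positive")
  expect_error(sim_config(m = 1, f = 0, n = 10, growth = gp, length_cv = 0.7),
               "length_cv")
  expect_error(sim_config(m = 1, f = 0, n = 10, growth = gp, max_age = 1,
                          recruit_age = 2))
})
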
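# Independent oracles used across the suite. These deliberately avoid lm()
# and the package's own code paths: plain normal equations and extra
# sum-of-squares arithmetic.

# Simple linear regression by explicit normal equations.
ols_oracle <- function(x, y) {
  n <- length(y)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  df <- n - 2L
  s2 <- sum(res^2) / df
  se_slope <- sqrt(s2 / (sxx - sx^2 / n))
  list(slope = slope, intercept = intercept, se_slope = se_slope, df = df,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Residual sum of squares of y on a design matrix, via normal equations.
rss_oracle <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% b)^2)
}

# Extra-sum-of-squares F test of nested designs (reduced within full).
f_oracle <- function(X_full, X_red, y) {
  ss_full <- rss_oracle(X_full, y)
  ss_red <- rss_oracle(X_red, y)
  df1 <- ncol(X_full) - ncol(X_red)
  df2 <- length(y) - ncol(X_full)
  f <- ((ss_red - ss_full) / df1) / (ss_full / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# Full-interaction ANCOVA design matrix (treatment coding, first level ref).
interaction_design <- function(group, age) {
  g <- factor(group)
  k <- nlevels(g)
  X <- cbind(1, age)
  for (l in levels(g)[-1]) {
    d <- as.numeric(g == l)
    X <- cbind(X, d, d * age)
  }
  X
}
reduced_design <- function(group, age) {
  g <- factor(group)
  X <- cbind(1, age)
  for (l in levels(g)[-1]) X <- cbind(X, as.numeric(g == l))
  X
}

# Exact exponential catch curve on a regular age grid (fractional counts).
noiseless_af <- function(z, b = 8, ages = seq(1.1, 4.1, by = 0.2)) {
  as_age_frequency(ages, exp(b - z * ages))
}

# A catch_curve fit from explicit (age, log-count) limb values, entering
# through the public constructor so the usual fit path is exercised.
limb_fit <- function(ages, log_counts) {
  estimate_z(as_age_frequency(ages, exp(log_counts),
                              class_width = round(ages[2] - ages[1], 10)),
             recruit_age = ages[1])
}

loco_growth <- function() growth_params(150, 0.433, 0)
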
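# independent ICC(3,1) oracle via the two-way ANOVA fitted by stats::aov
icc_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(value = c(x, y),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(value ~ subject + rater, data = d))[[1]]
  msr <- tab["subject", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse)
}

# Steiger (1980) oracle coded independently from the pooled-correlation
# covariance in expanded polynomial form
steiger_oracle <- function(r12, r13, r23, n) {
  rb <- (r12 + r13) / 2
  num <- r23 * (1 - rb^2 - rb^2) - (rb^2 / 2) * (1 - rb^2 - rb^2 - r23^2)
  s <- num / ((1 - rb^2) * (1 - rb^2))
  z <- (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 * (1 - s)))
  list(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

test_that("ICC(3,1) matches the ANOVA oracle and its closed-form cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc_3_1(x, x), 1)
  # consistency form ignores a fixed session shift
  expect_equal(icc_3_1(x, x + 10), 1)
  expect_error(icc_3_1(1:2, 2:3), "at least 3")
  expect_warning(out <- icc_3_1(rep(1, 5), rep(1, 5)), "undefined")
  expect_true(is.na(out))
  set.seed(5)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    a <- rnorm(n); b <- 0.6 * a + rnorm(n, 0, 0.7)
    expect_equal(icc_3_1(a, b), icc_oracle(a, b), tolerance = 1e-10)
  }
  # independent inputs concentrate near zero
  set.seed(9)
  expect_lt(abs(icc_3_1(rnorm(2000), rnorm(2000))), 0.08)
})

test_that("Spearman correlation equals brute-force mid-rank Pearson", {
  expect_equal(spearman_rho(1:8, exp(1:8)), 1)
  expect_equal(spearman_rho(1:8, -(1:8)), -1)
  midrank_pearson <- function(x, y) {
    rk <- function(v) {
      sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
    }
    cor(rk(x), rk(y))
  }
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y), midrank_pearson(x, y), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    a <- sample(1:5, 12, replace = TRUE)
    b <- sample(1:5, 12, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_rho(a, b), midrank_pearson(a, b), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b))
  expect_warning(out <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
})

test_that("Steiger's z matches an independent implementation", {
  s <- steiger_z(0.6, 0.6, 0.3, 20)
  expect_equal(s$z, 0)
  expect_equal(s$p, 1)
  # antisymmetry
  s1 <- steiger_z(0.8, 0.5, 0.6, 17)
  s2 <- steiger_z(0.5, 0.8, 0.6, 17)
  expect_equal(s1$z, -s2$z)
  o <- steiger_oracle(0.8, 0.5, 0.6, 17)
  expect_equal(s1$z, o$z, tolerance = 1e-10)
  expect_equal(s1$p, o$p, tolerance = 1e-10)
  set.seed(14)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    X <- matrix(rnorm(n * 3), n)
    X[, 2] <- X[, 2] + runif(1, -1, 1) * X[, 1]
    X[, 3] <- X[, 3] + runif(1, -1, 1) * X[, 1]
    C <- cor(X)
    r <- c(C[1, 2], C[1, 3], C[2, 3])
    got <- steiger_z(r[1], r[2], r[3], n)
    want <- steiger_oracle(r[1], r[2], r[3], n)
    expect_equal(got$z, want$z, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_error(steiger_z(1, 0.5, 0.2, 10), "strictly inside")
})

test_that("NRMSE arithmetic and invariances hold", {
  truth <- seq(0, 66, length.out = 12)
  expect_equal(nrmse(truth, truth), 0)
  expect_equal(nrmse(truth + 6.6, truth), 10)
  est <- truth + rnorm(12)
  expect_equal(nrmse(est + 5, truth + 5), nrmse(est, truth))
  expect_error(nrmse(est, rep(1, 12)), "zero range")
})

test_that("reliability mask is inclusive at the threshold", {
  set.seed(6)
  a <- rnorm(10); b <- 0.8 * a + rnorm(10, 0, 0.5)
  icc_ab <- icc_3_1(a, b)
  h1 <- tibble::tibble(subject_id = letters[1:10], f = a)
  h2 <- tibble::tibble(subject_id = letters[1:10], f = b)
  at <- feature_reliability(h1, h2, threshold = icc_ab)
  expect_true(at$reliable)
  above <- feature_reliability(h1, h2, threshold = icc_ab + 1e-12)
  expect_false(above$reliable)
})

test_that("duplicated halves give ICC 1; noise features are masked", {
  st <- fixture_segtab()
  tabs <- features_from_segments(st)
  dup <- feature_reliability(tabs$half1, tabs$half1)
  ok <- !is.na(dup$icc)
  expect_true(all(dup$icc[ok] == 1))
  expect_true(all(dup$reliable[ok]))
  # replace a feature by pure per-subject noise: reliability collapses
  set.seed(31)
  masked <- 0L
  for (i in 1:5) {
    h1 <- tabs$half1; h2 <- tabs$half2
    h1$v_mean_mean <- rnorm(nrow(h1))
    h2$v_mean_mean <- rnorm(nrow(h2))
    rel <- feature_reliability(h1, h2)
    if (!rel$reliable[rel$feature == "v_mean_mean"]) masked <- masked + 1L
  }
  expect_gte(masked, 4L)
})

test_that("split-half protocol uses temporally disjoint data", {
  st <- fixture_segtab()
  coh <- fixture_cohort()
  mid <- coh[[1]]$duration_s / 2
  s1 <- st$segments[st$segments$half == "h1" & st$segments$subject_id == "S01", ]
  s2 <- st$segments[st$segments$half == "h2" & st$segments$subject_id == "S01", ]
  expect_true(all(s1$end_s <= mid + 1 / st$fs))
  expect_true(all(s2$start_s >= mid - 1e-9))
  # the full protocol returns one ICC per engineered feature
  shr <- split_half_reliability(coh, "anatomical")
  expect_s3_class(shr, "split_half_result")
  expect_equal(nrow(shr$icc), 91L)
  expect_true(any(shr$icc$reliable))
})
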
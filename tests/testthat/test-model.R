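exact_loss <- function(pred, targets) {
  1 - mean(apply(as.matrix(targets), 2, function(s)
    suppressWarnings(spearman_rho(pred, s))))
}

test_that("soft rank-correlation loss approaches exact Spearman as tau -> 0", {
  set.seed(1)
  targets <- cbind(rnorm(17), rnorm(17), rnorm(17))
  pred <- targets[, 1] + 0.01 * rnorm(17)
  # predictions monotone in every target
  mono <- sort(rnorm(17))
  t_mono <- cbind(mono + 1, 2 * mono, exp(mono))
  expect_lt(soft_spearman_loss(mono, t_mono, tau = 0.001), 1e-3)
  # anti-monotone in a single target contributes 1 - (-1) = 2
  expect_equal(soft_spearman_loss(mono, cbind(-mono), tau = 0.001), 2,
               tolerance = 1e-3)
  # surrogate close to the exact loss on random batches
  set.seed(2)
  for (i in 1:50) {
    p <- rnorm(17)
    tg <- cbind(rnorm(17), rnorm(17), rnorm(17))
    expect_equal(soft_spearman_loss(p, tg, tau = 0.01), exact_loss(p, tg),
                 tolerance = 0.02)
  }
  expect_warning(out <- soft_spearman_loss(rep(0.5, 8), targets[1:8, ]),
                 "constant")
  expect_equal(out, 1)
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(7)
  for (i in 1:5) {
    p <- rnorm(10)
    tg <- cbind(rnorm(10), rnorm(10))
    got <- segmotor:::.soft_spearman(p, tg, tau = 0.1, grad = TRUE)
    eps <- 1e-6
    num <- vapply(seq_along(p), function(k) {
      ph <- p; ph[k] <- ph[k] + eps
      pl <- p; pl[k] <- pl[k] - eps
      (segmotor:::.soft_spearman(ph, tg, 0.1)$loss -
         segmotor:::.soft_spearman(pl, tg, 0.1)$loss) / (2 * eps)
    }, 0)
    expect_equal(got$grad, num, tolerance = 1e-5)
  }
})

test_that("the assessor learns a perfectly informative feature", {
  set.seed(12)
  n <- 12
  theta <- seq(0.05, 0.9, length.out = n)
  x <- tibble::tibble(subject_id = sprintf("S%02d", 1:n),
                      good = 1 - theta,
                      junk = rnorm(n))
  scores <- tibble::tibble(fma_ue = 66 * (1 - theta),
                           wmft_pt_median = 2 + 25 * theta,
                           wmft_fas = 5 * (1 - theta))
  m <- train_assessor(x, scores, lr = 5e-3, seed = 4, epochs = 40)
  expect_gte(m$train_rho_bar, 0.95)
  pred <- predict(m, x)
  expect_true(all(pred >= 0 & pred <= 1))
  # seeded determinism
  m2 <- train_assessor(x, scores, lr = 5e-3, seed = 4, epochs = 40)
  expect_identical(m2$theta, m$theta)
  expect_error(train_assessor(x[1:3, ], scores[1:3, ], 1e-3), "at least 4")
  td <- tidy(m)
  expect_equal(td$term, c("good", "junk", "(bias)"))
  expect_equal(glance(m)$n_features, 2L)
})

test_that("nested LOSOCV never leaks the test subject and permutes to null", {
  set.seed(30)
  n <- 9
  theta <- runif(n, 0.05, 0.9)
  feats <- tibble::tibble(subject_id = sprintf("S%02d", 1:n),
                          f1 = 1 - theta + rnorm(n, 0, 0.05),
                          f2 = -theta + rnorm(n, 0, 0.05),
                          f3 = rnorm(n))
  scores <- tibble::tibble(subject_id = feats$subject_id, theta = theta,
                           fma_ue = pmin(pmax(66 * (1 - theta) + rnorm(n, 0, 2), 0), 66),
                           wmft_pt_median = 2 + 25 * theta^1.5,
                           wmft_fas = 5 * (1 - theta),
                           mal_aou = 5 * (1 - theta), mal_qom = 5 * (1 - theta))
  res <- nested_losocv(feats, scores, lr_grid = c(1e-3, 1e-2), seed = 2,
                       epochs = 15)
  for (fold in res$lineage) {
    expect_false(fold$test_id %in% fold$train_ids)
    expect_equal(length(fold$train_ids), n - 1L)
  }
  expect_equal(nrow(res$estimates), n)
  expect_true(all(res$estimates$estimate >= 0 & res$estimates$estimate <= 1))
  expect_gt(res$rho_bar, 0.5)
  # permutation null: shuffling subjects' scores destroys validity
  set.seed(44)
  nulls <- vapply(1:8, function(i) {
    sc_p <- scores
    perm <- sample(n)
    sc_p[c("fma_ue", "wmft_pt_median", "wmft_fas", "mal_aou", "mal_qom")] <-
      sc_p[perm, c("fma_ue", "wmft_pt_median", "wmft_fas", "mal_aou", "mal_qom")]
    nested_losocv(feats, sc_p, lr_grid = 1e-3, seed = i, epochs = 10)$rho_bar
  }, 0)
  expect_lt(abs(mean(nulls)), 0.35)
  expect_lt(min(nulls), res$rho_bar)
  expect_error(nested_losocv(feats[1:4, ], scores[1:4, ]), "at least 5")
})

test_that("end-to-end assessment recovers impairment on a small cohort", {
  coh <- fixture_cohort()
  st <- fixture_segtab()
  res <- assess_cohort(coh, segtab = st, seed = 1, epochs = 10)
  expect_s3_class(res, "cohort_result")
  expect_equal(nrow(res$estimates), length(coh))
  # higher estimate = better motor status: negative association with theta
  rho_theta <- cor(res$estimates$estimate, cohort_scores(coh)$theta,
                   method = "spearman")
  expect_lt(rho_theta, 0)
  expect_equal(tidy(res)$measure,
               c("fma_ue", "wmft_pt_median", "wmft_fas", "mal_aou", "mal_qom"))
  expect_true(is.finite(glance(res)$nrmse_fma))
  # deterministic given the seed
  res2 <- assess_cohort(coh, segtab = st, seed = 1, epochs = 10)
  expect_identical(res2$estimates$estimate, res$estimates$estimate)
})

test_that("subsampling at p = 100 reproduces the full pipeline exactly", {
  coh <- fixture_cohort()
  st <- fixture_segtab()
  full <- assess_cohort(coh, segtab = st, seed = 2, epochs = 8)
  sub <- subsample_experiment(coh, segtab = st, p_grid = 100, repeats = 1,
                              seed = 2, epochs = 8)
  expect_equal(sub$n_reliable, sum(full$reliability$reliable))
  expect_equal(sub$rho_bar, full$rho_bar)
  expect_equal(sub$icc, full$icc)
  # distinct repeats draw distinct subsets
  s1 <- segmotor:::.sample_segments(st, 50, seed = 101)
  s2 <- segmotor:::.sample_segments(st, 50, seed = 102)
  expect_false(identical(s1$segments$start_idx, s2$segments$start_idx))
  expect_equal(nrow(s1$segments), nrow(s2$segments), tolerance = 0.05)
})

test_that("movement-type split partitions segments and runs both groups", {
  coh <- fixture_cohort()
  st <- fixture_segtab()
  ints <- stats::setNames(lapply(coh, function(r) r$linear_intervals),
                          vapply(coh, function(r) r$subject_id, ""))
  cls <- classify_segment_movement(st$segments, ints)
  expect_equal(nrow(cls), nrow(st$segments))
  expect_true(all(cls$movement_type %in% c("linear", "nonlinear")))
  expect_gt(sum(cls$movement_type == "linear"), 0)
  expect_gt(sum(cls$movement_type == "nonlinear"), 0)
  # hand case: 60% of the span inside a linear interval -> linear
  seg <- tibble::tibble(subject_id = "A", start_s = 0, end_s = 1)
  got <- classify_segment_movement(seg, list(A = tibble::tibble(start_s = 0, end_s = 0.6)))
  expect_equal(got$movement_type, "linear")
  got2 <- classify_segment_movement(seg, list(A = tibble::tibble(start_s = 0, end_s = 0.4)))
  expect_equal(got2$movement_type, "nonlinear")
  mts <- movement_type_split(coh, segtab = st, seed = 2, epochs = 6)
  expect_s3_class(mts$linear, "cohort_result")
  expect_s3_class(mts$nonlinear, "cohort_result")
})
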
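## Motor-status regressor: a sigmoid-output model trained with a
## differentiable rank-correlation surrogate of the 1 - rho_bar loss, under
## nested leave-one-subject-out cross-validation.

#' Differentiable rank-correlation training loss
#'
#' Surrogate of `1 - rho_bar`, where `rho_bar` is the average Spearman
#' correlation of the predictions with the training targets (FMA-UE,
#' negative median WMFT performance time, WMFT-FAS).  Prediction ranks are
#' softened by pairwise sigmoid comparisons at temperature `tau`; target
#' ranks are exact mid-ranks.  As `tau` goes to 0 the surrogate approaches
#' the exact Spearman loss.
#'
#' @param pred Numeric predictions (length n >= 3).
#' @param targets Numeric matrix (n x m) of training targets, already signed
#'   so that higher = better.
#' @param tau Softness temperature (default 0.1).
#' @return The scalar loss; constant predictions give loss 1 with a warning.
#' @export
soft_spearman_loss <- function(pred, targets, tau = 0.1) {
  .soft_spearman(pred, as.matrix(targets), tau)$loss
}

.soft_spearman <- function(pred, targets, tau = 0.1, grad = FALSE) {
  n <- length(pred)
  stopifnot(n >= 3L, nrow(targets) == n)
  if (stats::sd(pred) < 1e-12) {
    warning("constant predictions: rank-correlation loss degenerate")
    return(list(loss = 1, grad = rep(0, n)))
  }
  d <- outer(pred, pred, "-") / tau
  sig <- stats::plogis(d)
  r <- rowSums(sig) # soft ranks (self term contributes 0.5)
  rc <- r - mean(r)
  rn <- sqrt(sum(rc^2))
  m <- ncol(targets)
  loss <- 0
  g_r <- rep(0, n)
  for (k in seq_len(m)) {
    s <- rank(targets[, k])
    sc <- s - mean(s)
    sn <- sqrt(sum(sc^2))
    if (sn < 1e-12) next
    ck <- sum(rc * sc) / (rn * sn)
    loss <- loss + (1 - ck) / m
    if (grad) {
      dc_dr <- (sc / sn - ck * rc / rn) / rn
      g_r <- g_r - dc_dr / m
    }
  }
  out <- list(loss = loss)
  if (grad) {
    sp <- sig * (1 - sig) / tau # symmetric in (i, j)
    diag_terms <- rowSums(sp) - diag(sp)
    # d r_l / d p_i = -sp[l, i] off-diagonal, sum_j sp[i, j] on the diagonal
    out$grad <- as.numeric(diag_terms * g_r - (sp %*% g_r - diag(sp) * g_r))
  }
  out
}

#' Exact average Spearman validity of predictions against signed targets
#' @noRd
.rho_bar <- function(pred, targets) {
  mean(apply(as.matrix(targets), 2L, function(s)
    suppressWarnings(spearman_rho(pred, s))))
}

.signed_targets <- function(scores) {
  cbind(fma_ue = scores$fma_ue,
        neg_wmft_pt = -scores$wmft_pt_median,
        wmft_fas = scores$wmft_fas)
}

#' Train the sigmoid-output motor-status assessor
#'
#' Fits a linear map (optionally with one hidden layer) from reliable
#' features to a single sigmoid-squashed output in \[0, 1\], minimizing the
#' soft rank-correlation loss with Adam.  Features are z-scored with
#' training-set statistics; higher output = better motor status.
#'
#' @param x Feature matrix or data frame (subjects x reliable features; a
#'   `subject_id` column is dropped).
#' @param scores Data frame with `fma_ue`, `wmft_pt_median`, `wmft_fas`
#'   rows aligned with `x` (self-reported MAL scales are never used in
#'   training).
#' @param lr Adam learning rate.
#' @param seed Integer seed (deterministic given data + seed).
#' @param epochs Training epochs (default 30).
#' @param batch_size Mini-batch size (default 8; trailing batches smaller
#'   than 4 are folded into the previous one).
#' @param tau Soft-rank temperature.
#' @param hidden Hidden-layer width; 0 (default) fits the plain
#'   input-to-sigmoid-output model.
#' @return An object of class `motor_assessor`.
#' @export
train_assessor <- function(x, scores, lr = 1e-3, seed = 1L, epochs = 30L,
                           batch_size = 8L, tau = 0.1, hidden = 0L) {
  xm <- .feature_matrix(x)
  n <- nrow(xm)
  if (n < 4L) stop("need at least 4 training subjects")
  targets <- .signed_targets(scores)
  stopifnot(nrow(targets) == n)
  center <- colMeans(xm)
  scale <- apply(xm, 2L, stats::sd)
  scale[scale < 1e-12] <- 1
  xz <- sweep(sweep(xm, 2L, center), 2L, scale, "/")
  p <- ncol(xz)
  with_seed(seed, {
    if (hidden > 0L) {
      theta <- list(w1 = matrix(stats::rnorm(p * hidden, 0, 1 / sqrt(p)), p),
                    b1 = rep(0, hidden),
                    w2 = stats::rnorm(hidden, 0, 1 / sqrt(hidden)), b2 = 0)
    } else {
      theta <- list(w2 = stats::rnorm(p, 0, 1 / sqrt(p)), b2 = 0)
    }
    mom <- lapply(theta, function(v) v * 0)
    vel <- lapply(theta, function(v) v * 0)
    b1a <- 0.9; b2a <- 0.999; epsa <- 1e-8
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      batches <- lapply(starts, function(s) ord[s:min(s + batch_size - 1L, n)])
      nb <- length(batches)
      if (nb > 1L && length(batches[[nb]]) < 4L) {
        batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
        batches[[nb]] <- NULL
      }
      for (idx in batches) {
        xb <- xz[idx, , drop = FALSE]
        tb <- targets[idx, , drop = FALSE]
        if (hidden > 0L) {
          h_lin <- sweep(xb %*% theta$w1, 2L, theta$b1, "+")
          h_act <- tanh(h_lin)
          z <- as.numeric(h_act %*% theta$w2) + theta$b2
        } else {
          z <- as.numeric(xb %*% theta$w2) + theta$b2
        }
        pr <- stats::plogis(z)
        sl <- suppressWarnings(.soft_spearman(pr, tb, tau, grad = TRUE))
        dz <- sl$grad * pr * (1 - pr)
        if (hidden > 0L) {
          gw2 <- as.numeric(t(h_act) %*% dz)
          gb2 <- sum(dz)
          dh <- outer(dz, theta$w2) * (1 - h_act^2)
          grads <- list(w1 = t(xb) %*% dh, b1 = colSums(dh), w2 = gw2, b2 = gb2)
        } else {
          grads <- list(w2 = as.numeric(t(xb) %*% dz), b2 = sum(dz))
        }
        step <- step + 1L
        for (nm in names(theta)) {
          mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * grads[[nm]]
          vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * grads[[nm]]^2
          mhat <- mom[[nm]] / (1 - b1a^step)
          vhat <- vel[[nm]] / (1 - b2a^step)
          theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + epsa)
        }
        if (any(!is.finite(unlist(theta)))) stop("training diverged: non-finite parameters")
      }
    }
    model <- structure(list(theta = theta, hidden = hidden, center = center,
                            scale = scale, feature_names = colnames(xm),
                            lr = lr, seed = seed, epochs = epochs, tau = tau),
                       class = "motor_assessor")
    model$train_rho_bar <- .rho_bar(predict(model, x), targets)
    model
  })
}

.feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- x[setdiff(names(x), "subject_id")]
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' @export
predict.motor_assessor <- function(object, newdata, ...) {
  xm <- .feature_matrix(newdata)
  xm <- xm[, object$feature_names, drop = FALSE]
  xz <- sweep(sweep(xm, 2L, object$center), 2L, object$scale, "/")
  if (object$hidden > 0L) {
    h <- tanh(sweep(xz %*% object$theta$w1, 2L, object$theta$b1, "+"))
    z <- as.numeric(h %*% object$theta$w2) + object$theta$b2
  } else {
    z <- as.numeric(xz %*% object$theta$w2) + object$theta$b2
  }
  stats::plogis(z)
}

#' @export
print.motor_assessor <- function(x, ...) {
  cat(sprintf("<motor_assessor> %d features | lr = %g | epochs = %d | training rho_bar = %.3f\n",
              length(x$feature_names), x$lr, x$epochs, x$train_rho_bar))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.motor_assessor <- function(x, ...) {
  if (x$hidden > 0L) {
    tibble::tibble(term = x$feature_names,
                   estimate = sqrt(rowSums(x$theta$w1^2)))
  } else {
    tibble::tibble(term = c(x$feature_names, "(bias)"),
                   estimate = c(x$theta$w2, x$theta$b2))
  }
}

#' @export
glance.motor_assessor <- function(x, ...) {
  tibble::tibble(train_rho_bar = x$train_rho_bar, lr = x$lr, epochs = x$epochs,
                 n_features = length(x$feature_names), hidden = x$hidden)
}

#' Nested leave-one-subject-out cross-validation of the motor assessor
#'
#' The outer loop holds out one subject at a time; an inner LOSOCV over the
#' remaining subjects selects the Adam learning rate from a log-spaced grid
#' by held-out average Spearman validity; the final model is refit on all
#' training subjects and scores the test subject.  Pooled out-of-fold
#' estimates are then correlated with each clinical measure, and output
#' reliability is the ICC(3,1) of the fold models applied to each subject's
#' two temporal-half feature vectors.
#'
#' @param features Tibble `subject_id` + reliable feature columns (full
#'   recording).
#' @param scores Tibble from [cohort_scores()] aligned by `subject_id`.
#' @param half1,half2 Optional temporal-half feature tables (same columns)
#'   for output reliability.
#' @param lr_grid Learning-rate grid (default 5 log-spaced points in
#'   \[1e-4, 1e-2\]).
#' @param seed Base seed; per-fold seeds are derived deterministically.
#' @param epochs,batch_size,tau,hidden Passed to [train_assessor()].
#' @return An object of class `cohort_result`: estimates, per-measure
#'   validity, average clinician validity `rho_bar`, output ICC, NRMSE
#'   against FMA-UE (estimate rescaled to the 0-66 range), and fold lineage.
#' @export
nested_losocv <- function(features, scores, half1 = NULL, half2 = NULL,
                          lr_grid = 10^seq(-4, -2, length.out = 5),
                          seed = 1L, epochs = 30L, batch_size = 8L, tau = 0.1,
                          hidden = 0L) {
  ids <- features$subject_id
  n <- length(ids)
  if (n < 5L) stop("need at least 5 subjects for nested LOSOCV")
  scores <- scores[match(ids, scores$subject_id), ]
  est <- rep(NA_real_, n)
  est_h1 <- rep(NA_real_, n); est_h2 <- rep(NA_real_, n)
  lr_sel <- rep(NA_real_, n)
  lineage <- vector("list", n)
  for (i in seq_len(n)) {
    tr_ids <- ids[-i]
    xtr <- features[features$subject_id %in% tr_ids, ]
    str_ <- scores[scores$subject_id %in% tr_ids, ]
    # inner LOSOCV over the training subjects only
    inner_rho <- purrr::map_dbl(lr_grid, function(lr) {
      preds <- rep(NA_real_, length(tr_ids))
      for (j in seq_along(tr_ids)) {
        xt <- xtr[xtr$subject_id != tr_ids[j], ]
        st <- str_[str_$subject_id != tr_ids[j], ]
        m <- train_assessor(xt, st, lr = lr, seed = seed + 1000L * i + j,
                            epochs = epochs, batch_size = batch_size,
                            tau = tau, hidden = hidden)
        preds[j] <- predict(m, xtr[xtr$subject_id == tr_ids[j], ])
      }
      .rho_bar(preds, .signed_targets(str_))
    })
    lr_sel[i] <- lr_grid[which.max(inner_rho)]
    model <- train_assessor(xtr, str_, lr = lr_sel[i], seed = seed + 1000L * i,
                            epochs = epochs, batch_size = batch_size,
                            tau = tau, hidden = hidden)
    est[i] <- predict(model, features[i, ])
    if (!is.null(half1) && ids[i] %in% half1$subject_id &&
        !is.null(half2) && ids[i] %in% half2$subject_id) {
      est_h1[i] <- predict(model, half1[half1$subject_id == ids[i], ])
      est_h2[i] <- predict(model, half2[half2$subject_id == ids[i], ])
    }
    lineage[[i]] <- list(test_id = ids[i], train_ids = tr_ids)
  }
  measures <- c("fma_ue", "wmft_pt_median", "wmft_fas", "mal_aou", "mal_qom")
  validity <- tibble::tibble(
    measure = measures,
    rho = purrr::map_dbl(measures, function(m)
      suppressWarnings(spearman_rho(est, scores[[m]])))
  )
  rho_bar <- .rho_bar(est, .signed_targets(scores))
  icc <- if (any(is.finite(est_h1))) {
    suppressWarnings(icc_3_1(est_h1[is.finite(est_h1)], est_h2[is.finite(est_h1)]))
  } else NA_real_
  structure(list(
    estimates = tibble::tibble(subject_id = ids, estimate = est,
                               estimate_h1 = est_h1, estimate_h2 = est_h2,
                               lr = lr_sel),
    validity = validity,
    rho_bar = rho_bar,
    icc = icc,
    nrmse_fma = nrmse(66 * est, scores$fma_ue),
    scores = scores,
    lineage = lineage,
    seed = seed
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> n = %d | rho_bar = %.3f | output ICC = %.3f | NRMSE vs FMA-UE = %.1f%%\n",
              nrow(x$estimates), x$rho_bar, x$icc, x$nrmse_fma))
  invisible(x)
}

#' @export
tidy.cohort_result <- function(x, ...) x$validity

#' @export
glance.cohort_result <- function(x, ...) {
  tibble::tibble(n = nrow(x$estimates), rho_bar = x$rho_bar, icc = x$icc,
                 nrmse_fma = x$nrmse_fma,
                 rho_fma = x$validity$rho[x$validity$measure == "fma_ue"])
}

#' End-to-end motor-deficit assessment of a cohort
#'
#' Runs segmentation, feature aggregation, split-half reliability filtering
#' (ICC(3,1) >= 0.75, inclusive) and nested LOSOCV for the chosen method.
#'
#' @inheritParams cohort_segments
#' @inheritParams nested_losocv
#' @param icc_threshold Reliability cut-off for feature elimination.
#' @param segtab Optional precomputed [cohort_segments()] output (reused by
#'   the experiments).
#' @return A `cohort_result` with the reliability report attached as
#'   `$reliability` (a tibble `feature, icc, reliable`).
#' @export
assess_cohort <- function(cohort, method = "anatomical", icc_threshold = 0.75,
                          detected_intervals = NULL, use_truth_orientation = FALSE,
                          lr_grid = 10^seq(-4, -2, length.out = 5), seed = 1L,
                          epochs = 30L, segtab = NULL, ...) {
  if (is.null(segtab)) {
    segtab <- cohort_segments(cohort, method = method,
                              detected_intervals = detected_intervals,
                              use_truth_orientation = use_truth_orientation, ...)
  }
  tabs <- features_from_segments(segtab)
  rel <- feature_reliability(tabs$half1, tabs$half2, threshold = icc_threshold)
  keep <- rel$feature[rel$reliable]
  if (length(keep) == 0L) stop("no reliable features at ICC >= ", icc_threshold)
  scores <- cohort_scores(cohort)
  res <- nested_losocv(tabs$full[c("subject_id", keep)], scores,
                       half1 = tabs$half1[c("subject_id", keep)],
                       half2 = tabs$half2[c("subject_id", keep)],
                       lr_grid = lr_grid, seed = seed, epochs = epochs)
  res$reliability <- rel
  res$method <- method
  res
}
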
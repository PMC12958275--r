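## Sliding-window detection of straight-path (linear) movements with a small
## 1-D convolutional network over the six local-frame IMU channels.
## The network (three conv layers of 30 filters, kernel 11, ReLU -> batch
## norm, two max-pool stages, global average pooling, softmax head) and its
## Adam optimizer are implemented directly with im2col matrix products.

#' Detector configuration
#'
#' @param n_conv Number of convolutional layers (3).
#' @param filters Filters per layer (30).
#' @param kernel Kernel size (11).
#' @param pool Max-pool size and stride (2).
#' @param threshold Initial decision boundary on the positive-class score.
#' @param seed Training seed.
#' @param epochs,lr,batch_size Adam training settings.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(n_conv = 3L, filters = 30L, kernel = 11L, pool = 2L,
                            threshold = 0.5, seed = 1L, epochs = 30L,
                            lr = 1e-3, batch_size = 8L) {
  structure(list(n_conv = n_conv, filters = filters, kernel = kernel,
                 pool = pool, threshold = threshold, seed = as.integer(seed),
                 epochs = epochs, lr = lr, batch_size = batch_size),
            class = "detector_config")
}

#' Build labeled sliding windows from an IMU recording
#'
#' 3-second windows over the six local-frame channels with 1/3 overlap
#' between adjacent windows (stride = 2/3 of the window).  A window is
#' labeled positive exactly when some annotated interval lies entirely
#' within it.
#'
#' @param rec An [imu_recording()].
#' @param annotations Tibble with `start_s`, `end_s` (may be empty).
#' @param window_s Window length (s); `window_s * fs` must be integral.
#' @return A tibble `start_idx, start_s, end_s, label` with the window
#'   signal as a list column `data` (window x 6 matrices); empty when the
#'   recording is shorter than one window.
#' @export
make_windows <- function(rec, annotations = NULL, window_s = 3) {
  fs <- imu_fs(rec)
  win <- window_s * fs
  if (abs(win - round(win)) > 1e-9) stop("`window_s * fs` must be integral")
  win <- as.integer(round(win))
  stride <- as.integer(round(win * 2 / 3))
  m <- .axis_mat(rec, c("ax", "ay", "az", "gx", "gy", "gz"))
  n <- nrow(m)
  if (n < win) {
    return(tibble::tibble(start_idx = integer(), start_s = numeric(),
                          end_s = numeric(), label = integer(), data = list()))
  }
  starts <- seq(1L, n - win + 1L, by = stride)
  t0 <- rec$t[1L]
  out <- tibble::tibble(
    start_idx = starts,
    start_s = t0 + (starts - 1L) / fs,
    end_s = t0 + (starts - 1L + win) / fs,
    data = lapply(starts, function(s) m[s:(s + win - 1L), , drop = FALSE])
  )
  out$label <- if (is.null(annotations) || nrow(annotations) == 0L) 0L else {
    purrr::map2_int(out$start_s, out$end_s, function(a, b)
      as.integer(any(annotations$start_s >= a & annotations$end_s <= b)))
  }
  out[c("start_idx", "start_s", "end_s", "label", "data")]
}

## ---- minimal 1-D CNN ----

.windows_to_array <- function(windows) {
  b <- nrow(windows)
  L <- nrow(windows$data[[1L]])
  C <- ncol(windows$data[[1L]])
  arr <- array(0, c(b, L, C))
  for (i in seq_len(b)) arr[i, , ] <- windows$data[[i]]
  arr
}

.im2col <- function(arr, k) {
  d <- dim(arr); b <- d[1L]; L <- d[2L]; C <- d[3L]
  lo <- L - k + 1L
  X <- matrix(0, b * lo, k * C)
  for (c in seq_len(C)) for (j in seq_len(k)) {
    X[, (c - 1L) * k + j] <- as.vector(arr[, j:(j + lo - 1L), c])
  }
  X
}

.col2im <- function(dX, k, dims) {
  b <- dims[1L]; L <- dims[2L]; C <- dims[3L]
  lo <- L - k + 1L
  darr <- array(0, dims)
  for (c in seq_len(C)) for (j in seq_len(k)) {
    darr[, j:(j + lo - 1L), c] <- darr[, j:(j + lo - 1L), c] +
      matrix(dX[, (c - 1L) * k + j], b, lo)
  }
  darr
}

.cnn_init <- function(cfg, in_ch = 6L) {
  k <- cfg$kernel; f <- cfg$filters
  layer <- function(cin) {
    list(W = matrix(stats::rnorm(k * cin * f, 0, sqrt(2 / (k * cin))), k * cin, f),
         b = rep(0, f), gamma = rep(1, f), beta = rep(0, f),
         run_mean = rep(0, f), run_var = rep(1, f))
  }
  convs <- vector("list", cfg$n_conv)
  cin <- in_ch
  for (i in seq_len(cfg$n_conv)) { convs[[i]] <- layer(cin); cin <- f }
  list(convs = convs,
       fc_W = matrix(stats::rnorm(f * 2, 0, sqrt(1 / f)), f, 2),
       fc_b = c(0, 0))
}

.bn_fwd <- function(y, layer, training, eps = 1e-5) {
  if (training) {
    mu <- colMeans(y)
    va <- colMeans(sweep(y, 2L, mu)^2)
  } else {
    mu <- layer$run_mean; va <- layer$run_var
  }
  xhat <- sweep(sweep(y, 2L, mu), 2L, sqrt(va + eps), "/")
  out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
  list(out = out, xhat = xhat, mu = mu, va = va, eps = eps)
}

.cnn_forward <- function(params, arr, cfg, training = FALSE) {
  caches <- list()
  f <- cfg$filters
  x <- arr
  for (li in seq_along(params$convs)) {
    ly <- params$convs[[li]]
    dims_in <- dim(x)
    X <- .im2col(x, cfg$kernel)
    y <- sweep(X %*% ly$W, 2L, ly$b, "+")
    relu_mask <- y > 0
    y <- y * relu_mask
    bn <- .bn_fwd(y, ly, training)
    lo <- dims_in[2L] - cfg$kernel + 1L
    a <- array(bn$out, c(dims_in[1L], lo, f))
    cache <- list(X = X, relu_mask = relu_mask, bn = bn, dims_in = dims_in, lo = lo)
    if (li < length(params$convs)) {
      # max-pool size 2 stride 2 after the first n_conv - 1 layers
      lp <- lo %/% 2L
      a1 <- a[, seq(1L, 2L * lp, by = 2L), , drop = FALSE]
      a2 <- a[, seq(2L, 2L * lp, by = 2L), , drop = FALSE]
      take_first <- a1 >= a2
      cache$take_first <- take_first
      cache$lp <- lp
      a <- ifelse(take_first, a1, a2)
    }
    caches[[li]] <- cache
    x <- a
  }
  gap <- apply(x, c(1L, 3L), mean) # B x filters
  logits <- sweep(gap %*% params$fc_W, 2L, params$fc_b, "+")
  mx <- apply(logits, 1L, max)
  el <- exp(logits - mx)
  probs <- el / rowSums(el)
  list(probs = probs, gap = gap, caches = caches, last = x)
}

.cnn_backward <- function(params, fwd, labels, cfg) {
  B <- nrow(fwd$probs)
  f <- cfg$filters
  y1 <- cbind(1 - labels, labels)
  dlogits <- (fwd$probs - y1) / B
  grads <- list(fc_W = t(fwd$gap) %*% dlogits, fc_b = colSums(dlogits))
  dgap <- dlogits %*% t(params$fc_W)
  Llast <- dim(fwd$last)[2L]
  dx <- array(0, dim(fwd$last))
  for (c in seq_len(f)) dx[, , c] <- matrix(dgap[, c], B, Llast) / Llast
  grads$convs <- vector("list", length(params$convs))
  for (li in rev(seq_along(params$convs))) {
    ly <- params$convs[[li]]
    ca <- fwd$caches[[li]]
    if (li < length(params$convs)) {
      # un-pool
      dfull <- array(0, c(B, ca$lo, f))
      up1 <- dx * ca$take_first
      up2 <- dx * !ca$take_first
      dfull[, seq(1L, 2L * ca$lp, by = 2L), ] <- up1
      dfull[, seq(2L, 2L * ca$lp, by = 2L), ] <- dfull[, seq(2L, 2L * ca$lp, by = 2L), , drop = FALSE] + up2
      dx <- dfull
    }
    dY <- dx; dim(dY) <- c(B * ca$lo, f)
    # batch-norm backward
    bn <- ca$bn
    N <- nrow(dY)
    dgamma <- colSums(dY * bn$xhat)
    dbeta <- colSums(dY)
    dxhat <- sweep(dY, 2L, ly$gamma, "*")
    inv_sd <- 1 / sqrt(bn$va + bn$eps)
    # dx = inv_sd/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat * xhat))
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * bn$xhat)
    dY2 <- sweep(
      N * dxhat - matrix(s1, N, f, byrow = TRUE) - bn$xhat * matrix(s2, N, f, byrow = TRUE),
      2L, inv_sd / N, "*")
    dY2 <- dY2 * ca$relu_mask
    grads$convs[[li]] <- list(W = t(ca$X) %*% dY2, b = colSums(dY2),
                              gamma = dgamma, beta = dbeta)
    if (li > 1L) dx <- .col2im(dY2 %*% t(ly$W), cfg$kernel, ca$dims_in)
  }
  grads
}

.scale_windows <- function(arr, center, scale) {
  for (c in seq_len(dim(arr)[3L])) arr[, , c] <- (arr[, , c] - center[c]) / scale[c]
  arr
}

#' Train the linear-movement window detector
#'
#' Trains the convolutional detector on labeled windows, then tunes the
#' decision boundary on the validation windows to maximize precision
#' (ties broken toward higher recall).  Channels are z-scored with
#' training-set statistics; training is deterministic given the seed.
#'
#' @param train,val Window tibbles from [make_windows()]; training windows
#'   must contain both classes.
#' @param cfg A [detector_config()].
#' @return A `linear_detector` object with fields `threshold`,
#'   `val_precision`, `val_recall`.
#' @export
train_detector <- function(train, val, cfg = detector_config()) {
  if (length(unique(train$label)) < 2L) stop("training windows must contain both classes")
  arr <- .windows_to_array(train)
  center <- apply(arr, 3L, mean)
  scale <- apply(arr, 3L, stats::sd)
  scale[scale < 1e-12] <- 1
  arr <- .scale_windows(arr, center, scale)
  labels <- train$label
  n <- dim(arr)[1L]
  with_seed(cfg$seed, {
    params <- .cnn_init(cfg)
    adam_m <- rapply(params, function(v) v * 0, how = "replace")
    adam_v <- rapply(params, function(v) v * 0, how = "replace")
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        if (length(idx) < 2L) next
        fwd <- .cnn_forward(params, arr[idx, , , drop = FALSE], cfg, training = TRUE)
        # update batch-norm running statistics
        for (li in seq_along(params$convs)) {
          bn <- fwd$caches[[li]]$bn
          params$convs[[li]]$run_mean <- 0.9 * params$convs[[li]]$run_mean + 0.1 * bn$mu
          params$convs[[li]]$run_var <- 0.9 * params$convs[[li]]$run_var + 0.1 * bn$va
        }
        grads <- .cnn_backward(params, fwd, labels[idx], cfg)
        step <- step + 1L
        upd <- function(path_get, path_set) {
          g <- path_get(grads); m0 <- path_get(adam_m); v0 <- path_get(adam_v)
          m1 <- b1 * m0 + (1 - b1) * g
          v1 <- b2 * v0 + (1 - b2) * g^2
          adam_m <<- path_set(adam_m, m1); adam_v <<- path_set(adam_v, v1)
          path_set_p <- path_set
          delta <- cfg$lr * (m1 / (1 - b1^step)) / (sqrt(v1 / (1 - b2^step)) + eps)
          params <<- path_set_p(params, path_get(params) - delta)
          invisible(NULL)
        }
        for (li in seq_along(params$convs)) {
          for (fld in c("W", "b", "gamma", "beta")) {
            local({
              li0 <- li; fld0 <- fld
              upd(function(x) x$convs[[li0]][[fld0]],
                  function(x, v) { x$convs[[li0]][[fld0]] <- v; x })
            })
          }
        }
        upd(function(x) x$fc_W, function(x, v) { x$fc_W <- v; x })
        upd(function(x) x$fc_b, function(x, v) { x$fc_b <- v; x })
      }
    }
    model <- structure(list(params = params, cfg = cfg, center = center,
                            scale = scale, threshold = cfg$threshold),
                       class = "linear_detector")
    val_scores <- predict_window_scores(model, val)
    th <- .tune_threshold(val_scores, val$label)
    model$threshold <- th
    mtr <- detection_metrics(val_scores, val$label, threshold = th)
    model$val_precision <- mtr$precision
    model$val_recall <- mtr$recall
    model
  })
}

.tune_threshold <- function(scores, labels, default = 0.5) {
  cand <- sort(unique(c(default, scores)))
  best <- default; best_p <- -1; best_r <- -1
  for (th in cand) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1L)
    if (sum(pred) == 0L) next
    p <- tp / sum(pred)
    r <- tp / max(1L, sum(labels == 1L))
    if (p > best_p + 1e-12 || (abs(p - best_p) <= 1e-12 && r > best_r)) {
      best <- th; best_p <- p; best_r <- r
    }
  }
  best
}

#' Positive-class scores for a set of windows
#'
#' @param model A trained `linear_detector`.
#' @param windows Window tibble.
#' @return Numeric vector of P(linear) in \[0, 1\].
#' @export
predict_window_scores <- function(model, windows) {
  if (nrow(windows) == 0L) return(numeric())
  arr <- .scale_windows(.windows_to_array(windows), model$center, model$scale)
  out <- numeric(nrow(windows))
  bs <- 64L
  for (s in seq(1L, nrow(windows), by = bs)) {
    idx <- s:min(s + bs - 1L, nrow(windows))
    fwd <- .cnn_forward(model$params, arr[idx, , , drop = FALSE], model$cfg,
                        training = FALSE)
    out[idx] <- fwd$probs[, 2L]
  }
  out
}

#' Merge overlapping or abutting intervals
#'
#' @param intervals Tibble with `start_s`, `end_s`.
#' @return Merged maximal intervals, sorted; idempotent and
#'   order-independent.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  iv <- dplyr::arrange(intervals, .data$start_s, .data$end_s)
  starts <- iv$start_s[1L]; ends <- iv$end_s[1L]
  for (i in seq_len(nrow(iv))[-1L]) {
    k <- length(starts)
    if (iv$start_s[i] <= ends[k] + 1e-12) {
      ends[k] <- max(ends[k], iv$end_s[i])
    } else {
      starts <- c(starts, iv$start_s[i]); ends <- c(ends, iv$end_s[i])
    }
  }
  tibble::tibble(start_s = starts, end_s = ends)
}

#' Predict merged linear-movement intervals for a recording
#'
#' Scores all sliding windows and merges those at or above the decision
#' boundary that overlap or abut into maximal variable-length intervals.
#'
#' @param model A trained `linear_detector`.
#' @param rec An [imu_recording()].
#' @param threshold Decision boundary (defaults to the tuned one).
#' @return A tibble `start_s, end_s, kind = "detected"`.
#' @export
predict_intervals <- function(model, rec, threshold = model$threshold) {
  windows <- make_windows(rec)
  if (nrow(windows) == 0L) return(tibble::tibble(start_s = numeric(), end_s = numeric(), kind = character()))
  sc <- predict_window_scores(model, windows)
  pos <- windows[sc >= threshold, c("start_s", "end_s")]
  out <- merge_intervals(pos)
  if (nrow(out) > 0L) out$kind <- "detected" else out$kind <- character()
  out
}

#' Window-level detection metrics
#'
#' Precision, recall and F1 at a threshold, and the area under the
#' precision-recall curve by trapezoid integration over recall.
#'
#' @param scores Positive-class scores.
#' @param labels 0/1 window labels.
#' @param threshold Decision boundary for the thresholded metrics.
#' @return A tibble `precision, recall, f1, auc_pr`.
#' @export
detection_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pos <- sum(labels == 1L)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  if (sum(pred) == 0L) {
    warning("no predicted positives: precision undefined, reported as 0")
    precision <- 0
  } else precision <- tp / sum(pred)
  recall <- if (pos == 0L) 0 else tp / pos
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  # PR curve over descending score thresholds
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord] == 1L
  tp_c <- cumsum(lab)
  fp_c <- cumsum(!lab)
  keep <- c(diff(scores[ord]) != 0, TRUE) # last index of each tied block
  prec <- tp_c[keep] / (tp_c[keep] + fp_c[keep])
  rec <- if (pos == 0L) rep(0, sum(keep)) else tp_c[keep] / pos
  rec <- c(0, rec); prec <- c(if (length(prec)) prec[1L] else 1, prec)
  auc <- sum(diff(rec) * (utils::head(prec, -1L) + utils::tail(prec, -1L)) / 2)
  tibble::tibble(precision = precision, recall = recall, f1 = f1, auc_pr = auc)
}
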
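#' Training specification for the MLP
#'
#' Online backpropagation settings. Defaults follow the chromatogram
#' emulator's regime: learning rate 0.1, momentum 0.03, per-epoch random
#' shuffling of the exemplars, a stopping root-mean-square error of
#' 0.15, and target encoding at `scale_margin` / `1 - scale_margin`
#' (0.1/0.9) to keep sigmoid outputs away from saturation.
#'
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param rms_target stopping RMS error.
#' @param scale_margin target-encoding margin in `[0, 0.5)`.
#' @param max_epochs maximum training epochs.
#' @param shuffle_each_epoch shuffle exemplar order every epoch.
#' @param seed RNG seed for weight init and shuffling.
#' @return a list of class `train_spec`.
#' @export
train_spec <- function(lr = 0.1, momentum = 0.03, rms_target = 0.15,
                       scale_margin = 0.1, max_epochs = 1000,
                       shuffle_each_epoch = TRUE, seed = 1L) {
  stopifnot(lr > 0, momentum >= 0, momentum < 1,
            rms_target > 0, scale_margin >= 0, scale_margin < 0.5,
            max_epochs >= 1)
  structure(list(lr = lr, momentum = momentum, rms_target = rms_target,
                 scale_margin = scale_margin,
                 max_epochs = as.integer(max_epochs),
                 shuffle_each_epoch = shuffle_each_epoch,
                 seed = as.integer(seed)),
            class = "train_spec")
}

#' Window and normalize chromatograms for the network
#'
#' Restricts each trace to the retention-time window (half-open
#' `[min, max)`), resampling linearly to `n_points` if the grid inside
#' the window differs, then maps the whole matrix to `[0, 1]` using its
#' single global minimum and maximum (not per-feature), which are stored
#' for identical application at inference.
#'
#' @param chroms a [chromatogram_set()] (or list with `rt` and
#'   `intensity`).
#' @param rt_window two-element numeric window in minutes.
#' @param n_points number of input nodes (default 205).
#' @return list with `X` (samples x `n_points` matrix in `[0, 1]`),
#'   `rt` (window grid), and `norm` (`min`, `max`).
#' @export
window_and_normalize <- function(chroms, rt_window = c(10, 14),
                                 n_points = 205) {
  rt <- chroms$rt
  step <- mean(diff(rt))
  if (rt_window[1] < min(rt) - 1e-9 || rt_window[2] > max(rt) + step) {
    stop("rt_window outside the data span", call. = FALSE)
  }
  idx <- which(rt >= rt_window[1] & rt < rt_window[2])
  if (length(idx) == n_points) {
    X <- chroms$intensity[, idx, drop = FALSE]
    grid <- rt[idx]
  } else {
    warning("window holds ", length(idx), " points; resampling to ",
            n_points)
    grid <- seq(rt_window[1], rt_window[2], length.out = n_points + 1)[1:n_points]
    X <- t(apply(chroms$intensity, 1, function(v) {
      stats::approx(rt, v, xout = grid, rule = 2)$y
    }))
  }
  lo <- min(X)
  hi <- max(X)
  if (hi == lo) {
    warning("constant data; all values map to 0")
    Xn <- matrix(0, nrow(X), ncol(X))
  } else {
    Xn <- (X - lo) / (hi - lo)
  }
  rownames(Xn) <- rownames(chroms$intensity)
  list(X = Xn, rt = grid, norm = list(min = lo, max = hi))
}

#' Apply a stored normalization
#' @param X raw matrix (samples x window points).
#' @param norm the `norm` element from [window_and_normalize()].
#' @return normalized matrix.
#' @export
apply_normalization <- function(X, norm) {
  if (norm$max == norm$min) return(matrix(0, nrow(X), ncol(X)))
  (X - norm$min) / (norm$max - norm$min)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(n_in, n_hidden, n_out, init_range = 0.5) {
  list(W1 = matrix(stats::runif(n_hidden * n_in, -init_range, init_range),
                   n_hidden, n_in),
       b1 = stats::runif(n_hidden, -init_range, init_range),
       W2 = matrix(stats::runif(n_out * n_hidden, -init_range, init_range),
                   n_out, n_hidden),
       b2 = stats::runif(n_out, -init_range, init_range))
}

mlp_forward_all <- function(w, X) {
  A1 <- sigmoid(tcrossprod(X, w$W1) + matrix(w$b1, nrow(X), length(w$b1),
                                             byrow = TRUE))
  sigmoid(tcrossprod(A1, w$W2) + matrix(w$b2, nrow(X), length(w$b2),
                                        byrow = TRUE))
}

#' Train a one-hidden-layer sigmoid MLP by online backpropagation
#'
#' Per-exemplar gradient-descent updates with momentum on the squared
#' error, exemplar order reshuffled every epoch. Training stops when the
#' epoch-end root-mean-square output error (over all exemplars and
#' output nodes) reaches `spec$rms_target`, at `spec$max_epochs`, or if
#' the RMS rises for 10 consecutive epochs (divergence halt, flagged).
#' Weights initialize uniformly in `[-0.5, 0.5]` from `spec$seed`.
#'
#' @param X input matrix (samples x inputs), values in `[0, 1]`.
#' @param targets target matrix (samples x outputs).
#' @param n_hidden hidden-layer width.
#' @param spec a [train_spec()].
#' @param init_range half-width of the uniform weight initialization.
#' @return a list of class `mlp_model`: weight matrices `W1`/`W2`, bias
#'   vectors `b1`/`b2`, `activation`, and a `log` (RMS trajectory, final
#'   status, seed).
#' @export
mlp_train <- function(X, targets, n_hidden, spec = train_spec(),
                      init_range = 0.5) {
  X <- as.matrix(X)
  targets <- as.matrix(targets)
  stopifnot(nrow(X) == nrow(targets))
  n <- nrow(X)
  set.seed(spec$seed)
  w <- mlp_init(ncol(X), n_hidden, ncol(targets), init_range)
  v <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, W2 = w$W2 * 0, b2 = w$b2 * 0)
  lr <- spec$lr
  mom <- spec$momentum
  rms_log <- numeric(0)
  status <- "max_epochs"
  rising <- 0L
  prev_rms <- Inf
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- if (spec$shuffle_each_epoch) sample.int(n) else seq_len(n)
    for (i in ord) {
      x <- X[i, ]
      a1 <- sigmoid(drop(w$W1 %*% x) + w$b1)
      yv <- sigmoid(drop(w$W2 %*% a1) + w$b2)
      d2 <- (yv - targets[i, ]) * yv * (1 - yv)
      d1 <- drop(crossprod(w$W2, d2)) * a1 * (1 - a1)
      v$W2 <- mom * v$W2 - lr * tcrossprod(d2, a1)
      v$b2 <- mom * v$b2 - lr * d2
      v$W1 <- mom * v$W1 - lr * tcrossprod(d1, x)
      v$b1 <- mom * v$b1 - lr * d1
      w$W2 <- w$W2 + v$W2
      w$b2 <- w$b2 + v$b2
      w$W1 <- w$W1 + v$W1
      w$b1 <- w$b1 + v$b1
    }
    rms <- sqrt(mean((mlp_forward_all(w, X) - targets)^2))
    rms_log <- c(rms_log, rms)
    if (rms <= spec$rms_target) {
      status <- "converged"
      break
    }
    rising <- if (rms > prev_rms) rising + 1L else 0L
    if (rising >= 10L) {
      status <- "diverged"
      warning("training halted: RMS increased for 10 consecutive epochs")
      break
    }
    prev_rms <- rms
  }
  structure(list(
    W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
    activation = "sigmoid",
    log = list(epochs = length(rms_log), rms = rms_log,
               final_rms = rms_log[length(rms_log)],
               status = status, seed = spec$seed)
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %d-%d-%d sigmoid, %d epochs, final RMS %.4f (%s)\n",
              ncol(x$W1), nrow(x$W1), nrow(x$W2),
              x$log$epochs, x$log$final_rms, x$log$status))
  invisible(x)
}

#' Forward pass of a trained MLP
#' @param model an `mlp_model`.
#' @param X input matrix (samples x inputs) or a single input vector.
#' @return output matrix (samples x outputs).
#' @export
predict_mlp <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  mlp_forward_all(model, as.matrix(X))
}

#' Analytic backprop gradient of the summed squared error
#'
#' Full-batch gradient of `0.5 * sum((f(X) - T)^2)` with respect to each
#' weight and bias, used to verify the online updates against central
#' finite differences.
#'
#' @param model an `mlp_model` (or weight list).
#' @param X inputs.
#' @param targets targets.
#' @return list of gradients `W1`, `b1`, `W2`, `b2`.
#' @export
mlp_gradient <- function(model, X, targets) {
  X <- as.matrix(X)
  targets <- as.matrix(targets)
  A1 <- sigmoid(tcrossprod(X, model$W1) +
                  matrix(model$b1, nrow(X), length(model$b1), byrow = TRUE))
  Y <- sigmoid(tcrossprod(A1, model$W2) +
                 matrix(model$b2, nrow(X), length(model$b2), byrow = TRUE))
  D2 <- (Y - targets) * Y * (1 - Y)
  D1 <- (D2 %*% model$W2) * A1 * (1 - A1)
  list(W1 = crossprod(D1, X), b1 = colSums(D1),
       W2 = crossprod(D2, A1), b2 = colSums(D2))
}

#' Train the canine-diagnosis classifier
#'
#' A fully connected `n_inputs`-`n_hidden`-2 sigmoid MLP whose two
#' output nodes represent canine-indicated positive and canine-indicated
#' negative alerts. Targets use the scale-margin encoding
#' (`1 - margin` / `margin`). The labels are the dog's calls, not biopsy
#' truth.
#'
#' @param X normalized input matrix from [window_and_normalize()].
#' @param calls character/factor of `"positive"`/`"negative"` canine
#'   calls per sample.
#' @param spec a [train_spec()].
#' @param n_hidden hidden width (default 32).
#' @return an `mlp_model` with `classes = c("positive", "negative")` and
#'   any normalization carried in `$norm` by the caller.
#' @export
train_classifier <- function(X, calls, spec = train_spec(), n_hidden = 32) {
  calls <- as.character(calls)
  stopifnot(all(calls %in% c("positive", "negative")))
  m <- spec$scale_margin
  targets <- cbind(positive = ifelse(calls == "positive", 1 - m, m),
                   negative = ifelse(calls == "positive", m, 1 - m))
  model <- mlp_train(X, targets, n_hidden, spec)
  model$classes <- c("positive", "negative")
  model
}

#' Classify samples with a trained classifier
#' @param model classifier from [train_classifier()].
#' @param X normalized inputs.
#' @return character vector of calls (`"positive"`/`"negative"`).
#' @export
classify_mlp <- function(model, X) {
  out <- predict_mlp(model, X)
  model$classes[max.col(out, ties.method = "first")]
}

#' Train the auto-associative reconstruction network
#'
#' A bottleneck MLP (`n_inputs`-`n_hidden`-`n_inputs`) trained to
#' reproduce its input, fitted on canine-negative-indicated spectra
#' only. Applied to a new spectrum it produces the nearest
#' canine-negative-like spectrum it has learned; the input-minus-output
#' residual then exposes anomalous features. The per-grid-point
#' envelope of absolute training residuals (with the median and overall
#' maximum) is stored for thresholding difference spectra.
#'
#' @param X_negative normalized spectra of canine-negative-indicated
#'   samples (samples x inputs).
#' @param spec a [train_spec()].
#' @param n_hidden bottleneck width (default 32).
#' @return an `mlp_model` with `median_abs_resid` recorded.
#' @export
train_autoassociator <- function(X_negative, spec = train_spec(),
                                 n_hidden = 32) {
  X_negative <- as.matrix(X_negative)
  model <- mlp_train(X_negative, X_negative, n_hidden, spec)
  resid <- X_negative - predict_mlp(model, X_negative)
  model$median_abs_resid <- stats::median(abs(resid))
  model$max_abs_resid <- max(abs(resid))
  model$resid_envelope <- apply(abs(resid), 2, max)
  model
}
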
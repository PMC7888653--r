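#' Sure-independence screening rank
#'
#' Ranks predictors by marginal utility: the absolute coefficient of a
#' univariate logistic fit on the standardized predictor. Used to cut the
#' screened compound set to at most `n / log(n)` before penalized
#' fitting.
#'
#' @param X numeric matrix (samples x predictors).
#' @param y 0/1 response.
#' @param cap maximum predictors retained; default `floor(n / log(n))`.
#' @return integer vector of retained column indices, strongest first.
#' @export
sis_rank <- function(X, y, cap = NULL) {
  n <- nrow(X)
  if (is.null(cap)) cap <- max(1L, floor(n / log(n)))
  util <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(0)
    z <- (x - mean(x)) / s
    fit <- tryCatch(suppressWarnings(
      stats::glm.fit(cbind(1, z), y, family = stats::binomial(),
                     control = list(maxit = 25))),
      error = function(e) NULL)
    if (is.null(fit)) 0 else abs(fit$coefficients[2])
  }, numeric(1))
  util[!is.finite(util)] <- 0
  ord <- order(util, decreasing = TRUE)
  ord[seq_len(min(cap, ncol(X)))]
}

scad_deriv <- function(beta, lambda, a = 3.7) {
  b <- abs(beta)
  ifelse(b <= lambda, lambda, pmax(a * lambda - b, 0) / (a - 1))
}

mcp_deriv <- function(beta, lambda, a = 3) {
  pmax(lambda - abs(beta) / a, 0)
}

# One local-linear-approximation pass: weighted-lasso logistic fit where
# coefficient j carries per-unit penalty pen[j]; glmnet rescales
# penalty.factor to mean 1, so the effective lambda is mean(pen).
lla_step <- function(X, y, pen) {
  if (all(pen <= 1e-10)) {
    fit <- suppressWarnings(
      stats::glm(y ~ X, family = stats::binomial(),
                 control = list(maxit = 50)))
    beta <- stats::coef(fit)
    return(list(intercept = beta[1], beta = beta[-1]))
  }
  lam_eff <- mean(pen)
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial",
                   lambda = lam_eff, penalty.factor = pen,
                   standardize = FALSE, maxit = 1e5))
  list(intercept = as.numeric(fit$a0),
       beta = as.numeric(fit$beta))
}

penalty_deriv <- function(penalty) {
  switch(penalty,
         SCAD = scad_deriv,
         MCP = mcp_deriv,
         lasso = function(beta, lambda) rep(lambda, length(beta)))
}

pad_cols <- function(X) {
  # glmnet needs >= 2 columns; pad with a null column when necessary
  if (ncol(X) < 2) cbind(X, .pad = 0) else X
}

fit_scad_at <- function(X, y, lambda, penalty = "SCAD", n_lla = 3,
                        beta_init = NULL) {
  deriv <- penalty_deriv(penalty)
  pad <- ncol(X) < 2
  Xf <- pad_cols(X)
  beta <- if (is.null(beta_init)) rep(0, ncol(Xf)) else
    c(beta_init, rep(0, ncol(Xf) - length(beta_init)))
  res <- list(intercept = 0, beta = beta)
  for (it in seq_len(n_lla)) {
    pen <- deriv(beta, lambda)
    if (pad) pen[length(pen)] <- lambda
    res <- lla_step(Xf, y, pen)
    if (max(abs(res$beta - beta)) < 1e-6) {
      beta <- res$beta
      break
    }
    beta <- res$beta
  }
  if (pad) res$beta <- res$beta[-length(res$beta)]
  res
}

# SCAD/MCP solutions over a whole lambda grid: one lasso path call
# provides the local-linear-approximation starting points, then each
# lambda gets its reweighted refinement steps.
scad_path <- function(X, y, lambdas, penalty = "SCAD", n_lla = 3) {
  Xf <- pad_cols(X)
  init <- tryCatch(
    glmnet::glmnet(Xf, y, family = "binomial", lambda = lambdas,
                   standardize = FALSE, maxit = 1e5),
    error = function(e) NULL)
  lapply(seq_along(lambdas), function(l) {
    b0 <- if (!is.null(init) && l <= ncol(init$beta)) {
      as.numeric(init$beta[seq_len(ncol(X)), l])
    } else NULL
    tryCatch(
      fit_scad_at(X, y, lambdas[l], penalty, n_lla = max(n_lla - 1, 1),
                  beta_init = b0),
      error = function(e) NULL)
  })
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Penalized logistic regression with sure-independence screening
#'
#' Two-stage sparse logistic model for screened VOC panels: marginal
#' ranking first cuts the predictors to at most `n / log(n)`, then a
#' concave-penalized (SCAD by default) logistic regression is solved by
#' local-linear-approximation iterations around a weighted-lasso inner
#' solver. The tuning parameter is chosen by stratified k-fold
#' cross-validated deviance.
#'
#' @param table a [voc_table()] restricted to the screened compound set,
#'   or a plain samples-x-compounds matrix.
#' @param labels `"cancer"`/`"control"` per sample (taken from `table`
#'   when it is a [voc_table()]).
#' @param folds cross-validation folds for tuning (default 10).
#' @param seed seed for fold assignment.
#' @param penalty `"SCAD"` (default), `"MCP"` or `"lasso"`.
#' @param nlambda length of the tuning-parameter grid.
#' @param sis_cap cap for the screening stage; `NULL` for `n / log(n)`.
#' @param lambda optional fixed tuning parameter; skips cross-validation.
#' @param rule tuning choice: `"min"` (default) takes the minimizer of
#'   the cross-validated deviance; `"1se"` takes the sparsest model
#'   within one standard error of the minimum.
#' @return a list of class `logistic_fit` with `intercept`, named
#'   `coefficients` over the selected compounds, `selected_set`,
#'   `lambda`, `converged`, and `method = "penalized"`.
#' @export
fit_penalized_logistic <- function(table, labels = NULL, folds = 10,
                                   seed = 1L,
                                   penalty = c("SCAD", "MCP", "lasso"),
                                   nlambda = 30, sis_cap = NULL,
                                   lambda = NULL, rule = c("min", "1se")) {
  penalty <- match.arg(penalty)
  rule <- match.arg(rule)
  if (inherits(table, "voc_table")) {
    X <- table$abundance
    labels <- as.character(table$labels)
  } else {
    X <- as.matrix(table)
  }
  y <- as.integer(labels == "cancer")
  n <- nrow(X)
  stopifnot(folds >= 2, n >= folds, ncol(X) >= 1)
  # log1p stabilizes the heavy-tailed abundances, then standardize
  X <- log1p(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  X <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  set.seed(seed)
  sel_sis <- sis_rank(X, y, cap = sis_cap)
  Xs <- X[, sel_sis, drop = FALSE]

  if (is.null(lambda)) {
    lam_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
    lambdas <- exp(seq(log(lam_max), log(lam_max * 0.01),
                       length.out = nlambda))
    fold <- stratified_folds(y, folds)
    cv_dev <- matrix(NA_real_, folds, nlambda)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1) next
      fits <- scad_path(Xs[tr, , drop = FALSE], y[tr], lambdas, penalty)
      for (l in seq_along(lambdas)) {
        if (is.null(fits[[l]])) next
        eta <- fits[[l]]$intercept +
          Xs[!tr, , drop = FALSE] %*% fits[[l]]$beta
        cv_dev[f, l] <- binomial_deviance(y[!tr], stats::plogis(eta))
      }
    }
    mean_dev <- colMeans(cv_dev, na.rm = TRUE)
    if (rule == "1se") {
      k <- colSums(!is.na(cv_dev))
      se_dev <- apply(cv_dev, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(k, 1))
      best <- which.min(mean_dev)
      thr <- mean_dev[best] + se_dev[best]
      lambda <- lambdas[min(which(mean_dev <= thr))]
    } else {
      lambda <- lambdas[which.min(mean_dev)]
    }
  }
  final <- tryCatch(fit_scad_at(Xs, y, lambda, penalty),
                    error = function(e) NULL)
  converged <- !is.null(final) && all(is.finite(final$beta))
  if (is.null(final)) final <- list(intercept = stats::qlogis(mean(y)),
                                    beta = rep(0, ncol(Xs)))
  nz <- which(abs(final$beta) > 1e-8)
  structure(list(
    intercept = unname(final$intercept),
    coefficients = stats::setNames(final$beta[nz], colnames(Xs)[nz]),
    selected_set = colnames(Xs)[nz],
    lambda = lambda, penalty = penalty,
    converged = converged, method = "penalized",
    scaling = list(center = ctr, scale = scl)
  ), class = "logistic_fit")
}

#' Firth bias-reduced logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' `l(b) + 0.5 * log det I(b)` by Newton iterations with
#' hat-value-adjusted responses, yielding finite coefficients even under
#' complete separation. Convergence is declared when the penalized score
#' norm falls below `tol`; a singular information matrix triggers a
#' ridge-stabilized fallback, flagged on the fit.
#'
#' @param X predictor matrix (no intercept column; one is added).
#' @param y 0/1 response (or `"cancer"`/`"control"` labels).
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the penalized score.
#' @return a list of class `logistic_fit` with `intercept`, named
#'   `coefficients`, `converged`, `ridged` and `method = "firth"`.
#' @export
firth_fit <- function(X = NULL, y, max_iter = 200, tol = 1e-8) {
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "cancer")
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) {
    Xd <- matrix(1, n, 1)
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (n < ncol(X)) {
      warning("fewer samples than predictors in Firth fit")
    }
    Xd <- cbind(`(Intercept)` = 1, X)
  }
  p <- ncol(Xd)
  beta <- rep(0, p)
  ridged <- FALSE
  penalized_ll <- function(beta) {
    eta <- drop(Xd %*% beta)
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    info <- crossprod(Xd * w, Xd)
    ld <- determinant(info, logarithm = TRUE)
    sum(y * eta - log1p(exp(eta))) + 0.5 * as.numeric(ld$modulus)
  }
  converged <- FALSE
  ll_old <- penalized_ll(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-12)
    XW <- Xd * sqrt(w)
    info <- crossprod(XW)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) {
      ridged <- TRUE
      inv <- solve(info + diag(1e-6, p))
    }
    h <- rowSums((XW %*% inv) * XW)
    score <- drop(crossprod(Xd, y - pr + h * (0.5 - pr)))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    delta <- drop(inv %*% score)
    score_norm <- function(b) {
      e <- drop(Xd %*% b)
      q <- stats::plogis(e)
      wq <- pmax(q * (1 - q), 1e-12)
      XWq <- Xd * sqrt(wq)
      invq <- tryCatch(solve(crossprod(XWq)),
                       error = function(e2) solve(crossprod(XWq) +
                                                    diag(1e-6, p)))
      hq <- rowSums((XWq %*% invq) * XWq)
      max(abs(drop(crossprod(Xd, y - q + hq * (0.5 - q)))))
    }
    # step halving: accept a step that improves the penalized likelihood
    # or shrinks the penalized score (guards against oscillation on the
    # likelihood plateau near the boundary)
    step <- 1
    s_old <- max(abs(score))
    repeat {
      cand <- beta + step * delta
      ll_new <- penalized_ll(cand)
      if (is.finite(ll_new) &&
          (ll_new > ll_old + 1e-12 || score_norm(cand) < s_old ||
           step < 1e-6)) {
        break
      }
      step <- step / 2
    }
    beta <- beta + step * delta
    ll_old <- penalized_ll(beta)
  }
  nms <- colnames(Xd)
  structure(list(
    intercept = unname(beta[1]),
    coefficients = if (p > 1) stats::setNames(beta[-1], nms[-1]) else numeric(0),
    selected_set = if (p > 1) nms[-1] else character(0),
    converged = converged, ridged = ridged, method = "firth"
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit (%s%s): intercept %.4f, %d predictor(s)%s\n",
              x$method,
              if (!is.null(x$penalty)) paste0("/", x$penalty) else "",
              x$intercept, length(x$coefficients),
              if (isTRUE(x$converged)) "" else " [not converged]"))
  if (length(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted probabilities from a logistic fit
#'
#' @param fit a `logistic_fit` from [fit_penalized_logistic()] or
#'   [firth_fit()].
#' @param X new-data matrix whose columns include the fit's selected set
#'   (for penalized fits, raw abundances: the stored log1p/standardize
#'   transform is re-applied).
#' @return numeric vector of probabilities.
#' @export
predict_logistic <- function(fit, X) {
  X <- as.matrix(X)
  eta <- rep(fit$intercept, nrow(X))
  if (length(fit$coefficients)) {
    nms <- names(fit$coefficients)
    Z <- X[, nms, drop = FALSE]
    if (!is.null(fit$scaling)) {
      Z <- log1p(Z)
      Z <- sweep(sweep(Z, 2, fit$scaling$center[nms]), 2,
                 fit$scaling$scale[nms], "/")
    }
    eta <- eta + drop(Z %*% fit$coefficients)
  }
  stats::plogis(eta)
}

#' Jackknife (leave-one-out) ROC for the screened-penalized-Firth chain
#'
#' For each held-out sample the whole modelling chain is repeated on the
#' remaining samples — prevalence filter, rank-sum screen at
#' `screen_alpha`, sure-independence screening with penalized selection,
#' and (by default) the Firth refit on the selected panel — and the
#' held-out probability is recorded. The assembled out-of-sample
#' probabilities give an honest ROC curve, countering the over-optimism
#' that in-sample variable selection induces.
#'
#' @param table a [voc_table()] (unfiltered; filtering happens inside
#'   each fold).
#' @param screen_alpha screening cutoff inside each fold (default 0.2).
#' @param prevalence_min prevalence cutoff inside each fold.
#' @param folds cross-validation folds for tuning inside each fold.
#' @param seed base RNG seed.
#' @param firth_refit repeat the Firth refit inside every fold (default
#'   `TRUE`); when `FALSE` the penalized fit's probabilities are used
#'   directly.
#' @param penalty passed to [fit_penalized_logistic()].
#' @param ... further tuning arguments (`nlambda`, `rule`, `sis_cap`)
#'   passed to [fit_penalized_logistic()].
#' @return a list of class `roc_result`: `thresholds`, `tpr`, `fpr`,
#'   `auc`, `jackknife_probs`.
#' @export
jackknife_roc <- function(table, screen_alpha = 0.2, prevalence_min = 0.03,
                          folds = 10, seed = 1L, firth_refit = TRUE,
                          penalty = "SCAD", ...) {
  stopifnot(inherits(table, "voc_table"))
  y <- as.character(table$labels)
  n <- nrow(table$abundance)
  if (min(table(y)) < 3) {
    stop("need at least 3 samples per class for jackknife ROC", call. = FALSE)
  }
  probs <- rep(NA_real_, n)
  prev_loo <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sub <- voc_table(table$abundance[-i, , drop = FALSE], y[-i])
    if (min(table(sub$labels)) < 2) {
      warning("fold ", i, " skipped: a class is (nearly) absent")
      next
    }
    prev_loo[i] <- mean(sub$labels == "cancer")
    filt <- prevalence_filter(sub, prevalence_min)
    scr <- screen_vocs(filt, alpha = screen_alpha)
    kept <- scr$compound[scr$kept_alpha]
    if (length(kept) == 0) {
      # no informative features: predict the fold prevalence (a zero
      # score after centering, below)
      probs[i] <- prev_loo[i]
      next
    }
    sub_kept <- voc_table(filt$abundance[, kept, drop = FALSE],
                          as.character(sub$labels))
    pen <- fit_penalized_logistic(sub_kept, folds = min(folds, n - 1),
                                  seed = seed + i, penalty = penalty, ...)
    newx <- table$abundance[i, kept, drop = FALSE]
    if (length(pen$selected_set) == 0) {
      probs[i] <- prev_loo[i]
      next
    }
    if (firth_refit) {
      Z <- log1p(filt$abundance[, pen$selected_set, drop = FALSE])
      ff <- firth_fit(Z, as.character(sub$labels))
      zi <- log1p(table$abundance[i, pen$selected_set, drop = FALSE])
      probs[i] <- predict_logistic(ff, zi)
    } else {
      probs[i] <- predict_logistic(pen, newx)
    }
  }
  ok <- !is.na(probs)
  # centering on each fold's training prevalence removes the systematic
  # leave-one-out class-imbalance tilt from the ranking
  scores <- probs - prev_loo
  r <- pROC::roc(response = y[ok], predictor = scores[ok],
                 levels = c("control", "cancer"), direction = "<",
                 quiet = TRUE)
  structure(list(
    thresholds = r$thresholds,
    tpr = r$sensitivities,
    fpr = 1 - r$specificities,
    auc = as.numeric(r$auc),
    jackknife_probs = probs,
    jackknife_scores = scores
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f over %d jackknife probabilities\n",
              x$auc, sum(!is.na(x$jackknife_probs))))
  invisible(x)
}
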
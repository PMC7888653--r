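sim_window <- function(seed, n_case = 30, n_control = 30, specs = NULL) {
  d <- simulation_design(n_case = n_case, n_control = n_control,
                         seed = seed)
  cs <- if (is.null(specs)) simulate_chromatograms(d) else
    simulate_chromatograms(d, specs)
  wn <- window_and_normalize(cs)
  list(wn = wn,
       calls = ifelse(cs$samples$cohort == "cancer",
                      "positive", "negative"))
}

test_that("windowing yields 205 inputs and an invariant normalization", {
  d <- simulation_design(n_case = 2, n_control = 2, seed = 1)
  cs <- simulate_chromatograms(d)
  expect_gt(length(cs$rt), 1500)   # near-9000-point analogue, full run
  wn <- window_and_normalize(cs, c(10, 14), 205)
  expect_equal(ncol(wn$X), 205)
  expect_true(all(wn$X >= 0 & wn$X <= 1))
  expect_true(all(wn$rt >= 10 & wn$rt < 14))

  # affine transforms of the input leave the normalized matrix unchanged
  cs2 <- cs
  cs2$intensity <- 3.7 * cs$intensity + 11
  wn2 <- window_and_normalize(cs2, c(10, 14), 205)
  expect_equal(wn2$X, wn$X, tolerance = 1e-12)

  # full-span window is an identity selection (with resampling warning
  # only if the grid size differs)
  wn_full <- window_and_normalize(cs, range(cs$rt) + c(0, 1e-6),
                                  length(cs$rt))
  expect_equal(ncol(wn_full$X), length(cs$rt))

  expect_warning(window_and_normalize(cs, c(10, 14), 100), "resampling")
  cs$intensity[] <- 5
  expect_warning(out <- window_and_normalize(cs, c(10, 14), 205),
                 "constant")
  expect_true(all(out$X == 0))
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  X <- matrix(runif(8 * 5), 8, 5)
  targets <- matrix(runif(8 * 2), 8, 2)
  set.seed(8)
  model <- uroscent:::mlp_init(5, 3, 2)
  g <- mlp_gradient(model, X, targets)
  loss <- function(m) 0.5 * sum((predict_mlp(m, X) - targets)^2)
  eps <- 1e-6
  for (field in c("W1", "W2", "b1", "b2")) {
    idx <- seq_along(model[[field]])
    for (k in sample(idx, min(6, length(idx)))) {
      up <- model
      up[[field]][k] <- up[[field]][k] + eps
      dn <- model
      dn[[field]][k] <- dn[[field]][k] - eps
      fd <- (loss(up) - loss(dn)) / (2 * eps)
      expect_equal(g[[field]][k], fd, tolerance = 1e-6)
    }
  }
})

test_that("training loss is non-increasing in the small-rate limit", {
  set.seed(3)
  X <- matrix(runif(20 * 6), 20, 6)
  targets <- matrix(runif(20 * 2, 0.1, 0.9), 20, 2)
  m <- mlp_train(X, targets, 4,
                 train_spec(lr = 0.01, momentum = 0, rms_target = 1e-9,
                            max_epochs = 150, shuffle_each_epoch = FALSE,
                            seed = 3))
  expect_true(all(diff(m$log$rms) <= 1e-6))
})

test_that("XOR is learnable to the stopping RMS", {
  xor_x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  xor_t <- matrix(c(0.1, 0.9, 0.9, 0.1), 4, 1)
  ok <- 0
  for (s in 1:10) {
    m <- mlp_train(xor_x, xor_t, 2,
                   train_spec(lr = 0.7, momentum = 0.3, rms_target = 0.15,
                              max_epochs = 20000, seed = s),
                   init_range = 1)
    if (m$log$final_rms < 0.15) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("the classifier reproduces simulated canine calls on training data", {
  sw <- sim_window(13, n_case = 50, n_control = 50)
  clf <- train_classifier(sw$wn$X, sw$calls,
                          train_spec(seed = 13, max_epochs = 300))
  expect_equal(clf$log$status, "converged")
  expect_gte(mean(classify_mlp(clf, sw$wn$X) == sw$calls), 0.95)
  # seeded determinism of final weights
  clf2 <- train_classifier(sw$wn$X, sw$calls,
                           train_spec(seed = 13, max_epochs = 300))
  expect_identical(clf$W1, clf2$W1)
  expect_identical(clf$W2, clf2$W2)
})

test_that("skeletonization follows a planted dominant path exactly", {
  model <- structure(list(
    W1 = matrix(c(5, 0.1, 0.1,      # hidden 1 <- inputs (planted: in 1)
                  0.1, 0.1, 0.1),   # hidden 2
                nrow = 2, byrow = TRUE),
    b1 = c(0, 0),
    W2 = matrix(c(5, 0.1), 1, 2),   # output <- hidden (planted: hid 1)
    b2 = 0, activation = "sigmoid",
    log = list()), class = "mlp_model")
  tr <- skeletonize(model, 1, keep_per_layer = 1)
  expect_equal(tr$dominant$input[1], 1)
  expect_equal(tr$dominant$saliency[1], 25)
  expect_equal(tr$dominant$sign[1], 1)
  expect_equal(nrow(tr$retained), 2)   # one output edge + one input edge

  # no pruning: saliency equals the exhaustive all-paths computation
  set.seed(5)
  rnd <- structure(list(
    W1 = matrix(rnorm(4 * 6), 4, 6), b1 = rnorm(4),
    W2 = matrix(rnorm(2 * 4), 2, 4), b2 = rnorm(2),
    activation = "sigmoid", log = list()), class = "mlp_model")
  tr_full <- skeletonize(rnd, 2, keep_per_layer = 99)
  oracle <- vapply(1:6, function(i) {
    max(abs(rnd$W1[, i]) * abs(rnd$W2[2, ]))
  }, numeric(1))
  expect_equal(tr_full$saliency, oracle, tolerance = 1e-12)
})

test_that("skeletonization localizes a single planted discriminative peak", {
  specs <- c(list(peak_spec(10.8, 0.03, 900, "shared"),
                  peak_spec(12.4, 0.03, 1100, "shared")),
             list(peak_spec(13.18, 0.03, 900, "case_excess")))
  hits <- 0
  for (s in 1:10) {
    sw <- sim_window(200 + s, n_case = 20, n_control = 20, specs = specs)
    clf <- train_classifier(sw$wn$X, sw$calls,
                            train_spec(seed = s, max_epochs = 300))
    tr <- skeletonize(clf, "positive", keep_per_layer = 3, rt = sw$wn$rt)
    if (abs(tr$dominant$rt[1] - 13.18) <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("the auto-associator reconstructs and retrieves its exemplars", {
  sw <- sim_window(21)
  Xn <- sw$wn$X[sw$calls == "negative", ]
  aa <- train_autoassociator(Xn, train_spec(seed = 21, rms_target = 0.01,
                                            max_epochs = 5000))
  expect_lt(sqrt(mean((predict_mlp(aa, Xn) - Xn)^2)), 0.15)

  # nearest-exemplar ("database lookup") behaviour
  recon <- predict_mlp(aa, Xn)
  n <- nrow(Xn)
  hits <- 0
  for (i in seq_len(n)) {
    d2 <- colSums((t(Xn) - recon[i, ])^2)
    if (which.min(d2) == i) hits <- hits + 1
  }
  expect_gte(hits / n, 0.9)

  # seeded determinism
  aa2 <- train_autoassociator(Xn, train_spec(seed = 21, rms_target = 0.01,
                                             max_epochs = 5000))
  expect_identical(aa$W1, aa2$W1)
})

test_that("difference spectra expose planted excesses and depletions", {
  sw <- sim_window(33)
  Xn <- sw$wn$X[sw$calls == "negative", ]
  aa <- train_autoassociator(Xn, train_spec(seed = 33, rms_target = 0.01,
                                            max_epochs = 5000))
  # a canine-negative training sample carries no anomalous regions
  ds_null <- difference_spectrum(aa, Xn[1, ], sw$wn$rt)
  expect_equal(nrow(ds_null$excesses) + nrow(ds_null$depletions), 0)

  # a positive sample shows both planted excesses and the depletions
  xpos <- sw$wn$X[which(sw$calls == "positive")[1], ]
  ds <- difference_spectrum(aa, xpos, sw$wn$rt)
  expect_true(any(abs(ds$excesses$apex_rt - 13.177) <= 0.05))
  expect_true(any(abs(ds$excesses$apex_rt - 13.563) <= 0.05))
  expect_true(any(abs(ds$depletions$apex_rt - 12.698) <= 0.05))
})

test_that("both extraction methods localize the planted signals across seeds", {
  hits_sk <- 0
  hits_ex1 <- 0
  hits_ex2 <- 0
  hits_dep <- 0
  n_seed <- 10
  for (s in seq_len(n_seed)) {
    sw <- sim_window(300 + s)
    clf <- train_classifier(sw$wn$X, sw$calls,
                            train_spec(seed = s, max_epochs = 300))
    tr <- skeletonize(clf, "positive", keep_per_layer = 3, rt = sw$wn$rt)
    top <- tr$dominant$rt[seq_len(min(6, nrow(tr$dominant)))]
    if (any(abs(top - 13.177) <= 0.05) || any(abs(top - 13.563) <= 0.05)) {
      hits_sk <- hits_sk + 1
    }
    Xn <- sw$wn$X[sw$calls == "negative", ]
    aa <- train_autoassociator(Xn, train_spec(seed = s, rms_target = 0.01,
                                              max_epochs = 5000))
    xpos <- sw$wn$X[which(sw$calls == "positive")[1], ]
    ds <- difference_spectrum(aa, xpos, sw$wn$rt)
    if (any(abs(ds$excesses$apex_rt - 13.177) <= 0.05)) hits_ex1 <- hits_ex1 + 1
    if (any(abs(ds$excesses$apex_rt - 13.563) <= 0.05)) hits_ex2 <- hits_ex2 + 1
    if (any(abs(ds$depletions$apex_rt - 12.698) <= 0.05)) hits_dep <- hits_dep + 1
  }
  expect_gte(hits_sk, 8)
  expect_gte(hits_ex1, 8)
  expect_gte(hits_ex2, 8)
  expect_gte(hits_dep, 8)
})

test_that("the concordance report cross-validates the two methods", {
  sw <- sim_window(44)
  clf <- train_classifier(sw$wn$X, sw$calls,
                          train_spec(seed = 44, max_epochs = 300))
  sk <- skeletonize(clf, "positive", keep_per_layer = 3, rt = sw$wn$rt)
  Xn <- sw$wn$X[sw$calls == "negative", ]
  aa <- train_autoassociator(Xn, train_spec(seed = 44, rms_target = 0.01,
                                            max_epochs = 5000))
  pos <- which(sw$calls == "positive")[1:5]
  diffs <- lapply(pos, function(i) {
    difference_spectrum(aa, sw$wn$X[i, ], sw$wn$rt)
  })
  conc <- concordance_report(sk, diffs)
  expect_gte(sum(conc$method == "both"), 1)

  # an empty difference set leaves only skeleton regions
  conc0 <- concordance_report(sk, list())
  expect_true(all(conc0$method == "skeleton_only"))

  # null data: no region flagged by both for most seeds
  specs_null <- list(peak_spec(10.8, 0.03, 900, "shared"),
                     peak_spec(12.4, 0.03, 1100, "shared"),
                     peak_spec(13.2, 0.03, 800, "shared"))
  both_null <- 0
  for (s in 1:10) {
    swn <- sim_window(500 + s, n_case = 15, n_control = 30,
                      specs = specs_null)
    clfn <- train_classifier(swn$wn$X, swn$calls,
                             train_spec(seed = s, max_epochs = 60))
    skn <- skeletonize(clfn, "positive", keep_per_layer = 3,
                       rt = swn$wn$rt)
    Xnn <- swn$wn$X[swn$calls == "negative", ]
    aan <- train_autoassociator(Xnn,
                                train_spec(seed = s, rms_target = 0.01,
                                           max_epochs = 3000))
    xp <- swn$wn$X[which(swn$calls == "positive")[1], ]
    dn <- difference_spectrum(aan, xp, swn$wn$rt)
    cn <- concordance_report(skn, list(dn))
    if (any(cn$method == "both")) both_null <- both_null + 1
  }
  expect_lte(both_null, 2)
})
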
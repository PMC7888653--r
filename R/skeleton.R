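#' Network skeletonization: dominant input extraction
#'
#' Works backward from the chosen output node, retaining only the
#' `keep_per_layer` largest-magnitude weights into it; for each hidden
#' node so retained, the `keep_per_layer` largest-magnitude incoming
#' weights are kept in turn. The saliency of an input is the maximum,
#' over retained paths, of the product of absolute weights along the
#' path, and its sign of influence is the product of the weight signs on
#' that maximizing path. With `keep_per_layer` at or above the fan-in no
#' pruning occurs and the ranking equals the exhaustive all-paths
#' computation.
#'
#' @param model an `mlp_model`.
#' @param output_node output index or name (for classifiers,
#'   `"positive"` or `"negative"`).
#' @param keep_per_layer weights retained per node per layer (default 3).
#' @param rt optional retention-time grid mapping inputs to minutes.
#' @return a list of class `saliency_trace`: `output_node`, `retained`
#'   (data.frame of kept weights), `saliency` (per input), and
#'   `dominant` (inputs ranked by saliency, with `rt` if given and the
#'   sign of influence).
#' @export
skeletonize <- function(model, output_node = 1, keep_per_layer = 3,
                        rt = NULL) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.character(output_node)) {
    output_node <- match(output_node, model$classes)
    if (is.na(output_node)) stop("unknown output node", call. = FALSE)
  }
  w2 <- model$W2[output_node, ]
  n_hidden <- length(w2)
  n_in <- ncol(model$W1)
  k2 <- min(keep_per_layer, n_hidden)
  hid_keep <- order(abs(w2), decreasing = TRUE)[seq_len(k2)]
  retained <- data.frame(layer = integer(0), from = integer(0),
                         to = integer(0), weight = numeric(0))
  saliency <- rep(0, n_in)
  sign_in <- rep(0, n_in)
  for (h in hid_keep) {
    retained <- rbind(retained,
                      data.frame(layer = 2L, from = h,
                                 to = output_node, weight = w2[h]))
    w1 <- model$W1[h, ]
    k1 <- min(keep_per_layer, n_in)
    in_keep <- order(abs(w1), decreasing = TRUE)[seq_len(k1)]
    retained <- rbind(retained,
                      data.frame(layer = 1L, from = in_keep, to = h,
                                 weight = w1[in_keep]))
    path <- abs(w1[in_keep]) * abs(w2[h])
    better <- path > saliency[in_keep]
    saliency[in_keep][better] <- path[better]
    sign_in[in_keep][better] <- sign(w1[in_keep][better]) * sign(w2[h])
  }
  ord <- order(saliency, decreasing = TRUE)
  ord <- ord[saliency[ord] > 0]
  dominant <- data.frame(input = ord, saliency = saliency[ord],
                         sign = sign_in[ord])
  if (!is.null(rt)) dominant$rt <- rt[ord]
  structure(list(output_node = output_node, retained = retained,
                 saliency = saliency, dominant = dominant),
            class = "saliency_trace")
}

#' @export
print.saliency_trace <- function(x, ...) {
  cat(sprintf("saliency_trace: output %d, %d retained weights\n",
              x$output_node, nrow(x$retained)))
  print(utils::head(x$dominant, 5))
  invisible(x)
}

contiguous_regions <- function(flag, residual, rt, min_width = 3) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_width)
  out <- lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    apex <- i[which.max(abs(residual[i]))]
    data.frame(start_rt = rt[min(i)], end_rt = rt[max(i)],
               apex_rt = rt[apex], magnitude = residual[apex])
  })
  if (!length(out)) {
    return(data.frame(start_rt = numeric(0), end_rt = numeric(0),
                      apex_rt = numeric(0), magnitude = numeric(0)))
  }
  df <- do.call(rbind, out)
  df[order(abs(df$magnitude), decreasing = TRUE), , drop = FALSE]
}

#' Difference spectrum from the auto-associator
#'
#' Residual `r = x - model(x)` between a (normalized) spectrum and its
#' auto-associative reconstruction. Maximal contiguous regions with
#' `r > tau` are reported as elute excesses and regions with `r < -tau`
#' as depletions, each with its apex retention time and magnitude,
#' sorted by absolute magnitude. A region must span at least
#' `min_width` consecutive grid points (about two peak sigmas on the
#' default grid) — shorter threshold crossings are noise, not elutes.
#' The default threshold is per grid point: 1.25 times the training
#' set's residual envelope at that retention time. Residuals
#' concentrate at imperfectly memorized peaks, so a single global
#' multiple of a location-free scale either alarms on in-distribution
#' peak misfit or misses depletions; the local envelope sits just above
#' everything the training set can produce at each point while staying
#' far below a genuinely novel feature there.
#'
#' @param model auto-associator from [train_autoassociator()].
#' @param x one normalized spectrum (vector), normalized with the same
#'   stored min/max as the training data.
#' @param rt retention-time grid for the window.
#' @param tau anomaly threshold, scalar or per-point vector; default
#'   `1.25 * model$resid_envelope`.
#' @param min_width minimum region width in grid points (default 3).
#' @return a list of class `difference_spectrum`: `rt`, `residual`,
#'   `excesses`, `depletions`, `tau`.
#' @export
difference_spectrum <- function(model, x, rt, tau = NULL, min_width = 3) {
  x <- as.numeric(x)
  stopifnot(length(x) == length(rt))
  if (is.null(tau)) {
    if (is.null(model$resid_envelope)) {
      stop("model carries no training residual scale; supply tau",
           call. = FALSE)
    }
    tau <- 1.25 * model$resid_envelope
  }
  recon <- drop(predict_mlp(model, x))
  residual <- x - recon
  structure(list(
    rt = rt, residual = residual, tau = tau,
    excesses = contiguous_regions(residual > tau, residual, rt, min_width),
    depletions = contiguous_regions(residual < -tau, residual, rt,
                                    min_width)
  ), class = "difference_spectrum")
}

#' @export
print.difference_spectrum <- function(x, ...) {
  cat(sprintf(
    "difference_spectrum: %d excess / %d depletion region(s), mean tau %.4f\n",
    nrow(x$excesses), nrow(x$depletions), mean(x$tau)))
  invisible(x)
}

merge_rts <- function(rts, gap) {
  if (!length(rts)) return(data.frame(rt = numeric(0)))
  rts <- sort(rts)
  grp <- cumsum(c(1, diff(rts) > gap))
  data.frame(rt = as.numeric(tapply(rts, grp, mean)))
}

#' Concordance of skeletonization and auto-associative filtering
#'
#' Compares the retention-time regions flagged by the two extraction
#' methods: the top skeleton inputs (saliency within `top_frac` of the
#' maximum, merged when closer than `merge_gap` minutes) against the
#' apexes of the difference-spectrum excesses and depletions pooled over
#' samples. Regions are labelled `"both"`, `"skeleton_only"` or
#' `"difference_only"` according to whether a counterpart lies within
#' `tol` minutes.
#'
#' @param skeleton a `saliency_trace` with `rt` mapped.
#' @param diffs a list of `difference_spectrum` objects (possibly
#'   empty).
#' @param top_frac saliency fraction defining the skeleton's flagged
#'   inputs (default 0.5).
#' @param merge_gap merge distance for nearby skeleton inputs (minutes).
#' @param tol agreement tolerance (minutes, default 0.1).
#' @return data.frame of class `concordance_report` with columns `rt`,
#'   `method` (`both`/`skeleton_only`/`difference_only`).
#' @export
concordance_report <- function(skeleton, diffs, top_frac = 0.5,
                               merge_gap = 0.1, tol = 0.1) {
  stopifnot(inherits(skeleton, "saliency_trace"))
  if (is.null(skeleton$dominant$rt)) {
    stop("skeleton has no retention-time mapping", call. = FALSE)
  }
  dom <- skeleton$dominant
  sk_rt <- merge_rts(dom$rt[dom$saliency >= top_frac * max(dom$saliency)],
                     merge_gap)$rt
  di_rt <- unlist(lapply(diffs, function(d) {
    c(d$excesses$apex_rt, d$depletions$apex_rt)
  }))
  di_rt <- merge_rts(di_rt, merge_gap)$rt
  near <- function(a, b) length(b) > 0 && any(abs(b - a) <= tol)
  rows <- list()
  for (r in sk_rt) {
    rows[[length(rows) + 1]] <- data.frame(
      rt = r, method = if (near(r, di_rt)) "both" else "skeleton_only")
  }
  for (r in di_rt) {
    if (!near(r, sk_rt)) {
      rows[[length(rows) + 1]] <- data.frame(rt = r,
                                             method = "difference_only")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rt = numeric(0), method = character(0))
  out <- out[order(out$rt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("concordance_report", class(out))
  out
}
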
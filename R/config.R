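#' Pipeline configuration
#'
#' Collects the scalar settings shared across the four analysis arms in one
#' validated list. Defaults follow the published study protocol: VOCs seen in
#' fewer than 3% of samples are dropped, screening uses a liberal p < 0.2
#' cutoff ahead of model building, taxa tables are rarefied to 2,700 clean
#' sequences, reagent-contaminant correlation uses a Spearman cutoff of 0.30,
#' and the chromatogram classifier reads 205 abundance points from the
#' 10-14 min retention-time window into 32 sigmoid hidden units.
#'
#' @param prevalence_min minimum fraction of samples in which a VOC must be
#'   observed (nonzero) to survive filtering.
#' @param screen_alpha p-value cutoff for the screening stage feeding the
#'   penalized model.
#' @param da_alpha p-value cutoff used for display/reporting of significant
#'   features.
#' @param cv_folds folds for cross-validated tuning of the penalized model.
#' @param rarefaction_depth reads per sample after rarefaction.
#' @param spearman_cutoff correlation threshold (strict `>`) for
#'   indicator-based contaminant flagging.
#' @param rt_window two-element numeric, retention-time window in minutes
#'   presented to the neural network.
#' @param n_input number of input nodes (grid points inside `rt_window`).
#' @param n_hidden hidden-layer width.
#' @param lr backpropagation learning rate.
#' @param momentum backpropagation momentum term.
#' @param rms_target stopping root-mean-square error for training.
#' @param scale_margin target encoding margin (targets are `scale_margin`
#'   and `1 - scale_margin` rather than 0/1, avoiding sigmoid saturation).
#' @param seed integer seed recorded with the configuration.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(prevalence_min = 0.03,
                            screen_alpha = 0.2,
                            da_alpha = 0.05,
                            cv_folds = 10,
                            rarefaction_depth = 2700,
                            spearman_cutoff = 0.30,
                            rt_window = c(10, 14),
                            n_input = 205,
                            n_hidden = 32,
                            lr = 0.1,
                            momentum = 0.03,
                            rms_target = 0.15,
                            scale_margin = 0.1,
                            seed = 1L) {
  stopifnot(
    prevalence_min > 0, prevalence_min < 1,
    screen_alpha > 0, screen_alpha <= 1,
    da_alpha > 0, da_alpha <= 1,
    cv_folds >= 2,
    rarefaction_depth >= 1,
    length(rt_window) == 2, rt_window[1] < rt_window[2],
    n_input > 0, n_hidden > 0,
    lr > 0, momentum >= 0,
    rms_target > 0,
    scale_margin >= 0, scale_margin < 0.5
  )
  structure(list(
    prevalence_min = prevalence_min, screen_alpha = screen_alpha,
    da_alpha = da_alpha, cv_folds = as.integer(cv_folds),
    rarefaction_depth = as.integer(rarefaction_depth),
    spearman_cutoff = spearman_cutoff, rt_window = as.numeric(rt_window),
    n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
    lr = lr, momentum = momentum, rms_target = rms_target,
    scale_margin = scale_margin, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
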
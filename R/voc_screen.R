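#' Prevalence filter for VOC tables
#'
#' Removes compounds observed (nonzero) in fewer than
#' `ceil(min_prevalence * n_samples)` samples; the sample set is
#' unchanged. With the default 3% threshold a compound seen in 1 of 36
#' samples (2.8%) is removed.
#'
#' @param table a [voc_table()].
#' @param min_prevalence minimum fraction of samples with nonzero
#'   abundance, in (0, 1).
#' @return the filtered [voc_table()].
#' @export
prevalence_filter <- function(table, min_prevalence = 0.03) {
  stopifnot(inherits(table, "voc_table"),
            min_prevalence > 0, min_prevalence < 1)
  if (ncol(table$abundance) == 0 || nrow(table$abundance) == 0) {
    stop("empty VOC table", call. = FALSE)
  }
  n <- nrow(table$abundance)
  need <- ceiling(min_prevalence * n)
  keep <- colSums(table$abundance > 0) >= need
  voc_table(table$abundance[, keep, drop = FALSE], as.character(table$labels))
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test with mid-ranks for ties: exact enumeration for small
#' tie-free samples (combined n <= `exact_max`), otherwise the normal
#' approximation with tie and continuity corrections. Chosen over
#' parametric tests because zero-inflated abundance data violate
#' normality; completely tied data (all values identical) degenerate to
#' p = 1.
#'
#' @param x,y numeric value vectors for the two groups.
#' @param exact_max largest combined sample size for exact enumeration.
#' @return list with `statistic` (the Mann-Whitney U for group `x`) and
#'   `p_value`.
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  vals <- c(x, y)
  if (length(unique(vals)) == 1) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  ties <- any(duplicated(vals))
  use_exact <- !ties && (length(vals) <= exact_max)
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  p <- ht$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(ht$statistic), p_value = min(p, 1))
}

#' Screen compounds by rank-sum test
#'
#' Per-compound two-sided rank-sum p-values comparing cancer vs control,
#' with kept flags at the (liberal) modelling cutoff `alpha` and at the
#' display cutoff `da_alpha`. No multiplicity adjustment is applied by
#' default (`adjust = "none"`); set `adjust = "BH"` for
#' Benjamini-Hochberg adjusted flags.
#'
#' @param table a [voc_table()] (already prevalence-filtered).
#' @param alpha screening p-value cutoff feeding the model (default 0.2).
#' @param da_alpha display cutoff (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `screen_result`: `compound`, `prevalence`,
#'   `p_value`, `kept_alpha`, `kept_display`.
#' @export
screen_vocs <- function(table, alpha = 0.2, da_alpha = 0.05,
                        adjust = c("none", "BH")) {
  stopifnot(inherits(table, "voc_table"))
  adjust <- match.arg(adjust)
  grp <- table$labels
  if (min(table(grp)) < 2) {
    stop("need at least 2 samples per class to screen", call. = FALSE)
  }
  ab <- table$abundance
  p <- apply(ab, 2, function(v) {
    rank_sum_test(v[grp == "cancer"], v[grp == "control"])$p_value
  })
  padj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  res <- data.frame(
    compound = colnames(ab),
    prevalence = colMeans(ab > 0),
    p_value = unname(p),
    kept_alpha = unname(padj <= alpha),
    kept_display = unname(padj <= da_alpha),
    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("screen_result", class(res))
  res
}
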
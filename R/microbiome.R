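relative_abundance <- function(counts) {
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  sweep(counts, 2, tot, "/")
}

#' Phase 1: negative-control abundance filter
#'
#' Flags species whose mean relative abundance across the negative
#' extraction controls is at least `ratio_threshold` times their mean
#' relative abundance across true samples, and which appear in at least
#' `min_control_prevalence` controls. Species absent from every control
#' are never flagged.
#'
#' @param table a [taxa_table()].
#' @param ratio_threshold control-to-true mean relative-abundance ratio
#'   (default 1: at least as abundant in controls as in samples).
#' @param min_control_prevalence minimum number of controls with a
#'   nonzero count (default 2).
#' @return character vector of flagged species.
#' @export
phase1_negative_control_filter <- function(table, ratio_threshold = 1,
                                           min_control_prevalence = 2) {
  stopifnot(inherits(table, "taxa_table"))
  neg <- table$is_negative_control
  if (!any(neg)) {
    warning("no negative controls present; phase 1 skipped")
    return(character(0))
  }
  rel <- relative_abundance(table$counts)
  mean_neg <- rowMeans(rel[, neg, drop = FALSE])
  mean_true <- rowMeans(rel[, !neg, drop = FALSE])
  prev_neg <- rowSums(table$counts[, neg, drop = FALSE] > 0)
  flagged <- mean_neg > 0 &
    mean_neg >= ratio_threshold * mean_true &
    prev_neg >= min_control_prevalence
  rownames(table$counts)[flagged]
}

#' Phase 2: indicator-species Spearman correlation filter
#'
#' Flags any non-indicator species whose Spearman correlation (mid-rank,
#' computed on relative abundances across the true samples only) with at
#' least one indicator contaminant species strictly exceeds `cutoff`.
#' Constant species have undefined correlation and are never flagged.
#'
#' @param table a [taxa_table()].
#' @param indicators character vector of indicator species (must be
#'   present in the table).
#' @param cutoff correlation threshold, strict `>` (default 0.30).
#' @return character vector of flagged species.
#' @export
phase2_indicator_correlation <- function(table, indicators, cutoff = 0.30) {
  stopifnot(inherits(table, "taxa_table"))
  missing <- setdiff(indicators, rownames(table$counts))
  if (length(missing)) {
    stop("indicator species not in table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rel <- relative_abundance(table$counts)[, !table$is_negative_control,
                                          drop = FALSE]
  others <- setdiff(rownames(rel), indicators)
  if (!length(others)) return(character(0))
  rho <- suppressWarnings(
    stats::cor(t(rel[others, , drop = FALSE]),
               t(rel[indicators, , drop = FALSE]),
               method = "spearman"))
  max_rho <- apply(rho, 1, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) -Inf else max(r)
  })
  others[max_rho > cutoff]
}

#' Phase 3: contaminant genus blacklist filter
#'
#' Flags every species whose genus token (the first whitespace-separated
#' word of the species name) is on the blacklist of common reagent
#' contaminant genera.
#'
#' @param table a [taxa_table()].
#' @param genera character vector of blacklisted genera; defaults to
#'   [default_contaminant_genera()].
#' @return character vector of flagged species.
#' @export
phase3_genus_blacklist <- function(table,
                                   genera = default_contaminant_genera()) {
  stopifnot(inherits(table, "taxa_table"))
  sp <- rownames(table$counts)
  genus <- vapply(strsplit(sp, "\\s+"), `[`, "", 1)
  sp[genus %in% genera]
}

#' Three-phase contaminant removal
#'
#' Runs the negative-control abundance filter, the indicator-correlation
#' filter and the genus blacklist, removes the union of flagged species
#' (plus the indicator set itself, which is contaminant by definition),
#' and records per-species evidence for audit.
#'
#' @param table a [taxa_table()].
#' @param indicators indicator contaminant species for phase 2.
#' @param genera genus blacklist for phase 3.
#' @param ratio_threshold,min_control_prevalence phase 1 parameters.
#' @param cutoff phase 2 Spearman threshold.
#' @param drop_indicators also remove the indicator species themselves
#'   (default `TRUE`).
#' @return list with `table` (cleaned [taxa_table()]) and `report`
#'   (class `contaminant_report`: the three phase sets, the removed
#'   union, and an evidence data.frame).
#' @export
remove_contaminants <- function(table, indicators,
                                genera = default_contaminant_genera(),
                                ratio_threshold = 1,
                                min_control_prevalence = 2,
                                cutoff = 0.30, drop_indicators = TRUE) {
  p1 <- phase1_negative_control_filter(table, ratio_threshold,
                                       min_control_prevalence)
  p2 <- phase2_indicator_correlation(table, indicators, cutoff)
  p3 <- phase3_genus_blacklist(table, genera)
  removed <- union(union(p1, p2), p3)
  if (drop_indicators) removed <- union(removed, indicators)

  rel <- relative_abundance(table$counts)
  neg <- table$is_negative_control
  mean_neg <- rowMeans(rel[, neg, drop = FALSE])
  mean_true <- rowMeans(rel[, !neg, drop = FALSE])
  genus <- vapply(strsplit(rownames(rel), "\\s+"), `[`, "", 1)
  rho_max <- rep(NA_real_, nrow(rel))
  names(rho_max) <- rownames(rel)
  others <- setdiff(rownames(rel), indicators)
  if (length(others) && length(indicators)) {
    rho <- suppressWarnings(
      stats::cor(t(rel[others, !neg, drop = FALSE]),
                 t(rel[indicators, !neg, drop = FALSE]),
                 method = "spearman"))
    rho_max[others] <- apply(rho, 1, function(r) {
      r <- r[is.finite(r)]
      if (!length(r)) NA_real_ else max(r)
    })
  }
  evidence <- data.frame(
    species = rownames(rel),
    control_abundance_ratio = ifelse(mean_true > 0, mean_neg / mean_true,
                                     ifelse(mean_neg > 0, Inf, 0)),
    max_spearman_indicator = unname(rho_max),
    blacklist_genus = genus %in% genera,
    is_indicator = rownames(rel) %in% indicators,
    removed = rownames(rel) %in% removed,
    row.names = NULL, stringsAsFactors = FALSE)

  keep <- setdiff(rownames(table$counts), removed)
  cleaned <- taxa_table(table$counts[keep, , drop = FALSE],
                        table$is_negative_control, table$labels)
  report <- structure(list(phase1_flagged = p1, phase2_flagged = p2,
                           phase3_flagged = p3, removed = removed,
                           evidence = evidence),
                      class = "contaminant_report")
  list(table = cleaned, report = report)
}

#' @export
print.contaminant_report <- function(x, ...) {
  cat(sprintf(
    "contaminant_report: %d removed (phase1 %d, phase2 %d, phase3 %d)\n",
    length(x$removed), length(x$phase1_flagged),
    length(x$phase2_flagged), length(x$phase3_flagged)))
  invisible(x)
}

#' Rarefy a taxa table to even depth
#'
#' Draws exactly `depth` reads per sample without replacement; samples
#' with fewer than `depth` total reads are dropped and reported, never
#' resampled with replacement.
#'
#' @param table a [taxa_table()].
#' @param depth target reads per sample (default 2700).
#' @param seed RNG seed.
#' @return list with `table` (rarefied [taxa_table()]) and `dropped`
#'   (character vector of removed sample ids).
#' @export
rarefy_table <- function(table, depth = 2700, seed = 1L) {
  stopifnot(inherits(table, "taxa_table"), depth >= 1)
  tot <- colSums(table$counts)
  keep <- tot >= depth
  if (!any(keep)) stop("all samples below rarefaction depth", call. = FALSE)
  set.seed(seed)
  # depth and integrality are validated above; rrarefy's own advisory
  # warnings would only repeat that
  sub <- t(suppressWarnings(
    vegan::rrarefy(t(table$counts[, keep, drop = FALSE]), depth)))
  storage.mode(sub) <- "integer"
  list(table = taxa_table(sub, table$is_negative_control[keep],
                          table$labels[keep]),
       dropped = colnames(table$counts)[!keep])
}

as_sample_matrix <- function(x) {
  if (inherits(x, "taxa_table")) t(x$counts) else as.matrix(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = 1 - 2 * sum(min(x_i, x_j)) / (sum(x_i) + sum(x_j))` between
#' sample pairs. Pairs of all-zero samples are undefined and set to 0
#' with a warning.
#'
#' @param x a [taxa_table()] or a samples-x-species matrix.
#' @return symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  m <- as_sample_matrix(x)
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (any(!is.finite(d))) {
    warning("all-zero sample pair(s); distance set to 0")
    d[!is.finite(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Unweighted UniFrac distance matrix
#'
#' Fraction of tree branch length unique to either sample's set of
#' observed species (presence/absence basis), over the branch length
#' spanned by their union. Every species in the table must be a tree
#' tip; an unrooted tree is midpoint-rooted with a warning.
#'
#' @param table a [taxa_table()] or samples-x-species matrix.
#' @param tree an `ape::phylo` tree (or path to a newick file).
#' @return symmetric distance matrix.
#' @export
unweighted_unifrac <- function(table, tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  m <- as_sample_matrix(table)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing)) {
    stop("species missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    warning("unrooted tree; rooting at midpoint")
    tree <- phangorn::midpoint(tree)
  }
  if (length(tree$tip.label) > ncol(m)) {
    tree <- ape::keep.tip(tree, colnames(m))
  }
  d <- as.matrix(picante::unifrac(m, tree))
  diag(d) <- 0
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Negative eigenvalues are reported and their
#' axes omitted.
#'
#' @param d symmetric distance matrix.
#' @return list with `coordinates` (samples x positive axes),
#'   `eigenvalues` (all), and `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  if (all(d == 0)) {
    return(list(coordinates = matrix(0, nrow(d), 1,
                                     dimnames = list(rownames(d), "Axis.1")),
                eigenvalues = rep(0, nrow(d)),
                negative_eigenvalues = numeric(0)))
  }
  p <- ape::pcoa(stats::as.dist(d))
  ev <- p$values$Eigenvalues
  list(coordinates = p$vectors,
       eigenvalues = ev,
       negative_eigenvalues = ev[ev < 0])
}

#' Mann-Whitney differential abundance
#'
#' Per-species two-sided rank-sum test on relative abundances across the
#' true samples, cancer vs control. Mean percent abundance is reported
#' over the samples positive for the species in each group (0 when no
#' sample is positive), together with per-group prevalence. Species
#' absent everywhere are skipped.
#'
#' @param table a [taxa_table()] (typically contaminant-removed and
#'   rarefied).
#' @return data.frame with columns `species`, `U`, `p_value`,
#'   `mean_percent_cancer`, `mean_percent_control`, `prevalence_cancer`,
#'   `prevalence_control`.
#' @export
differential_abundance <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  true_idx <- !table$is_negative_control
  rel <- relative_abundance(table$counts)[, true_idx, drop = FALSE] * 100
  lab <- table$labels[true_idx]
  if (min(table(lab)) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  rows <- lapply(rownames(rel), function(sp) {
    v <- rel[sp, ]
    if (all(v == 0)) return(NULL)
    ca <- v[lab == "cancer"]
    co <- v[lab == "control"]
    ht <- rank_sum_test(ca, co)
    data.frame(
      species = sp, U = ht$statistic, p_value = ht$p_value,
      mean_percent_cancer = if (any(ca > 0)) mean(ca[ca > 0]) else 0,
      mean_percent_control = if (any(co > 0)) mean(co[co > 0]) else 0,
      prevalence_cancer = mean(ca > 0),
      prevalence_control = mean(co > 0),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-profile clustering separation
#'
#' Hierarchical clustering view of the full (cleaned, rarefied) profile:
#' Euclidean distance on log-transformed relative abundances of the
#' `top_n` most abundant species, with the mean silhouette width of the
#' cancer/control labels on that distance as a separation score (near 0
#' means the whole-profile structure does not separate the groups).
#'
#' @param table a [taxa_table()].
#' @param top_n number of most-abundant species used (default 25).
#' @param pseudocount added before the log transform.
#' @return list with `silhouette` (mean label silhouette width),
#'   `hclust` (the dendrogram) and `dist`.
#' @export
cluster_separation <- function(table, top_n = 25, pseudocount = 1e-6) {
  stopifnot(inherits(table, "taxa_table"))
  true_idx <- !table$is_negative_control
  rel <- relative_abundance(table$counts)[, true_idx, drop = FALSE]
  lab <- table$labels[true_idx]
  top <- order(rowMeans(rel), decreasing = TRUE)[seq_len(min(top_n, nrow(rel)))]
  lg <- log(rel[top, , drop = FALSE] + pseudocount)
  d <- stats::dist(t(lg))
  hc <- stats::hclust(d, method = "average")
  sil <- cluster::silhouette(as.integer(factor(lab)), d)
  list(silhouette = mean(sil[, "sil_width"]), hclust = hc, dist = d)
}
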
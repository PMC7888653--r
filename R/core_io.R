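#' Chromatogram set container
#'
#' A set of total-ion chromatograms on one shared retention-time grid,
#' together with the sample manifest (sample id and cohort per trace).
#'
#' @param rt numeric vector of retention times in minutes, strictly
#'   increasing.
#' @param intensity numeric matrix, samples in rows, one column per grid
#'   point; all abundances must be non-negative.
#' @param samples data.frame with columns `sample_id` (unique) and `cohort`
#'   (`"cancer"` or `"control"`), one row per row of `intensity`.
#' @return an object of class `chromatogram_set`.
#' @export
chromatogram_set <- function(rt, intensity, samples) {
  intensity <- as.matrix(intensity)
  if (is.null(dim(intensity))) intensity <- matrix(intensity, nrow = 1)
  if (any(diff(rt) <= 0)) {
    stop("retention times must be strictly increasing", call. = FALSE)
  }
  if (ncol(intensity) != length(rt)) {
    stop("intensity must have one column per retention time", call. = FALSE)
  }
  if (any(intensity < 0)) stop("abundances must be non-negative", call. = FALSE)
  samples <- validate_samples(samples, nrow(intensity))
  rownames(intensity) <- samples$sample_id
  structure(list(rt = as.numeric(rt), intensity = intensity,
                 samples = samples),
            class = "chromatogram_set")
}

validate_samples <- function(samples, n) {
  samples <- as.data.frame(samples)
  if (!all(c("sample_id", "cohort") %in% names(samples))) {
    stop("manifest needs columns sample_id and cohort", call. = FALSE)
  }
  if (nrow(samples) != n) {
    stop("manifest rows must match number of samples", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  bad <- !samples$cohort %in% c("cancer", "control")
  if (any(bad)) {
    stop("cohort must be 'cancer' or 'control' (offending: ",
         paste(unique(samples$cohort[bad]), collapse = ", "), ")",
         call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$cohort <- as.character(samples$cohort)
  samples
}

#' @export
print.chromatogram_set <- function(x, ...) {
  cat(sprintf("chromatogram_set: %d samples x %d points, rt %.3f-%.3f min\n",
              nrow(x$intensity), length(x$rt), min(x$rt), max(x$rt)))
  print(table(x$samples$cohort))
  invisible(x)
}

#' Read chromatograms from a wide CSV
#'
#' The on-disk format is a wide CSV whose first column is `retention_time`
#' (minutes) and whose remaining columns hold one abundance trace per
#' sample. The manifest maps CSV columns to sample ids and cohorts.
#'
#' @param path path to the chromatogram CSV.
#' @param manifest data.frame (or path to a CSV) with columns `sample_id`
#'   and `cohort`; an optional `column` gives the CSV column name when it
#'   differs from `sample_id`.
#' @return a [chromatogram_set()].
#' @export
read_chromatograms <- function(path, manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  manifest <- as.data.frame(manifest)
  if (is.null(manifest$column)) manifest$column <- manifest$sample_id
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"retention_time" %in% names(df)) {
    stop("chromatogram CSV must have a 'retention_time' column", call. = FALSE)
  }
  rt <- df$retention_time
  if (any(diff(rt) <= 0)) {
    stop("non-monotone retention times in ", path, call. = FALSE)
  }
  missing <- setdiff(manifest$column, names(df))
  if (length(missing)) {
    stop("sample column(s) absent from ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  intensity <- t(as.matrix(df[, manifest$column, drop = FALSE]))
  chromatogram_set(rt, intensity,
                   manifest[, c("sample_id", "cohort"), drop = FALSE])
}

#' Write chromatograms to a wide CSV
#'
#' @param x a [chromatogram_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromatograms <- function(x, path) {
  stopifnot(inherits(x, "chromatogram_set"))
  df <- data.frame(retention_time = x$rt, check.names = FALSE)
  for (i in seq_len(nrow(x$intensity))) {
    df[[x$samples$sample_id[i]]] <- x$intensity[i, ]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' VOC abundance table container
#'
#' Samples-by-compound abundance matrix keyed by CAS registry number, with
#' a case/control label per sample. Zero abundances are treated as true
#' zeros (compound not observed), not missing values.
#'
#' @param abundance non-negative numeric matrix, samples in rows (rownames
#'   are sample ids), compounds in columns (colnames are CAS numbers).
#' @param labels character/factor of `"cancer"`/`"control"`, one per sample.
#' @return an object of class `voc_table`.
#' @export
voc_table <- function(abundance, labels) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundances must be non-negative", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(abundance)) {
    stop("one label per sample required", call. = FALSE)
  }
  if (!all(labels %in% c("cancer", "control"))) {
    stop("labels must be 'cancer' or 'control'", call. = FALSE)
  }
  if (is.null(rownames(abundance))) {
    rownames(abundance) <- sprintf("S%03d", seq_len(nrow(abundance)))
  }
  if (is.null(colnames(abundance))) {
    colnames(abundance) <- sprintf("VOC%04d", seq_len(ncol(abundance)))
  }
  structure(list(abundance = abundance,
                 labels = factor(labels, levels = c("cancer", "control"))),
            class = "voc_table")
}

#' @export
print.voc_table <- function(x, ...) {
  cat(sprintf("voc_table: %d samples x %d compounds (%d cancer / %d control)\n",
              nrow(x$abundance), ncol(x$abundance),
              sum(x$labels == "cancer"), sum(x$labels == "control")))
  invisible(x)
}

#' Read a VOC table from CSV
#'
#' @param path CSV with a `sample_id` first column and one column per
#'   compound (CAS registry numbers as column names).
#' @param manifest data.frame or CSV path with `sample_id` and `cohort`.
#' @return a [voc_table()].
#' @export
read_voc_table <- function(path, manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("VOC CSV must have a 'sample_id' column", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  idx <- match(df$sample_id, manifest$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from manifest: ",
         paste(df$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  voc_table(m, manifest$cohort[idx])
}

#' Write a VOC table to CSV
#' @param x a [voc_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_voc_table <- function(x, path) {
  stopifnot(inherits(x, "voc_table"))
  df <- data.frame(sample_id = rownames(x$abundance), check.names = FALSE)
  df <- cbind(df, as.data.frame(x$abundance, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Taxa count table container
#'
#' Species-by-sample integer count matrix with negative extraction controls
#' flagged and a case/control label per true (non-control) sample.
#'
#' @param counts non-negative integer matrix, species in rows (rownames
#'   `"Genus species"`), samples in columns.
#' @param is_negative_control logical per sample column.
#' @param labels `"cancer"`/`"control"` per sample; entries for negative
#'   controls are ignored (may be `NA`).
#' @return an object of class `taxa_table`.
#' @export
taxa_table <- function(counts, is_negative_control, labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || any(!nzchar(trimws(rownames(counts))))) {
    stop("every species needs a non-empty name", call. = FALSE)
  }
  if (length(is_negative_control) != ncol(counts)) {
    stop("one negative-control flag per sample required", call. = FALSE)
  }
  if (is.null(labels)) labels <- rep(NA_character_, ncol(counts))
  labels <- as.character(labels)
  ok <- is_negative_control | labels %in% c("cancer", "control")
  if (!all(ok)) {
    stop("every true sample needs a 'cancer' or 'control' label", call. = FALSE)
  }
  labels[is_negative_control] <- NA_character_
  structure(list(counts = counts,
                 is_negative_control = as.logical(is_negative_control),
                 labels = labels),
            class = "taxa_table")
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf("taxa_table: %d species x %d samples (%d negative controls)\n",
              nrow(x$counts), ncol(x$counts), sum(x$is_negative_control)))
  invisible(x)
}

#' Read a species-level taxa table from TSV
#'
#' Rows are species (first column `species`, `"Genus species"` strings),
#' remaining columns are samples. Columns whose name starts with
#' `neg_prefix` are flagged as negative extraction controls unless an
#' explicit `negative_controls` vector is given.
#'
#' @param path TSV path.
#' @param neg_prefix column-name prefix flagging negative controls
#'   (default `"NEG_"`).
#' @param negative_controls optional character vector of control column
#'   names, overriding the prefix rule.
#' @param labels optional named character vector (`sample -> cohort`) for
#'   the true samples.
#' @return a [taxa_table()].
#' @export
read_taxa_table <- function(path, neg_prefix = "NEG_",
                            negative_controls = NULL, labels = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"species" %in% names(df)) {
    stop("taxa TSV must have a 'species' first column", call. = FALSE)
  }
  sp <- as.character(df$species)
  if (any(is.na(sp) | !nzchar(trimws(sp)))) {
    stop("empty species name in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "species"), drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(m != round(m)) || any(m < 0)) {
    stop("taxa counts must be non-negative integers", call. = FALSE)
  }
  rownames(m) <- sp
  if (is.null(negative_controls)) {
    neg <- startsWith(colnames(m), neg_prefix)
  } else {
    neg <- colnames(m) %in% negative_controls
  }
  lab <- rep(NA_character_, ncol(m))
  if (!is.null(labels)) lab[match(names(labels), colnames(m))] <- labels
  if (is.null(labels)) lab[!neg] <- "control"
  taxa_table(m, neg, lab)
}

#' Write a taxa table to TSV
#' @param x a [taxa_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(x, path) {
  stopifnot(inherits(x, "taxa_table"))
  df <- data.frame(species = rownames(x$counts), check.names = FALSE)
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
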
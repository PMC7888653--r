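#' Carousel trial records
#'
#' In a carousel scent-detection trial a dog inspects four pots per set
#' (one cancer sample, three biopsy-negative controls) over one or more
#' passes ("runs"). A run ends when the dog indicates the target (`"T"`),
#' indicates a control (`"X"`, a false call: the control is replaced by a
#' blank and the dog searches again), or completes the line with no
#' indication (`"-"`, the set is re-run). A second false call ends the set.
#'
#' @param dog dog name.
#' @param sets list of [set_record()]s.
#' @param overrides optional named list; `false_positives` and/or
#'   `controls_presented` replace the tallies derived from the run codes,
#'   for records whose per-run table and recorded counts disagree.
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(dog, sets, overrides = NULL) {
  stopifnot(is.character(dog), length(sets) >= 1)
  sets <- lapply(sets, function(s) {
    if (!inherits(s, "set_record")) do.call(set_record, s) else s
  })
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), c("false_positives", "controls_presented"))
    if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  structure(list(dog = dog, sets = sets, overrides = overrides),
            class = "trial_record")
}

#' One sample set of a carousel trial
#'
#' @param target_position position (1-4) of the cancer sample.
#' @param runs character vector of run outcomes, in order: `"T"` (target
#'   indicated), `"X"` (control falsely indicated), `"-"` (no indication).
#' @param reward_scheme `"positive_bias"` or `"balanced"`.
#' @return an object of class `set_record`.
#' @export
set_record <- function(target_position, runs,
                       reward_scheme = c("balanced", "positive_bias")) {
  reward_scheme <- match.arg(reward_scheme)
  target_position <- as.integer(target_position)
  stopifnot(target_position >= 1, target_position <= 4, length(runs) >= 1)
  runs <- as.character(runs)
  if (!all(runs %in% c("T", "X", "-"))) {
    stop("run outcomes must be 'T', 'X' or '-'", call. = FALSE)
  }
  hits <- which(runs == "T")
  if (length(hits) > 1) {
    stop("at most one target indication per set", call. = FALSE)
  }
  if (length(hits) == 1 && hits != length(runs)) {
    stop("runs recorded after a target indication ended the set", call. = FALSE)
  }
  second_x <- which(cumsum(runs == "X") == 2)[1]
  if (!is.na(second_x) && second_x != length(runs)) {
    stop("runs recorded after a second false call ended the set", call. = FALSE)
  }
  structure(list(target_position = target_position, runs = runs,
                 reward_scheme = reward_scheme),
            class = "set_record")
}

#' Score a dog's trial record
#'
#' Tallies set-level outcomes: a set counts as a true positive when its
#' final pass indicated the target, and as a false negative otherwise;
#' every control indication (`"X"`) counts one distinct false positive.
#' Unless overridden, each set presents 3 controls. Sensitivity and
#' specificity are reported as percentages rounded to one decimal.
#'
#' @param record a [trial_record()].
#' @param controls_per_set controls presented per set (default 3).
#' @return a list of class `performance_summary` with counts and the two
#'   percentages.
#' @export
score_dog <- function(record, controls_per_set = 3) {
  stopifnot(inherits(record, "trial_record"))
  finals <- vapply(record$sets, function(s) s$runs[length(s$runs)], "")
  tp <- sum(finals == "T")
  fn <- length(record$sets) - tp
  fp <- sum(vapply(record$sets, function(s) sum(s$runs == "X"), 0L))
  controls <- controls_per_set * length(record$sets)
  ov <- record$overrides
  if (!is.null(ov$false_positives)) fp <- as.integer(ov$false_positives)
  if (!is.null(ov$controls_presented)) controls <- as.integer(ov$controls_presented)
  structure(list(
    dog = record$dog,
    true_positives = tp, false_negatives = fn,
    false_positives = fp, controls_presented = controls,
    sensitivity = round(100 * tp / (tp + fn), 1),
    specificity = round(100 * (1 - fp / controls), 1)
  ), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf(
    "%s: TP=%d FN=%d FP=%d/%d controls | sensitivity %.1f%% specificity %.1f%%\n",
    x$dog, x$true_positives, x$false_negatives, x$false_positives,
    x$controls_presented, x$sensitivity, x$specificity))
  invisible(x)
}

#' Chance probability of consecutive correct picks
#'
#' Probability of picking the one target out of `n_pots` pots `k_sets`
#' times in a row under random choice: `(1/n_pots)^k_sets`.
#'
#' @param k_sets number of consecutive sets.
#' @param n_pots pots per set.
#' @return a probability.
#' @export
chance_prob_consecutive <- function(k_sets, n_pots) {
  stopifnot(k_sets >= 0, n_pots >= 2)
  (1 / n_pots)^k_sets
}

#' Binomial tail probability of few misses
#'
#' Probability of at most `max_misses` failures in `n_sets` independent
#' trials each succeeding with probability `p_success`; the chance-level
#' null for a detection trial treats each set as a random yes/no decision
#' (`p_success = 0.5`).
#'
#' @param n_sets number of sets.
#' @param p_success per-set success probability under the null.
#' @param max_misses maximum number of missed sets included in the tail.
#' @return a probability.
#' @export
binomial_tail_misses <- function(n_sets, p_success, max_misses) {
  stopifnot(p_success >= 0, p_success <= 1,
            max_misses >= 0, max_misses <= n_sets)
  stats::pbinom(max_misses, size = n_sets, prob = 1 - p_success)
}

#' Read trial records from JSON
#'
#' The schema is `{"records": [{"dog": ..., "sets": [{"target_position":
#' ..., "reward_scheme": ..., "runs": ["-","X","T"]}], "overrides":
#' {...}}]}`; a single record object (no `records` wrapper) is also
#' accepted.
#'
#' @param path JSON path.
#' @return a list of [trial_record()]s.
#' @export
read_trial_records <- function(path) {
  if (!file.exists(path)) stop("trial record file not found: ", path,
                               call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- if (!is.null(j$records)) j$records else list(j)
  lapply(recs, function(r) {
    sets <- lapply(r$sets, function(s) {
      set_record(s$target_position, unlist(s$runs),
                 if (is.null(s$reward_scheme)) "balanced" else s$reward_scheme)
    })
    trial_record(r$dog, sets, overrides = r$overrides)
  })
}

#' Write trial records to JSON
#' @param records list of [trial_record()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_records <- function(records, path) {
  recs <- lapply(records, function(r) {
    out <- list(dog = r$dog, sets = lapply(r$sets, function(s) {
      list(target_position = s$target_position,
           reward_scheme = s$reward_scheme, runs = as.list(s$runs))
    }))
    if (!is.null(r$overrides)) out$overrides <- r$overrides
    out
  })
  jsonlite::write_json(list(records = recs), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Double-blind pilot trial records
#'
#' The per-run outcomes of the two dogs in the double-blind pilot trial
#' (7 sets of one Gleason 9 cancer sample among three biopsy-negative
#' controls each). The first dog's record tallies directly from its run
#' codes; the second dog's record carries the recorded-count overrides
#' (6 false positives over 20 presented controls) used for its published
#' performance summary.
#'
#' @return a named list with elements `florin` and `midas`.
#' @export
pilot_trial_records <- function() {
  path <- system.file("extdata", "pilot_trial.json", package = "uroscent")
  recs <- read_trial_records(path)
  names(recs) <- vapply(recs, function(r) tolower(r$dog), "")
  recs
}
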
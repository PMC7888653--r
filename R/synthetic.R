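#' Simulation design
#'
#' Study-design parameters for the synthetic-data generators. Defaults
#' emulate the pilot study's conditions: 12 cancer vs 38 biopsy-negative
#' control samples with six blank extraction negative controls; a
#' chromatographic run spanning 0-31 min sampled every 4/205 min (so the
#' 10-14 min window holds exactly 205 points); zero-inflated log-normal
#' VOC abundances with a handful of case/control-differential compounds;
#' negative-binomial taxa counts mixed with a reagent-contaminant
#' component tracked by 10 indicator species; and dogs whose
#' per-presentation accuracy matches the pilot dogs' observed 71.4%
#' sensitivity / 76.2% specificity.
#'
#' @param n_case,n_control numbers of cancer and control samples.
#' @param n_neg_control number of blank extraction negative controls.
#' @param rt_span two-element numeric, run span in minutes.
#' @param rt_step grid spacing in minutes.
#' @param baseline constant chromatogram baseline (abundance units).
#' @param noise_sd additive Gaussian baseline noise SD.
#' @param zero_inflation probability a VOC abundance is a structural zero.
#' @param n_voc,n_effect_voc total and differential VOC counts.
#' @param effect_log_fc log fold change planted in differential features.
#' @param n_species,n_contaminant total and contaminant species counts.
#' @param indicator_species number of indicator contaminant species.
#' @param n_da_species non-contaminant species planted as differentially
#'   abundant between cancer and control.
#' @param dog_sensitivity,dog_specificity per-presentation indication
#'   probabilities for the simulated dog.
#' @param seed default seed used by the generators.
#' @return a list of class `simulation_design`.
#' @export
simulation_design <- function(n_case = 12, n_control = 38, n_neg_control = 6,
                              rt_span = c(0, 31), rt_step = 4 / 205,
                              baseline = 50, noise_sd = 10,
                              zero_inflation = 0.3,
                              n_voc = 1157, n_effect_voc = 7,
                              effect_log_fc = 2,
                              n_species = 150, n_contaminant = 30,
                              indicator_species = 10, n_da_species = 3,
                              dog_sensitivity = 0.714,
                              dog_specificity = 0.762,
                              seed = 1L) {
  stopifnot(
    n_case >= 1, n_control >= 1, n_neg_control >= 0,
    length(rt_span) == 2, rt_span[1] < rt_span[2], rt_step > 0,
    baseline >= 0, noise_sd >= 0,
    zero_inflation >= 0, zero_inflation <= 1,
    n_voc >= 1, n_effect_voc >= 0,
    n_species >= 1, n_contaminant >= 0, n_contaminant <= n_species,
    indicator_species >= 0, indicator_species <= max(n_contaminant, 1),
    n_da_species >= 0,
    dog_sensitivity >= 0, dog_sensitivity <= 1,
    dog_specificity >= 0, dog_specificity <= 1
  )
  if (n_effect_voc > n_voc) {
    stop("n_effect_voc cannot exceed n_voc", call. = FALSE)
  }
  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_neg_control = as.integer(n_neg_control),
    rt_span = as.numeric(rt_span), rt_step = rt_step,
    baseline = baseline, noise_sd = noise_sd,
    zero_inflation = zero_inflation,
    n_voc = as.integer(n_voc), n_effect_voc = as.integer(n_effect_voc),
    effect_log_fc = effect_log_fc,
    n_species = as.integer(n_species),
    n_contaminant = as.integer(n_contaminant),
    indicator_species = as.integer(indicator_species),
    n_da_species = as.integer(n_da_species),
    dog_sensitivity = dog_sensitivity, dog_specificity = dog_specificity,
    seed = as.integer(seed)
  ), class = "simulation_design")
}

#' Chromatographic peak specification
#'
#' A Gaussian elution peak with a group effect: `shared` peaks appear in
#' every sample, `case_excess` peaks only in cancer samples, and
#' `case_depletion` peaks only in controls (their absence in cancer
#' samples is the planted depletion).
#'
#' @param rt_center apex retention time (minutes).
#' @param width Gaussian sigma (minutes).
#' @param amplitude peak height (abundance units).
#' @param group_effect one of `"shared"`, `"case_excess"`,
#'   `"case_depletion"`.
#' @return a list of class `peak_spec`.
#' @export
peak_spec <- function(rt_center, width, amplitude,
                      group_effect = c("shared", "case_excess",
                                       "case_depletion")) {
  group_effect <- match.arg(group_effect)
  stopifnot(width > 0, amplitude >= 0)
  structure(list(rt_center = rt_center, width = width,
                 amplitude = amplitude, group_effect = group_effect),
            class = "peak_spec")
}

#' Default planted peak set
#'
#' Shared peaks across the run plus the planted group-specific signals:
#' excesses in cancer samples at 13.177 and 13.563 min and depletions
#' (control-only peaks) at 12.698, 10.561, 10.899 and 11.473 min.
#'
#' @return list of [peak_spec()]s.
#' @export
default_peak_specs <- function() {
  shared_rt <- c(2.4, 4.1, 6.7, 8.9, 10.2, 11.9, 12.3, 13.9, 16.5, 19.8, 24.2)
  shared_amp <- c(900, 1200, 700, 1500, 1000, 850, 1100, 950, 1300, 800, 600)
  specs <- Map(function(r, a) peak_spec(r, 0.03, a, "shared"),
               shared_rt, shared_amp)
  c(specs,
    list(peak_spec(13.177, 0.03, 800, "case_excess"),
         peak_spec(13.563, 0.03, 650, "case_excess"),
         peak_spec(12.698, 0.03, 700, "case_depletion"),
         peak_spec(10.561, 0.03, 400, "case_depletion"),
         peak_spec(10.899, 0.03, 400, "case_depletion"),
         peak_spec(11.473, 0.03, 400, "case_depletion")))
}

#' Simulate total-ion chromatograms
#'
#' Each trace is a constant baseline plus Gaussian peaks plus additive
#' Gaussian noise (truncated at zero). Cancer samples carry the
#' `case_excess` peaks; controls carry the `case_depletion` peaks.
#' Per-peak log-normal sample-to-sample amplitude variation (sdlog 0.4,
#' about a 40% coefficient of variation, typical of between-subject
#' differences in urinary headspace peak areas) individualizes each trace.
#'
#' @param design a [simulation_design()].
#' @param peak_specs list of [peak_spec()]s.
#' @param seed RNG seed (defaults to `design$seed`).
#' @return a [chromatogram_set()].
#' @export
simulate_chromatograms <- function(design, peak_specs = default_peak_specs(),
                                   seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  for (p in peak_specs) {
    if (p$rt_center < design$rt_span[1] || p$rt_center > design$rt_span[2]) {
      stop("peak rt_center ", p$rt_center, " outside simulated run span",
           call. = FALSE)
    }
  }
  set.seed(seed)
  rt <- seq(design$rt_span[1], design$rt_span[2], by = design$rt_step)
  n <- design$n_case + design$n_control
  cohort <- rep(c("cancer", "control"), c(design$n_case, design$n_control))
  intensity <- matrix(design$baseline, nrow = n, ncol = length(rt))
  for (p in peak_specs) {
    shape <- exp(-0.5 * ((rt - p$rt_center) / p$width)^2)
    present <- switch(p$group_effect,
                      shared = rep(TRUE, n),
                      case_excess = cohort == "cancer",
                      case_depletion = cohort == "control")
    jitter <- stats::rlnorm(n, 0, 0.25)
    for (i in which(present)) {
      intensity[i, ] <- intensity[i, ] + p$amplitude * jitter[i] * shape
    }
  }
  if (design$noise_sd > 0) {
    intensity <- intensity +
      matrix(stats::rnorm(length(intensity), 0, design$noise_sd), nrow = n)
  }
  intensity <- pmax(intensity, 0)
  samples <- data.frame(
    sample_id = sprintf("SIM-%03d", seq_len(n)),
    cohort = cohort, stringsAsFactors = FALSE)
  chromatogram_set(rt, intensity, samples)
}

#' Simulate a zero-inflated VOC table
#'
#' Abundances are log-normal with compound-specific baselines, censored
#' at a per-compound detection limit set to the `zero_inflation`
#' quantile of the compound's baseline distribution: a measurement
#' below the limit is recorded as zero, so undisturbed compounds are
#' zero with probability `zero_inflation` exactly, while shifted
#' compounds shift their zero rate along with their mean (as real
#' GC-MS peaks do around the limit of detection). The first
#' `n_effect_voc` compounds carry a group shift of `effect_log_fc` on the
#' log-mean, alternating in sign (elevated / reduced in cancer).
#'
#' @param design a [simulation_design()].
#' @param seed RNG seed.
#' @return list with elements `table` (a [voc_table()]) and `truth`
#'   (effect compound ids and signs).
#' @export
simulate_voc_table <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  n <- design$n_case + design$n_control
  p <- design$n_voc
  labels <- rep(c("cancer", "control"), c(design$n_case, design$n_control))
  cas <- sprintf("%d-%02d-%d",
                 sample(50:99999, p, replace = TRUE),
                 sample(0:99, p, replace = TRUE),
                 sample(0:9, p, replace = TRUE))
  cas <- make.unique(cas, sep = "x")
  mu <- stats::runif(p, log(10), log(1000))
  effect_sign <- integer(p)
  k <- design$n_effect_voc
  if (k > 0) effect_sign[seq_len(k)] <- rep_len(c(1L, -1L), k)
  shift <- outer(labels == "cancer", effect_sign * design$effect_log_fc)
  logm <- matrix(mu, n, p, byrow = TRUE) + shift
  ab <- matrix(stats::rlnorm(n * p, meanlog = logm, sdlog = 1), n, p)
  lod <- stats::qlnorm(design$zero_inflation, meanlog = mu, sdlog = 1)
  ab[ab < matrix(lod, n, p, byrow = TRUE)] <- 0
  rownames(ab) <- sprintf("SIM-%03d", seq_len(n))
  colnames(ab) <- cas
  list(table = voc_table(ab, labels),
       truth = list(effect_compounds = cas[seq_len(k)],
                    effect_sign = effect_sign[seq_len(k)]))
}

contaminant_genera_pool <- c(
  "Ralstonia", "Bradyrhizobium", "Sphingomonas", "Methylobacterium",
  "Burkholderia", "Delftia", "Comamonas", "Cupriavidus", "Pelomonas",
  "Herbaspirillum", "Phyllobacterium", "Stenotrophomonas", "Variovorax",
  "Afipia", "Mesorhizobium")

community_genera_pool <- c(
  "Lactobacillus", "Gardnerella", "Prevotella", "Streptococcus",
  "Staphylococcus", "Corynebacterium", "Finegoldia", "Anaerococcus",
  "Dolosigranulum", "Escherichia", "Enterococcus", "Veillonella",
  "Peptoniphilus", "Actinomyces", "Ureaplasma", "Aerococcus",
  "Fusobacterium", "Campylobacter", "Atopobium", "Sneathia")

#' Default reagent-contaminant genus blacklist
#'
#' A stand-in list of genera widely reported as DNA-extraction-kit and
#' reagent contaminants in low-biomass 16S studies, used by the third
#' contaminant-removal phase when no user list is supplied.
#'
#' @return character vector of genus names.
#' @export
default_contaminant_genera <- function() contaminant_genera_pool

#' Simulate a taxa count table with reagent-contaminant structure
#'
#' Non-contaminant species follow negative-binomial counts around a
#' log-normal community profile; a latent per-sample reagent factor
#' drives all contaminant species jointly, so contaminants are
#' Spearman-correlated with the indicator set across true samples and
#' dominate the (low-biomass) negative extraction controls, where
#' non-contaminants appear only as sparse noise counts. Roughly half the
#' contaminants carry blacklisted reagent genera; the rest take ordinary
#' genus names so the correlation phase has work of its own. The first
#' `n_da_species` non-contaminants are planted as differentially
#' abundant, alternating elevated/reduced in cancer (the first of them,
#' *Dolosigranulum pigrum*-like, is elevated). True-sample totals are
#' topped up to at least `min_depth` reads so rarefaction drops no sample
#' by construction.
#'
#' @param design a [simulation_design()].
#' @param seed RNG seed.
#' @param min_depth guaranteed minimum true-sample library size.
#' @return list with elements `table` (a [taxa_table()]) and `truth`
#'   (contaminant, indicator and differential species names).
#' @export
simulate_taxa_table <- function(design, seed = design$seed,
                                min_depth = 2700) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$n_contaminant > design$n_species) {
    stop("n_contaminant cannot exceed n_species", call. = FALSE)
  }
  set.seed(seed)
  n_true <- design$n_case + design$n_control
  n_neg <- design$n_neg_control
  n_sp <- design$n_species
  n_con <- design$n_contaminant
  labels <- rep(c("cancer", "control"), c(design$n_case, design$n_control))

  con_genera <- c(
    rep_len(contaminant_genera_pool, max(ceiling(n_con / 2), 1))[seq_len(ceiling(n_con / 2))],
    rep_len(community_genera_pool, max(floor(n_con / 2), 1))[seq_len(floor(n_con / 2))])
  con_names <- sprintf("%s contam%02d", con_genera[seq_len(n_con)],
                       seq_len(n_con))
  n_bio <- n_sp - n_con
  bio_names <- sprintf("%s simsp%03d",
                       rep_len(community_genera_pool, n_bio), seq_len(n_bio))
  if (design$n_da_species >= 1 && n_bio >= 1) {
    bio_names[1] <- "Dolosigranulum pigrum"
  }
  species <- c(con_names, bio_names)

  counts <- matrix(0L, nrow = n_sp, ncol = n_true + n_neg)

  # biological community in true samples
  base <- stats::rlnorm(n_bio, meanlog = 3, sdlog = 1.2)
  da_sign <- integer(n_bio)
  if (design$n_da_species > 0) {
    da_sign[seq_len(min(design$n_da_species, n_bio))] <-
      rep_len(c(1L, -1L), min(design$n_da_species, n_bio))
  }
  lib <- stats::rlnorm(n_true, meanlog = log(30000), sdlog = 0.15)
  for (i in seq_len(n_true)) {
    mu <- base * exp(ifelse(labels[i] == "cancer", 1, 0) *
                       da_sign * design$effect_log_fc)
    mu <- mu / sum(mu) * lib[i] * 0.97
    counts[n_con + seq_len(n_bio), i] <-
      stats::rnbinom(n_bio, mu = mu, size = 5)
  }

  # reagent contamination: latent factor per true sample, dominant in negs
  if (n_con > 0) {
    loading <- stats::rlnorm(n_con, meanlog = 0, sdlog = 0.5)
    reagent <- stats::rlnorm(n_true, meanlog = 0, sdlog = 1)
    for (i in seq_len(n_true)) {
      mu <- loading * reagent[i] * 30
      counts[seq_len(n_con), i] <- counts[seq_len(n_con), i] +
        stats::rnbinom(n_con, mu = mu, size = 8)
    }
    for (j in seq_len(n_neg)) {
      mu <- loading * 400
      counts[seq_len(n_con), n_true + j] <-
        stats::rnbinom(n_con, mu = mu, size = 8)
    }
  }
  # sparse cross-over noise of biological species into negative controls
  if (n_neg > 0 && n_bio > 0) {
    counts[n_con + seq_len(n_bio), n_true + seq_len(n_neg)] <-
      stats::rpois(n_bio * n_neg, 0.05)
  }

  # guarantee rarefiable true samples
  for (i in seq_len(n_true)) {
    deficit <- min_depth - sum(counts[, i])
    if (deficit > 0) {
      top <- which.max(counts[, i])
      counts[top, i] <- counts[top, i] + deficit
    }
  }

  rownames(counts) <- species
  colnames(counts) <- c(sprintf("SIM-%03d", seq_len(n_true)),
                        sprintf("NEG_%02d", seq_len(n_neg)))
  tab <- taxa_table(counts,
                    is_negative_control = rep(c(FALSE, TRUE),
                                              c(n_true, n_neg)),
                    labels = c(labels, rep(NA, n_neg)))
  list(table = tab,
       truth = list(
         contaminants = con_names,
         indicators = con_names[seq_len(min(design$indicator_species,
                                            n_con))],
         differential = bio_names[which(da_sign != 0)],
         differential_sign = da_sign[da_sign != 0]))
}

#' Simulate carousel scent-detection trials
#'
#' Each set places one cancer sample among three controls in a 4-pot
#' carousel. On each pass the dog sniffs pots in order; a cancer pot is
#' indicated with probability `dog_sensitivity` and a control pot with
#' probability `1 - dog_specificity` (blanks are never indicated). A
#' false call replaces that control with a blank and the dog searches
#' again; a second false call ends the set; a pass with no indication is
#' re-run up to `max_runs` passes.
#'
#' @param design a [simulation_design()].
#' @param n_sets number of sets.
#' @param seed RNG seed.
#' @param dog name for the simulated dog.
#' @param max_runs maximum passes per set.
#' @return list with `record` (a [trial_record()]) and `presentations`
#'   (a data.frame logging every pot presentation with its ground truth
#'   and the dog's response).
#' @export
simulate_trial <- function(design, n_sets, seed = design$seed,
                           dog = "SimDog", max_runs = 4) {
  stopifnot(inherits(design, "simulation_design"), n_sets >= 1)
  set.seed(seed)
  sens <- design$dog_sensitivity
  spec <- design$dog_specificity
  sets <- vector("list", n_sets)
  pres <- list()
  for (s in seq_len(n_sets)) {
    target <- sample.int(4, 1)
    kind <- ifelse(seq_len(4) == target, "target", "control")
    runs <- character(0)
    false_calls <- 0L
    for (r in seq_len(max_runs)) {
      call <- "-"
      for (pos in seq_len(4)) {
        indicated <- switch(kind[pos],
          target = stats::runif(1) < sens,
          control = stats::runif(1) < (1 - spec),
          blank = FALSE)
        pres[[length(pres) + 1]] <- data.frame(
          set = s, run = r, position = pos, kind = kind[pos],
          indicated = indicated)
        if (indicated) {
          call <- if (kind[pos] == "target") "T" else "X"
          if (call == "X") kind[pos] <- "blank"
          break
        }
      }
      runs <- c(runs, call)
      if (call == "T") break
      if (call == "X") {
        false_calls <- false_calls + 1L
        if (false_calls == 2L) break
      }
    }
    sets[[s]] <- set_record(target, runs, "balanced")
  }
  list(record = trial_record(dog, sets),
       presentations = do.call(rbind, pres))
}
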
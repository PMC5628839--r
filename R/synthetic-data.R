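#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the detection pipeline
#' assumes: a mixed-gender cohort of HC and PD subjects, repeated phonation
#' recordings per subject, single speech/voiced/unvoiced recordings, a
#' subject random effect inducing within-subject correlation (the speaker
#' identity that grouped bootstrap sampling must guard against), and a sparse
#' mean shift on the informative features for the PD class. It makes no
#' attempt at acoustic realism.
#'
#' Features are generated as
#' `x_rj = delta * 1[PD] * 1[j informative] + u_sj + e_rj`, with the subject
#' effect `u_sj ~ N(0, subject_sd^2)` drawn once per subject and feature,
#' shared across that subject's recordings and across modalities of the same
#' channel, and `e_rj ~ N(0, noise_sd^2)` fresh per recording. Informative
#' features are the first `n_informative` columns of each set, so importance
#' tests can assert their recovery. Gender is assigned independently of class
#' and by default has no feature effect.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param prop_pd fraction of subjects with PD (class 2); the PD count is
#'   `round(n_subjects * prop_pd)`.
#' @param prop_female probability a subject is female.
#' @param recordings_per_modality named integer vector of recordings per
#'   subject per modality; names from `P`, `S`, `V`, `U`.
#' @param feature_set_sizes named integer vector: features per feature set.
#' @param n_informative number of informative features per set (the first
#'   columns).
#' @param class_effect mean shift `delta` (in noise-sd units) added to
#'   informative features of PD subjects.
#' @param subject_sd sd of the per-subject, per-feature random effect.
#' @param noise_sd sd of the per-recording noise.
#' @param gender_effect mean shift added to informative features of female
#'   subjects; 0 by default (stratification is exercised without it).
#' @param channels channels to simulate (subset of `"AC"`, `"SP"`).
#' @param missing list of `list(subject=, channel=, modality=)` recording
#'   cells to omit (all feature sets of that cell lose the subject's rows).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_subjects = 99L,
                              prop_pd = 64 / 99,
                              prop_female = 58 / 99,
                              recordings_per_modality = c(P = 3L, S = 1L,
                                                          V = 1L, U = 1L),
                              feature_set_sizes = c(acoustic = 100L),
                              n_informative = 20L,
                              class_effect = 1,
                              subject_sd = 1,
                              noise_sd = 1,
                              gender_effect = 0,
                              channels = c("AC", "SP"),
                              missing = list(),
                              seed = 1L) {
  if (n_subjects < 2) stop("need at least two subjects")
  if (prop_pd < 0 || prop_pd > 1) stop("prop_pd must be in [0, 1]")
  if (prop_female < 0 || prop_female > 1) stop("prop_female must be in [0, 1]")
  if (is.null(names(feature_set_sizes)) || any(names(feature_set_sizes) == "")) {
    stop("feature_set_sizes must be named")
  }
  if (any(feature_set_sizes < 1)) stop("feature sets need at least 1 feature")
  if (n_informative > min(feature_set_sizes)) {
    stop("n_informative exceeds the smallest feature set size")
  }
  if (class_effect < 0 || subject_sd < 0) stop("effect sizes and sds must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!all(names(recordings_per_modality) %in% c("P", "S", "V", "U"))) {
    stop("modalities must be among P, S, V, U")
  }
  if (any(recordings_per_modality < 1)) stop("recordings per modality must be >= 1")
  if (!all(channels %in% c("AC", "SP"))) stop("channels must be among AC, SP")
  structure(
    list(n_subjects = as.integer(n_subjects), prop_pd = prop_pd,
         prop_female = prop_female,
         recordings_per_modality = recordings_per_modality,
         feature_set_sizes = feature_set_sizes,
         n_informative = as.integer(n_informative),
         class_effect = class_effect, subject_sd = subject_sd,
         noise_sd = noise_sd, gender_effect = gender_effect,
         channels = channels, missing = missing, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Simulate a multi-channel, multi-modality cohort
#'
#' Generates one [feature_table()] per (channel, modality, feature set)
#' combination under the generative model documented in
#' [simulation_config()]. All tables share the same subject roster except
#' where `missing` cells remove a subject's recordings.
#'
#' @param config a [simulation_config()].
#' @return named list of [feature_table()]s, names `"<channel>_<modality>_<set>"`;
#'   each table carries its channel/modality in the records.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  subjects <- sprintf("subj%03d", seq_len(n))
  n_pd <- round(n * config$prop_pd)
  class <- c(rep(2L, n_pd), rep(1L, n - n_pd))
  gender <- ifelse(stats::runif(n) < config$prop_female, "female", "male")

  tables <- list()
  for (channel in config$channels) {
    for (set in names(config$feature_set_sizes)) {
      p <- config$feature_set_sizes[[set]]
      # subject effect: one draw per subject x feature, shared across the
      # channel's modalities (this is the speaker-identity signal)
      u <- matrix(stats::rnorm(n * p, 0, config$subject_sd), nrow = n)
      shift <- config$class_effect * (class == 2L) %o%
        c(rep(1, config$n_informative), rep(0, p - config$n_informative))
      if (config$gender_effect != 0) {
        shift <- shift + config$gender_effect * (gender == "female") %o%
          c(rep(1, config$n_informative), rep(0, p - config$n_informative))
      }
      for (mod in names(config$recordings_per_modality)) {
        reps <- config$recordings_per_modality[[mod]]
        subj_idx <- rep(seq_len(n), each = reps)
        rec_id <- sprintf("%s_%s_r%d", subjects[subj_idx], mod,
                          rep(seq_len(reps), times = n))
        keep <- !drop_mask(subjects[subj_idx], channel, mod, config$missing)
        subj_idx <- subj_idx[keep]
        rec_id <- rec_id[keep]
        m <- length(subj_idx)
        eps <- matrix(stats::rnorm(m * p, 0, config$noise_sd), nrow = m)
        x <- shift[subj_idx, , drop = FALSE] + u[subj_idx, , drop = FALSE] + eps
        records <- data.frame(
          subject_id = subjects[subj_idx], recording_id = rec_id,
          class = class[subj_idx], gender = gender[subj_idx],
          channel = channel, modality = mod, stringsAsFactors = FALSE)
        key <- paste(channel, mod, set, sep = "_")
        tables[[key]] <- feature_table(
          x, records, feature_set = set,
          feature_names = sprintf("%s_f%04d", set, seq_len(p)))
      }
    }
  }
  tables
}

drop_mask <- function(subject_ids, channel, modality, missing) {
  out <- rep(FALSE, length(subject_ids))
  for (m in missing) {
    if (identical(m$channel, channel) && identical(m$modality, modality)) {
      out <- out | subject_ids == m$subject
    }
  }
  out
}

#' Write every table of a simulated cohort to a directory
#'
#' One CSV per (channel, modality, feature set), named after the list keys.
#'
#' @param tables output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_cohort <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(key) {
    write_feature_table(tables[[key]], file.path(dir, paste0(key, ".csv")))
  }, character(1))
  invisible(paths)
}
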
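#' Genotype wear profile
#'
#' Baseline and end-of-loading friction levels, wear-onset time and noise
#' structure for one Prg4 genotype. The generator treats friction as a
#' function of cumulative loading hours only: flat at `baseline_mean` until
#' `onset_hours`, then a linear ramp reaching `final_mean` at 26 h of
#' loading. Between-animal and within-measurement (trial) variation are
#' multiplicative (log-normal), consistent with analysing friction on the
#' log scale.
#'
#' @param baseline_mean,baseline_sd Group mean/SD of the baseline
#'   coefficient of friction.
#' @param final_mean,final_sd Group mean/SD after 26 h of cumulative
#'   loading (`final_mean >= baseline_mean`).
#' @param onset_hours Cumulative loading hours before friction begins to
#'   rise (in `[0, 26]`).
#' @param animal_cv Between-animal coefficient of variation of the shared
#'   log-normal animal effect; defaults to `baseline_sd / baseline_mean`.
#' @param trial_sd Within-measurement replicate noise, in coefficient-of-
#'   friction units at baseline; defaults to 10% of `baseline_mean`
#'   (typical pendulum-trial repeatability).
#' @return A `genotype_profile`.
#' @export
genotype_profile <- function(baseline_mean, baseline_sd, final_mean, final_sd,
                             onset_hours,
                             animal_cv = baseline_sd / baseline_mean,
                             trial_sd = 0.1 * baseline_mean) {
  check_positive(baseline_mean, "baseline_mean")
  check_positive(baseline_sd, "baseline_sd")
  check_positive(final_mean, "final_mean")
  check_positive(final_sd, "final_sd")
  check_nonnegative(animal_cv, "animal_cv")
  check_nonnegative(trial_sd, "trial_sd")
  if (final_mean < baseline_mean)
    jf_error("final_mean must be >= baseline_mean", "config_error")
  if (onset_hours < 0 || onset_hours > 26)
    jf_error("onset_hours must lie in [0, 26]", "config_error")
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 final_mean = final_mean, final_sd = final_sd,
                 onset_hours = onset_hours, animal_cv = animal_cv,
                 trial_sd = trial_sd),
            class = "genotype_profile")
}

#' Default genotype profiles
#'
#' Calibration anchors of the synthetic study: group baseline and
#' end-of-loading means/SDs for wild-type (Prg4+/+), heterozygous (Prg4+/-)
#' and lubricin-null (Prg4-/-) knees, with wear onset at 7, 5 and 0 h of
#' cumulative loading respectively (null joints rise from the start of
#' loading; wild-type joints are flat through at least 6 h; heterozygous
#' joints are flat through 4 h with a mild rise by 6 h).
#'
#' @return Named list of [genotype_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    "Prg4+/+" = genotype_profile(0.036, 0.0096, 0.061, 0.034, onset_hours = 7),
    "Prg4+/-" = genotype_profile(0.030, 0.0044, 0.12, 0.049, onset_hours = 5),
    "Prg4-/-" = genotype_profile(0.077, 0.0095, 0.13, 0.014, onset_hours = 0))
}

#' Default measurement schedule
#'
#' 16 experimental time points: baseline, six during the initial 2-h loading
#' block, one after the 12-h unloading gap, and eight during the final 24-h
#' loading block (26 h cumulative loading, 38 h wall clock). Control limbs
#' are measured at 0 and 38 h wall clock only.
#'
#' @return List with `experimental` and `control` data frames
#'   (`timepoint_id`, `loading_h`, `wallclock_h`).
#' @export
default_schedule <- function() {
  loading <- c(0, 1 / 3, 2 / 3, 1, 4 / 3, 5 / 3, 2, 2, 4, 6, 9, 12, 15, 18, 22, 26)
  wall <- c(0, 1 / 3, 2 / 3, 1, 4 / 3, 5 / 3, 2, 14, 16, 18, 21, 24, 27, 30, 34, 38)
  list(
    experimental = data.frame(timepoint_id = seq_along(loading),
                              loading_h = loading, wallclock_h = wall),
    control = data.frame(timepoint_id = 1:2, loading_h = c(0, 0),
                         wallclock_h = c(0, 38)))
}

#' Study design
#'
#' Paired-limb longitudinal design: per animal one knee is cyclically loaded
#' (experimental) and the contralateral knee rests unloaded in medium
#' (control); friction is measured with three pendulum trials per joint per
#' time point.
#'
#' @param genotypes Character vector of genotype labels.
#' @param n_per_genotype Animals per genotype (default 12).
#' @param experimental_timepoints,control_timepoints Data frames with
#'   columns `timepoint_id`, `loading_h`, `wallclock_h`.
#' @param trials_per_measurement Pendulum trials per joint per time point.
#' @return A `study_design`.
#' @export
study_design <- function(genotypes = c("Prg4+/+", "Prg4+/-", "Prg4-/-"),
                         n_per_genotype = 12,
                         experimental_timepoints = default_schedule()$experimental,
                         control_timepoints = default_schedule()$control,
                         trials_per_measurement = 3) {
  check_positive(n_per_genotype, "n_per_genotype")
  check_positive(trials_per_measurement, "trials_per_measurement")
  for (tp in list(experimental_timepoints, control_timepoints)) {
    stopifnot(is.data.frame(tp),
              all(c("timepoint_id", "loading_h", "wallclock_h") %in% names(tp)))
    if (is.unsorted(tp$wallclock_h))
      jf_error("wall-clock times must be non-decreasing", "config_error")
    if (any(tp$loading_h > tp$wallclock_h + 1e-9))
      jf_error("cumulative loading cannot exceed wall-clock time", "config_error")
  }
  structure(list(genotypes = genotypes,
                 n_per_genotype = as.integer(n_per_genotype),
                 experimental_timepoints = experimental_timepoints,
                 control_timepoints = control_timepoints,
                 trials_per_measurement = as.integer(trials_per_measurement)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Study design: %d genotypes x %d animals, paired limbs, %d + %d time points, %d trials/measurement\n",
    length(x$genotypes), x$n_per_genotype, nrow(x$experimental_timepoints),
    nrow(x$control_timepoints), x$trials_per_measurement))
  invisible(x)
}

#' Population friction trajectory under cumulative loading
#'
#' Control limbs stay at the genotype baseline throughout (unloaded joints
#' show no change); experimental limbs stay at baseline until the wear
#' onset, then rise linearly in cumulative loading hours to the final level
#' at 26 h. Because the trajectory is a function of cumulative loading only,
#' it is constant across unloading gaps by construction.
#'
#' @param profile A [genotype_profile()].
#' @param limb `"experimental"` or `"control"`.
#' @param loading_h Cumulative loading hours (vectorised; must lie in
#'   `[0, 26]`).
#' @return Coefficient-of-friction values.
#' @export
true_cof_trajectory <- function(profile, limb = c("experimental", "control"),
                                loading_h) {
  limb <- match.arg(limb)
  if (any(!is.finite(loading_h)) || any(loading_h < 0) || any(loading_h > 26))
    jf_error("loading_h must lie in [0, 26]", "config_error")
  if (limb == "control") return(rep(profile$baseline_mean, length(loading_h)))
  on <- profile$onset_hours
  ramp <- pmax(loading_h - on, 0) / max(26 - on, .Machine$double.eps)
  profile$baseline_mean + (profile$final_mean - profile$baseline_mean) * ramp
}

lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

## Mean-one log-normal multipliers with coefficient of variation cv.
rlnorm_mean1 <- function(n, cv) {
  s <- lognormal_sdlog(cv)
  if (all(s == 0)) return(rep(1, n))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate a complete synthetic study dataset
#'
#' Emulates the statistical structure of the loading experiment: per animal
#' a log-normal multiplicative effect (shared by both limbs) scales the
#' genotype's population trajectory; each measurement consists of
#' `trials_per_measurement` replicate coefficients of friction. At
#' `fidelity = "summary"` trial values are the animal-level truth times
#' log-normal trial noise; at `fidelity = "physics"` every trial is a full
#' simulate -> render markers -> track -> estimate round trip with the
#' Coulomb coefficient set to the animal-level value, the start angle drawn
#' uniformly from 10-14 degrees, and marker noise `noise_sd`. Ordinal
#' histology scores for both tibial plateaus are generated alongside (see
#' [generate_histology()]).
#'
#' @param design A [study_design()].
#' @param profiles Named list of [genotype_profile()] covering
#'   `design$genotypes`.
#' @param fidelity `"summary"` (fast, default) or `"physics"`.
#' @param seed Integer seed; identical seeds yield identical datasets.
#' @param score_profiles Histology cell profiles, see
#'   [default_score_profiles()].
#' @param config Pendulum configuration for physics fidelity.
#' @param layout Marker layout for physics fidelity.
#' @param noise_sd Marker noise (mm) for physics fidelity.
#' @param out_dir Optional directory; at physics fidelity per-trial marker
#'   trajectory files are written there.
#' @return A `study_dataset`: list with long-format `cof` and `histology`
#'   data frames plus the generating design, profiles, seed and fidelity.
#' @export
generate_study <- function(design = study_design(),
                           profiles = default_profiles(),
                           fidelity = c("summary", "physics"),
                           seed = 1L,
                           score_profiles = default_score_profiles(),
                           config = pendulum_config(),
                           layout = default_marker_layout(),
                           noise_sd = 0.05,
                           out_dir = NULL) {
  fidelity <- match.arg(fidelity)
  stopifnot(inherits(design, "study_design"))
  missing_g <- setdiff(design$genotypes, names(profiles))
  if (length(missing_g))
    jf_error(paste("no profile for genotype:", paste(missing_g, collapse = ", ")),
             "config_error")

  with_seed(seed, {
    # animal table with shared multiplicative effects
    animals <- expand.grid(idx = seq_len(design$n_per_genotype),
                           genotype = design$genotypes,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
    animals$animal_id <- sprintf("%s_%02d", genotype_code(animals$genotype), animals$idx)
    cvs <- vapply(profiles[animals$genotype], `[[`, numeric(1), "animal_cv")
    animals$animal_effect <- stats::rlnorm(
      nrow(animals), meanlog = -lognormal_sdlog(cvs)^2 / 2,
      sdlog = lognormal_sdlog(cvs))

    # measurement grid
    sched <- function(limb) {
      tp <- if (limb == "experimental") design$experimental_timepoints
            else design$control_timepoints
      merge(animals, cbind(tp, limb = limb), by = NULL)
    }
    meas <- rbind(sched("experimental"), sched("control"))
    meas <- meas[order(match(meas$genotype, design$genotypes), meas$idx,
                       meas$limb, meas$timepoint_id), ]
    meas <- meas[rep(seq_len(nrow(meas)), each = design$trials_per_measurement), ]
    meas$trial_id <- rep(seq_len(design$trials_per_measurement),
                         length.out = nrow(meas))
    rownames(meas) <- NULL

    base_means <- vapply(profiles[meas$genotype], `[[`, numeric(1),
                         "baseline_mean")
    trial_sds <- vapply(profiles[meas$genotype], `[[`, numeric(1), "trial_sd")
    truth <- vapply(seq_len(nrow(meas)), function(i)
      true_cof_trajectory(profiles[[meas$genotype[i]]], meas$limb[i],
                          meas$loading_h[i]), numeric(1))
    mu_animal <- truth * meas$animal_effect

    if (fidelity == "summary") {
      cof <- mu_animal * rlnorm_mean1(nrow(meas), trial_sds / base_means)
    } else {
      if (!is.null(out_dir) && !dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE)
      cof <- numeric(nrow(meas))
      for (i in seq_len(nrow(meas))) {
        cfg_i <- config
        cfg_i$start_angle <- stats::runif(1, 10, 14)
        traj <- simulate_free_oscillation(cfg_i, friction_params(mu_animal[i]))
        frames <- render_markers(traj, layout, noise_sd = noise_sd)
        if (!is.null(out_dir)) {
          fn <- sprintf("%s_%s_tp%02d_trial%d.csv", meas$animal_id[i],
                        meas$limb[i], meas$timepoint_id[i], meas$trial_id[i])
          write_trajectory(frames, file.path(out_dir, fn))
        }
        cof[i] <- estimate_trial(estimate_angles(frames, layout), cfg_i)$mu_hat
      }
    }

    cof_df <- data.frame(animal_id = meas$animal_id, genotype = meas$genotype,
                         limb = meas$limb, timepoint_id = meas$timepoint_id,
                         cumulative_loading_h = meas$loading_h,
                         wallclock_h = meas$wallclock_h,
                         trial_id = meas$trial_id, cof = cof,
                         stringsAsFactors = FALSE)
    hist_df <- generate_histology(design, score_profiles, seed = NULL,
                                  animals = animals)

    structure(list(cof = cof_df, histology = hist_df, design = design,
                   profiles = profiles, seed = seed, fidelity = fidelity),
              class = "study_dataset")
  })
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic study (%s fidelity, seed %s): %d CoF records, %d histology records\n",
    x$fidelity, format(x$seed), nrow(x$cof), nrow(x$histology)))
  cat(sprintf("  %d animals across %s\n",
              length(unique(x$cof$animal_id)),
              paste(x$design$genotypes, collapse = ", ")))
  invisible(x)
}

#' Histology score cell profiles
#'
#' Per genotype x treatment cell, the mean and SD of each of the three
#' cartilage-integrity categories: articular cartilage surface structure
#' (0-4), surface layer morphology (0-3) and pericellular Safranin O loss
#' (0-4). Defaults are the study's calibration anchors.
#'
#' @return Data frame with columns `genotype`, `limb`, `category`, `mean`,
#'   `sd`, `max_score`.
#' @export
default_score_profiles <- function() {
  g <- c("Prg4+/+", "Prg4+/-", "Prg4-/-")
  df <- rbind(
    data.frame(genotype = rep(g, each = 2),
               limb = rep(c("experimental", "control"), 3),
               category = "structure",
               mean = c(0.21, 0.21, 0.40, 0.20, 2.05, 1.91),
               sd = c(0.33, 0.40, 0.52, 0.26, 0.52, 0.77), max_score = 4),
    data.frame(genotype = rep(g, each = 2),
               limb = rep(c("experimental", "control"), 3),
               category = "surface",
               mean = c(0.38, 0.30, 0.65, 0.25, 2.09, 1.59),
               sd = c(0.43, 0.33, 0.47, 0.26, 0.20, 0.86), max_score = 3),
    data.frame(genotype = rep(g, each = 2),
               limb = rep(c("experimental", "control"), 3),
               category = "safranin",
               mean = c(0.88, 0.83, 1.55, 1.40, 1.14, 1.18),
               sd = c(0.74, 0.65, 0.99, 1.17, 0.60, 0.98), max_score = 4))
  rownames(df) <- NULL
  df
}

#' Generate ordinal histology scores
#'
#' Per joint, per tibial plateau (medial/lateral), per category: a latent
#' Gaussian draw at the cell mean/SD is truncated to the category range and
#' rounded to the nearest 0.5 — the consensus scale on which multi-observer
#' scores are reported.
#'
#' @param design A [study_design()].
#' @param score_profiles See [default_score_profiles()].
#' @param seed Integer seed (`NULL` continues the current RNG stream).
#' @param animals Internal: precomputed animal table.
#' @return Data frame with columns `animal_id`, `genotype`, `limb`,
#'   `plateau`, `category`, `score`.
#' @export
generate_histology <- function(design = study_design(),
                               score_profiles = default_score_profiles(),
                               seed = NULL, animals = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(animals)) {
    animals <- expand.grid(idx = seq_len(design$n_per_genotype),
                           genotype = design$genotypes,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    animals$animal_id <- sprintf("%s_%02d", genotype_code(animals$genotype), animals$idx)
  }
  with_seed(seed, {
    rows <- merge(
      merge(merge(animals[, c("animal_id", "genotype")],
                  data.frame(limb = c("experimental", "control"),
                             stringsAsFactors = FALSE), by = NULL),
            data.frame(plateau = c("medial", "lateral"),
                       stringsAsFactors = FALSE), by = NULL),
      score_profiles, by = c("genotype", "limb"))
    rows <- rows[order(rows$genotype, rows$animal_id, rows$limb,
                       rows$category, rows$plateau), ]
    rownames(rows) <- NULL
    latent <- stats::rnorm(nrow(rows), rows$mean, rows$sd)
    clamped <- pmin(pmax(latent, 0), rows$max_score)
    rows$score <- round(clamped * 2) / 2
    rows[, c("animal_id", "genotype", "limb", "plateau", "category", "score")]
  })
}
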
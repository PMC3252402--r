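## Delimited-text I/O. Everything is plain comma-separated text with a
## header; reals are written with 17 significant digits so write/read round
## trips are exact to better than 1e-12 relative.

read_checked_csv <- function(path, expected_prefix = NULL) {
  if (!file.exists(path)) jf_error(paste("file not found:", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    jf_error(sprintf("parse error in %s: no data rows", path), "parse_error")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!is.null(expected_prefix) &&
      !identical(header[seq_along(expected_prefix)], expected_prefix))
    jf_error(sprintf("parse error in %s at line 1: unexpected header", path),
             "parse_error")
  nf <- lengths(strsplit(lines[-1L], ",", fixed = TRUE))
  bad <- which(nf != length(header))
  if (length(bad))
    jf_error(sprintf("parse error in %s at line %d: expected %d fields, found %d",
                     path, bad[1L] + 1L, length(header), nf[bad[1L]]),
             "parse_error")
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_df <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read marker trajectory files
#'
#' One file per pendulum trial: columns `frame`, `time_s`, then `<marker>_x_mm`
#' and `<marker>_y_mm` for each of the 8 markers.
#'
#' @param frames A `marker_frames` object.
#' @param path Output file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `marker_frames` object.
#' @export
write_trajectory <- function(frames, path) {
  stopifnot(inherits(frames, "marker_frames"))
  pos <- frames$positions
  nm <- dimnames(pos)[[2L]]
  df <- data.frame(frame = seq_along(frames$times) - 1L,
                   time_s = frames$times)
  for (j in seq_along(nm)) {
    df[[paste0(nm[j], "_x_mm")]] <- pos[, j, 1L]
    df[[paste0(nm[j], "_y_mm")]] <- pos[, j, 2L]
  }
  write_df(df, path)
}

#' @param layout The [marker_layout()] the file's markers refer to.
#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, layout = default_marker_layout()) {
  df <- read_checked_csv(path, expected_prefix = c("frame", "time_s"))
  nm <- marker_names(layout)
  need <- c(rbind(paste0(nm, "_x_mm"), paste0(nm, "_y_mm")))
  miss <- setdiff(need, names(df))
  if (length(miss))
    jf_error(sprintf("parse error in %s: missing columns %s", path,
                     paste(miss, collapse = ", ")), "parse_error")
  nfr <- nrow(df)
  pos <- array(NA_real_, dim = c(nfr, length(nm), 2L),
               dimnames = list(NULL, nm, c("x", "y")))
  for (j in seq_along(nm)) {
    pos[, j, 1L] <- df[[paste0(nm[j], "_x_mm")]]
    pos[, j, 2L] <- df[[paste0(nm[j], "_y_mm")]]
  }
  structure(list(times = df$time_s, positions = pos, layout = layout,
                 noise_sd = NA_real_),
            class = "marker_frames")
}

#' Write / read angle-series files
#'
#' Columns `time_s`, `angle_rad`, `residual_mm`.
#'
#' @param series An `angle_series`.
#' @param path File path.
#' @return `write_angle_series` returns `path` invisibly; `read_angle_series`
#'   an `angle_series`.
#' @export
write_angle_series <- function(series, path) {
  write_df(data.frame(time_s = series$times, angle_rad = series$angles,
                      residual_mm = series$residual_rms), path)
}

#' @rdname write_angle_series
#' @export
read_angle_series <- function(path) {
  df <- read_checked_csv(path, c("time_s", "angle_rad", "residual_mm"))
  structure(list(times = df$time_s, angles = df$angle_rad,
                 residual_rms = df$residual_mm, n_interpolated = 0L),
            class = "angle_series")
}

#' Write / read study dataset tables
#'
#' Two tidy tables under `dir`: `cof.csv` (one row per trial) and
#' `histology.csv` (one row per plateau score).
#'
#' @param dataset A `study_dataset`.
#' @param dir Directory (created if needed).
#' @return `write_study` returns `dir` invisibly; `read_study` a
#'   `study_dataset` (tables only; design and profiles are not serialised).
#' @export
write_study <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_df(dataset$cof, file.path(dir, "cof.csv"))
  write_df(dataset$histology, file.path(dir, "histology.csv"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  cof <- read_checked_csv(file.path(dir, "cof.csv"),
                          c("animal_id", "genotype", "limb"))
  hist <- read_checked_csv(file.path(dir, "histology.csv"),
                           c("animal_id", "genotype", "limb"))
  structure(list(cof = cof, histology = hist, design = NULL, profiles = NULL,
                 seed = NA_integer_, fidelity = "file"),
            class = "study_dataset")
}

#' Run configuration
#'
#' A nested list mirroring the module parameter names: `pendulum`
#' ([pendulum_config()] fields), `friction` ([friction_params()] fields),
#' `study` (`n_per_genotype`, `trials_per_measurement`, per-genotype profile
#' fields), `analysis` (`alpha`), plus `seed`, `fidelity` and `out_dir`.
#' Serialised as YAML.
#'
#' @param seed Integer seed for the run.
#' @param fidelity `"summary"` or `"physics"`.
#' @param out_dir Output directory for [run_pipeline()].
#' @param alpha Significance level for the analysis stage.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, fidelity = "summary",
                               out_dir = tempfile("jointfriction_run_"),
                               alpha = 0.05) {
  profs <- default_profiles()
  structure(list(
    pendulum = unclass(pendulum_config()),
    friction = unclass(friction_params()),
    study = list(n_per_genotype = 12L, trials_per_measurement = 3L,
                 profiles = lapply(profs, unclass)),
    analysis = list(alpha = alpha),
    seed = as.integer(seed), fidelity = fidelity, out_dir = out_dir),
    class = "run_config")
}

#' @param config A `run_config`.
#' @param path YAML file path.
#' @rdname default_run_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) jf_error(paste("file not found:", path), "io_error")
  cfg <- yaml::read_yaml(path)
  needed <- c("pendulum", "study", "analysis", "seed", "fidelity", "out_dir")
  miss <- setdiff(needed, names(cfg))
  if (length(miss))
    jf_error(paste("config missing sections:", paste(miss, collapse = ", ")),
             "parse_error")
  structure(cfg, class = "run_config")
}

run_config_objects <- function(config) {
  pc <- do.call(pendulum_config,
                config$pendulum[setdiff(names(config$pendulum),
                                        "equilibrium_flexion")])
  pc$equilibrium_flexion <- config$pendulum$equilibrium_flexion
  profiles <- lapply(config$study$profiles, function(p)
    do.call(genotype_profile, p))
  design <- study_design(genotypes = names(profiles),
                         n_per_genotype = config$study$n_per_genotype,
                         trials_per_measurement = config$study$trials_per_measurement)
  list(pendulum = pc, profiles = profiles, design = design)
}
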
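#' Run the end-to-end pipeline
#'
#' Generate the synthetic study at the configured fidelity, fit the mixed
#' model on log coefficient of friction, run the two-way histology ANOVA
#' and the friction-histology correlation, and write all artifacts (dataset
#' tables, effects and contrast tables, ANOVA tables, a calibration summary
#' comparing generated group means to the configured profile anchors, and a
#' reproducibility manifest) to the configured output directory. The run is
#' deterministic given the seed.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @return Invisibly, a list with the `dataset`, `effects`, `anova`,
#'   `correlation` and `summary` objects and the output directory.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  obj <- run_config_objects(config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      jf_error(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "pipeline_error")
    })
  }

  dataset <- stage("generate", generate_study(
    design = obj$design, profiles = obj$profiles,
    fidelity = config$fidelity, seed = config$seed, config = obj$pendulum,
    out_dir = if (identical(config$fidelity, "physics"))
      file.path(out_dir, "trials") else NULL))
  stage("write-dataset", write_study(dataset, file.path(out_dir, "dataset")))

  effects <- stage("mixed-model",
                   fit_cof_mixed_model(dataset,
                                       alpha = config$analysis$alpha))
  write_df(effects$contrasts, file.path(out_dir, "cof_contrasts.csv"))
  an_df <- as.data.frame(effects$anova)
  an_df <- cbind(effect = rownames(an_df), an_df)
  write_df(an_df, file.path(out_dir, "cof_anova.csv"))

  hist_an <- stage("histology-anova", anova_histology(dataset))
  write_df(hist_an$cell_stats, file.path(out_dir, "histology_cells.csv"))

  correl <- stage("correlation", correlate_cof_histology(dataset))
  write_df(correl, file.path(out_dir, "cof_histology_correlation.csv"))

  summary_df <- stage("summary", calibration_summary(dataset))
  write_df(summary_df, file.path(out_dir, "calibration_summary.csv"))

  cfg_path <- file.path(out_dir, "run_config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    package = "jointfriction",
    version = as.character(utils::packageVersion("jointfriction")),
    seed = config$seed,
    fidelity = config$fidelity,
    config_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = dataset, effects = effects, anova = hist_an,
                 correlation = correl, summary = summary_df,
                 out_dir = out_dir))
}

#' Compare generated group means with the profile anchors
#'
#' Per genotype, the generated baseline mean (both limbs at time zero) and
#' the final experimental mean (last experimental time point) next to the
#' profile's configured values.
#'
#' @param dataset A `study_dataset` carrying its generating profiles.
#' @return Data frame with columns `genotype`, `quantity`, `generated`,
#'   `target`, `relative_error`.
#' @export
calibration_summary <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"), !is.null(dataset$profiles))
  cof <- dataset$cof
  rows <- list()
  for (g in names(dataset$profiles)) {
    p <- dataset$profiles[[g]]
    d <- cof[cof$genotype == g, ]
    base <- mean(d$cof[d$wallclock_h == min(d$wallclock_h)])
    final <- mean(d$cof[d$limb == "experimental" &
                          d$wallclock_h == max(d$wallclock_h)])
    rows[[g]] <- data.frame(
      genotype = g,
      quantity = c("baseline_mean", "final_mean"),
      generated = c(base, final),
      target = c(p$baseline_mean, p$final_mean),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$relative_error <- out$generated / out$target - 1
  rownames(out) <- NULL
  out
}
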
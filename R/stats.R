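category_maxima <- c(structure = 4, surface = 3, safranin = 4)

#' Aggregate plateau histology scores for one joint
#'
#' Scores for the two tibial plateaus are averaged to one score per category
#' per joint, and the three category means are summed to the joint total
#' (ceiling 4 + 3 + 4 = 11). Applied to already-aggregated per-joint scores
#' (one record per category) it returns them unchanged, with a warning.
#'
#' @param plateau_scores Data frame with columns `category` (`structure`,
#'   `surface`, `safranin`) and `score`, normally two records (one per
#'   plateau) per category.
#' @return A `histology_score` list: `structure`, `surface`, `safranin`,
#'   `total`.
#' @export
aggregate_histology <- function(plateau_scores) {
  stopifnot(is.data.frame(plateau_scores),
            all(c("category", "score") %in% names(plateau_scores)))
  out <- list()
  for (cat_name in names(category_maxima)) {
    sc <- plateau_scores$score[plateau_scores$category == cat_name]
    if (length(sc) == 0L)
      jf_error(sprintf("no scores for category '%s'", cat_name),
               "validation_error")
    if (length(sc) == 1L)
      warning(sprintf("only one plateau score for category '%s'", cat_name))
    if (length(sc) > 2L)
      jf_error(sprintf("more than two plateau scores for category '%s'",
                       cat_name), "validation_error")
    if (any(sc < 0 | sc > category_maxima[[cat_name]]))
      jf_error(sprintf("score outside [0, %g] for category '%s'",
                       category_maxima[[cat_name]], cat_name),
               "validation_error")
    out[[cat_name]] <- mean(sc)
  }
  out$total <- out$structure + out$surface + out$safranin
  structure(out, class = "histology_score")
}

#' @export
print.histology_score <- function(x, ...) {
  cat(sprintf(
    "Histology: structure %.2f, surface %.2f, safranin %.2f; total %.2f / 11\n",
    x$structure, x$surface, x$safranin, x$total))
  invisible(x)
}

## Per-joint wide table of aggregated category scores and totals.
aggregate_histology_joints <- function(histology) {
  stopifnot(is.data.frame(histology),
            all(c("animal_id", "genotype", "limb", "category", "score") %in%
                  names(histology)))
  key <- interaction(histology$animal_id, histology$limb, drop = TRUE)
  parts <- lapply(split(histology, key), function(d) {
    hs <- aggregate_histology(d[, c("category", "score")])
    data.frame(animal_id = d$animal_id[1L], genotype = d$genotype[1L],
               limb = d$limb[1L], structure = hs$structure,
               surface = hs$surface, safranin = hs$safranin, total = hs$total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

## Per-measurement (animal x limb x time point) mean of replicate trials.
aggregate_cof_trials <- function(cof) {
  agg <- stats::aggregate(
    cof ~ animal_id + genotype + limb + timepoint_id + cumulative_loading_h +
      wallclock_h, data = cof, FUN = mean)
  agg[order(agg$genotype, agg$animal_id, agg$limb, agg$wallclock_h), ]
}

## Fixed-effect design rows for given cells, on the fitted model's column
## basis; averages rows when a factor is given several levels.
contrast_row <- function(terms_obj, coefs, data_levels, genotype, limb, time) {
  nd <- expand.grid(genotype = genotype, limb = limb, time = time,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nd$genotype <- factor(nd$genotype, levels = data_levels$genotype)
  nd$limb <- factor(nd$limb, levels = data_levels$limb)
  nd$time <- factor(nd$time, levels = data_levels$time)
  mm <- stats::model.matrix(terms_obj, nd)
  row <- colMeans(mm)
  dropped <- setdiff(names(row), coefs)
  if (any(abs(row[dropped]) > 1e-10))
    jf_error("contrast involves a rank-deficient (unobserved) cell",
             "contrast_error")
  row[coefs]
}

#' Mixed model on log coefficient of friction
#'
#' The replicate trials of each measurement are averaged, the mean is
#' log-transformed, and a Gaussian linear mixed model is fitted with fixed
#' effects genotype, limb and time point (categorical, keyed on wall-clock
#' hour) plus all two-way interactions, and a random intercept per animal
#' (limbs of one animal are paired). Effects are tested with Satterthwaite
#' F tests; pairwise genotype contrasts are reported at baseline (averaged
#' over limbs) and at the final time point on the loaded limb, as t tests
#' with Satterthwaite degrees of freedom. Because control limbs are observed
#' at a subset of the time points, inestimable limb-by-time columns are
#' dropped from the fixed-effect basis.
#'
#' @param dataset A `study_dataset`, or a data frame shaped like its `cof`
#'   component.
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return An `effects_table` list: `model` (the `lmerModLmerTest` fit),
#'   `anova` (Satterthwaite F table), `contrasts` (data frame of genotype
#'   log-ratios with SE, df, t and p), `varcomp` (random-effect standard
#'   deviations), `singular` flag and `alpha`.
#' @export
fit_cof_mixed_model <- function(dataset, alpha = 0.05) {
  cof <- if (inherits(dataset, "study_dataset")) dataset$cof else dataset
  stopifnot(is.data.frame(cof),
            all(c("animal_id", "genotype", "limb", "wallclock_h", "cof") %in%
                  names(cof)))
  if (any(cof$cof <= 0))
    jf_error("coefficient of friction values must be positive",
             "validation_error")
  if (length(unique(cof$genotype)) < 2L || length(unique(cof$limb)) < 2L ||
      length(unique(cof$wallclock_h)) < 2L)
    jf_error("need >= 2 genotypes, both limbs and >= 2 time points",
             "validation_error")

  agg <- aggregate_cof_trials(cof)
  agg$log_cof <- log(agg$cof)
  agg$time <- factor(agg$wallclock_h,
                     levels = sort(unique(agg$wallclock_h)))
  # levels in order of appearance (generation order), not locale collation
  agg$genotype <- factor(agg$genotype, levels = unique(cof$genotype))
  agg$limb <- factor(agg$limb, levels = c("control", "experimental"))

  m <- suppressMessages(lmerTest::lmer(
    log_cof ~ genotype + limb + time + genotype:limb + genotype:time +
      limb:time + (1 | animal_id),
    data = agg,
    control = lme4::lmerControl(check.rankX = "silent.drop.cols",
                                calc.derivs = FALSE)))
  singular <- lme4::isSingular(m)
  if (singular)
    message("singular fit: between-animal variance estimated at zero")

  an <- tryCatch(suppressMessages(stats::anova(m)),
                 error = function(e) stats::anova(m, ddf = "lme4"))

  lv <- list(genotype = levels(agg$genotype), limb = levels(agg$limb),
             time = levels(agg$time))
  trm <- stats::delete.response(stats::terms(
    log_cof ~ genotype + limb + time + genotype:limb + genotype:time +
      limb:time))
  coefs <- names(lme4::fixef(m))
  t_base <- lv$time[1L]
  t_final <- lv$time[length(lv$time)]
  pairs <- utils::combn(lv$genotype, 2, simplify = FALSE)

  rows <- list()
  for (p in pairs) {
    for (at in c("baseline", "final")) {
      if (at == "baseline") {
        rA <- contrast_row(trm, coefs, lv, p[2L], lv$limb, t_base)
        rB <- contrast_row(trm, coefs, lv, p[1L], lv$limb, t_base)
      } else {
        rA <- contrast_row(trm, coefs, lv, p[2L], "experimental", t_final)
        rB <- contrast_row(trm, coefs, lv, p[1L], "experimental", t_final)
      }
      L <- rA - rB
      ct <- lmerTest::contest1D(m, L)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = sprintf("%s - %s", p[2L], p[1L]), at = at,
        estimate = ct[["Estimate"]], se = ct[["Std. Error"]],
        df = ct[["df"]], t = ct[["t value"]], p = ct[["Pr(>|t|)"]],
        stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)

  vc <- as.data.frame(lme4::VarCorr(m))

  structure(list(model = m, anova = an, contrasts = contrasts, varcomp = vc,
                 singular = singular, alpha = alpha, n_obs = nrow(agg)),
            class = "effects_table")
}

#' @export
print.effects_table <- function(x, ...) {
  cat(sprintf("Mixed model on log CoF (%d measurement means%s)\n", x$n_obs,
              if (x$singular) ", singular fit" else ""))
  cat("Fixed-effect tests:\n")
  print(x$anova)
  cat(sprintf("\nGenotype contrasts (log-ratio scale, alpha = %.2f):\n",
              x$alpha))
  print(x$contrasts, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Two-way ANOVA on histology scores
#'
#' Plateau scores are aggregated per joint, then each category score and the
#' total are analysed by a two-way analysis of variance with genotype,
#' treatment (loaded vs control limb) and their interaction. Cell means and
#' SDs are reported alongside.
#'
#' @param histology Data frame of plateau-level histology records (as in a
#'   `study_dataset`), or a `study_dataset`.
#' @return An `anova_histology` list: per response the `aov` summary table,
#'   plus `cell_stats` (mean and SD per genotype x treatment cell).
#' @export
anova_histology <- function(histology) {
  if (inherits(histology, "study_dataset")) histology <- histology$histology
  joints <- aggregate_histology_joints(histology)
  joints$genotype <- factor(joints$genotype)
  joints$limb <- factor(joints$limb)
  if (nlevels(joints$genotype) < 2L || nlevels(joints$limb) < 2L)
    jf_error("need >= 2 levels of genotype and treatment", "validation_error")
  counts <- table(joints$genotype, joints$limb)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)[1L, ]
    jf_error(sprintf("empty cell: genotype %s, limb %s",
                     rownames(counts)[empty[1L]], colnames(counts)[empty[2L]]),
             "empty_cell_error")
  }
  if (any(counts < 2L))
    jf_error("interaction is unidentifiable with single-replicate cells",
             "validation_error")

  responses <- c("structure", "surface", "safranin", "total")
  tables <- lapply(responses, function(r) {
    fit <- stats::aov(stats::reformulate("genotype * limb", r), data = joints)
    tab <- summary(fit)[[1L]]
    rownames(tab) <- trimws(rownames(tab))
    tab
  })
  names(tables) <- responses

  cell_stats <- do.call(rbind, lapply(responses, function(r) {
    m <- stats::aggregate(joints[[r]],
                          by = list(genotype = joints$genotype,
                                    limb = joints$limb), FUN = mean)
    s <- stats::aggregate(joints[[r]],
                          by = list(genotype = joints$genotype,
                                    limb = joints$limb), FUN = stats::sd)
    data.frame(category = r, genotype = m$genotype, limb = m$limb,
               mean = m$x, sd = s$x, stringsAsFactors = FALSE)
  }))

  structure(list(tables = tables, cell_stats = cell_stats,
                 n_joints = nrow(joints)),
            class = "anova_histology")
}

#' @export
print.anova_histology <- function(x, ...) {
  cat(sprintf("Two-way ANOVA on histology (%d joints)\n", x$n_joints))
  for (r in names(x$tables)) {
    cat("\n==", r, "==\n")
    print(x$tables[[r]])
  }
  invisible(x)
}

#' Correlation of final friction with histology total score
#'
#' Spearman rank correlation (histology is ordinal) between each joint's
#' final coefficient of friction (trial mean at that limb's last time point)
#' and its total histology score, overall and within genotype. Constant
#' scores make the correlation undefined; such strata are flagged rather
#' than tested.
#'
#' @param dataset A `study_dataset`.
#' @return Data frame with one row per stratum (`overall` plus each
#'   genotype): `n`, `rho`, `p`, `flag`.
#' @export
correlate_cof_histology <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  agg <- aggregate_cof_trials(dataset$cof)
  split_key <- interaction(agg$animal_id, agg$limb, drop = TRUE)
  finals <- do.call(rbind, lapply(split(agg, split_key), function(d) {
    d[which.max(d$wallclock_h), c("animal_id", "genotype", "limb", "cof")]
  }))
  joints <- merge(finals, aggregate_histology_joints(dataset$histology),
                  by = c("animal_id", "genotype", "limb"))
  if (nrow(joints) < 3L)
    jf_error("need at least 3 joints for a correlation", "validation_error")

  one <- function(d, label) {
    if (nrow(d) < 3L || stats::sd(d$total) == 0 || stats::sd(d$cof) == 0)
      return(data.frame(stratum = label, n = nrow(d), rho = NA_real_,
                        p = NA_real_, flag = "undefined",
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(d$cof, d$total, method = "spearman",
                                           exact = FALSE))
    data.frame(stratum = label, n = nrow(d), rho = unname(ct$estimate),
               p = ct$p.value, flag = NA_character_, stringsAsFactors = FALSE)
  }
  out <- rbind(one(joints, "overall"),
               do.call(rbind, lapply(split(joints, joints$genotype),
                                     function(d) one(d, d$genotype[1L]))))
  rownames(out) <- NULL
  out
}
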
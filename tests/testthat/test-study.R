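test_that("default profiles carry the calibrated group anchors", {
  p <- default_profiles()
  expect_equal(p[["Prg4-/-"]]$baseline_mean, 0.077)
  expect_equal(p[["Prg4-/-"]]$baseline_sd, 0.0095)
  expect_equal(p[["Prg4+/+"]]$baseline_mean, 0.036)
  expect_equal(p[["Prg4+/-"]]$baseline_mean, 0.030)
  expect_equal(p[["Prg4+/+"]]$final_mean, 0.061)
  expect_equal(p[["Prg4+/-"]]$final_mean, 0.12)
  expect_equal(p[["Prg4-/-"]]$final_mean, 0.13)
  expect_true(all(vapply(p, function(x) x$final_mean >= x$baseline_mean,
                         logical(1))))
  expect_equal(vapply(p, `[[`, numeric(1), "onset_hours"),
               c("Prg4+/+" = 7, "Prg4+/-" = 5, "Prg4-/-" = 0))
})

test_that("population trajectories honour onset, ramp and flat controls", {
  p <- default_profiles()
  hs <- c(0, 2, 5, 9, 14, 26)
  expect_equal(true_cof_trajectory(p[["Prg4+/+"]], "control", hs),
               rep(0.036, length(hs)))
  expect_equal(true_cof_trajectory(p[["Prg4-/-"]], "experimental", 26), 0.13)
  expect_equal(true_cof_trajectory(p[["Prg4+/+"]], "experimental", 4), 0.036)
  expect_equal(true_cof_trajectory(p[["Prg4+/-"]], "experimental", 4), 0.030)
  # the ramp is linear in cumulative loading beyond onset
  mid <- true_cof_trajectory(p[["Prg4-/-"]], "experimental", 13)
  expect_equal(mid, (0.077 + 0.13) / 2)
  expect_error(true_cof_trajectory(p[["Prg4+/+"]], "experimental", 30),
               class = "config_error")
})

test_that("the default design has the published arithmetic", {
  ds <- generate_study(seed = 3)
  cof <- ds$cof
  expect_identical(length(unique(cof$animal_id)), 36L)
  expect_identical(nrow(unique(cof[, c("animal_id", "limb")])), 72L)
  expect_identical(nrow(cof), 36L * (16L + 2L) * 3L)
  per_exp <- table(cof$timepoint_id[cof$limb == "experimental"])
  expect_identical(length(per_exp), 16L)
  per_ctl <- table(cof$timepoint_id[cof$limb == "control"])
  expect_identical(length(per_ctl), 2L)
  expect_identical(sum(cof$genotype == "Prg4+/+" &
                         cof$timepoint_id == 1 & cof$limb == "experimental" &
                         cof$trial_id == 1), 12L)
  # schedule includes the 12-hour unloaded gap with no added loading
  sch <- default_schedule()$experimental
  gap <- which(diff(sch$wallclock_h) == 12)
  expect_length(gap, 1L)
  expect_equal(diff(sch$loading_h)[gap], 0)
})

test_that("switching off noise collapses every trial onto the truth", {
  ds <- generate_study(profiles = noiseless_profiles(), seed = 5)
  base_wt <- ds$cof$cof[ds$cof$genotype == "Prg4+/+" &
                          ds$cof$cumulative_loading_h == 0 &
                          ds$cof$limb == "experimental"]
  expect_true(all(base_wt == 0.036))
  ctl <- ds$cof$cof[ds$cof$genotype == "Prg4-/-" & ds$cof$limb == "control"]
  expect_true(all(ctl == 0.077))
})

test_that("identical seeds reproduce the dataset exactly", {
  a <- generate_study(seed = 99)
  b <- generate_study(seed = 99)
  expect_identical(a$cof, b$cof)
  expect_identical(a$histology, b$histology)
  c_ <- generate_study(seed = 100)
  expect_false(identical(a$cof$cof, c_$cof$cof))
})

test_that("paired limbs share the animal effect", {
  ds <- generate_study(seed = 8)
  base <- ds$cof[ds$cof$cumulative_loading_h == 0 & ds$cof$timepoint_id == 1, ]
  m <- aggregate(cof ~ animal_id + limb, data = base, FUN = mean)
  w <- reshape(m, idvar = "animal_id", timevar = "limb", direction = "wide")
  expect_gt(cor(w$cof.experimental, w$cof.control), 0.5)
})

test_that("generated study is calibrated to the group anchors", {
  nrep <- 200
  targets_base <- c("Prg4+/+" = 0.036, "Prg4+/-" = 0.030, "Prg4-/-" = 0.077)
  targets_final <- c("Prg4+/+" = 0.061, "Prg4+/-" = 0.12, "Prg4-/-" = 0.13)
  sums <- withr::with_seed(31, {
    reps <- lapply(seq_len(nrep), function(r)
      calibration_summary(generate_study(seed = sample.int(2^30, 1))))
    do.call(rbind, reps)
  })
  for (g in names(targets_base)) {
    base <- mean(sums$generated[sums$genotype == g &
                                  sums$quantity == "baseline_mean"])
    fin <- mean(sums$generated[sums$genotype == g &
                                 sums$quantity == "final_mean"])
    expect_lt(abs(base / targets_base[[g]] - 1), 0.05)
    expect_lt(abs(fin / targets_final[[g]] - 1), 0.10)
  }
})

test_that("histology scores respect the consensus scale and its ceilings", {
  hs <- generate_histology(seed = 41)
  expect_true(all(hs$score >= 0))
  expect_true(all(hs$score * 2 == round(hs$score * 2)))   # 0.5 steps
  for (cat_name in c("structure", "surface", "safranin")) {
    mx <- c(structure = 4, surface = 3, safranin = 4)[[cat_name]]
    expect_true(all(hs$score[hs$category == cat_name] <= mx))
  }
  expect_identical(nrow(hs), 36L * 2L * 2L * 3L)

  # zero-spread profiles round the wild-type structure mean (0.21) to 0
  sp <- default_score_profiles()
  sp$sd <- 1e-12
  h0 <- generate_histology(score_profiles = sp, seed = 42)
  wt_exp_structure <- h0$score[h0$genotype == "Prg4+/+" &
                                 h0$limb == "experimental" &
                                 h0$category == "structure"]
  expect_true(all(wt_exp_structure == 0))
})

test_that("histology cell means are calibrated to their profile anchors", {
  sp <- default_score_profiles()
  nrep <- 200
  ok <- withr::with_seed(51, {
    hits <- matrix(FALSE, nrep, nrow(sp))
    for (r in seq_len(nrep)) {
      hs <- generate_histology(seed = sample.int(2^30, 1))
      joint <- aggregate(score ~ genotype + limb + category + animal_id,
                         data = hs, FUN = mean)
      cm <- aggregate(score ~ genotype + limb + category, data = joint,
                      FUN = mean)
      m <- merge(sp, cm, by = c("genotype", "limb", "category"))
      hits[r, ] <- abs(m$score - m$mean) <= 3 * m$sd / sqrt(12)
    }
    colMeans(hits)
  })
  expect_true(all(ok >= 0.95))
})

test_that("physics fidelity runs the full measurement chain per trial", {
  sch <- default_schedule()
  design <- study_design(
    n_per_genotype = 1,
    experimental_timepoints = sch$experimental[c(1, 16), ],
    control_timepoints = sch$control,
    trials_per_measurement = 2)
  out <- withr::local_tempdir()
  ds <- generate_study(design, fidelity = "physics", seed = 61,
                       out_dir = out)
  n_expected <- 3L * 1L * (2L + 2L) * 2L
  expect_identical(nrow(ds$cof), n_expected)
  expect_identical(length(list.files(out, pattern = "\\.csv$")), n_expected)
  # each physics trial lands near its genotype truth despite marker noise
  truth <- ifelse(ds$cof$limb == "control" | ds$cof$cumulative_loading_h == 0,
                  vapply(ds$cof$genotype, function(g)
                    default_profiles()[[g]]$baseline_mean, numeric(1)),
                  vapply(ds$cof$genotype, function(g)
                    default_profiles()[[g]]$final_mean, numeric(1)))
  expect_true(all(abs(ds$cof$cof / truth - 1) < 0.75))
  expect_true(all(ds$cof$cof > 0))
})
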
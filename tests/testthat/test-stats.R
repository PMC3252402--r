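test_that("plateau aggregation averages categories and sums the total", {
  hs <- aggregate_histology(plateau_df(c(2, 2), c(2, 2.5), c(1, 1)))
  expect_equal(hs$structure, 2)
  expect_equal(hs$surface, 2.25)
  expect_equal(hs$safranin, 1)
  expect_equal(hs$total, 5.25)

  expect_equal(aggregate_histology(
    plateau_df(c(0, 0), c(0, 0), c(0, 0)))$total, 0)

  ceiling_score <- aggregate_histology(plateau_df(c(4, 4), c(3, 3), c(4, 4)))
  expect_identical(ceiling_score$total, 11)

  # idempotence: aggregating per-joint scores returns them unchanged
  once <- plateau_df(1.5, 2, 0.5)
  w <- capture_warnings(again <- aggregate_histology(once))
  expect_length(w, 3)
  expect_match(w, "one plateau", all = TRUE)
  expect_equal(unclass(again)[c("structure", "surface", "safranin")],
               list(structure = 1.5, surface = 2, safranin = 0.5))

  expect_error(aggregate_histology(plateau_df(c(5, 1), c(1, 1), c(1, 1))),
               class = "validation_error")
  expect_error(aggregate_histology(plateau_df(c(1, 1), c(1, 1), numeric(0))),
               class = "validation_error")
})

test_that("the mixed model recovers the baseline genotype log-ratio", {
  ds <- generate_study(seed = 1)
  eff <- fit_cof_mixed_model(ds)
  expect_false(eff$singular)
  row <- eff$contrasts[eff$contrasts$contrast == "Prg4-/- - Prg4+/+" &
                         eff$contrasts$at == "baseline", ]
  expect_identical(nrow(row), 1L)
  expect_lt(abs(row$estimate - log(0.077 / 0.036)), 2 * row$se)
  expect_lt(row$p, 0.001)
  # variance components are reported and non-negative
  expect_true(all(eff$varcomp$vcov >= 0))
  expect_true(all(eff$contrasts$p >= 0 & eff$contrasts$p <= 1))
})

test_that("a degenerate zero-noise dataset flags the singular fit", {
  ds <- generate_study(profiles = noiseless_profiles(), seed = 2)
  expect_message(eff <- fit_cof_mixed_model(ds), "singular")
  expect_true(eff$singular)
})

test_that("non-positive friction values are rejected by the model stage", {
  ds <- generate_study(seed = 3)
  ds$cof$cof[5] <- 0
  expect_error(fit_cof_mixed_model(ds), class = "validation_error")
})

test_that("balanced two-way ANOVA decomposes the total sum of squares", {
  ds <- generate_study(seed = 4)
  an <- anova_histology(ds)
  joints <- ds$histology
  joint <- aggregate(score ~ animal_id + genotype + limb + category,
                     data = joints, FUN = mean)
  totals <- aggregate(score ~ animal_id + genotype + limb, data = joint,
                      FUN = sum)
  for (r in c("structure", "total")) {
    tab <- an$tables[[r]]
    y <- if (r == "total") totals$score
         else joint$score[joint$category == r]
    expect_equal(sum(tab[["Sum Sq"]]), sum((y - mean(y))^2),
                 tolerance = 1e-8)
  }
  # Table-layout cell stats cover all 3 x 2 cells for all four responses
  expect_identical(nrow(an$cell_stats), 4L * 6L)
})

test_that("histology ANOVA has power for the structure genotype effect", {
  nrep <- 200
  pvals <- withr::with_seed(71, vapply(seq_len(nrep), function(r) {
    hs <- generate_histology(seed = sample.int(2^30, 1))
    ds <- structure(list(histology = hs), class = "study_dataset")
    an <- anova_histology(ds)
    an$tables$structure["genotype", "Pr(>F)"]
  }, numeric(1)))
  expect_gte(mean(pvals < 0.001), 0.95)
})

test_that("histology ANOVA keeps its size under the null", {
  sp <- default_score_profiles()
  sp$mean <- 1.2
  sp$sd <- 0.6
  nrep <- 400
  pvals <- withr::with_seed(72, vapply(seq_len(nrep), function(r) {
    hs <- generate_histology(score_profiles = sp, seed = sample.int(2^30, 1))
    ds <- structure(list(histology = hs), class = "study_dataset")
    anova_histology(ds)$tables$total["genotype", "Pr(>F)"]
  }, numeric(1)))
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.09)
})

test_that("degenerate factorial layouts are rejected", {
  ds <- generate_study(seed = 5)
  only_exp <- ds$histology[ds$histology$limb == "experimental", ]
  expect_error(anova_histology(structure(list(histology = only_exp),
                                         class = "study_dataset")),
               class = "validation_error")
  one_cell_gone <- ds$histology[!(ds$histology$genotype == "Prg4-/-" &
                                    ds$histology$limb == "control"), ]
  expect_error(anova_histology(structure(list(histology = one_cell_gone),
                                         class = "study_dataset")),
               class = "empty_cell_error")
  single <- ds$histology[ds$histology$animal_id %in%
                           unique(ds$histology$animal_id[
                             !duplicated(ds$histology$genotype)]), ]
  expect_error(anova_histology(structure(list(histology = single),
                                         class = "study_dataset")),
               class = "validation_error")
})

test_that("friction and histology are uncorrelated when independent", {
  # identical score profiles across genotypes: scores carry no friction
  # information by construction
  sp <- default_score_profiles()
  sp$mean <- 1.2
  sp$sd <- 0.6
  nrep <- 100
  res <- withr::with_seed(73, vapply(seq_len(nrep), function(r) {
    ds <- generate_study(seed = sample.int(2^30, 1), score_profiles = sp)
    ov <- correlate_cof_histology(ds)
    ov <- ov[ov$stratum == "overall", ]
    abs(ov$rho) < 0.4 && ov$p > 0.05
  }, logical(1)))
  expect_gte(mean(res), 0.90)
})

test_that("a perfectly monotone pairing gives rho = 1", {
  ds <- generate_study(seed = 6)
  joints <- unique(ds$cof[, c("animal_id", "genotype", "limb")])
  fin <- ds$cof[ds$cof$wallclock_h == 38, ]
  fin <- aggregate(cof ~ animal_id + limb, data = fin, FUN = mean)
  # rebuild histology so each joint's scores rank exactly as its final CoF
  ranks <- rank(fin$cof, ties.method = "first")
  key <- paste(fin$animal_id, fin$limb)
  ds$histology$score <- 3 * ranks[match(
    paste(ds$histology$animal_id, ds$histology$limb), key)] / max(ranks)
  ov <- correlate_cof_histology(ds)
  expect_equal(ov$rho[ov$stratum == "overall"], 1, tolerance = 1e-12)

  # constant scores are flagged, not tested
  ds$histology$score <- 1
  flat <- correlate_cof_histology(ds)
  expect_identical(flat$flag[flat$stratum == "overall"], "undefined")
})
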
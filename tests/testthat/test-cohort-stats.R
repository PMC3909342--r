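test_that("percentage differences behave as 100 * (MRI - CT) / CT", {
  expect_equal(percent_diff(60, 60), 0)
  expect_equal(percent_diff(102, 100), 2)
  for (ct in c(0.5, 30, 78)) {
    expect_equal(percent_diff(0.98 * ct, ct), -2)
  }
  expect_error(percent_diff(5, 0), "degenerate")
})

test_that("summaries use the n-1 SD and a 2-SD half-width, permutation invariant", {
  d <- tibble::tibble(
    diagnosis = "Prostate", structure = "PTV", dvh_point = "D_median",
    modality = "MRI_u", pct_diff = c(1, 2, 3)
  )
  s <- summarize_diffs(d)
  expect_equal(s$mean_pct, 2)
  expect_equal(s$sd_pct, 1)
  expect_equal(s$half_width_2sd, 2)

  s0 <- summarize_diffs(dplyr::mutate(d, pct_diff = c(2, 2, 2)))
  expect_equal(s0$mean_pct, 2)
  expect_equal(s0$half_width_2sd, 0)

  sp <- summarize_diffs(dplyr::mutate(d, pct_diff = c(3, 1, 2)))
  expect_equal(sp$mean_pct, s$mean_pct)
  expect_equal(sp$sd_pct, s$sd_pct)

  expect_error(summarize_diffs(d[1, ]), "at least 2")
})

test_that("summary labels render in the 'mean ± 2SD' report format", {
  expect_equal(format_pm(1.3, 1.4), "1.3 ± 1.4")
  expect_equal(format_pm(-0.25, 1.96), "-0.2 ± 2.0")
  d <- tibble::tibble(diagnosis = "g", structure = "s", dvh_point = "p",
                      modality = "m", pct_diff = c(0.6, 1.3, 2.0))
  expect_equal(summarize_diffs(d)$label, "1.3 ± 1.4")
})

test_that("one-way ANOVA matches the hand sum-of-squares example and edge cases", {
  an <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(an$F, 3)
  expect_equal(an$df_between, 2L)
  expect_equal(an$df_within, 6L)
  expect_equal(an$p, stats::pf(3, 2, 6, lower.tail = FALSE))

  eq <- one_way_anova(list(a = c(1, 3), b = c(0, 4), c = c(-1, 5)))
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)

  degen <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_identical(degen$flag, "zero_within_variance")
  expect_equal(degen$p, 0)

  ident <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_identical(ident$flag, "all_identical")
  expect_true(is.nan(ident$F))

  expect_error(one_way_anova(list(a = 1:3)), "two groups")
  expect_error(one_way_anova(list(a = 1, b = 1:3)), "two observations")
})

test_that("ANOVA agrees with the stats::aov reference on random datasets", {
  withr::local_seed(99)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:12, 1), mean = rnorm(1)))
    names(groups) <- paste0("g", seq_len(k))
    an <- one_way_anova(groups)
    df <- data.frame(y = unlist(groups),
                     f = factor(rep(names(groups), lengths(groups))))
    ref <- summary(stats::aov(y ~ f, df))[[1]]
    expect_equal(an$F, ref[["F value"]][1], tolerance = 1e-8)
    expect_equal(an$p, ref[["Pr(>F)"]][1], tolerance = 1e-8)
  }
})

test_that("ANOVA F is invariant under shift and positive scaling", {
  withr::local_seed(12)
  groups <- lapply(1:3, function(i) rnorm(8, i))
  f0 <- one_way_anova(groups)$F
  expect_equal(one_way_anova(lapply(groups, function(x) x + 17))$F, f0)
  expect_equal(one_way_anova(lapply(groups, function(x) x * 3.5))$F, f0)
})

test_that("Tukey HSD agrees with stats::TukeyHSD and the two-group t-test identity", {
  withr::local_seed(17)
  for (rep in 1:40) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(4:10, 1), mean = rnorm(1)))
    names(groups) <- paste0("g", seq_len(k))
    tk <- tukey_hsd(groups)
    df <- data.frame(y = unlist(groups),
                     f = factor(rep(names(groups), lengths(groups))))
    ref <- stats::TukeyHSD(stats::aov(y ~ f, df))$f
    key <- paste(tk$group2, tk$group1, sep = "-")
    expect_equal(tk$mean_diff, unname(ref[key, "diff"]), tolerance = 1e-8)
    expect_equal(tk$ci_low, unname(ref[key, "lwr"]), tolerance = 1e-6)
    expect_equal(tk$ci_high, unname(ref[key, "upr"]), tolerance = 1e-6)
    expect_equal(tk$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-3)
  }

  # two groups: adjusted p equals the pooled-variance t-test p (q = t * sqrt(2))
  g2 <- list(a = rnorm(9, 0), b = rnorm(7, 0.8))
  tk2 <- tukey_hsd(g2)
  tt <- stats::t.test(g2$b, g2$a, var.equal = TRUE)
  expect_equal(tk2$p_adj, tt$p.value, tolerance = 1e-9)
})

test_that("Tukey adjusted p is conservative relative to unadjusted pairwise t-tests", {
  withr::local_seed(23)
  # the unadjusted counterpart shares the pooled within-group variance and
  # its df; slack 2e-3 covers the ~4-digit accuracy of ptukey near p = 1
  for (rep in 1:20) {
    groups <- lapply(1:3, function(i) rnorm(7, rnorm(1)))
    names(groups) <- paste0("g", 1:3)
    tk <- tukey_hsd(groups)
    an <- one_way_anova(groups)
    msw <- an$ss_within / an$df_within
    for (j in seq_len(nrow(tk))) {
      n1 <- length(groups[[tk$group1[j]]]); n2 <- length(groups[[tk$group2[j]]])
      tstat <- abs(tk$mean_diff[j]) / sqrt(msw * (1 / n1 + 1 / n2))
      p_unadj <- 2 * stats::pt(tstat, an$df_within, lower.tail = FALSE)
      expect_gte(tk$p_adj[j] + 2e-3, p_unadj)
    }
  }
})

test_that("identical groups give zero differences and p_adj 1", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  tk <- tukey_hsd(g)
  expect_true(all(tk$mean_diff == 0))
  expect_true(all(tk$p_adj > 1 - 1e-12))
})

test_that("assumption checks pass at roughly 1 - alpha under the null", {
  withr::local_seed(31)
  nrep <- 400
  norm_pass <- homog_pass <- logical(nrep)
  for (i in seq_len(nrep)) {
    groups <- lapply(1:3, function(j) rnorm(15))
    rep_out <- check_assumptions(groups)
    norm_pass[i] <- all(rep_out$normality$pass)
    homog_pass[i] <- rep_out$homogeneity$pass
  }
  # per-group Shapiro at alpha 0.05, three groups: all-pass rate ~ 0.95^3
  expect_equal(mean(norm_pass), 0.95^3, tolerance = 0.05)
  expect_equal(mean(homog_pass), 0.95, tolerance = 0.05)
})

test_that("assumption checks flag a grossly heteroscedastic group", {
  withr::local_seed(37)
  fails <- vapply(1:60, function(i) {
    groups <- list(a = rnorm(50, sd = 1), b = rnorm(50, sd = 1),
                   c = rnorm(50, sd = sqrt(10)))
    !check_assumptions(groups)$homogeneity$pass
  }, logical(1))
  expect_gt(mean(fails), 0.9)
})

test_that("constant data is reported as not assessable", {
  out <- check_assumptions(list(a = c(2, 2, 2), b = c(3, 3, 3)))
  expect_false(out$assessable$normality)
  expect_false(out$assessable$homogeneity)
})

test_that("Levene statistic matches the car reference implementation", {
  skip_if_not_installed("car")
  withr::local_seed(41)
  groups <- lapply(1:3, function(i) rnorm(12, sd = i))
  names(groups) <- paste0("g", 1:3)
  mine <- check_assumptions(groups)$homogeneity
  df <- data.frame(y = unlist(groups),
                   f = factor(rep(names(groups), lengths(groups))))
  ref <- car::leveneTest(y ~ f, df, center = stats::median)
  expect_equal(mine$F, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(mine$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("power: null case equals alpha, frozen worked example, monotone in n and effect", {
  expect_equal(power_mean_difference(60, 1, 0, 21), 0.05, tolerance = 1e-10)
  # frozen noncentral-t oracle value for the one-sample design at
  # baseline 1.94 Gy, sd 0.03 Gy, detectable 2%, n = 21, alpha 0.05
  expect_equal(power_mean_difference(1.94, 0.03, 2, 21), 0.999876004415,
               tolerance = 1e-9)
  # matches power.t.test as an independent reference
  ref <- stats::power.t.test(n = 21, delta = 1.94 * 0.02, sd = 0.03,
                             type = "one.sample")$power
  expect_equal(power_mean_difference(1.94, 0.03, 2, 21), ref, tolerance = 1e-6)
  # power.t.test drops the opposite-tail rejection term (~1e-4 here); the
  # exact two-sided power is slightly larger
  ref2 <- stats::power.t.test(n = 15, delta = 0.5, sd = 1, type = "two.sample")$power
  mine2 <- power_mean_difference(100, 1, 0.5, 15, design = "two_sample")
  expect_gte(mine2, ref2)
  expect_equal(mine2, ref2, tolerance = 5e-3)

  ns <- c(5, 10, 20, 40, 80)
  pw_n <- vapply(ns, function(n) power_mean_difference(60, 2, 1, n), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  effs <- c(0.2, 0.5, 1, 2)
  pw_e <- vapply(effs, function(e) power_mean_difference(60, 2, e, 12), numeric(1))
  expect_true(all(diff(pw_e) > 0))
})

test_that("analyze_cohort on a CT-identical table gives 0 ± 0 and F = 0", {
  withr::local_seed(43)
  base <- tidyr::expand_grid(
    patient_id = sprintf("p%02d", 1:8),
    diagnosis = "Prostate", structure = "PTV",
    dvh_point = c("D_median", "D_2%"),
    modality = c("CT", "MRI_u", "MRI_b")
  )
  # per-patient values vary, but all modalities equal CT exactly
  vals <- tibble::tibble(patient_id = sprintf("p%02d", 1:8),
                         pv = 60 + rnorm(8))
  cohort <- dplyr::left_join(base, vals, by = "patient_id") |>
    dplyr::mutate(value = pv, unit = "Gy") |>
    dplyr::select(-"pv")
  res <- analyze_cohort(cohort)
  expect_true(all(res$summaries$mean_pct == 0))
  expect_true(all(res$summaries$half_width_2sd == 0))
  expect_true(all(res$anova$F == 0))
  expect_true(all(!res$anova$significant))
  expect_equal(nrow(res$tukey), 0L)
})

test_that("analyze_cohort recovers simulated group means and flags real shifts", {
  tab <- simulate_cohort(seed = 314)
  res <- analyze_cohort(tab)
  ref <- reference_summaries()
  joined <- dplyr::inner_join(
    res$summaries, ref,
    by = c("diagnosis", "structure", "dvh_point", "modality"),
    suffix = c("", "_ref")
  )
  expect_equal(nrow(joined), nrow(ref))
  # recovered means within 3 SD/sqrt(n) of the generating means (allow a few
  # of the 68 cells at the boundary)
  z_ok <- abs(joined$mean_pct - joined$mean_pct_ref) <=
    3 * joined$sd_pct_ref / sqrt(joined$n_ref) + 1e-12
  expect_gt(mean(z_ok), 0.95)
  # the prostate unit-density D_median shift (+1.3%) is a real, detectable
  # effect: its ANOVA across CT/MRI_u/MRI_b is significant
  an <- dplyr::filter(res$anova, diagnosis == "Prostate", structure == "PTV",
                      dvh_point == "D_median")
  expect_true(an$significant)
  expect_gt(nrow(res$tukey), 0L)
})

test_that("stratification splits structures and drops undersized strata", {
  withr::local_seed(47)
  cohort <- tidyr::expand_grid(
    patient_id = sprintf("p%02d", 1:5),
    diagnosis = "Prostate", structure = "Rectum",
    dvh_point = "D_10%", modality = c("CT", "MRI_u")
  ) |>
    dplyr::mutate(
      dose_level = ifelse(patient_id <= "p04", "high", "low"),
      value = 50 + rnorm(dplyr::n()), unit = "Gy"
    )
  expect_warning(res <- analyze_cohort(cohort, stratify_by = "dose_level"),
                 "fewer than 2")
  expect_true(all(grepl("\\[high\\]", res$summaries$structure)))
  expect_false(any(grepl("\\[low\\]", res$summaries$structure)))
})

test_that("tidiers return the documented shapes", {
  an <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  td <- tidy(an)
  expect_equal(td$term, c("between", "within"))
  expect_equal(td$statistic[1], 3)
  gl <- glance(an)
  expect_equal(gl$n_total, 9L)

  tk <- tukey_hsd(list(a = rnorm(5), b = rnorm(5)))
  expect_named(tidy(tk),
               c("contrast", "estimate", "conf.low", "conf.high", "adj.p.value"))

  res <- analyze_cohort(simulate_cohort(seed = 2))
  expect_identical(tidy(res), res$summaries)
  expect_equal(glance(res)$n_cells, nrow(res$summaries))
})
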
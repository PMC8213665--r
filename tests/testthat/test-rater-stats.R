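test_that("confusion counts partition episodes for each task", {
  cohort <- simulate_test_cohort(seed = 12)
  gold <- tibble::tibble(scan_id = cohort$subject_id, group = cohort$group)

  # a rater who calls everything abnormal
  all_abn <- tibble::tibble(
    rater_id = "R", experience = "consultant", scan_id = gold$scan_id,
    condition = "with_report", normality_call = "abnormal",
    diagnosis_call = "AD", confidence_normality = 3, confidence_diagnosis = 3
  )
  cc <- confusion_counts(all_abn, gold, task = "volume_loss")
  expect_equal(cc$tp, 30); expect_equal(cc$fp, 15)
  expect_equal(cc$tn, 0); expect_equal(cc$fn, 0)

  # a perfect rater
  perfect <- all_abn %>%
    dplyr::mutate(
      normality_call = ifelse(gold$group == "control", "normal", "abnormal"),
      diagnosis_call = ifelse(gold$group == "control", "none", gold$group)
    )
  cp <- confusion_counts(perfect, gold, task = "volume_loss")
  expect_equal(unlist(cp[, c("tp", "tn", "fp", "fn")]),
               c(tp = 30, tn = 15, fp = 0, fn = 0))

  # the AD-vs-normal task restricts to AD patients and controls: 16 + 15
  ca <- confusion_counts(perfect, gold, task = "AD_vs_normal")
  expect_equal(ca$tp + ca$tn + ca$fp + ca$fn, 31)

  expect_error(confusion_counts(all_abn, gold[-1, ], task = "volume_loss"),
               "missing from gold")
})

test_that("metric triple matches its defining ratios", {
  expect_equal(metric_triple(tibble::tibble(tp = 12, tn = 0, fp = 1, fn = 4))$sensitivity, 75)
  expect_equal(metric_triple(tibble::tibble(tp = 30, tn = 15, fp = 0, fn = 0))$accuracy, 100)
  expect_equal(round(metric_triple(tibble::tibble(tp = 9, tn = 23, fp = 4, fn = 9))$accuracy, 1),
               71.1)
  # zero denominator flags the metric as undefined rather than crashing
  und <- metric_triple(tibble::tibble(tp = 0, tn = 5, fp = 2, fn = 0))
  expect_true(is.na(und$sensitivity))
  expect_false(is.na(und$specificity))
})

test_that("metric triple equals an exhaustive per-episode recount", {
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
      call <- sample(c(TRUE, FALSE), n, replace = TRUE)
      counts <- tibble::tibble(
        tp = sum(truth & call), tn = sum(!truth & !call),
        fp = sum(!truth & call), fn = sum(truth & !call)
      )
      mt <- metric_triple(counts)
      # oracle: direct episode loops
      acc <- mean(truth == call) * 100
      sens <- if (any(truth)) mean(call[truth]) * 100 else NA_real_
      spec <- if (any(!truth)) mean(!call[!truth]) * 100 else NA_real_
      expect_equal(mt$accuracy, acc)
      expect_equal(mt$sensitivity, sens)
      expect_equal(mt$specificity, spec)
    }
  })
})

test_that("group aggregation averages group means, not raters, for the combined row", {
  per <- tibble::tibble(
    experience = rep(c("consultant", "registrar", "analyst"), each = 3),
    condition = "without_report",
    value = c(70, 68, 68.7, 75, 76, 75.5, 60, 70, 80)
  )
  agg <- aggregate_group_metrics(per, value_col = "value")
  combined <- agg$mean[agg$experience == "all_combined"]
  group_means <- agg$mean[agg$experience != "all_combined"]
  expect_equal(combined, mean(group_means))
  # unweighted: unequal groups still count equally
  uneq <- dplyr::bind_rows(per, tibble::tibble(experience = "analyst",
                                               condition = "without_report",
                                               value = 80))
  agg2 <- aggregate_group_metrics(uneq, value_col = "value")
  expect_equal(agg2$mean[agg2$experience == "all_combined"],
               mean(agg2$mean[agg2$experience != "all_combined"]))
  # single group: combined equals that group's mean
  one <- aggregate_group_metrics(per[1:3, ], value_col = "value")
  expect_equal(one$mean[one$experience == "all_combined"],
               one$mean[one$experience == "consultant"])
  # SD uses the n-1 denominator
  expect_equal(agg$sd[agg$experience == "consultant"], sd(c(70, 68, 68.7)))
})

test_that("McNemar statistics match closed forms", {
  r <- mcnemar_test(5, 15, exact = FALSE)
  expect_equal(round(r$statistic, 2), 4.05)
  expect_equal(r$statistic, oracle_mcnemar_chisq(5, 15))

  expect_equal(mcnemar_test(10, 10, exact = FALSE, correct = FALSE)$statistic, 0)

  ex <- mcnemar_test(0, 8, exact = TRUE)
  expect_equal(round(ex$p_value, 4), 0.0078)
  expect_equal(ex$p_value, 2 * 0.5^8)

  # default method selection: exact below 25 discordant pairs
  expect_equal(mcnemar_test(5, 15)$method, "exact_binomial")
  expect_equal(mcnemar_test(15, 15)$method, "chisq_corrected")
  expect_true(is.na(mcnemar_test(0, 0)$p_value))

  # continuity correction can only shrink the statistic; exact p in [0,1]
  withr::with_seed(42, {
    for (i in 1:50) {
      b <- sample(0:30, 1); c <- sample(0:30, 1)
      if (b + c == 0) next
      corr <- mcnemar_test(b, c, exact = FALSE, correct = TRUE)$statistic
      raw <- mcnemar_test(b, c, exact = FALSE, correct = FALSE)$statistic
      expect_lte(corr, raw + 1e-12)
      p <- mcnemar_test(b, c, exact = TRUE)$p_value
      expect_gte(p, 0); expect_lte(p, 1)
      expect_equal(mcnemar_test(b, c, exact = FALSE, correct = FALSE)$statistic,
                   oracle_mcnemar_chisq(b, c, correct = FALSE))
    }
  })
})

test_that("paired t and Cohen's d reproduce hand-computed values", {
  # differences (5, 6, 6): mean 17/3, sd sqrt(1/3), t = mean/ (sd/sqrt(3))
  res <- paired_t_and_d(c(70, 72, 68), c(75, 78, 74))
  orc <- oracle_paired_t(c(70, 72, 68), c(75, 78, 74))
  expect_equal(res$t, orc$t)
  expect_equal(res$t, 17)  # (17/3) / (sqrt(1/3)/sqrt(3)) = 17
  expect_equal(res$p_value, orc$p)

  # pooled-SD d from summary statistics equivalent to means 68.9/80, SDs 5/10
  expect_equal((80 - 68.9) / sqrt((5^2 + 10^2) / 2), 1.404, tolerance = 1e-3)

  ident <- paired_t_and_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0); expect_equal(ident$cohens_d, 0)

  shift <- paired_t_and_d(c(1, 2, 3), c(3, 4, 5))
  expect_true(is.infinite(shift$t) && shift$t > 0)
  expect_equal(shift$p_value, 0)

  # the SD-of-differences convention is available as an option
  dd <- paired_t_and_d(c(70, 72, 68), c(75, 78, 74), d_method = "diff")
  expect_equal(dd$cohens_d, (17 / 3) / sqrt(1 / 3))
})

test_that("Cohen's kappa matches the chance-corrected formula", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1)

  # 2x2 agreement table a=20, b=5, c=10, d=10 over 45 items
  rater <- c(rep("abn", 20), rep("abn", 5), rep("nor", 10), rep("nor", 10))
  gold <- c(rep("abn", 20), rep("nor", 5), rep("abn", 10), rep("nor", 10))
  k <- cohens_kappa(rater, gold)
  expect_equal(round(k$kappa, 3), 0.308)
  expect_equal(k$p_o, 30 / 45)
  expect_equal(k$p_e, (25 * 30 + 20 * 15) / 45^2)

  # undefined when both sides are constant
  expect_true(is.na(cohens_kappa(rep("x", 4), rep("x", 4))$kappa))

  # property: equals the brute-force oracle and is relabel-invariant
  withr::with_seed(43, {
    for (i in 1:30) {
      n <- sample(8:40, 1)
      cats <- sample(2:3, 1)
      r <- sample(letters[1:cats], n, replace = TRUE)
      g <- sample(letters[1:cats], n, replace = TRUE)
      k1 <- cohens_kappa(r, g)$kappa
      if (is.na(k1)) next
      expect_equal(k1, oracle_kappa(r, g), tolerance = 1e-12)
      relabel <- c(a = "z", b = "q", c = "m")
      expect_equal(cohens_kappa(relabel[r], relabel[g])$kappa, k1,
                   tolerance = 1e-12)
      if (all(r == g)) expect_equal(k1, 1)
    }
  })
})

test_that("Cronbach's alpha matches its variance decomposition", {
  m <- cbind(c(1, 2, 1, 2), c(1, 1, 2, 2))
  expect_equal(cronbach_alpha(m), 0)

  two <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))  # perfectly correlated raters
  expect_equal(cronbach_alpha(two), 1)
  ident <- cbind(c(0, 1, 0, 1, 1), c(0, 1, 0, 1, 1), c(0, 1, 0, 1, 1))
  expect_equal(cronbach_alpha(ident), 1)

  expect_true(is.na(cronbach_alpha(cbind(c(1, 2), c(2, 1)))))  # zero total variance
})

test_that("ICC(3,1)/(3,k) match a brute-force two-way ANOVA", {
  m <- matrix(c(9, 6, 8, 7, 2, 1, 4, 1, 5, 3, 6, 2), nrow = 4)
  orc <- oracle_icc(m)
  got <- icc_two_way_mixed(m)
  expect_equal(got$icc_single, orc[["single"]], tolerance = 1e-12)
  expect_equal(got$icc_average, orc[["average"]], tolerance = 1e-12)

  ident <- cbind(c(1, 3, 5, 2), c(1, 3, 5, 2))
  got_id <- icc_two_way_mixed(ident)
  expect_equal(got_id$icc_single, 1)
  expect_equal(got_id$icc_average, 1)

  # ICC(3,k) >= ICC(3,1) whenever scans vary more than the error
  withr::with_seed(44, {
    for (i in 1:20) {
      mm <- matrix(rnorm(6 * 4, mean = rep(rnorm(6, sd = 2), 4)), nrow = 6)
      res <- icc_two_way_mixed(mm)
      if (res$ms_rows > res$ms_error) {
        expect_gte(res$icc_average, res$icc_single)
      }
      orc2 <- oracle_icc(mm)
      expect_equal(res$icc_single, orc2[["single"]], tolerance = 1e-10)
    }
  })
})

test_that("alpha equals ICC(3,k) (consistency form) algebraically", {
  withr::with_seed(45, {
    for (i in 1:20) {
      m <- matrix(rbinom(8 * 5, 1, 0.5), nrow = 8)
      a <- cronbach_alpha(m)
      icc <- icc_two_way_mixed(m)$icc_average
      if (is.na(a) || is.na(icc)) next
      expect_equal(a, icc, tolerance = 1e-10)
    }
  })
})

make_cells <- function(fun, n_per_group = 3) {
  grid <- tidyr::expand_grid(
    rater_id = sprintf("r%02d", seq_len(3 * n_per_group)),
    report = c("without_report", "with_report"),
    normality = c("normal", "abnormal"),
    correctness = c("correct", "incorrect")
  )
  grid$experience <- rep(c("consultant", "registrar", "analyst"),
                         each = 8 * n_per_group)
  grid$confidence <- fun(grid)
  grid
}

test_that("confidence ANOVA behaves on degenerate and constructed designs", {
  flat <- make_cells(function(g) rep(3, nrow(g)))
  res <- confidence_anova(flat)
  expect_true(all(res$F == 0))
  expect_true(all(res$p_value == 1))

  # additive report main effect over small cell noise: the report F must
  # dominate every within-rater interaction
  withr::with_seed(46, {
    add <- make_cells(function(g) {
      3 + 0.5 * (g$report == "with_report") +
        rep(rnorm(9, sd = 0.3), each = 8) + rnorm(nrow(g), sd = 0.05)
    })
  })
  res_add <- confidence_anova(add)
  orc <- oracle_mixed_anova(add)
  cmp <- merge(res_add, orc, by = "effect", suffixes = c("_pkg", "_orc"))
  expect_equal(cmp$F_pkg, cmp$F_orc, tolerance = 1e-8)
  expect_equal(cmp$partial_eta_sq_pkg, cmp$partial_eta_sq_orc, tolerance = 1e-8)
  rep_F <- res_add$F[res_add$effect == "report"]
  inter <- res_add$F[res_add$effect %in%
                       c("report x normality", "report x correctness",
                         "report x normality x correctness")]
  expect_gt(rep_F, 100 * max(inter))

  # doubling every confidence leaves F and partial eta^2 unchanged
  withr::with_seed(47, {
    noisy <- make_cells(function(g) runif(nrow(g), 1, 5))
  })
  doubled <- noisy; doubled$confidence <- 2 * doubled$confidence
  r1 <- confidence_anova(noisy); r2 <- confidence_anova(doubled)
  expect_equal(r1$F, r2$F, tolerance = 1e-10)
  expect_equal(r1$partial_eta_sq, r2$partial_eta_sq, tolerance = 1e-10)

  # missing cells are an error, not imputed
  expect_error(confidence_anova(noisy[-1, ]), "cell")
})

test_that("paired-design sample sizes match their approximations", {
  expect_equal(paired_t_sample_size(0.53, method = "normal_approx"), 28)
  expect_equal(paired_t_sample_size(0.8, method = "noncentral_t"), 15)
  expect_equal(paired_t_sample_size(0.8), oracle_paired_n(0.8))

  # monotone in d; noncentral-t n >= normal approximation - 1
  last <- Inf
  for (d in c(0.3, 0.45, 0.6, 0.8, 1.1)) {
    for (pw in c(0.8, 0.9)) {
      nt <- paired_t_sample_size(d, power = pw)
      na <- paired_t_sample_size(d, power = pw, method = "normal_approx")
      expect_gte(nt, na - 1)
    }
    n_here <- paired_t_sample_size(d)
    expect_lte(n_here, last)
    last <- n_here
  }
})

test_that("the full study analysis emits coherent tables on a tiny study", {
  res <- analyse_study(tiny_ratings(), tiny_gold())
  expect_named(res, c("metrics", "metric_summary", "mcnemar",
                      "kappa_volume_loss", "kappa_diagnosis",
                      "correct_diagnoses", "reliability", "confidence"))
  expect_equal(sort(unique(res$metrics$task)),
               sort(c("volume_loss", "AD_vs_normal", "FTD_vs_normal")))
  expect_equal(nrow(res$kappa_volume_loss$per_rater), 2)
  # two raters can't fill all eight confidence cells here
  expect_null(res$confidence)
  # per-rater kappas agree with direct computation for rater R1 without report
  r1 <- tiny_ratings() %>%
    dplyr::filter(rater_id == "R1", condition == "without_report")
  truth <- ifelse(tiny_gold()$group[match(r1$scan_id, tiny_gold()$scan_id)] ==
                    "control", "normal", "abnormal")
  expect_equal(
    res$kappa_volume_loss$per_rater$without_report[
      res$kappa_volume_loss$per_rater$rater_id == "R1"],
    oracle_kappa(r1$normality_call, truth)
  )
})
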
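#' Confusion counts per rater and condition
#'
#' Scores forced-choice ratings against the gold-standard diagnosis for
#' one of three tasks:
#' \describe{
#'   \item{`volume_loss`}{all scans; positives are patient scans (AD or
#'     FTD), a positive call is "abnormal".}
#'   \item{`AD_vs_normal`}{restricted to AD patients and controls; a
#'     positive call is abnormal-with-AD (strict, default) or any
#'     abnormal call (`convention = "abnormal_only"`).}
#'   \item{`FTD_vs_normal`}{symmetric with FTD.}
#' }
#' The strict convention requires the correct sub-diagnosis for a true
#' positive; how a, say, FTD-called AD scan should be scored is not
#' settled usage, so the convention is configurable.
#'
#' @param ratings A validated rating tibble ([read_ratings()]).
#' @param gold A tibble with columns `scan_id` and `group`
#'   (`control`/`AD`/`FTD`) covering every scan in `ratings`.
#' @param task One of `"volume_loss"`, `"AD_vs_normal"`, `"FTD_vs_normal"`.
#' @param convention `"strict"` or `"abnormal_only"` (differential tasks
#'   only).
#' @return A tibble with one row per rater x condition: `rater_id`,
#'   `experience`, `condition`, `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(ratings, gold,
                             task = c("volume_loss", "AD_vs_normal", "FTD_vs_normal"),
                             convention = c("strict", "abnormal_only")) {
  task <- match.arg(task)
  convention <- match.arg(convention)
  ratings <- validate_ratings(ratings)
  missing <- setdiff(unique(ratings$scan_id), gold$scan_id)
  if (length(missing) > 0) {
    abort(paste0("Scan(s) missing from gold standard: ", paste(missing, collapse = ", ")))
  }
  scored <- ratings %>%
    left_join(gold %>% select("scan_id", "group"), by = "scan_id")

  if (task == "volume_loss") {
    scored <- scored %>%
      mutate(truth = .data$group %in% c("AD", "FTD"),
             call = .data$normality_call == "abnormal")
  } else {
    disease <- if (task == "AD_vs_normal") "AD" else "FTD"
    scored <- scored %>%
      filter(.data$group %in% c(disease, "control")) %>%
      mutate(
        truth = .data$group == disease,
        call = if (convention == "strict") {
          .data$normality_call == "abnormal" & .data$diagnosis_call == disease
        } else {
          .data$normality_call == "abnormal"
        }
      )
  }
  scored %>%
    group_by(.data$rater_id, .data$experience, .data$condition) %>%
    summarise(
      tp = sum(.data$truth & .data$call),
      tn = sum(!.data$truth & !.data$call),
      fp = sum(!.data$truth & .data$call),
      fn = sum(.data$truth & !.data$call),
      .groups = "drop"
    )
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Appends the three signal-detection metrics, expressed as percentages:
#' accuracy = (TP+TN)/(TP+TN+FP+FN) x 100, sensitivity = TP/(TP+FN) x
#' 100, specificity = TN/(TN+FP) x 100. A zero denominator yields `NA`
#' for that metric (undefined, not an error).
#'
#' @param counts A tibble with columns `tp`, `tn`, `fp`, `fn` (e.g. from
#'   [confusion_counts()]).
#' @return `counts` with `sensitivity`, `specificity`, `accuracy` columns
#'   appended.
#' @export
metric_triple <- function(counts) {
  assert_cols(counts, c("tp", "tn", "fp", "fn"), "Confusion counts")
  if (any(counts$tp + counts$tn + counts$fp + counts$fn == 0)) {
    abort("Confusion counts must total at least one episode")
  }
  safe_ratio <- function(num, den) ifelse(den > 0, num / den * 100, NA_real_)
  counts %>%
    mutate(
      sensitivity = safe_ratio(.data$tp, .data$tp + .data$fn),
      specificity = safe_ratio(.data$tn, .data$tn + .data$fp),
      accuracy = safe_ratio(.data$tp + .data$tn,
                            .data$tp + .data$tn + .data$fp + .data$fn)
    )
}

#' Group means, SDs and the all-groups-combined row
#'
#' Summarises a per-rater metric by experience group: mean and SD
#' (denominator n-1) over the group's raters, plus an
#' `"all_combined"` row whose mean is the unweighted mean of the group
#' means (each experience level contributes equally regardless of group
#' size) and whose SD is taken over all raters pooled.
#'
#' @param per_rater A tibble with an `experience` column and the metric
#'   in `value_col`; any columns named in `by` (e.g. `condition`) are
#'   kept as grouping keys.
#' @param value_col Name of the metric column.
#' @param by Extra grouping columns, default `"condition"` if present.
#' @return A tibble of `experience` (including `"all_combined"`), the
#'   `by` keys, `mean` and `sd`.
#' @export
aggregate_group_metrics <- function(per_rater, value_col = "value",
                                    by = intersect("condition", names(per_rater))) {
  assert_cols(per_rater, c("experience", value_col), "Per-rater metrics")
  if (any(table(per_rater$experience) == 0) || nrow(per_rater) == 0) {
    abort("Every experience group must contain at least one rater")
  }
  groups <- per_rater %>%
    group_by(across(all_of(c(by, "experience")))) %>%
    summarise(mean = mean(.data[[value_col]]),
              sd = sd(.data[[value_col]]), .groups = "drop")
  combined <- groups %>%
    group_by(across(all_of(by))) %>%
    summarise(mean = mean(.data$mean), .groups = "drop") %>%
    mutate(experience = "all_combined")
  pooled_sd <- per_rater %>%
    group_by(across(all_of(by))) %>%
    summarise(sd = sd(.data[[value_col]]), .groups = "drop")
  combined <- if (length(by) > 0) {
    left_join(combined, pooled_sd, by = by)
  } else {
    mutate(combined, sd = pooled_sd$sd)
  }
  bind_rows(groups, combined) %>%
    select(all_of(by), "experience", "mean", "sd")
}

#' McNemar test for paired dichotomous outcomes
#'
#' Compares correct/incorrect calls across two paired conditions using
#' only the discordant pair counts: `b` (correct in the first condition
#' only) and `c` (correct in the second only). The default is the
#' continuity-corrected chi-squared statistic
#' \eqn{(|b-c|-1)^2/(b+c)} on 1 df; when `b + c < 25` (small discordant
#' counts, typical of reader studies this size) an exact two-sided
#' binomial test of `b` successes in `b + c` trials at probability 1/2
#' is used instead. Set `exact` explicitly to override.
#'
#' @param b,c Non-negative discordant counts.
#' @param exact `TRUE`/`FALSE` to force the exact binomial or the
#'   chi-squared form; `NULL` (default) picks exact when `b + c < 25`.
#' @param correct Apply the continuity correction in the chi-squared
#'   form? Default `TRUE`.
#' @return A one-row tibble: `b`, `c`, `method`, `statistic` (`NA` for
#'   the exact test), `p_value`. When `b + c == 0` the test is undefined
#'   and `p_value` is `NA`.
#' @export
mcnemar_test <- function(b, c, exact = NULL, correct = TRUE) {
  if (b < 0 || c < 0) abort("Discordant counts must be non-negative")
  if (b + c == 0) {
    return(tibble(b = b, c = c, method = "undefined",
                  statistic = NA_real_, p_value = NA_real_))
  }
  if (is.null(exact)) exact <- (b + c) < 25
  if (exact) {
    p <- binom.test(b, b + c, p = 0.5)$p.value
    tibble(b = b, c = c, method = "exact_binomial",
           statistic = NA_real_, p_value = p)
  } else {
    tab <- matrix(c(0, b, c, 0), nrow = 2)
    ht <- mcnemar.test(tab, correct = correct)
    tibble(b = b, c = c,
           method = if (correct) "chisq_corrected" else "chisq",
           statistic = unname(ht$statistic), p_value = ht$p.value)
  }
}

#' Paired t test with Cohen's d across two rating conditions
#'
#' The paired t test is computed on the per-rater differences. Cohen's d
#' uses the pooled-SD convention
#' \eqn{d = (\bar x_{with} - \bar x_{without}) / \sqrt{(s_1^2+s_2^2)/2}}
#' by default, which treats the two conditions' spreads symmetrically;
#' the SD-of-differences convention is available via `d_method`.
#'
#' @param x_without,x_with Per-rater metric values under the two
#'   conditions, paired by position (same rater order).
#' @param d_method `"pooled"` (default) or `"diff"` (mean difference /
#'   SD of differences).
#' @return A one-row tibble: `mean_without`, `mean_with`, `sd_without`,
#'   `sd_with`, `t`, `df`, `p_value`, `cohens_d`. When the differences
#'   have zero variance, `t` is 0 (identical vectors) or signed `Inf`
#'   (constant nonzero shift).
#' @export
paired_t_and_d <- function(x_without, x_with, d_method = c("pooled", "diff")) {
  d_method <- match.arg(d_method)
  if (length(x_without) != length(x_with) || length(x_with) < 2) {
    abort("Paired samples must have equal length >= 2")
  }
  diffs <- x_with - x_without
  s1 <- sd(x_without); s2 <- sd(x_with); sdiff <- sd(diffs)
  md <- mean(diffs)
  n <- length(diffs)
  # t.test() refuses near-constant differences; treat them as a constant
  # shift (infinite t) rather than crashing a whole study analysis
  near_constant <- sdiff <= 1e-10 * max(1, abs(md))
  if (near_constant) {
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    ht <- t.test(x_with, x_without, paired = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  pooled <- sqrt((s1^2 + s2^2) / 2)
  d <- switch(d_method,
    pooled = if (pooled == 0) 0 else md / pooled,
    diff = if (sdiff == 0) {
      if (md == 0) 0 else sign(md) * Inf
    } else md / sdiff
  )
  tibble(mean_without = mean(x_without), mean_with = mean(x_with),
         sd_without = s1, sd_with = s2,
         t = t_stat, df = n - 1, p_value = p, cohens_d = d)
}

#' Cohen's kappa against a gold standard
#'
#' Unweighted chance-corrected agreement
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} between one rater's labels and
#' the gold standard, where \eqn{p_o} is the observed agreement and
#' \eqn{p_e} the agreement expected from the two marginal label
#' distributions. Works for any label set: binary normal/abnormal for
#' volume-loss agreement, three-class normal/AD/FTD for diagnosis
#' agreement.
#'
#' @param rater_labels,gold_labels Equal-length label vectors.
#' @param categories Optional complete category set (ensures marginals
#'   cover unobserved labels; the kappa value is unaffected).
#' @return A one-row tibble: `kappa`, `p_o`, `p_e`, `n`. When both
#'   sides are constant and identical (`p_e = 1`), kappa is undefined
#'   and returned as `NA`.
#' @export
cohens_kappa <- function(rater_labels, gold_labels, categories = NULL) {
  if (length(rater_labels) != length(gold_labels) || length(rater_labels) < 1) {
    abort("Label vectors must have equal positive length")
  }
  if (is.null(categories)) {
    categories <- sort(unique(c(as.character(rater_labels),
                                as.character(gold_labels))))
  }
  r <- factor(rater_labels, levels = categories)
  g <- factor(gold_labels, levels = categories)
  if (anyNA(r) || anyNA(g)) abort("Labels outside the declared category set")
  n <- length(r)
  p_o <- mean(r == g)
  p_e <- sum(prop.table(table(r)) * prop.table(table(g)))
  kappa <- if (abs(1 - p_e) < 1e-12) NA_real_ else (p_o - p_e) / (1 - p_e)
  tibble(kappa = kappa, p_o = p_o, p_e = p_e, n = n)
}

#' Cronbach's alpha across raters
#'
#' Internal-consistency reliability with raters as items and scans as
#' cases: \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} where
#' \eqn{s_i^2} are the per-rater score variances and \eqn{s_T^2} the
#' variance of the per-scan score sums. For dichotomous
#' abnormal = 1 / normal = 0 codings this measures how consistently the
#' rater panel flags the same scans.
#'
#' @param score_matrix Numeric matrix, scans in rows, raters in columns
#'   (>= 2 of each).
#' @return Alpha as a single number; `NA` when the total score variance
#'   is zero (undefined).
#' @export
cronbach_alpha <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) abort("Need at least 2 scans and 2 raters")
  if (anyNA(m)) abort("Score matrix must be complete")
  k <- ncol(m)
  total_var <- var(rowSums(m))
  if (total_var == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Intraclass correlation, two-way mixed model, consistency form
#'
#' ICC(3,1) and ICC(3,k) from the mean squares of a two-way ANOVA
#' without interaction (scans as random rows, raters as fixed columns):
#' \eqn{ICC(3,1) = (MS_R - MS_E)/(MS_R + (k-1)MS_E)} for a single
#' rater's reliability and \eqn{ICC(3,k) = (MS_R - MS_E)/MS_R} for the
#' k-rater average. The consistency form (rather than absolute
#' agreement) ignores systematic rater strictness differences.
#'
#' @inheritParams cronbach_alpha
#' @return A one-row tibble: `icc_single`, `icc_average`, `ms_rows`,
#'   `ms_raters`, `ms_error`. Both ICCs are `NA` when the matrix is
#'   degenerate (no between-scan variance).
#' @export
icc_two_way_mixed <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) abort("Need at least 2 scans and 2 raters")
  if (anyNA(m)) abort("Score matrix must be complete")
  long <- data.frame(
    value = as.vector(m),
    scan = factor(rep(seq_len(nrow(m)), times = ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  # only the mean squares are used, so anova()'s perfect-fit F-test warning
  # (identical columns) is irrelevant here
  tab <- suppressWarnings(anova(lm(value ~ scan + rater, data = long)))
  ms_rows <- tab["scan", "Mean Sq"]
  ms_raters <- tab["rater", "Mean Sq"]
  ms_error <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  if (ms_rows == 0 && ms_error == 0) {
    single <- average <- NA_real_
  } else {
    single <- (ms_rows - ms_error) / (ms_rows + (k - 1) * ms_error)
    average <- if (ms_rows == 0) NA_real_ else (ms_rows - ms_error) / ms_rows
  }
  tibble(icc_single = single, icc_average = average,
         ms_rows = ms_rows, ms_raters = ms_raters, ms_error = ms_error)
}

#' Four-way mixed ANOVA of assessment confidence
#'
#' Analyses per-rater confidence cell means in a design with three
#' within-rater factors (report availability x scan normality x
#' correctness of the call, 2 x 2 x 2) and one between-rater factor
#' (experience level). Fits the classical repeated-measures
#' sums-of-squares partition (via `stats::aov` with an error stratum per
#' within-factor combination) and reports, per effect, the F ratio, its
#' df pair, the p value, and partial
#' \eqn{\eta^2 = SS_{effect}/(SS_{effect} + SS_{error})} using the error
#' term of the effect's own stratum.
#'
#' @param cell_means A tibble with one row per rater x within-cell:
#'   columns `rater_id`, `experience`, `report`
#'   (`with_report`/`without_report`), `normality` (`normal`/`abnormal`),
#'   `correctness` (`correct`/`incorrect`) and `confidence` (the cell
#'   mean on the 1-5 scale). All 8 cells must be present for every
#'   rater; missing cells are an error (no imputation).
#' @return A tibble with one row per effect: `effect`, `df1`, `df2`,
#'   `F`, `p_value`, `partial_eta_sq`.
#' @export
confidence_anova <- function(cell_means) {
  needed <- c("rater_id", "experience", "report", "normality",
              "correctness", "confidence")
  assert_cols(cell_means, needed, "Confidence cell means")
  counts <- cell_means %>% count(.data$rater_id)
  if (any(counts$n != 8) ||
      nrow(distinct(cell_means, .data$rater_id, .data$report,
                    .data$normality, .data$correctness)) != nrow(cell_means)) {
    abort("Each rater must contribute exactly one mean per 2x2x2 within-cell (missing cells are not imputed)")
  }
  dat <- cell_means %>%
    mutate(across(c("rater_id", "experience", "report", "normality",
                    "correctness"), factor))
  fit <- aov(confidence ~ report * normality * correctness * experience +
               Error(rater_id / (report * normality * correctness)),
             data = dat)
  strata <- summary(fit)
  # sums of squares below floating-point resolution of the data are treated
  # as exactly zero, so a constant design reports F = 0 rather than 0/0 noise
  ss_tol <- max(sum((dat$confidence - mean(dat$confidence))^2), 1) * 1e-12
  purrr::map_dfr(strata, function(s) {
    tab <- s[[1]]
    terms <- trimws(rownames(tab))
    resid_row <- which(terms == "Residuals")
    if (length(resid_row) == 0) return(tibble())
    ss_err <- tab[resid_row, "Sum Sq"]
    df_err <- tab[resid_row, "Df"]
    if (ss_err < ss_tol) ss_err <- 0
    eff <- setdiff(seq_len(nrow(tab)), resid_row)
    if (length(eff) == 0) return(tibble())
    ss_eff <- tab[eff, "Sum Sq"]
    ss_eff[ss_eff < ss_tol] <- 0
    f_val <- dplyr::case_when(
      ss_eff == 0 ~ 0,
      ss_err == 0 ~ Inf,
      TRUE ~ (ss_eff / tab[eff, "Df"]) / (ss_err / df_err)
    )
    tibble(
      effect = gsub(":", " x ", terms[eff]),
      df1 = tab[eff, "Df"],
      df2 = df_err,
      F = f_val,
      p_value = dplyr::case_when(
        ss_eff == 0 ~ 1,
        ss_err == 0 ~ 0,
        TRUE ~ pf(f_val, tab[eff, "Df"], df_err, lower.tail = FALSE)
      ),
      partial_eta_sq = ifelse(ss_eff == 0 & ss_err == 0, 0,
                              ss_eff / (ss_eff + ss_err))
    )
  })
}

#' Sample size for a paired t test
#'
#' Number of raters required to detect a standardised paired effect of
#' size `d` at two-sided level `alpha` with the target power. The
#' default iterates the noncentral-t power function
#' ([stats::power.t.test()], `type = "paired"`) and rounds up; the
#' normal approximation
#' \eqn{n = \lceil (z_{1-\alpha/2} + z_{1-\beta})^2 / d^2 \rceil}
#' is also available (slightly liberal at small n).
#'
#' @param d Standardised effect size (> 0), mean difference over SD of
#'   differences.
#' @param alpha Two-sided significance level.
#' @param power Target power in (0.5, 1).
#' @param method `"noncentral_t"` (default) or `"normal_approx"`.
#' @return Required number of pairs (raters), an integer.
#' @examples
#' paired_t_sample_size(0.53, method = "normal_approx")
#' @export
paired_t_sample_size <- function(d, alpha = 0.05, power = 0.80,
                                 method = c("noncentral_t", "normal_approx")) {
  method <- match.arg(method)
  if (d <= 0 || alpha <= 0 || alpha >= 1 || power <= 0.5 || power >= 1) {
    abort("Require d > 0, 0 < alpha < 1 and 0.5 < power < 1")
  }
  if (method == "normal_approx") {
    ceiling((qnorm(1 - alpha / 2) + qnorm(power))^2 / d^2)
  } else {
    ceiling(power.t.test(delta = d, sd = 1, sig.level = alpha, power = power,
                         type = "paired", alternative = "two.sided")$n)
  }
}

# Per-rater x condition kappa table with net changes and per-group paired
# tests; task = "volume_loss" (binary) or "diagnosis" (three-class).
kappa_table <- function(ratings, gold, task = c("volume_loss", "diagnosis")) {
  task <- match.arg(task)
  scored <- validate_ratings(ratings) %>%
    left_join(gold %>% select("scan_id", "group"), by = "scan_id")
  if (task == "volume_loss") {
    scored <- scored %>%
      mutate(call = ifelse(.data$normality_call == "abnormal", "abnormal", "normal"),
             truth = ifelse(.data$group %in% c("AD", "FTD"), "abnormal", "normal"))
    cats <- c("normal", "abnormal")
  } else {
    scored <- scored %>%
      mutate(call = ifelse(.data$normality_call == "normal", "normal",
                           .data$diagnosis_call),
             truth = ifelse(.data$group == "control", "normal", .data$group))
    cats <- c("normal", "AD", "FTD")
  }
  per <- scored %>%
    group_by(.data$rater_id, .data$experience, .data$condition) %>%
    summarise(kappa = cohens_kappa(.data$call, .data$truth,
                                   categories = cats)$kappa,
              .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "kappa") %>%
    mutate(net_change = .data$with_report - .data$without_report) %>%
    arrange(match(.data$experience, c("consultant", "registrar", "analyst")),
            .data$rater_id)
  group_p <- per %>%
    group_by(.data$experience) %>%
    summarise(p_value = if (n() >= 2) {
      paired_t_and_d(.data$without_report, .data$with_report)$p_value
    } else NA_real_, .groups = "drop")
  overall <- tibble(
    mean_without = mean(per$without_report), sd_without = sd(per$without_report),
    mean_with = mean(per$with_report), sd_with = sd(per$with_report),
    mean_net_change = mean(per$net_change),
    p_value = paired_t_and_d(per$without_report, per$with_report)$p_value
  )
  list(per_rater = per, group_p = group_p, overall = overall)
}

# Mean percentage of patient scans given the correct sub-diagnosis, per
# condition, averaged over raters.
correct_diagnosis_rate <- function(ratings, gold, disease) {
  validate_ratings(ratings) %>%
    left_join(gold %>% select("scan_id", "group"), by = "scan_id") %>%
    filter(.data$group == disease) %>%
    group_by(.data$rater_id, .data$condition) %>%
    summarise(pct = mean(.data$normality_call == "abnormal" &
                           .data$diagnosis_call == disease) * 100,
              .groups = "drop") %>%
    group_by(.data$condition) %>%
    summarise(mean = mean(.data$pct), sd = sd(.data$pct), .groups = "drop")
}

# Confidence cell means per rater: report x normality(truth) x correctness.
confidence_cell_means <- function(ratings, gold) {
  validate_ratings(ratings) %>%
    left_join(gold %>% select("scan_id", "group"), by = "scan_id") %>%
    mutate(
      normality = ifelse(.data$group %in% c("AD", "FTD"), "abnormal", "normal"),
      correctness = ifelse((.data$normality_call == "abnormal") ==
                             (.data$normality == "abnormal"),
                           "correct", "incorrect")
    ) %>%
    group_by(.data$rater_id, .data$experience, condition = .data$condition,
             normality = .data$normality, correctness = .data$correctness) %>%
    summarise(confidence = mean(.data$confidence_normality), .groups = "drop") %>%
    rename(report = "condition")
}

#' Full multi-rater study analysis
#'
#' Runs the complete statistical pipeline of a with/without-report
#' reader study: per-rater confusion counts and metric triples for the
#' volume-loss and AD/FTD differential tasks, group-level summaries with
#' paired t tests and Cohen's d, McNemar tests on pooled discordant
#' episodes, per-rater kappa tables (binary and three-class) with net
#' changes, correct sub-diagnosis percentages, Cronbach's alpha and
#' ICC(3,1)/(3,k) per condition, and (when every rater populates all
#' eight confidence cells) the four-way mixed confidence ANOVA.
#'
#' @inheritParams confusion_counts
#' @return A named list of tibbles: `metrics` (long per-rater metrics for
#'   all tasks), `metric_summary` (group x condition means/SDs with
#'   paired tests, one block per task and metric), `mcnemar` (per task),
#'   `kappa_volume_loss`, `kappa_diagnosis` (per-rater tables with group
#'   p values and the overall row), `correct_diagnoses` (AD and FTD),
#'   `reliability` (alpha + ICC per condition), `confidence` (ANOVA
#'   effects, or `NULL` when cells are incomplete).
#' @export
analyse_study <- function(ratings, gold, convention = c("strict", "abnormal_only")) {
  convention <- match.arg(convention)
  ratings <- validate_ratings(ratings)
  tasks <- c("volume_loss", "AD_vs_normal", "FTD_vs_normal")

  metrics <- purrr::map_dfr(tasks, function(tk) {
    confusion_counts(ratings, gold, task = tk, convention = convention) %>%
      metric_triple() %>%
      mutate(task = tk, .before = 1)
  })

  metric_long <- metrics %>%
    tidyr::pivot_longer(cols = c("sensitivity", "specificity", "accuracy"),
                        names_to = "metric", values_to = "value")

  metric_summary <- metric_long %>%
    group_by(.data$task, .data$metric) %>%
    dplyr::group_modify(function(df, key) {
      agg <- aggregate_group_metrics(df, value_col = "value", by = "condition")
      wide <- df %>%
        select("rater_id", "experience", "condition", "value") %>%
        tidyr::pivot_wider(names_from = "condition", values_from = "value")
      tests <- wide %>%
        group_by(.data$experience) %>%
        summarise(res = list(if (n() >= 2) {
          paired_t_and_d(.data$without_report, .data$with_report)
        } else {
          tibble(p_value = NA_real_, cohens_d = NA_real_)
        }), .groups = "drop") %>%
        tidyr::unnest("res") %>%
        select("experience", "p_value", "cohens_d")
      all_t <- if (nrow(wide) >= 2) {
        paired_t_and_d(wide$without_report, wide$with_report)
      } else {
        tibble(p_value = NA_real_, cohens_d = NA_real_)
      }
      tests <- bind_rows(tests, tibble(experience = "all_combined",
                                       p_value = all_t$p_value,
                                       cohens_d = all_t$cohens_d))
      agg %>%
        tidyr::pivot_wider(names_from = "condition",
                           values_from = c("mean", "sd")) %>%
        left_join(tests, by = "experience")
    }) %>%
    ungroup()

  mcnemar <- purrr::map_dfr(tasks, function(tk) {
    sc <- confusion_scored_correct(ratings, gold, tk, convention)
    disc <- sc %>%
      tidyr::pivot_wider(names_from = "condition", values_from = "correct") %>%
      summarise(b = sum(.data$without_report & !.data$with_report),
                c = sum(!.data$without_report & .data$with_report))
    mcnemar_test(disc$b, disc$c) %>% mutate(task = tk, .before = 1)
  })

  reliability <- purrr::map_dfr(c("without_report", "with_report"), function(cond) {
    m <- ratings %>%
      filter(.data$condition == cond) %>%
      mutate(score = as.numeric(.data$normality_call == "abnormal")) %>%
      select("scan_id", "rater_id", "score") %>%
      tidyr::pivot_wider(names_from = "rater_id", values_from = "score") %>%
      select(-"scan_id") %>%
      as.matrix()
    icc <- icc_two_way_mixed(m)
    tibble(condition = cond, cronbach_alpha = cronbach_alpha(m),
           icc_single = icc$icc_single, icc_average = icc$icc_average)
  })

  confidence <- tryCatch(
    confidence_anova(confidence_cell_means(ratings, gold)),
    error = function(e) NULL
  )

  list(
    metrics = metrics,
    metric_summary = metric_summary,
    mcnemar = mcnemar,
    kappa_volume_loss = kappa_table(ratings, gold, "volume_loss"),
    kappa_diagnosis = kappa_table(ratings, gold, "diagnosis"),
    correct_diagnoses = bind_rows(
      correct_diagnosis_rate(ratings, gold, "AD") %>% mutate(disease = "AD", .before = 1),
      correct_diagnosis_rate(ratings, gold, "FTD") %>% mutate(disease = "FTD", .before = 1)
    ),
    reliability = reliability,
    confidence = confidence
  )
}

# Episode-level correctness per task (paired over rater x scan), used for
# the McNemar discordant counts.
confusion_scored_correct <- function(ratings, gold, task, convention) {
  scored <- ratings %>%
    left_join(gold %>% select("scan_id", "group"), by = "scan_id")
  if (task == "volume_loss") {
    scored <- scored %>%
      mutate(correct = (.data$normality_call == "abnormal") ==
               (.data$group %in% c("AD", "FTD")))
  } else {
    disease <- if (task == "AD_vs_normal") "AD" else "FTD"
    scored <- scored %>%
      filter(.data$group %in% c(disease, "control")) %>%
      mutate(pos_call = if (convention == "strict") {
        .data$normality_call == "abnormal" & .data$diagnosis_call == disease
      } else {
        .data$normality_call == "abnormal"
      },
      correct = .data$pos_call == (.data$group == disease))
  }
  scored %>% select("rater_id", "scan_id", "condition", "correct")
}
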
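# Independent brute-force oracles for the rater statistics, written
# directly from first principles (loops and explicit mean subtractions)
# so they share no code path with the package implementations.

oracle_kappa <- function(rater, gold) {
  cats <- unique(c(rater, gold))
  n <- length(rater)
  p_o <- sum(rater == gold) / n
  p_e <- 0
  for (cat in cats) {
    p_e <- p_e + (sum(rater == cat) / n) * (sum(gold == cat) / n)
  }
  (p_o - p_e) / (1 - p_e)
}

oracle_alpha <- function(m) {
  k <- ncol(m)
  item_vars <- numeric(k)
  for (j in seq_len(k)) item_vars[j] <- var(m[, j])
  totals <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) totals[i] <- sum(m[i, ])
  k / (k - 1) * (1 - sum(item_vars) / var(totals))
}

# Two-way ANOVA mean squares by explicit sums over cells.
oracle_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m); col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  c(single = (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err),
    average = (ms_rows - ms_err) / ms_rows)
}

oracle_mcnemar_chisq <- function(b, c, correct = TRUE) {
  # the continuity correction only applies to asymmetric discordance:
  # at b == c the uncorrected statistic is already exactly 0
  if (correct && b != c) (abs(b - c) - 1)^2 / (b + c) else (b - c)^2 / (b + c)
}

oracle_paired_t <- function(x, y) {
  d <- y - x
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1))
}

# Brute-force mixed-ANOVA sums of squares for the 2x2x2 within
# (report, normality, correctness) x between (experience) design, via
# inclusion-exclusion over cell means. Returns F and partial eta^2 per
# effect, keyed like confidence_anova()'s `effect` column.
oracle_mixed_anova <- function(cells) {
  cells <- as.data.frame(cells)
  raters <- unique(cells$rater_id)
  N <- length(raters)
  exp_of <- sapply(raters, function(r) cells$experience[cells$rater_id == r][1])
  groups <- unique(exp_of)
  n_e <- table(factor(exp_of, levels = groups))
  G <- mean(cells$confidence)

  m_of <- function(...) {
    # mean of confidence within the named factor levels
    keep <- rep(TRUE, nrow(cells))
    sel <- list(...)
    for (nm in names(sel)) keep <- keep & cells[[nm]] == sel[[nm]]
    mean(cells$confidence[keep])
  }
  W <- list(report = unique(cells$report),
            normality = unique(cells$normality),
            correctness = unique(cells$correctness))

  ss <- list(); dfs <- list()
  # between: experience and rater-within-experience error
  ss$experience <- 8 * sum(n_e * sapply(groups, function(e) (m_of(experience = e) - G)^2))
  dfs$experience <- length(groups) - 1
  ss$err_between <- 8 * sum(sapply(raters, function(r) {
    (m_of(rater_id = r) - m_of(experience = exp_of[[r]]))^2
  }))
  dfs$err_between <- N - length(groups)

  # single within factors
  for (f in names(W)) {
    lv <- W[[f]]
    ss[[f]] <- 4 * N * sum(sapply(lv, function(a) {
      (do.call(m_of, stats::setNames(list(a), f)) - G)^2
    }))
    dfs[[f]] <- 1
    key_fe <- paste0(f, " x experience")
    ss[[key_fe]] <- 4 * sum(sapply(lv, function(a) {
      sum(n_e * sapply(groups, function(e) {
        (do.call(m_of, stats::setNames(list(a, e), c(f, "experience"))) -
           do.call(m_of, stats::setNames(list(a), f)) -
           m_of(experience = e) + G)^2
      }))
    }))
    dfs[[key_fe]] <- length(groups) - 1
    key_err <- paste0("err_", f)
    ss[[key_err]] <- 4 * sum(sapply(lv, function(a) {
      sum(sapply(raters, function(r) {
        e <- exp_of[[r]]
        (do.call(m_of, stats::setNames(list(a, r), c(f, "rater_id"))) -
           m_of(rater_id = r) -
           do.call(m_of, stats::setNames(list(a, e), c(f, "experience"))) +
           m_of(experience = e))^2
      }))
    }))
    dfs[[key_err]] <- N - length(groups)
  }

  # two-way within interactions
  pairs <- utils::combn(names(W), 2, simplify = FALSE)
  for (pr in pairs) {
    f1 <- pr[1]; f2 <- pr[2]
    key <- paste0(f1, " x ", f2)
    ss[[key]] <- 2 * N * sum(sapply(W[[f1]], function(a) {
      sum(sapply(W[[f2]], function(b) {
        (do.call(m_of, stats::setNames(list(a, b), c(f1, f2))) -
           do.call(m_of, stats::setNames(list(a), f1)) -
           do.call(m_of, stats::setNames(list(b), f2)) + G)^2
      }))
    }))
    dfs[[key]] <- 1
    key_e <- paste0(key, " x experience")
    ss[[key_e]] <- 2 * sum(sapply(W[[f1]], function(a) {
      sum(sapply(W[[f2]], function(b) {
        sum(n_e * sapply(groups, function(e) {
          (do.call(m_of, stats::setNames(list(a, b, e), c(f1, f2, "experience"))) -
             do.call(m_of, stats::setNames(list(a, b), c(f1, f2))) -
             do.call(m_of, stats::setNames(list(a, e), c(f1, "experience"))) -
             do.call(m_of, stats::setNames(list(b, e), c(f2, "experience"))) +
             do.call(m_of, stats::setNames(list(a), f1)) +
             do.call(m_of, stats::setNames(list(b), f2)) +
             m_of(experience = e) - G)^2
        }))
      }))
    }))
    dfs[[key_e]] <- length(groups) - 1
    key_err <- paste0("err_", key)
    ss[[key_err]] <- 2 * sum(sapply(W[[f1]], function(a) {
      sum(sapply(W[[f2]], function(b) {
        sum(sapply(raters, function(r) {
          e <- exp_of[[r]]
          (do.call(m_of, stats::setNames(list(a, b, r), c(f1, f2, "rater_id"))) -
             do.call(m_of, stats::setNames(list(a, r), c(f1, "rater_id"))) -
             do.call(m_of, stats::setNames(list(b, r), c(f2, "rater_id"))) +
             m_of(rater_id = r) -
             do.call(m_of, stats::setNames(list(a, b, e), c(f1, f2, "experience"))) +
             do.call(m_of, stats::setNames(list(a, e), c(f1, "experience"))) +
             do.call(m_of, stats::setNames(list(b, e), c(f2, "experience"))) -
             m_of(experience = e))^2
        }))
      }))
    }))
    dfs[[key_err]] <- N - length(groups)
  }

  # three-way within interaction by full inclusion-exclusion
  f1 <- "report"; f2 <- "normality"; f3 <- "correctness"
  ss3 <- 0
  for (a in W[[f1]]) for (b in W[[f2]]) for (cc in W[[f3]]) {
    ss3 <- ss3 + (do.call(m_of, stats::setNames(list(a, b, cc), c(f1, f2, f3))) -
      do.call(m_of, stats::setNames(list(a, b), c(f1, f2))) -
      do.call(m_of, stats::setNames(list(a, cc), c(f1, f3))) -
      do.call(m_of, stats::setNames(list(b, cc), c(f2, f3))) +
      do.call(m_of, stats::setNames(list(a), f1)) +
      do.call(m_of, stats::setNames(list(b), f2)) +
      do.call(m_of, stats::setNames(list(cc), f3)) - G)^2
  }
  key3 <- "report x normality x correctness"
  ss[[key3]] <- N * ss3
  dfs[[key3]] <- 1
  key3e <- paste0(key3, " x experience")
  # and its experience interaction + error by subtraction from the stratum total
  ss3e <- 0
  for (a in W[[f1]]) for (b in W[[f2]]) for (cc in W[[f3]]) {
    for (e in groups) {
      cell_e <- do.call(m_of, stats::setNames(list(a, b, cc, e),
                                              c(f1, f2, f3, "experience")))
      # deviation of the abc x e cell after removing all lower-order terms
      dev <- cell_e -
        do.call(m_of, stats::setNames(list(a, b, e), c(f1, f2, "experience"))) -
        do.call(m_of, stats::setNames(list(a, cc, e), c(f1, f3, "experience"))) -
        do.call(m_of, stats::setNames(list(b, cc, e), c(f2, f3, "experience"))) +
        do.call(m_of, stats::setNames(list(a, e), c(f1, "experience"))) +
        do.call(m_of, stats::setNames(list(b, e), c(f2, "experience"))) +
        do.call(m_of, stats::setNames(list(cc, e), c(f3, "experience"))) -
        m_of(experience = e)
      base <- do.call(m_of, stats::setNames(list(a, b, cc), c(f1, f2, f3))) -
        do.call(m_of, stats::setNames(list(a, b), c(f1, f2))) -
        do.call(m_of, stats::setNames(list(a, cc), c(f1, f3))) -
        do.call(m_of, stats::setNames(list(b, cc), c(f2, f3))) +
        do.call(m_of, stats::setNames(list(a), f1)) +
        do.call(m_of, stats::setNames(list(b), f2)) +
        do.call(m_of, stats::setNames(list(cc), f3)) - G
      ss3e <- ss3e + n_e[[e]] * (dev - base)^2
    }
  }
  ss[[key3e]] <- ss3e
  dfs[[key3e]] <- length(groups) - 1
  ss_total <- sum((cells$confidence - G)^2)
  key3err <- paste0("err_", key3)
  ss[[key3err]] <- ss_total - sum(unlist(ss))
  dfs[[key3err]] <- N - length(groups)

  # assemble F and partial eta squared per effect
  effect_error <- function(effect) {
    if (effect %in% c("experience")) return("err_between")
    base <- gsub(" x experience$", "", effect)
    if (base == effect && !grepl("experience", effect)) {
      return(paste0("err_", effect))
    }
    paste0("err_", base)
  }
  effects <- setdiff(names(ss), grep("^err_", names(ss), value = TRUE))
  out <- data.frame(effect = effects, F = NA_real_, partial_eta_sq = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(effects)) {
    ef <- effects[i]
    err <- effect_error(ef)
    ms_eff <- ss[[ef]] / dfs[[ef]]
    ms_err <- ss[[err]] / dfs[[err]]
    out$F[i] <- ms_eff / ms_err
    out$partial_eta_sq[i] <- ss[[ef]] / (ss[[ef]] + ss[[err]])
  }
  out
}

# Noncentral-t power of a paired t test at n pairs: independent of
# power.t.test's root finding (direct power evaluation and upward scan).
oracle_paired_n <- function(d, alpha = 0.05, power = 0.80) {
  n <- 2
  repeat {
    crit <- qt(1 - alpha / 2, df = n - 1)
    pw <- 1 - pt(crit, df = n - 1, ncp = d * sqrt(n)) +
      pt(-crit, df = n - 1, ncp = d * sqrt(n))
    if (pw >= power) return(n)
    n <- n + 1
    if (n > 10000) stop("no convergence")
  }
}

# Small deterministic fixtures -------------------------------------------

tiny_reference <- function(n = 80, seed = 11) {
  spec <- cohort_spec(
    groups = tibble::tibble(group = "control", n = as.integer(n),
                            age_mean = 70, age_sd = 10, prop_female = 0.5),
    region_model = default_region_model()
  )
  simulate_normative_population(spec, seed = seed)
}

# A tiny complete two-rater, four-scan rating table built by hand.
tiny_ratings <- function() {
  tibble::tibble(
    rater_id = rep(c("R1", "R2"), each = 8),
    experience = rep(c("consultant", "registrar"), each = 8),
    scan_id = rep(rep(c("s1", "s2", "s3", "s4"), each = 2), 2),
    condition = rep(c("without_report", "with_report"), 8),
    normality_call = c(
      "abnormal", "abnormal", "normal", "abnormal", "normal", "normal",
      "abnormal", "normal",
      "abnormal", "abnormal", "abnormal", "abnormal", "normal", "normal",
      "normal", "normal"
    ),
    diagnosis_call = c(
      "AD", "AD", "none", "FTD", "none", "none", "FTD", "none",
      "AD", "AD", "AD", "FTD", "none", "none", "none", "none"
    ),
    confidence_normality = rep(c(3, 4), 8),
    confidence_diagnosis = c(
      2, 3, NA, 3, NA, NA, 4, NA,
      3, 4, 2, 3, NA, NA, NA, NA
    )
  )
}

tiny_gold <- function() {
  tibble::tibble(scan_id = c("s1", "s2", "s3", "s4"),
                 group = c("AD", "FTD", "control", "control"))
}
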
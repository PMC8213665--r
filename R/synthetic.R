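#' Default generating model for regional volumes
#'
#' Per-region linear covariate model used by the cohort simulators:
#' volume (mL) = intercept + beta_age x age + beta_sex x male +
#' beta_tiv x TIV + Gaussian noise (SD `sigma`). The regions are the
#' rose-plot set of [default_region_map()] plus total grey and white
#' matter (for BPF). Magnitudes are typical adult values: age slopes
#' around -0.3%/year of the regional mean, TIV scaling close to
#' proportional, residual SDs of roughly 5-8% of the mean.
#'
#' @return A tibble with columns `region`, `intercept`, `beta_age`,
#'   `beta_sex`, `beta_tiv`, `sigma`.
#' @export
default_region_model <- function() {
  base <- tibble::tribble(
    ~region,             ~mean_vol, ~beta_age, ~sigma,
    "frontal_left",      75,        -0.25,     6,
    "frontal_right",     75,        -0.25,     6,
    "temporal_left",     55,        -0.20,     4.5,
    "temporal_right",    55,        -0.20,     4.5,
    "hippocampus_left",  3.2,       -0.016,    0.30,
    "hippocampus_right", 3.2,       -0.016,    0.30,
    "parietal_left",     55,        -0.18,     4.5,
    "parietal_right",    55,        -0.18,     4.5,
    "occipital_left",    35,        -0.08,     3,
    "occipital_right",   35,        -0.08,     3,
    "insula_left",       7,         -0.025,    0.6,
    "insula_right",      7,         -0.025,    0.6,
    "caudate_left",      3.6,       -0.012,    0.35,
    "caudate_right",     3.6,       -0.012,    0.35,
    "total_gm",          620,       -2.0,      30,
    "total_wm",          480,       -0.8,      28
  )
  base %>%
    mutate(
      beta_tiv = .data$mean_vol / 1450 * 0.9,
      beta_sex = 0.01 * .data$mean_vol,
      intercept = .data$mean_vol + 70 * (-.data$beta_age) - 1450 * .data$beta_tiv
    ) %>%
    select("region", "intercept", "beta_age", "beta_sex", "beta_tiv", "sigma")
}

#' Cohort specification for the synthetic generators
#'
#' Describes a cohort to simulate: per-group sizes and demographics, TIV
#' distribution by sex, the per-region generating model, and per-group
#' multiplicative atrophy factors. `normative_cohort_spec()` matches the
#' healthy reference population the normative model is fitted on
#' (n = 461, mean age 70.09, SD 12.05, 51.4% female);
#' `test_cohort_spec()` matches a 45-scan dementia reading study
#' (15 controls, 16 AD, 14 FTD, all around age 60) with AD atrophy
#' concentrated on hippocampal/temporal regions and FTD atrophy on
#' frontal/insular regions (default multiplier 0.80 on the targeted
#' regions, 0.95 elsewhere: young, short-duration patients with subtle
#' volume loss).
#'
#' @param groups Tibble with columns `group`, `n`, `age_mean`, `age_sd`,
#'   `prop_female`, and optional `mmse_mean`, `mmse_sd`, `duration_mean`,
#'   `duration_sd` (NA for absent).
#' @param age_range Ages are drawn from a normal truncated to this range.
#' @param tiv Tibble with columns `sex`, `mean`, `sd` (mL).
#' @param region_model Per-region generating coefficients
#'   ([default_region_model()]).
#' @param atrophy Named list: group -> named vector of multiplicative
#'   volume factors in (0, 1] applied to the model mean (regions absent
#'   from the vector get factor 1).
#' @return A list with class `"cohort_spec"`.
#' @export
cohort_spec <- function(groups, age_range = c(30, 100),
                        tiv = tibble(sex = c("female", "male"),
                                     mean = c(1400, 1550), sd = c(110, 120)),
                        region_model = default_region_model(),
                        atrophy = list()) {
  assert_cols(groups, c("group", "n", "age_mean", "age_sd", "prop_female"),
              "Cohort spec groups")
  if (any(groups$n <= 0)) abort("Group sizes must be positive")
  if (any(region_model$sigma <= 0)) abort("Region sigmas must be positive")
  for (g in names(atrophy)) {
    mult <- atrophy[[g]]
    if (any(mult <= 0 | mult > 1)) {
      abort(paste0("Atrophy multipliers must lie in (0, 1]; offending group: ", g))
    }
    unknown <- setdiff(names(mult), region_model$region)
    if (length(unknown) > 0) {
      abort(paste0("Atrophy names not in region model: ", paste(unknown, collapse = ", ")))
    }
  }
  structure(list(groups = groups, age_range = age_range, tiv = tiv,
                 region_model = region_model, atrophy = atrophy),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
normative_cohort_spec <- function() {
  cohort_spec(
    groups = tibble(group = "control", n = 461L, age_mean = 70.09,
                    age_sd = 12.05, prop_female = 0.514,
                    mmse_mean = NA_real_, mmse_sd = NA_real_,
                    duration_mean = NA_real_, duration_sd = NA_real_),
    age_range = c(30, 100)
  )
}

#' @rdname cohort_spec
#' @param ad_multiplier,ftd_multiplier Atrophy factor on the
#'   disease-typical regions; `mild_multiplier` applies everywhere else
#'   for patients.
#' @export
test_cohort_spec <- function(ad_multiplier = 0.80, ftd_multiplier = 0.80,
                             mild_multiplier = 0.95) {
  regions <- default_region_model()$region
  ad_focus <- c("hippocampus_left", "hippocampus_right",
                "temporal_left", "temporal_right")
  ftd_focus <- c("frontal_left", "frontal_right", "insula_left", "insula_right")
  make_mult <- function(focus, strong) {
    m <- stats::setNames(rep(mild_multiplier, length(regions)), regions)
    m[focus] <- strong
    m
  }
  cohort_spec(
    groups = tibble::tribble(
      ~group,    ~n,  ~age_mean, ~age_sd, ~prop_female, ~mmse_mean, ~mmse_sd, ~duration_mean, ~duration_sd,
      "control", 15L, 60,        8.7,     11 / 15,      26.9,       4,        NA_real_,       NA_real_,
      "AD",      16L, 61.7,      6.6,     7 / 16,       20.5,       6.4,      2.7,            1.6,
      "FTD",     14L, 59.9,      7.3,     3 / 14,       22,         9.1,      3.5,            2.4
    ),
    age_range = c(45, 85),
    atrophy = list(AD = make_mult(ad_focus, ad_multiplier),
                   FTD = make_mult(ftd_focus, ftd_multiplier))
  )
}

# Exact truncated-normal sampling via inverse CDF.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  u <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(u, mean, sd)
}

simulate_cohort <- function(spec, seed, id_prefix) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(derive_seed(seed, paste0("cohort-", id_prefix)), {
    rows <- purrr::pmap_dfr(spec$groups, function(group, n, age_mean, age_sd,
                                                  prop_female, ...) {
      extra <- list(...)
      age <- rtruncnorm(n, age_mean, age_sd, spec$age_range[1], spec$age_range[2])
      sex <- ifelse(runif(n) < prop_female, "female", "male")
      tiv_pars <- spec$tiv[match(sex, spec$tiv$sex), ]
      tiv <- rnorm(n, tiv_pars$mean, tiv_pars$sd)
      mmse <- if (!is.null(extra$mmse_mean) && !is.na(extra$mmse_mean)) {
        pmin(pmax(round(rnorm(n, extra$mmse_mean, extra$mmse_sd)), 0), 30)
      } else NA_real_
      duration <- if (!is.null(extra$duration_mean) && !is.na(extra$duration_mean)) {
        pmax(rnorm(n, extra$duration_mean, extra$duration_sd), 0.2)
      } else NA_real_
      out <- tibble(group = group, age = age, sex = sex, tiv = tiv,
                    mmse = as.numeric(mmse), disease_duration = duration)
      mult <- spec$atrophy[[group]]
      for (i in seq_len(nrow(spec$region_model))) {
        rm <- spec$region_model[i, ]
        mu <- rm$intercept + rm$beta_age * age +
          rm$beta_sex * as.numeric(sex == "male") + rm$beta_tiv * tiv
        f <- if (!is.null(mult) && rm$region %in% names(mult)) mult[[rm$region]] else 1
        out[[rm$region]] <- mu * f + rnorm(n, 0, rm$sigma)
      }
      out
    })
    rows <- rows %>%
      mutate(subject_id = sprintf("%s%03d", id_prefix, dplyr::row_number()),
             .before = 1)
    validate_volume_table(rows, regions = spec$region_model$region)
  })
}

#' Simulate a normative reference population
#'
#' Draws a healthy reference cohort from the spec's generating process:
#' truncated-normal ages, sex by the specified ratio, sex-specific TIV,
#' and per-region volumes from the linear covariate model plus Gaussian
#' noise. Deterministic for a fixed seed.
#'
#' @param spec A [cohort_spec()]; defaults to [normative_cohort_spec()]
#'   (n = 461).
#' @param seed Integer seed.
#' @return A volume table (tibble) suitable for [fit_normative_model()].
#' @examples
#' ref <- simulate_normative_population(seed = 7)
#' nrow(ref)
#' @export
simulate_normative_population <- function(spec = normative_cohort_spec(), seed = 1) {
  simulate_cohort(spec, seed, "N")
}

#' Simulate a labelled dementia test cohort
#'
#' Draws the reading-study test set: controls from the same generating
#' process as the reference population (clinic "controls" are modelled
#' as radiologically normal), AD and FTD patients with multiplicative
#' regional atrophy applied to the model mean before noise.
#'
#' @param spec A [cohort_spec()]; defaults to [test_cohort_spec()]
#'   (15 controls / 16 AD / 14 FTD).
#' @param seed Integer seed.
#' @return A volume table with a `group` column in
#'   `control`/`AD`/`FTD`.
#' @export
simulate_test_cohort <- function(spec = test_cohort_spec(), seed = 1) {
  simulate_cohort(spec, seed, "T")
}

#' Randomised episode schedule for one rater
#'
#' Builds the rating schedule for one rater: every scan exactly twice,
#' once per condition, in a pseudorandom order keyed on (seed,
#' rater_id) so each rater receives a distinct but reproducible
#' sequence - mitigating systematic learning or anchoring effects.
#'
#' @param scan_ids Unique scan identifiers.
#' @param rater_id Rater identifier (keys the permutation).
#' @param seed Integer base seed shared by the whole study.
#' @return A tibble with columns `position`, `scan_id`, `condition`.
#' @export
randomise_episodes <- function(scan_ids, rater_id, seed = 1) {
  if (length(scan_ids) == 0) abort("Scan list must be non-empty")
  if (anyDuplicated(scan_ids)) {
    abort(paste0("Duplicate scan id(s): ",
                 paste(unique(scan_ids[duplicated(scan_ids)]), collapse = ", ")))
  }
  episodes <- tidyr::expand_grid(scan_id = as.character(scan_ids),
                                 condition = c("without_report", "with_report"))
  withr::with_seed(derive_seed(seed, paste0("episodes-", rater_id)), {
    episodes <- episodes[sample.int(nrow(episodes)), ]
  })
  episodes %>% mutate(position = dplyr::row_number(), .before = 1)
}

#' Rater behaviour specification
#'
#' Describes one simulated rater: condition-specific sensitivity and
#' specificity for calling volume loss, the probability of picking the
#' correct sub-diagnosis given a correct abnormal call (separately for
#' AD and FTD scans, since the two patterns are not equally
#' recognisable), and a confidence model giving the mean 1-5 confidence
#' per (correctness, scan normality, condition) cell. Confidences are
#' drawn as a discretised Gaussian (SD `confidence_sd`) clipped to 1-5.
#'
#' @param rater_id Identifier.
#' @param experience `consultant`, `registrar` or `analyst`.
#' @param sensitivity,specificity Named numeric vectors with entries
#'   `without_report` and `with_report`, probabilities in \[0, 1\].
#' @param ad_dx_accuracy,ftd_dx_accuracy P(correct sub-diagnosis |
#'   abnormal call on an AD / FTD scan), per condition (same names).
#' @param confidence_base,confidence_correct,confidence_abnormal,confidence_report
#'   Additive confidence model: cell mean = base + correct-bonus +
#'   abnormal-scan bonus + with-report bonus, on the 1-5 scale.
#' @param confidence_sd SD of the pre-discretisation confidence draw.
#' @return A list with class `"rater_spec"`.
#' @export
rater_spec <- function(rater_id, experience,
                       sensitivity = c(without_report = 0.715, with_report = 0.822),
                       specificity = c(without_report = 0.785, with_report = 0.723),
                       ad_dx_accuracy = c(without_report = 0.80, with_report = 0.80),
                       ftd_dx_accuracy = c(without_report = 0.55, with_report = 0.55),
                       confidence_base = 3, confidence_correct = 0.8,
                       confidence_abnormal = 0.4, confidence_report = 0.2,
                       confidence_sd = 0.8) {
  for (p in list(sensitivity, specificity, ad_dx_accuracy, ftd_dx_accuracy)) {
    if (!all(c("without_report", "with_report") %in% names(p)) ||
        any(p < 0 | p > 1)) {
      abort("Rater probabilities must be named (without_report/with_report) and in [0, 1]")
    }
  }
  if (!experience %in% c("consultant", "registrar", "analyst")) {
    abort("experience must be consultant, registrar or analyst")
  }
  structure(
    list(rater_id = rater_id, experience = experience,
         sensitivity = sensitivity, specificity = specificity,
         ad_dx_accuracy = ad_dx_accuracy, ftd_dx_accuracy = ftd_dx_accuracy,
         confidence_base = confidence_base,
         confidence_correct = confidence_correct,
         confidence_abnormal = confidence_abnormal,
         confidence_report = confidence_report,
         confidence_sd = confidence_sd),
    class = "rater_spec"
  )
}

#' @rdname rater_spec
#' @param n_per_group Raters per experience level (default 3 x 3 = 9).
#' @param ... Passed on to [rater_spec()] for every rater.
#' @export
default_rater_specs <- function(n_per_group = 3, ...) {
  levels <- c(consultant = "A", registrar = "B", analyst = "C")
  purrr::flatten(purrr::imap(levels, function(prefix, exp_level) {
    purrr::map(seq_len(n_per_group), function(i) {
      rater_spec(paste0(prefix, i), exp_level, ...)
    })
  }))
}

#' Simulate a full multi-rater rating study
#'
#' Generates the forced-choice responses of a panel of simulated raters
#' over a labelled scan cohort. For each episode the normality call is a
#' Bernoulli draw from the rater's condition-specific sensitivity
#' (patient scans) or specificity (control scans); abnormal calls on
#' patient scans pick the correct sub-diagnosis with the rater's
#' AD/FTD-specific accuracy, abnormal calls on control scans pick AD or
#' FTD at even odds; confidences come from the rater's cell-mean model.
#' Fully deterministic for a fixed seed, independent of rater order.
#'
#' @param cohort A labelled cohort: tibble with `subject_id` (or
#'   `scan_id`) and `group` columns (e.g. [simulate_test_cohort()]).
#' @param raters List of [rater_spec()] objects
#'   ([default_rater_specs()]).
#' @param seed Integer seed; also keys the per-rater episode schedules.
#' @param schedules Optional named list (by rater id) of pre-built
#'   episode schedules from [randomise_episodes()]; they must cover
#'   exactly the cohort's scans.
#' @return A validated rating tibble ([validate_ratings()]).
#' @export
simulate_raters <- function(cohort, raters, seed = 1, schedules = NULL) {
  scan_col <- if ("scan_id" %in% names(cohort)) "scan_id" else "subject_id"
  gold <- tibble(scan_id = as.character(cohort[[scan_col]]),
                 group = cohort$group)
  if (anyDuplicated(gold$scan_id)) abort("Duplicate scan ids in cohort")
  if (!all(gold$group %in% c("control", "AD", "FTD"))) {
    abort("Cohort groups must be control/AD/FTD")
  }
  records <- purrr::map_dfr(raters, function(rs) {
    stopifnot(inherits(rs, "rater_spec"))
    sched <- if (!is.null(schedules)) {
      s <- schedules[[rs$rater_id]]
      if (is.null(s)) abort(paste0("No schedule supplied for rater ", rs$rater_id))
      if (!setequal(s$scan_id, gold$scan_id) ||
          nrow(s) != 2 * nrow(gold)) {
        abort(paste0("Schedule for rater ", rs$rater_id,
                     " does not cover the cohort's scans exactly twice"))
      }
      s
    } else {
      randomise_episodes(gold$scan_id, rs$rater_id, seed)
    }
    withr::with_seed(derive_seed(seed, paste0("rater-", rs$rater_id)), {
      sched <- sched %>% left_join(gold, by = "scan_id")
      n_ep <- nrow(sched)
      is_patient <- sched$group %in% c("AD", "FTD")
      p_abnormal <- ifelse(is_patient,
                           rs$sensitivity[sched$condition],
                           1 - rs$specificity[sched$condition])
      abnormal <- runif(n_ep) < p_abnormal
      dx_acc <- ifelse(sched$group == "AD",
                       rs$ad_dx_accuracy[sched$condition],
                       rs$ftd_dx_accuracy[sched$condition])
      correct_dx <- runif(n_ep) < dx_acc
      diagnosis <- dplyr::case_when(
        !abnormal ~ "none",
        sched$group == "AD" & correct_dx ~ "AD",
        sched$group == "AD" ~ "FTD",
        sched$group == "FTD" & correct_dx ~ "FTD",
        sched$group == "FTD" ~ "AD",
        TRUE ~ ifelse(runif(n_ep) < 0.5, "AD", "FTD")
      )
      correct_call <- abnormal == is_patient
      conf_mean <- rs$confidence_base +
        rs$confidence_correct * correct_call +
        rs$confidence_abnormal * is_patient +
        rs$confidence_report * (sched$condition == "with_report")
      draw_conf <- function(mu) {
        pmin(pmax(round(rnorm(length(mu), mu, rs$confidence_sd)), 1), 5)
      }
      tibble(
        rater_id = rs$rater_id,
        experience = rs$experience,
        scan_id = sched$scan_id,
        condition = sched$condition,
        normality_call = ifelse(abnormal, "abnormal", "normal"),
        diagnosis_call = diagnosis,
        confidence_normality = draw_conf(conf_mean),
        confidence_diagnosis = ifelse(abnormal, draw_conf(conf_mean), NA_real_)
      )
    })
  })
  validate_ratings(records)
}
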
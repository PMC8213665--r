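# Hand-built one-region model so percentile values can be checked in
# closed form.
manual_model <- function(variant = "gaussian", shape = NULL) {
  structure(
    list(
      coefficients = tibble::tibble(region = "r1", intercept = 200,
                                    beta_age = -0.5, beta_sex = 10,
                                    beta_tiv = 0.05, sigma = 8),
      cdf_variant = variant, shape = shape, n_reference = 461,
      age_range = c(30, 100), fit_date = "2026-01-01"
    ),
    class = "normative_model"
  )
}

manual_subject <- function(volume) {
  tibble::tibble(subject_id = "s", age = 70, sex = "male", tiv = 1450,
                 r1 = volume)
}
# predicted mean for the manual model at these covariates:
# 200 - 0.5*70 + 10 + 0.05*1450 = 247.5
mu0 <- 247.5

single_region_spec <- function(n = 461) {
  cohort_spec(
    groups = tibble::tibble(group = "control", n = as.integer(n),
                            age_mean = 70.09, age_sd = 12.05,
                            prop_female = 0.514),
    region_model = tibble::tibble(region = "r1", intercept = 200,
                                  beta_age = -0.5, beta_sex = 10,
                                  beta_tiv = 0.05, sigma = 8)
  )
}

test_that("fitting recovers known generating parameters on n = 461", {
  ref <- simulate_normative_population(single_region_spec(), seed = 21)
  m <- fit_normative_model(ref)
  expect_equal(m$n_reference, 461)

  X <- cbind(1, ref$age, as.numeric(ref$sex == "male"), ref$tiv)
  se <- sqrt(diag(solve(crossprod(X))) * 8^2)
  est <- unlist(m$coefficients[1, c("intercept", "beta_age", "beta_sex", "beta_tiv")])
  truth <- c(200, -0.5, 10, 0.05)
  expect_true(all(abs(est - truth) <= 3 * se))
  expect_lt(abs(m$coefficients$sigma - 8) / 8, 0.10)
})

test_that("degenerate references are rejected with informative errors", {
  ref <- tiny_reference(n = 40, seed = 5)
  const <- ref
  const$frontal_left <- 100 + 0.01 * const$tiv  # exact function of covariates
  expect_error(fit_normative_model(const, regions = "frontal_left"),
               "Degenerate residual variance")

  one_sex <- ref
  one_sex$sex <- "female"
  expect_error(fit_normative_model(one_sex), "both sexes")

  same_age <- ref
  same_age$age <- 70
  expect_error(fit_normative_model(same_age, regions = "frontal_left"),
               "[Dd]egenerate design|collinear")

  expect_error(fit_normative_model(ref[1:10, ]), "at least 30")
})

test_that("percentiles hit closed-form values at known z", {
  m <- manual_model()
  # z = 0: exactly the predicted mean
  expect_equal(volume_percentiles(m, manual_subject(mu0))$percentile, 50)
  # z = -1.6449: the 5th percentile of a standard normal
  p5 <- volume_percentiles(m, manual_subject(mu0 - 1.6449 * 8))$percentile
  expect_equal(p5, 5, tolerance = 0.01 / 5)
  # logistic approximation is also symmetric at z = 0
  ml <- manual_model("logistic_approx")
  expect_equal(volume_percentiles(ml, manual_subject(mu0))$percentile, 50)
  # display clipping: z = -5 is far below the displayable floor
  expect_equal(volume_percentiles(m, manual_subject(mu0 - 5 * 8))$percentile, 0.01)
  expect_gt(volume_percentiles(m, manual_subject(mu0 - 5 * 8),
                               clip = FALSE)$percentile, 0)
  expect_lt(volume_percentiles(m, manual_subject(mu0 - 5 * 8),
                               clip = FALSE)$percentile, 0.01)
})

test_that("gaussian and logistic variants agree within 2 points for |z| <= 3", {
  mg <- manual_model("gaussian")
  ml <- manual_model("logistic_approx")
  for (z in seq(-3, 3, by = 0.1)) {
    s <- manual_subject(mu0 + z * 8)
    diff <- abs(volume_percentiles(mg, s)$percentile -
                  volume_percentiles(ml, s)$percentile)
    expect_lt(diff, 2)
  }
})

test_that("percentile is strictly monotone in volume and covariate-consistent", {
  m <- manual_model()
  vols <- seq(mu0 - 30, mu0 + 30, by = 1)
  p <- vapply(vols, function(v) {
    volume_percentiles(m, manual_subject(v), clip = FALSE)$percentile
  }, numeric(1))
  expect_true(all(diff(p) > 0))

  # beta_age < 0: an older subject with the same volume is less atrophic
  # relative to peers, so the percentile must rise with age
  older <- manual_subject(mu0)
  older$age <- 80
  expect_gt(volume_percentiles(m, older)$percentile, 50)

  # generalised-logistic variant is monotone too
  ref <- simulate_normative_population(single_region_spec(461), seed = 9)
  mgl <- fit_normative_model(ref, cdf_variant = "generalised_logistic")
  pgl <- volume_percentiles(
    mgl,
    tibble::tibble(subject_id = paste0("q", seq_along(vols)), age = 70,
                   sex = "male", tiv = 1450, r1 = vols),
    clip = FALSE
  )
  expect_true(all(diff(pgl$percentile) > 0))
  # and close to gaussian when the data really are gaussian
  mid <- volume_percentiles(mgl, manual_subject(mu0))$percentile
  expect_lt(abs(mid - 50), 10)
})

test_that("residual percentiles are uncorrelated with the covariates", {
  ref <- simulate_normative_population(seed = 31)
  m <- fit_normative_model(ref)
  # fresh subjects from the fitted model's own generating process
  gen <- simulate_from_model <- local({
    b <- m$coefficients[m$coefficients$region == "hippocampus_left", ]
    withr::with_seed(77, {
      n <- 2000
      age <- runif(n, 40, 95)
      sex <- ifelse(runif(n) < 0.5, "female", "male")
      tiv <- rnorm(n, 1475, 120)
      mu <- b$intercept + b$beta_age * age + b$beta_sex * (sex == "male") +
        b$beta_tiv * tiv
      tibble::tibble(subject_id = paste0("g", 1:n), age = age, sex = sex,
                     tiv = tiv,
                     hippocampus_left = mu + rnorm(n, 0, b$sigma))
    })
  })
  p <- volume_percentiles(m, gen, regions = "hippocampus_left")$percentile
  expect_lt(abs(cor(p, gen$age, method = "spearman")), 0.05)
  expect_lt(abs(cor(p, gen$tiv, method = "spearman")), 0.05)
  expect_lt(abs(cor(p, as.numeric(gen$sex == "male"), method = "spearman")), 0.05)
})

test_that("brain parenchymal fraction follows its defining ratio", {
  s <- tibble::tibble(subject_id = "s", age = 60, sex = "female", tiv = 1375,
                      total_gm = 600, total_wm = 500)
  expect_equal(brain_parenchymal_fraction(s)$bpf, 0.8)

  boundary <- s
  boundary$total_gm <- 875  # GM + WM = TIV
  expect_error(brain_parenchymal_fraction(boundary), "TIV")
})

test_that("a subject at the normative median lands at BPF percentile 50", {
  ref <- simulate_normative_population(seed = 13)
  bm <- fit_bpf_model(ref)
  # synthetic subject with exactly the model-predicted BPF at age 65
  target_bpf <- bm$intercept + bm$beta_age * 65
  tiv <- 1450
  s <- tibble::tibble(subject_id = "med", age = 65, sex = "female", tiv = tiv,
                      total_gm = target_bpf * tiv / 2,
                      total_wm = target_bpf * tiv / 2)
  expect_equal(bpf_percentile(bm, s)$percentile, 50, tolerance = 2 / 50)
})

test_that("qc metrics follow the SNR/CNR conventions", {
  expect_equal(qc_metrics(120, 200, 10)$snr, 20)
  expect_equal(qc_metrics(120, 180, 10)$cnr, 6)
  expect_equal(qc_metrics(150, 150, 10)$cnr, 0)
  expect_error(qc_metrics(120, 180, 0), "positive")
})

test_that("normative models round-trip through JSON", {
  ref <- tiny_reference(n = 60, seed = 8)
  m <- fit_normative_model(ref)
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_model(m, path)
  back <- read_normative_model(path)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-12)
  expect_identical(back$cdf_variant, m$cdf_variant)
  expect_equal(back$n_reference, m$n_reference)
  s <- ref[1, ]
  expect_equal(volume_percentiles(back, s), volume_percentiles(m, s),
               tolerance = 1e-12)
})
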
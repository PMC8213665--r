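#' Fit a normative model of regional brain volumes
#'
#' For each region, fits an ordinary-least-squares regression of volume
#' (mL) on age (years), sex (coded 0 = female, 1 = male) and total
#' intracranial volume (TIV, mL) across a healthy reference population.
#' The residual standard deviation \eqn{\sigma} (denominator \eqn{n - 4})
#' defines, together with a cumulative-distribution variant, the mapping
#' from a new subject's volume to a percentile of the normative
#' population (see [volume_percentiles()]).
#'
#' Three CDF variants are available for the standardised residual
#' \eqn{z = (v - \beta x)/\sigma}:
#' \describe{
#'   \item{`gaussian`}{\eqn{100\,\Phi(z)} - the exact normal CDF (default).}
#'   \item{`logistic_approx`}{\eqn{100/(1 + e^{-1.702 z})} - the classical
#'     logistic approximation to the normal ogive.}
#'   \item{`generalised_logistic`}{\eqn{100\,(1 + Q e^{-Bz})^{-1/\nu}} - a
#'     Richards curve whose growth rate \eqn{B}, asymmetry \eqn{\nu} and
#'     offset \eqn{Q} are fitted by least squares to the empirical CDF of
#'     the pooled standardised residuals, allowing a mild skew in the
#'     reference distribution.}
#' }
#'
#' @param reference A volume table ([read_volume_table()]) of healthy
#'   reference subjects; at least 30 subjects, both sexes present, all
#'   with the same regions.
#' @param cdf_variant One of `"gaussian"`, `"logistic_approx"`,
#'   `"generalised_logistic"`.
#' @param regions Regions to model; defaults to all region columns.
#' @return An object of class `"normative_model"`: a list with elements
#'   `coefficients` (tibble: region, intercept, beta_age, beta_sex,
#'   beta_tiv, sigma), `cdf_variant`, `shape` (B, nu, Q; only for the
#'   generalised-logistic variant), `n_reference`, `age_range` and
#'   `fit_date`.
#' @examples
#' ref <- simulate_normative_population(seed = 1)
#' m <- fit_normative_model(ref)
#' glance(m)
#' @export
fit_normative_model <- function(reference,
                                cdf_variant = c("gaussian", "logistic_approx",
                                                "generalised_logistic"),
                                regions = NULL) {
  cdf_variant <- match.arg(cdf_variant)
  reference <- validate_volume_table(reference)
  if (is.null(regions)) regions <- volume_regions(reference)
  n <- nrow(reference)
  if (n < 30) abort("Reference population must have at least 30 subjects")
  if (length(unique(reference$sex)) < 2) {
    abort("Reference population must contain both sexes")
  }

  design <- data.frame(
    age = reference$age,
    sex_male = as.numeric(reference$sex == "male"),
    tiv = reference$tiv
  )
  std_resid <- list()
  coefs <- purrr::map_dfr(regions, function(rg) {
    fit <- lm(reference[[rg]] ~ age + sex_male + tiv, data = design)
    if (anyNA(coef(fit))) {
      abort(paste0("Degenerate design for region '", rg,
                   "': covariates are collinear or constant"))
    }
    sigma <- sqrt(sum(fit$residuals^2) / (n - 4))
    if (sigma <= .Machine$double.eps^0.5) {
      abort(paste0("Degenerate residual variance for region '", rg,
                   "': volumes are an exact function of the covariates"))
    }
    std_resid[[rg]] <<- fit$residuals / sigma
    b <- coef(fit)
    tibble(region = rg, intercept = b[[1]], beta_age = b[[2]],
           beta_sex = b[[3]], beta_tiv = b[[4]], sigma = sigma)
  })

  shape <- NULL
  if (cdf_variant == "generalised_logistic") {
    shape <- fit_richards_shape(unlist(std_resid, use.names = FALSE))
  }

  structure(
    list(
      coefficients = coefs,
      cdf_variant = cdf_variant,
      shape = shape,
      n_reference = n,
      age_range = range(reference$age),
      fit_date = format(Sys.Date())
    ),
    class = "normative_model"
  )
}

# Least-squares fit of the Richards CDF 1/(1 + Q exp(-B z))^(1/nu) to the
# empirical CDF of standardised residuals. Parameters kept positive via a
# log transform; initialised at the logistic approximation (B = 1.702,
# nu = Q = 1).
fit_richards_shape <- function(z) {
  z <- sort(z)
  ecdf_val <- (seq_along(z) - 0.5) / length(z)
  objective <- function(par) {
    B <- exp(par[1]); nu <- exp(par[2]); Q <- exp(par[3])
    fitted <- (1 + Q * exp(-B * z))^(-1 / nu)
    sum((fitted - ecdf_val)^2)
  }
  opt <- optim(c(log(1.702), 0, 0), objective, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(B = exp(opt$par[1]), nu = exp(opt$par[2]), Q = exp(opt$par[3]))
}

#' @export
print.normative_model <- function(x, ...) {
  cat("Normative volumetric model (", x$cdf_variant, " CDF)\n", sep = "")
  cat("  regions:     ", nrow(x$coefficients), "\n", sep = "")
  cat("  n_reference: ", x$n_reference, "\n", sep = "")
  cat("  age range:   ", num_fmt(x$age_range[1], 1), " - ",
      num_fmt(x$age_range[2], 1), " years\n", sep = "")
  invisible(x)
}

#' @describeIn fit_normative_model One row per region and coefficient
#'   (broom convention: columns `region`, `term`, `estimate`).
#' @param x A `normative_model`.
#' @param ... Unused.
#' @export
tidy.normative_model <- function(x, ...) {
  x$coefficients %>%
    tidyr::pivot_longer(cols = c("intercept", "beta_age", "beta_sex",
                                 "beta_tiv", "sigma"),
                        names_to = "term", values_to = "estimate")
}

#' @describeIn fit_normative_model One-row model summary.
#' @export
glance.normative_model <- function(x, ...) {
  tibble(
    n_reference = x$n_reference,
    n_regions = nrow(x$coefficients),
    cdf_variant = x$cdf_variant,
    age_min = x$age_range[1],
    age_max = x$age_range[2],
    mean_sigma = mean(x$coefficients$sigma)
  )
}

# Predicted normative mean volume for each subject x region.
normative_mean <- function(model, subjects, region) {
  b <- model$coefficients[model$coefficients$region == region, ]
  if (nrow(b) == 0) abort(paste0("Region '", region, "' not in normative model"))
  b$intercept + b$beta_age * subjects$age +
    b$beta_sex * as.numeric(subjects$sex == "male") +
    b$beta_tiv * subjects$tiv
}

# Map standardised residuals to percentiles under the model's CDF variant.
cdf_percentile <- function(model, z) {
  switch(model$cdf_variant,
    gaussian = 100 * pnorm(z),
    logistic_approx = 100 / (1 + exp(-1.702 * z)),
    generalised_logistic = {
      s <- model$shape
      100 * (1 + s$Q * exp(-s$B * z))^(-1 / s$nu)
    }
  )
}

#' Convert subject volumes to normative percentiles
#'
#' For each subject and region, standardises the observed volume against
#' the normative prediction, \eqn{z = (v - \beta x)/\sigma}, and maps it
#' through the model's CDF to a percentile of the healthy population.
#' Percentiles are clipped to \[0.01, 99.99\] for display (the rose plot
#' has a log radial axis, which cannot show 0).
#'
#' @param model A [fit_normative_model()] object.
#' @param subjects A volume table with the model's regions.
#' @param regions Regions to score; defaults to all regions in the model.
#' @param clip Clip percentiles to \[0.01, 99.99\]? Default `TRUE`.
#' @return A tibble with columns `subject_id`, `region`, `volume`, `z`,
#'   `percentile`.
#' @examples
#' ref <- simulate_normative_population(seed = 1)
#' m <- fit_normative_model(ref)
#' volume_percentiles(m, ref[1:2, ], regions = "hippocampus_left")
#' @export
volume_percentiles <- function(model, subjects, regions = NULL, clip = TRUE) {
  stopifnot(inherits(model, "normative_model"))
  subjects <- validate_volume_table(subjects)
  if (is.null(regions)) regions <- model$coefficients$region
  unknown <- setdiff(regions, model$coefficients$region)
  if (length(unknown) > 0) {
    abort(paste0("Region(s) not in normative model: ", paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(regions, names(subjects))
  if (length(missing_cols) > 0) {
    abort(paste0("Subject table lacks region column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  purrr::map_dfr(regions, function(rg) {
    b <- model$coefficients[model$coefficients$region == rg, ]
    if (b$sigma <= 0) abort(paste0("Model invalid: sigma <= 0 for region '", rg, "'"))
    z <- (subjects[[rg]] - normative_mean(model, subjects, rg)) / b$sigma
    p <- cdf_percentile(model, z)
    if (clip) p <- pmin(pmax(p, 0.01), 99.99)
    tibble(subject_id = subjects$subject_id, region = rg,
           volume = subjects[[rg]], z = z, percentile = p)
  })
}

#' Brain parenchymal fraction
#'
#' BPF = (grey-matter volume + white-matter volume) / TIV, a global,
#' head-size-normalised atrophy index in (0, 1). Parenchyma cannot exceed
#' the intracranial volume; rows violating that raise an error naming the
#' subject.
#'
#' @param subjects A volume table containing total grey- and white-matter
#'   columns.
#' @param gm,wm Names of the total grey- and white-matter columns.
#' @return The input tibble with a `bpf` column appended.
#' @export
brain_parenchymal_fraction <- function(subjects, gm = "total_gm", wm = "total_wm") {
  subjects <- validate_volume_table(subjects)
  assert_cols(subjects, c(gm, wm), "Volume table (for BPF)")
  parenchyma <- subjects[[gm]] + subjects[[wm]]
  bad <- subjects$subject_id[parenchyma >= subjects$tiv]
  if (length(bad) > 0) {
    abort(paste0("GM + WM >= TIV (parenchyma cannot fill the intracranial ",
                 "volume) for subject(s): ", paste(bad, collapse = ", ")))
  }
  subjects$bpf <- parenchyma / subjects$tiv
  subjects
}

#' Normative model for brain parenchymal fraction
#'
#' BPF already divides by TIV, so its normative model regresses BPF on
#' age only (regressing a ratio on its own denominator would be
#' circular). `bpf_percentile()` scores new subjects against it with a
#' Gaussian CDF.
#'
#' @param reference A healthy reference volume table with total GM/WM
#'   columns.
#' @inheritParams brain_parenchymal_fraction
#' @return `fit_bpf_model()`: an object of class `"bpf_model"` with the
#'   age regression coefficients and residual sigma. `bpf_percentile()`:
#'   a tibble with `subject_id`, `bpf`, `percentile`.
#' @export
fit_bpf_model <- function(reference, gm = "total_gm", wm = "total_wm") {
  reference <- brain_parenchymal_fraction(reference, gm = gm, wm = wm)
  fit <- lm(bpf ~ age, data = reference)
  sigma <- sqrt(sum(fit$residuals^2) / (nrow(reference) - 2))
  if (sigma <= .Machine$double.eps^0.5) abort("Degenerate BPF residual variance")
  structure(
    list(intercept = coef(fit)[[1]], beta_age = coef(fit)[[2]], sigma = sigma,
         n_reference = nrow(reference), age_range = range(reference$age),
         gm = gm, wm = wm),
    class = "bpf_model"
  )
}

#' @rdname fit_bpf_model
#' @param model A `bpf_model`.
#' @param subjects A volume table with the GM/WM columns used at fit time.
#' @param clip Clip percentiles to \[0.01, 99.99\]? Default `TRUE`.
#' @export
bpf_percentile <- function(model, subjects, clip = TRUE) {
  stopifnot(inherits(model, "bpf_model"))
  subjects <- brain_parenchymal_fraction(subjects, gm = model$gm, wm = model$wm)
  z <- (subjects$bpf - (model$intercept + model$beta_age * subjects$age)) / model$sigma
  p <- 100 * pnorm(z)
  if (clip) p <- pmin(pmax(p, 0.01), 99.99)
  tibble(subject_id = subjects$subject_id, bpf = subjects$bpf, percentile = p)
}

#' Scan-quality metrics
#'
#' Signal-to-noise and contrast-to-noise ratios from tissue signal
#' statistics: `snr = mean_wm / sd_background` and
#' `cnr = |mean_wm - mean_gm| / sd_background`. The signal regions used
#' for QC are a documented convention (white matter as the signal
#' reference, GM-WM contrast for CNR).
#'
#' @param mean_gm,mean_wm Mean image intensity in grey/white matter.
#' @param sd_background Standard deviation of background (air) intensity;
#'   must be positive.
#' @return A tibble with columns `snr` and `cnr`.
#' @export
qc_metrics <- function(mean_gm, mean_wm, sd_background) {
  if (any(sd_background <= 0)) abort("sd_background must be positive")
  tibble(snr = mean_wm / sd_background,
         cnr = abs(mean_wm - mean_gm) / sd_background)
}

#' Serialise a normative model to JSON
#'
#' Round-trips all coefficients, the CDF variant and shape parameters,
#' and the fit metadata, so a fitted model can be shipped alongside the
#' reporting pipeline.
#'
#' @param model A `normative_model`.
#' @param path Output / input JSON path.
#' @return `read_normative_model()` returns the restored
#'   `normative_model`.
#' @export
write_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  payload <- list(
    coefficients = model$coefficients,
    cdf_variant = model$cdf_variant,
    shape = model$shape,
    n_reference = model$n_reference,
    age_range = model$age_range,
    fit_date = model$fit_date
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(path) {
  if (!file.exists(path)) abort(paste0("Model file not found: ", path))
  payload <- jsonlite::fromJSON(path)
  structure(
    list(
      coefficients = as_tibble(payload$coefficients),
      cdf_variant = payload$cdf_variant,
      shape = if (!is.null(payload$shape)) as.list(payload$shape) else NULL,
      n_reference = payload$n_reference,
      age_range = payload$age_range,
      fit_date = payload$fit_date
    ),
    class = "normative_model"
  )
}
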
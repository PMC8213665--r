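#' Column schema for subject volume tables
#'
#' Maps the demographic columns of a CSV volume table onto the canonical
#' names used throughout the package. Any column not named in the schema
#' is treated as a brain-region volume column; region order follows column
#' order. Volumes are stored internally in mL; tables exported by tools
#' that report mm\eqn{^3} can declare `units = "mm3"` and are divided by
#' 1000 on read.
#'
#' @param id,age,sex,tiv Names of the mandatory demographic columns.
#' @param group,mmse,disease_duration Names of optional columns (set to
#'   `NULL` if absent from the file).
#' @param units Unit of the volume columns: `"mL"` (default) or `"mm3"`.
#' @return A named list with class `"volume_schema"`.
#' @export
volume_schema <- function(id = "subject_id", age = "age", sex = "sex",
                          tiv = "tiv", group = "group", mmse = "mmse",
                          disease_duration = "disease_duration",
                          units = c("mL", "mm3")) {
  units <- match.arg(units)
  structure(
    list(id = id, age = age, sex = sex, tiv = tiv, group = group,
         mmse = mmse, disease_duration = disease_duration, units = units),
    class = "volume_schema"
  )
}

#' Read and validate a subject volume table
#'
#' Reads a CSV of per-subject demographics and regional brain volumes into
#' a validated tibble, one row per subject. Mandatory columns are the
#' subject id, age (years), sex and total intracranial volume (TIV, mL);
#' every column not named in the schema is auto-detected as a region
#' volume column, preserving column order.
#'
#' Validation enforces: ages within \[18, 110\]; all volumes strictly
#' positive; TIV larger than every single region volume (regions may
#' overlap conceptually so they need not sum below TIV); sex canonicalised
#' to `"female"`/`"male"`; optional MMSE in \[0, 30\]. Errors name the
#' offending column or subject.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, header row).
#' @param schema A [volume_schema()] describing the demographic columns.
#' @return A tibble with canonical columns `subject_id`, `age`, `sex`,
#'   `group`, `tiv`, optional `mmse` and `disease_duration`, followed by
#'   one numeric column per region (mL). The region names are stored in
#'   the `"regions"` attribute, retrievable with [volume_regions()].
#' @seealso [write_volume_table()], [simulate_normative_population()]
#' @export
read_volume_table <- function(path, schema = volume_schema()) {
  if (!file.exists(path)) abort(paste0("Volume table not found: ", path))
  # force id/sex/group to character: a column of bare "F"s would otherwise
  # be guessed as logical
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  char_cols <- intersect(c(schema$id, schema$sex, schema$group), header)
  ct <- do.call(readr::cols,
                stats::setNames(rep(list(readr::col_character()),
                                    length(char_cols)), char_cols))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = ct)
  mandatory <- c(schema$id, schema$age, schema$sex, schema$tiv)
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Volume table is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  demo_cols <- unlist(schema[c("id", "age", "sex", "tiv", "group", "mmse",
                               "disease_duration")], use.names = FALSE)
  region_cols <- setdiff(names(raw), demo_cols)
  if (length(region_cols) < 1) {
    abort("Volume table has no region columns (all columns matched the demographic schema)")
  }

  out <- tibble(
    subject_id = as.character(raw[[schema$id]]),
    age = as.numeric(raw[[schema$age]]),
    sex = canonical_sex(raw[[schema$sex]]),
    group = if (!is.null(schema$group) && schema$group %in% names(raw)) {
      as.character(raw[[schema$group]])
    } else "unknown",
    tiv = as.numeric(raw[[schema$tiv]]),
    mmse = if (!is.null(schema$mmse) && schema$mmse %in% names(raw)) {
      as.numeric(raw[[schema$mmse]])
    } else NA_real_,
    disease_duration = if (!is.null(schema$disease_duration) &&
                           schema$disease_duration %in% names(raw)) {
      as.numeric(raw[[schema$disease_duration]])
    } else NA_real_
  )
  scale <- if (schema$units == "mm3") 1 / 1000 else 1
  for (rc in region_cols) out[[rc]] <- as.numeric(raw[[rc]]) * scale
  if (schema$units == "mm3") out$tiv <- out$tiv / 1000
  validate_volume_table(out, regions = region_cols)
}

#' @rdname read_volume_table
#' @param volumes A volume-table tibble as returned by
#'   `read_volume_table()` or the synthetic generators.
#' @export
write_volume_table <- function(volumes, path) {
  validate_volume_table(volumes)
  readr::write_csv(volumes, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_volume_table
#' @export
volume_regions <- function(volumes) {
  attr(volumes, "regions") %||%
    setdiff(names(volumes), c("subject_id", "age", "sex", "group", "tiv",
                              "mmse", "disease_duration"))
}

#' @rdname read_volume_table
#' @param regions Character vector of region column names; auto-detected
#'   when `NULL`.
#' @export
validate_volume_table <- function(volumes, regions = NULL) {
  assert_cols(volumes, c("subject_id", "age", "sex", "tiv"), "Volume table")
  volumes <- as_tibble(volumes)
  if (is.null(regions)) regions <- volume_regions(volumes)
  if (!"group" %in% names(volumes)) volumes$group <- "unknown"
  ok_groups <- c("control", "AD", "FTD", "unknown")
  bad_group <- setdiff(unique(volumes$group), ok_groups)
  if (length(bad_group) > 0) {
    abort(paste0("Unknown group label(s): ", paste(bad_group, collapse = ", "),
                 " (expected ", paste(ok_groups, collapse = "/"), ")"))
  }
  volumes$sex <- canonical_sex(volumes$sex)
  bad_age <- volumes$subject_id[is.na(volumes$age) | volumes$age < 18 | volumes$age > 110]
  if (length(bad_age) > 0) {
    abort(paste0("Age outside [18, 110] for subject(s): ",
                 paste(bad_age, collapse = ", ")))
  }
  bad_tiv <- volumes$subject_id[is.na(volumes$tiv) | volumes$tiv <= 0]
  if (length(bad_tiv) > 0) {
    abort(paste0("Non-positive TIV for subject(s): ", paste(bad_tiv, collapse = ", ")))
  }
  for (rc in regions) {
    v <- volumes[[rc]]
    bad <- volumes$subject_id[is.na(v) | v <= 0]
    if (length(bad) > 0) {
      abort(paste0("Non-positive volume in region '", rc, "' for subject(s): ",
                   paste(bad, collapse = ", ")))
    }
    over <- volumes$subject_id[v >= volumes$tiv]
    if (length(over) > 0) {
      abort(paste0("Region '", rc, "' volume exceeds TIV for subject(s): ",
                   paste(over, collapse = ", ")))
    }
  }
  if ("mmse" %in% names(volumes)) {
    m <- volumes$mmse
    bad <- volumes$subject_id[!is.na(m) & (m < 0 | m > 30)]
    if (length(bad) > 0) {
      abort(paste0("MMSE outside [0, 30] for subject(s): ", paste(bad, collapse = ", ")))
    }
  }
  attr(volumes, "regions") <- regions
  volumes
}

#' Read and validate a rater-response table
#'
#' Reads the forced-choice responses of a multi-rater study: one row per
#' rating episode, i.e. one rater assessing one scan in one condition
#' (with or without the quantitative report available). Each episode
#' records a normal/abnormal call with a 1-5 confidence, and, for
#' abnormal calls only, an AD/FTD differential diagnosis with its own
#' 1-5 confidence.
#'
#' Validation enforces the response logic: a diagnosis is present if and
#' only if the scan was called abnormal; confidences are integers in
#' 1-5; each (rater, scan, condition) triple appears at most once.
#'
#' @param path Path to a CSV with columns `rater_id`, `experience`
#'   (`consultant`/`registrar`/`analyst`), `scan_id`, `condition`
#'   (`with_report`/`without_report`), `normality_call`
#'   (`normal`/`abnormal`), `diagnosis_call` (`AD`/`FTD`/`none`),
#'   `confidence_normality`, `confidence_diagnosis` (empty when normal).
#' @return A validated tibble of rating records.
#' @seealso [ratings_completeness()], [simulate_raters()]
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) abort(paste0("Ratings table not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_ratings(raw)
}

#' @rdname read_ratings
#' @param ratings A rating-record tibble.
#' @export
write_ratings <- function(ratings, path) {
  validate_ratings(ratings)
  readr::write_csv(ratings, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_ratings
#' @export
validate_ratings <- function(ratings) {
  needed <- c("rater_id", "experience", "scan_id", "condition",
              "normality_call", "diagnosis_call", "confidence_normality")
  assert_cols(ratings, needed, "Ratings table")
  ratings <- as_tibble(ratings)
  ratings$rater_id <- as.character(ratings$rater_id)
  ratings$scan_id <- as.character(ratings$scan_id)
  if (!"confidence_diagnosis" %in% names(ratings)) {
    ratings$confidence_diagnosis <- NA_real_
  }
  ratings$diagnosis_call <- dplyr::coalesce(as.character(ratings$diagnosis_call), "none")

  check_enum <- function(col, allowed) {
    bad <- setdiff(unique(ratings[[col]]), allowed)
    if (length(bad) > 0) {
      abort(paste0("Invalid ", col, " value(s): ", paste(bad, collapse = ", "),
                   " (expected ", paste(allowed, collapse = "/"), ")"))
    }
  }
  check_enum("experience", c("consultant", "registrar", "analyst"))
  check_enum("condition", c("with_report", "without_report"))
  check_enum("normality_call", c("normal", "abnormal"))
  check_enum("diagnosis_call", c("AD", "FTD", "none"))

  inconsistent <- ratings %>%
    filter((.data$normality_call == "normal" & .data$diagnosis_call != "none") |
             (.data$normality_call == "abnormal" & .data$diagnosis_call == "none"))
  if (nrow(inconsistent) > 0) {
    ex <- inconsistent[1, ]
    abort(paste0(
      "Diagnosis call inconsistent with normality call (diagnosis must be ",
      "'none' iff call is 'normal'), e.g. rater ", ex$rater_id, " scan ",
      ex$scan_id, " ", ex$condition
    ))
  }

  conf_ok <- function(x) is.na(x) | (x %in% 1:5)
  if (!all(conf_ok(ratings$confidence_normality)) ||
      anyNA(ratings$confidence_normality)) {
    abort("confidence_normality must be an integer in 1..5 for every episode")
  }
  if (!all(conf_ok(ratings$confidence_diagnosis))) {
    abort("confidence_diagnosis must be an integer in 1..5 (or absent for normal calls)")
  }

  dup <- ratings %>%
    count(.data$rater_id, .data$scan_id, .data$condition) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate episode(s): rater ", dup$rater_id[1], " scan ",
                 dup$scan_id[1], " ", dup$condition[1]))
  }
  ratings
}

#' Per-rater completeness of a rating study
#'
#' A complete study has every rater assessing every scan exactly twice,
#' once with and once without the report. This reports, per rater, how
#' many of the expected episodes are present.
#'
#' @param ratings A validated rating tibble ([read_ratings()]).
#' @param scan_ids Character vector of all scan ids in the study; defaults
#'   to the scans observed in `ratings`.
#' @return A tibble with columns `rater_id`, `n_present`, `n_expected`,
#'   `complete`.
#' @export
ratings_completeness <- function(ratings, scan_ids = NULL) {
  ratings <- validate_ratings(ratings)
  if (is.null(scan_ids)) scan_ids <- unique(ratings$scan_id)
  n_expected <- length(scan_ids) * 2L
  ratings %>%
    filter(.data$scan_id %in% scan_ids) %>%
    group_by(.data$rater_id) %>%
    summarise(n_present = n(), .groups = "drop") %>%
    mutate(n_expected = n_expected, complete = .data$n_present == n_expected)
}
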
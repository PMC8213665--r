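#' Rose-plot radial and colour scales
#'
#' The rose plot draws one sector per region, with the radial extent of a
#' sector encoding the region's normative percentile on a log scale:
#' `rose_radius(p) = (log10(p) + 2) / 4`, mapping the display range
#' \[0.01, 100\] onto \[0, 1\] (so the 1st percentile sits at half
#' radius). Sector colour follows a traffic-light scheme, green to red
#' for high to low percentile; the default breakpoints (1, 5, 25) align
#' with conventional clinical percentile alarm levels and are
#' configurable.
#'
#' @param p Percentile(s) in \[0.01, 100\]. Values outside the range are
#'   an error; clipping belongs upstream ([volume_percentiles()]).
#' @param breaks Ascending thresholds `c(red_upper, orange_upper,
#'   yellow_upper)`: `p < breaks[1]` is red, `< breaks[2]` orange,
#'   `< breaks[3]` yellow, else green.
#' @return `rose_radius()`: radial extent in \[0, 1\]. `rose_colour()`: a
#'   factor with levels red/orange/yellow/green.
#' @examples
#' rose_radius(c(0.01, 1, 100))
#' rose_colour(c(0.5, 3, 10, 50))
#' @export
rose_radius <- function(p) {
  if (any(is.na(p)) || any(p < 0.01) || any(p > 100)) {
    abort("Percentile outside [0.01, 100]; clip upstream before plotting")
  }
  (log10(p) + 2) / 4
}

#' @rdname rose_radius
#' @export
rose_colour <- function(p, breaks = c(1, 5, 25)) {
  if (any(is.na(p)) || any(p < 0.01) || any(p > 100)) {
    abort("Percentile outside [0.01, 100]; clip upstream before plotting")
  }
  if (length(breaks) != 3 || is.unsorted(breaks, strictly = TRUE)) {
    abort("breaks must be three strictly increasing thresholds")
  }
  cls <- ifelse(p < breaks[1], "red",
         ifelse(p < breaks[2], "orange",
         ifelse(p < breaks[3], "yellow", "green")))
  factor(cls, levels = c("red", "orange", "yellow", "green"))
}

#' Rose-plot sector geometry
#'
#' Lays out one sector per region of the region map, in map order,
#' partitioning the circle into equal angular spans, with radial extent
#' [rose_radius()] and colour class [rose_colour()] from the region's
#' percentile.
#'
#' @param percentiles A tibble with columns `region` and `percentile`
#'   (e.g. from [volume_percentiles()] for one subject).
#' @param region_map A region map ([default_region_map()]).
#' @param breaks Colour breakpoints, see [rose_colour()].
#' @return A tibble with one row per sector: `region`, `lobe`,
#'   `start_deg`, `end_deg`, `percentile`, `radius`, `colour`.
#' @export
rose_geometry <- function(percentiles, region_map = default_region_map(),
                          breaks = c(1, 5, 25)) {
  region_map <- validate_region_map(region_map)
  missing <- setdiff(region_map$region, percentiles$region)
  if (length(missing) > 0) {
    abort(paste0("No percentile for rose region(s): ", paste(missing, collapse = ", ")))
  }
  n <- nrow(region_map)
  span <- 360 / n
  region_map %>%
    mutate(
      start_deg = (dplyr::row_number() - 1) * span,
      end_deg = dplyr::row_number() * span,
      percentile = percentiles$percentile[match(.data$region, percentiles$region)],
      radius = rose_radius(.data$percentile),
      colour = rose_colour(.data$percentile, breaks = breaks)
    )
}

#' Assemble everything one quantitative report needs
#'
#' Collects, for a single subject, the regional percentiles, left/right
#' hippocampal percentiles, brain parenchymal fraction with its own
#' normative percentile, optional scan-quality metrics, and the rose-plot
#' geometry, into one bundle that [render_report()] turns into a
#' document.
#'
#' @param model A fitted [fit_normative_model()].
#' @param bpf_model A fitted [fit_bpf_model()].
#' @param subject A one-row volume table for the subject to report.
#' @param region_map Region map for the rose plot.
#' @param qc Optional one-row tibble with `snr` and `cnr`
#'   ([qc_metrics()]); `NULL` marks QC as unavailable.
#' @param hippocampus Named character vector giving the left/right
#'   hippocampal region columns.
#' @param breaks Rose colour breakpoints.
#' @return An object of class `"qreport_bundle"`.
#' @export
build_report_bundle <- function(model, bpf_model, subject,
                                region_map = default_region_map(),
                                qc = NULL,
                                hippocampus = c(left = "hippocampus_left",
                                                right = "hippocampus_right"),
                                breaks = c(1, 5, 25)) {
  subject <- validate_volume_table(subject)
  if (nrow(subject) != 1) abort("A report bundle covers exactly one subject")
  rose_regions <- validate_region_map(region_map)$region
  pct <- volume_percentiles(model, subject,
                            regions = intersect(model$coefficients$region,
                                                union(rose_regions, hippocampus)))
  hip <- c(
    left = pct$percentile[pct$region == hippocampus[["left"]]],
    right = pct$percentile[pct$region == hippocampus[["right"]]]
  )
  bpf <- bpf_percentile(bpf_model, subject)
  structure(
    list(
      age = subject$age,
      sex = subject$sex,
      percentiles = pct %>% select("region", "percentile"),
      hippocampal = hip,
      bpf = bpf$bpf,
      bpf_percentile = bpf$percentile,
      qc = qc,
      rose = rose_geometry(pct %>% select("region", "percentile"),
                           region_map = region_map, breaks = breaks),
      bpf_model = bpf_model
    ),
    class = "qreport_bundle"
  )
}

#' @export
print.qreport_bundle <- function(x, ...) {
  cat("Quantitative report bundle\n")
  cat("  age/sex:            ", num_fmt(x$age, 1), " / ", x$sex, "\n", sep = "")
  cat("  hippocampus (L/R):  ", num_fmt(x$hippocampal[["left"]], 1), " / ",
      num_fmt(x$hippocampal[["right"]], 1), " %ile\n", sep = "")
  cat("  BPF:                ", num_fmt(x$bpf, 3), " (",
      num_fmt(x$bpf_percentile, 1), " %ile)\n", sep = "")
  cat("  rose sectors:       ", nrow(x$rose), "\n", sep = "")
  invisible(x)
}

rose_palette <- c(red = "#e74c3c", orange = "#e67e22",
                  yellow = "#f1c40f", green = "#2ecc71")

# Polar -> cartesian for the SVG rose; 0 deg at 12 o'clock, clockwise.
polar_xy <- function(deg, r, cx, cy, scale) {
  rad <- (deg - 90) * pi / 180
  c(cx + scale * r * cos(rad), cy + scale * r * sin(rad))
}

svg_rose <- function(rose, cx = 210, cy = 210, scale = 180,
                     gridlines = c(1, 5, 25, 50, 100)) {
  parts <- character(0)
  for (i in seq_len(nrow(rose))) {
    a0 <- polar_xy(rose$start_deg[i], rose$radius[i], cx, cy, scale)
    a1 <- polar_xy(rose$end_deg[i], rose$radius[i], cx, cy, scale)
    large <- if ((rose$end_deg[i] - rose$start_deg[i]) > 180) 1 else 0
    parts <- c(parts, sprintf(
      '<path d="M %s %s L %s %s A %s %s 0 %d 1 %s %s Z" fill="%s" stroke="#ffffff" stroke-width="1"><title>%s: %s</title></path>',
      num_fmt(cx, 2), num_fmt(cy, 2), num_fmt(a0[1], 2), num_fmt(a0[2], 2),
      num_fmt(scale * rose$radius[i], 2), num_fmt(scale * rose$radius[i], 2),
      large, num_fmt(a1[1], 2), num_fmt(a1[2], 2),
      rose_palette[[as.character(rose$colour[i])]],
      rose$region[i], num_fmt(rose$percentile[i], 1)
    ))
  }
  for (g in gridlines) {
    parts <- c(parts, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#999999" stroke-dasharray="3,3" stroke-width="0.8"/>',
      num_fmt(cx, 2), num_fmt(cy, 2), num_fmt(scale * rose_radius(g), 2)
    ))
  }
  # sector labels just outside the unit circle
  for (i in seq_len(nrow(rose))) {
    mid <- (rose$start_deg[i] + rose$end_deg[i]) / 2
    at <- polar_xy(mid, 1.08, cx, cy, scale)
    parts <- c(parts, sprintf(
      '<text x="%s" y="%s" font-size="8" text-anchor="middle">%s</text>',
      num_fmt(at[1], 2), num_fmt(at[2], 2), rose$region[i]
    ))
  }
  paste0(
    '<svg width="420" height="420" viewBox="0 0 420 420" xmlns="http://www.w3.org/2000/svg">',
    paste(parts, collapse = ""), "</svg>"
  )
}

svg_bpf_panel <- function(bpf_model, age, bpf,
                          curve_percentiles = c(5, 25, 50, 75, 95),
                          width = 420, height = 260) {
  a0 <- bpf_model$age_range[1]
  a1 <- bpf_model$age_range[2]
  ages <- seq(a0, a1, length.out = 25)
  # plotting window: BPF band around the normative curves
  b_lo <- bpf_model$intercept + bpf_model$beta_age * max(ages) - 4 * bpf_model$sigma
  b_hi <- bpf_model$intercept + bpf_model$beta_age * min(ages) + 4 * bpf_model$sigma
  b_lo <- min(b_lo, bpf - 0.02); b_hi <- max(b_hi, bpf + 0.02)
  px <- function(a) 40 + (a - a0) / (a1 - a0) * (width - 60)
  py <- function(b) (height - 30) - (b - b_lo) / (b_hi - b_lo) * (height - 50)
  parts <- character(0)
  for (p in curve_percentiles) {
    b <- bpf_model$intercept + bpf_model$beta_age * ages +
      bpf_model$sigma * qnorm(p / 100)
    pts <- paste(num_fmt(px(ages), 2), num_fmt(py(b), 2), sep = ",",
                 collapse = " ")
    parts <- c(parts, sprintf(
      '<polyline points="%s" fill="none" stroke="#7f8c8d" stroke-width="%s"/><text x="%s" y="%s" font-size="8" fill="#7f8c8d">%s</text>',
      pts, if (p == 50) "1.6" else "0.8",
      num_fmt(px(a1) + 2, 2), num_fmt(py(b[length(b)]) + 2, 2), num_fmt(p, 0)
    ))
  }
  parts <- c(parts, sprintf(
    '<circle cx="%s" cy="%s" r="5" fill="#e74c3c"/>',
    num_fmt(px(age), 2), num_fmt(py(bpf), 2)
  ))
  parts <- c(parts, sprintf(
    '<text x="%s" y="%s" font-size="10" text-anchor="middle">age (years)</text>',
    num_fmt(40 + (width - 60) / 2, 2), num_fmt(height - 6, 2)
  ))
  paste0(
    sprintf('<svg width="%d" height="%d" viewBox="0 0 %d %d" xmlns="http://www.w3.org/2000/svg">',
            width, height, width, height),
    paste(parts, collapse = ""), "</svg>"
  )
}

#' Render a quantitative report document
#'
#' Writes a self-contained single-page HTML document (SVG figures
#' embedded inline) with four panels: demographics, hippocampal
#' percentiles, BPF against the normative percentile curves (5/25/50/75/
#' 95 across age, subject as a red dot), and the traffic-light rose
#' plot. The demographics panel carries age and sex only - no subject
#' identifier and no clinical fields - mirroring the blinding of raters
#' in a reading study. Output is byte-deterministic for identical input.
#'
#' @param bundle A [build_report_bundle()] object; must include BPF.
#' @param path Output `.html` path.
#' @return `path`, invisibly.
#' @export
render_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "qreport_bundle"))
  if (is.null(bundle$bpf) || is.na(bundle$bpf)) {
    abort("Report bundle is missing the brain parenchymal fraction")
  }
  qc_html <- if (is.null(bundle$qc)) {
    "<p>SNR: not available &middot; CNR: not available</p>"
  } else {
    sprintf("<p>SNR: %s &middot; CNR: %s</p>",
            num_fmt(bundle$qc$snr, 1), num_fmt(bundle$qc$cnr, 1))
  }
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>Quantitative volumetric report</title>\n",
    "<style>body{font-family:sans-serif;max-width:900px;margin:auto}",
    ".panel{display:inline-block;vertical-align:top;margin:8px;padding:8px;",
    "border:1px solid #ddd;border-radius:6px}</style>\n</head>\n<body>\n",
    "<h1>Quantitative volumetric report</h1>\n",
    "<div class=\"panel\"><h2>Demographics</h2>",
    sprintf("<p>Age: %s years &middot; Sex: %s</p>",
            num_fmt(bundle$age, 0), bundle$sex),
    "<h2>Quality control</h2>", qc_html, "</div>\n",
    "<div class=\"panel\"><h2>Hippocampal volume percentiles</h2>",
    sprintf("<p>Left: %s &middot; Right: %s</p>",
            num_fmt(bundle$hippocampal[["left"]], 1),
            num_fmt(bundle$hippocampal[["right"]], 1)),
    sprintf("<h2>Brain parenchymal fraction</h2><p>BPF: %s (percentile %s)</p>",
            num_fmt(bundle$bpf, 3), num_fmt(bundle$bpf_percentile, 1)),
    svg_bpf_panel(bundle$bpf_model, bundle$age, bundle$bpf), "</div>\n",
    "<div class=\"panel\"><h2>Regional grey-matter percentiles</h2>",
    svg_rose(bundle$rose), "</div>\n",
    "</body>\n</html>\n"
  )
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

#' ggplot2 figures for report components
#'
#' `plot_rose()` draws the traffic-light rose plot of one subject's
#' regional percentiles (log radial scale); `plot_bpf()` draws the BPF
#' panel with the subject overlaid on normative percentile curves.
#'
#' @param bundle A [build_report_bundle()] object.
#' @return A ggplot object.
#' @export
plot_rose <- function(bundle) {
  stopifnot(inherits(bundle, "qreport_bundle"))
  rose <- bundle$rose
  ggplot2::ggplot(rose) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_deg, xmax = .data$end_deg,
                                    ymin = 0, ymax = .data$radius,
                                    fill = .data$colour),
                       colour = "white") +
    ggplot2::geom_hline(yintercept = rose_radius(c(1, 5, 25, 50, 100)),
                        linetype = "dashed", linewidth = 0.3, colour = "grey50") +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(
      limits = c(0, 360),
      breaks = (rose$start_deg + rose$end_deg) / 2,
      labels = rose$region
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::scale_fill_manual(values = rose_palette, drop = FALSE,
                               name = "percentile band") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(title = "Regional volume percentiles (log radial scale)")
}

#' @rdname plot_rose
#' @export
plot_bpf <- function(bundle) {
  stopifnot(inherits(bundle, "qreport_bundle"))
  m <- bundle$bpf_model
  ages <- seq(m$age_range[1], m$age_range[2], length.out = 50)
  curves <- tidyr::expand_grid(age = ages, pct = c(5, 25, 50, 75, 95)) %>%
    mutate(bpf = m$intercept + m$beta_age * .data$age +
             m$sigma * qnorm(.data$pct / 100))
  ggplot2::ggplot(curves, ggplot2::aes(.data$age, .data$bpf,
                                       group = .data$pct)) +
    ggplot2::geom_line(colour = "grey55", linewidth = 0.4) +
    ggplot2::annotate("point", x = bundle$age, y = bundle$bpf,
                      colour = "#e74c3c", size = 3) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "Brain parenchymal fraction vs normative curves",
                  x = "age (years)", y = "BPF")
}
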
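#' Region-to-lobe grouping for the rose plot
#'
#' A region map assigns every rose-plot region to a lobe and fixes the
#' display order of sectors. It is a tibble with columns `lobe` and
#' `region`, one row per sector, ordered as drawn (clockwise from the top).
#'
#' `default_region_map()` returns the package default: bilateral frontal,
#' temporal (with hippocampus), parietal, occipital and
#' subcortical/insular sectors. The exact region set shown on a report is
#' deliberately user-configurable because segmentation tools differ in
#' their parcellation; any map whose region names match the volume-table
#' columns is valid.
#'
#' @param path For `read_region_map()`, path to a JSON file of the form
#'   `{"groups": [{"lobe": "frontal", "regions": ["frontal_left", ...]}, ...]}`.
#' @param region_map A region-map tibble to validate or write.
#'
#' @return A tibble with columns `lobe` (character) and `region`
#'   (character), ordered for display.
#' @examples
#' default_region_map()
#' @export
default_region_map <- function() {
  tibble::tribble(
    ~lobe,         ~region,
    "frontal",     "frontal_left",
    "frontal",     "frontal_right",
    "temporal",    "temporal_left",
    "temporal",    "temporal_right",
    "temporal",    "hippocampus_left",
    "temporal",    "hippocampus_right",
    "parietal",    "parietal_left",
    "parietal",    "parietal_right",
    "occipital",   "occipital_left",
    "occipital",   "occipital_right",
    "subcortical", "insula_left",
    "subcortical", "insula_right",
    "subcortical", "caudate_left",
    "subcortical", "caudate_right"
  )
}

#' @rdname default_region_map
#' @export
read_region_map <- function(path) {
  if (!file.exists(path)) abort(paste0("Region map file not found: ", path))
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(parsed$groups)) abort("Region map JSON must have a top-level 'groups' array")
  out <- purrr::map_dfr(parsed$groups, function(g) {
    tibble(lobe = g$lobe, region = unlist(g$regions))
  })
  validate_region_map(out)
}

#' @rdname default_region_map
#' @export
write_region_map <- function(region_map, path) {
  validate_region_map(region_map)
  groups <- region_map %>%
    group_by(.data$lobe) %>%
    summarise(regions = list(.data$region), .groups = "drop") %>%
    # preserve first-appearance lobe order, not alphabetical
    arrange(match(.data$lobe, unique(region_map$lobe)))
  payload <- list(groups = purrr::pmap(groups, function(lobe, regions) {
    list(lobe = lobe, regions = regions)
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname default_region_map
#' @export
validate_region_map <- function(region_map) {
  assert_cols(region_map, c("lobe", "region"), "Region map")
  if (anyDuplicated(region_map$region)) {
    dup <- unique(region_map$region[duplicated(region_map$region)])
    abort(paste0("Region name(s) duplicated across groups: ", paste(dup, collapse = ", ")))
  }
  if (nrow(region_map) == 0) abort("Region map has no regions")
  as_tibble(region_map)
}
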
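#' Habitat suitability classes
#'
#' The four-class reclassification of the habitat suitability index:
#' not suitable 0.00-0.25, low 0.25-0.50, moderate 0.50-0.75, high
#' 0.75-1.00.  Intervals are lower-closed (an HSI of exactly 0.25 is
#' "low"); the top class is closed above so 1.0 is "high".
#'
#' @param map an `enm_grid` of HSI values in 0-1 (or a numeric vector).
#' @param breaks inner class edges.
#' @return same shape as the input with integer classes 1-4 (1 = not
#'   suitable ... 4 = high); nodata preserved.
#' @export
classify_suitability <- function(map, breaks = c(0.25, 0.5, 0.75)) {
  v <- if (inherits(map, "enm_grid")) map$values else as.numeric(map)
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1))
    stopf("HSI values must lie in [0, 1]")
  cls <- rep(NA_real_, length(v))
  cls[ok] <- findInterval(v[ok], breaks) + 1   # lower-closed bins
  if (inherits(map, "enm_grid"))
    new_grid(cls, map$nrows, map$ncols, map$xll, map$yll, map$cellsize,
             nodata = map$nodata)
  else cls
}

#' Per-scenario class area percentages
#'
#' Percentage of region cells in each suitability class.  By default
#' area = cell counting at fixed resolution; optional cosine-latitude
#' weighting approximates true cell areas on a geographic grid.
#'
#' @param class_grid integer class grid from [classify_suitability()].
#' @param region_mask 0/1 `enm_grid` defining the region denominator;
#'   defaults to all valid cells of `class_grid`.
#' @param scenario label stored in the result.
#' @param latitude_weighted weight cells by cos(latitude of cell
#'   centre).
#' @return an `enm_area_summary`: one-row data.frame with `scenario`,
#'   `pct_not`, `pct_low`, `pct_moderate`, `pct_high`, `pct_suitable`.
#' @export
area_summary <- function(class_grid, region_mask = NULL,
                         scenario = "current", latitude_weighted = FALSE) {
  if (is.null(region_mask)) {
    keep <- !is.na(class_grid$values)
  } else {
    if (!geom_equal(class_grid, region_mask)) stopf("mask geometry mismatch")
    keep <- !is.na(region_mask$values) & region_mask$values != 0
  }
  idx <- which(keep)
  if (!length(idx)) stopf("empty region mask")
  w <- if (latitude_weighted)
    cos(cell_center(class_grid, idx)$lat * pi / 180)
  else rep(1, length(idx))
  cls <- class_grid$values[idx]
  tot <- sum(w)
  pct <- vapply(1:4, function(k)
    100 * sum(w[!is.na(cls) & cls == k]) / tot, numeric(1))
  out <- data.frame(scenario = scenario, pct_not = pct[1],
                    pct_low = pct[2], pct_moderate = pct[3],
                    pct_high = pct[4], pct_suitable = pct[3] + pct[4],
                    stringsAsFactors = FALSE)
  class(out) <- c("enm_area_summary", "data.frame")
  out
}

#' Suitable-habitat percentage (moderate + high)
#' @param summary an `enm_area_summary` row, or a list/data.frame with
#'   `pct_moderate` and `pct_high`.
#' @return numeric percentage.
#' @export
suitable_percent <- function(summary) {
  summary$pct_moderate + summary$pct_high
}

#' Change in suitable percentage between scenarios
#' @param current,future suitable-habitat percentages.
#' @param digits decimals for the reported delta (default 2, matching
#'   percentage tables).
#' @return `future - current`, rounded.
#' @export
habitat_change <- function(current, future, digits = 2) {
  round(future - current, digits)
}

#' Growing / declining / fluctuating trend typology
#'
#' A species is "growing" when every future scenario's suitable
#' percentage strictly exceeds the current one, "declining" when every
#' one is strictly below, and "fluctuating" otherwise.  Comparisons use
#' the unrounded values.
#'
#' @param current current suitable percentage (or Schoener's D).
#' @param futures numeric vector of the four future-scenario values.
#' @return an `enm_typology`: list with `label` and `deltas`.
#' @export
trend_typology <- function(current, futures) {
  if (length(futures) != 4)
    stopf("expected exactly 4 future scenario values, got %d",
          length(futures))
  deltas <- futures - current
  label <- if (all(deltas > 0)) "growing"
           else if (all(deltas < 0)) "declining"
           else "fluctuating"
  structure(list(label = label, deltas = deltas), class = "enm_typology")
}

#' @export
print.enm_typology <- function(x, ...) {
  cat(sprintf("<%s: deltas %s>\n", x$label,
              paste(sprintf("%+.2f", x$deltas), collapse = ", ")))
  invisible(x)
}
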
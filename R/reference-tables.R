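# Reference results for four endangered Chinese holoparasites and their
# primary host plants, bundled as plain data for regression-testing the
# summary arithmetic, typology rule and post-hoc machinery against a
# published study's printed tables.  These are inputs, not outputs: the
# package never tunes anything toward them.

REF_SCENARIOS <- c("current", "RCP2.6-2050s", "RCP8.5-2050s",
                   "RCP2.6-2070s", "RCP8.5-2070s")

#' Reference habitat-area percentages
#'
#' Per-scenario class percentages (of the study region's total area)
#' for four parasitic plants and their primary hosts under a current
#' and four future climate scenarios.
#'
#' @return data.frame: species, role, scenario, pct_not, pct_low,
#'   pct_moderate, pct_high, pct_suitable.
#' @export
reference_area_percentages <- function() {
  sp <- list(
    list("Cynomorium songaricum", "parasite", c(
      91.35, 5.97, 2.13, 0.55, 2.68,
      91.69, 5.95, 1.93, 0.44, 2.37,
      91.71, 5.61, 2.24, 0.45, 2.69,
      91.65, 5.93, 2.01, 0.41, 2.42,
      90.89, 6.51, 2.16, 0.43, 2.59)),
    list("Nitraria sibirica", "host", c(
      65.91, 22.28, 10.81, 1.00, 11.81,
      62.21, 24.81, 11.94, 1.03, 12.97,
      61.96, 24.77, 12.30, 0.97, 13.27,
      62.58, 24.69, 11.54, 1.20, 12.74,
      62.78, 24.34, 11.74, 1.15, 12.89)),
    list("Boschniakia rossica", "parasite", c(
      88.62, 7.62, 2.96, 0.81, 3.77,
      87.99, 7.13, 3.99, 0.89, 4.88,
      88.48, 6.61, 3.96, 0.95, 4.91,
      88.54, 6.73, 3.62, 1.11, 4.73,
      88.52, 7.06, 3.28, 1.14, 4.42)),
    list("Alnus mandshurica", "host", c(
      95.05, 3.53, 1.24, 0.18, 1.42,
      95.14, 3.29, 1.47, 0.10, 1.57,
      94.53, 3.71, 1.66, 0.10, 1.76,
      94.83, 3.54, 1.43, 0.20, 1.63,
      94.49, 3.61, 1.73, 0.16, 1.89)),
    list("Cistanche deserticola", "parasite", c(
      91.01, 5.35, 3.27, 0.38, 3.65,
      90.58, 5.96, 3.04, 0.42, 3.46,
      90.56, 5.97, 3.14, 0.34, 3.48,
      90.35, 6.03, 3.34, 0.28, 3.62,
      90.26, 6.07, 3.40, 0.28, 3.68)),
    list("Haloxylon ammodendron", "host", c(
      83.11, 7.29, 9.31, 0.29, 9.60,
      79.78, 11.31, 8.41, 0.50, 8.91,
      79.48, 11.42, 8.86, 0.24, 9.10,
      79.65, 11.26, 8.69, 0.40, 9.09,
      80.28, 11.22, 7.41, 1.10, 8.51)),
    list("Cistanche mongolica", "parasite", c(
      97.33, 1.70, 0.78, 0.19, 0.97,
      95.59, 2.77, 1.51, 0.13, 1.64,
      95.31, 3.08, 1.52, 0.09, 1.61,
      95.67, 2.77, 1.48, 0.07, 1.55,
      95.32, 3.07, 1.53, 0.09, 1.62)),
    list("Tamarix ramosissima", "host", c(
      68.61, 17.96, 12.75, 0.68, 13.43,
      66.09, 19.74, 13.33, 0.83, 14.16,
      66.13, 20.15, 13.09, 0.63, 13.72,
      65.60, 20.11, 13.77, 0.52, 14.29,
      66.17, 20.71, 12.19, 0.93, 13.12)))
  do.call(rbind, lapply(sp, function(s) {
    m <- matrix(s[[3]], ncol = 5, byrow = TRUE)
    data.frame(species = s[[1]], role = s[[2]], scenario = REF_SCENARIOS,
               pct_not = m[, 1], pct_low = m[, 2], pct_moderate = m[, 3],
               pct_high = m[, 4], pct_suitable = m[, 5],
               stringsAsFactors = FALSE)
  }))
}

#' Reference Schoener's D niche-overlap values
#'
#' Per-scenario niche overlap between each parasite and its primary
#' host, for the same study system as
#' [reference_area_percentages()].
#'
#' @return data.frame: pair, scenario, d.
#' @export
reference_overlap_d <- function() {
  pairs <- list(
    list("C. songaricum-N. sibirica",
         c(0.5180, 0.5238, 0.5080, 0.5115, 0.5096)),
    list("B. rossica-A. mandshurica",
         c(0.6673, 0.6769, 0.7067, 0.7208, 0.7316)),
    list("C. deserticola-H. ammodendron",
         c(0.6585, 0.6684, 0.6577, 0.6792, 0.6746)),
    list("C. mongolica-T. ramosissima",
         c(0.2593, 0.2908, 0.2853, 0.2846, 0.2723)))
  do.call(rbind, lapply(pairs, function(p)
    data.frame(pair = p[[1]], scenario = REF_SCENARIOS, d = p[[2]],
               stringsAsFactors = FALSE)))
}

#' Reference trend labels
#'
#' Published growing/declining/fluctuating labels for the eight species
#' (habitat-area trend) and the four parasite-host pairs (overlap
#' trend).
#'
#' @return list with data.frames `species` and `pairs`.
#' @export
reference_trend_labels <- function() {
  list(
    species = data.frame(
      species = c("Cynomorium songaricum", "Nitraria sibirica",
                  "Boschniakia rossica", "Alnus mandshurica",
                  "Cistanche deserticola", "Haloxylon ammodendron",
                  "Cistanche mongolica", "Tamarix ramosissima"),
      label = c("fluctuating", "growing", "growing", "growing",
                "fluctuating", "declining", "growing", "fluctuating"),
      stringsAsFactors = FALSE),
    pairs = data.frame(
      pair = c("C. songaricum-N. sibirica", "B. rossica-A. mandshurica",
               "C. deserticola-H. ammodendron",
               "C. mongolica-T. ramosissima"),
      label = c("fluctuating", "growing", "fluctuating", "growing"),
      stringsAsFactors = FALSE))
}
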
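#' Read and clean a species occurrence table
#'
#' Reads a CSV of presence coordinates (WGS84 decimal degrees), removes
#' exact duplicate coordinate pairs and rejects rows with out-of-range
#' or unparseable coordinates.  Counts of dropped rows are attached as
#' attributes and reported via `message()`.
#'
#' @param path CSV path.
#' @param species optional species name to filter on; default keeps all
#'   rows (the file is then expected to hold one species).
#' @param col_species,col_lon,col_lat column names in the file.
#' @return an `enm_occurrences` object: data.frame with columns
#'   `species`, `lon`, `lat`; attributes `n_duplicates`, `n_rejected`.
#' @export
read_occurrences <- function(path, species = NULL,
                             col_species = "species",
                             col_lon = "longitude",
                             col_lat = "latitude") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        comment.char = "#")
  for (cl in c(col_species, col_lon, col_lat))
    if (!cl %in% names(df)) stopf("missing column '%s' in %s", cl, path)
  occ <- data.frame(
    species = as.character(df[[col_species]]),
    lon = suppressWarnings(as.numeric(df[[col_lon]])),
    lat = suppressWarnings(as.numeric(df[[col_lat]])),
    stringsAsFactors = FALSE)
  if (!is.null(species)) occ <- occ[occ$species == species, , drop = FALSE]
  bad <- is.na(occ$lon) | is.na(occ$lat) |
    occ$lon < -180 | occ$lon > 180 | occ$lat < -90 | occ$lat > 90
  n_rejected <- sum(bad)
  occ <- occ[!bad, , drop = FALSE]
  dup <- duplicated(occ[, c("species", "lon", "lat")])
  n_dup <- sum(dup)
  occ <- occ[!dup, , drop = FALSE]
  rownames(occ) <- NULL
  if (n_rejected > 0)
    message(sprintf("read_occurrences: rejected %d out-of-range/unparseable row(s)",
                    n_rejected))
  if (n_dup > 0)
    message(sprintf("read_occurrences: removed %d exact duplicate(s)", n_dup))
  structure(occ, class = c("enm_occurrences", "data.frame"),
            n_duplicates = n_dup, n_rejected = n_rejected)
}

#' Construct an occurrence set from coordinates
#' @param species species label.
#' @param lon,lat coordinate vectors.
#' @return an `enm_occurrences` data.frame.
#' @export
occurrences <- function(species, lon, lat) {
  stopifnot(length(lon) == length(lat))
  if (any(lon < -180 | lon > 180 | lat < -90 | lat > 90, na.rm = TRUE))
    stopf("coordinates out of WGS84 range")
  structure(
    data.frame(species = species, lon = as.numeric(lon),
               lat = as.numeric(lat), stringsAsFactors = FALSE),
    class = c("enm_occurrences", "data.frame"))
}

#' Spatial rarefaction: one record per grid cell
#'
#' Thins occurrences so that at most one record remains in each cell of
#' the supplied lattice (by default the climate stack's own grid, the
#' analogue of thinning at the modelling resolution).  Within a cell the
#' first record in input order is kept; records outside the grid extent
#' are dropped and reported.
#'
#' @param occ an `enm_occurrences` object.
#' @param grid an `enm_grid` (or stack layer) supplying the lattice.
#' @return rarefied `enm_occurrences` with attribute `cell` (kept cell
#'   indices) and `n_outside`.
#' @export
spatial_rarefy <- function(occ, grid) {
  if (inherits(grid, "enm_stack")) grid <- grid[[1]]
  idx <- cell_index(grid, occ$lon, occ$lat)
  outside <- is.na(idx)
  n_outside <- sum(outside)
  if (n_outside > 0)
    message(sprintf("spatial_rarefy: dropped %d record(s) outside the grid extent",
                    n_outside))
  occ2 <- occ[!outside, , drop = FALSE]
  idx <- idx[!outside]
  keep <- !duplicated(idx)
  out <- occ2[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    stopf("spatial rarefaction removed all records; use a coarser grid or more records")
  structure(out, class = c("enm_occurrences", "data.frame"),
            cell = idx[keep], n_outside = n_outside)
}

#' Draw background (pseudo-absence) cells
#'
#' Samples `n` distinct cells uniformly without replacement from the
#' valid cells of a mask.  Background cells may coincide with presence
#' cells (presence-background, not presence-absence, design).
#'
#' @param mask 0/1 `enm_grid` of valid cells.
#' @param n number of background points (capped at the number of valid
#'   cells, with a warning).
#' @param seed RNG seed for a reproducible draw.
#' @return integer vector of row-major cell indices.
#' @export
sample_background <- function(mask, n, seed = NULL) {
  cells <- mask_cells(mask)
  if (!length(cells)) stopf("mask has no valid cells")
  if (n >= length(cells)) {
    if (n > length(cells))
      warnf("requested %d background points but only %d valid cells; using all",
            n, length(cells))
    return(cells)
  }
  with_seed(seed, sort(sample(cells, n, replace = FALSE)))
}

#' Extract layer values at points or cells
#'
#' Builds the flat sample table used for model fitting: one row per
#' point, one column per layer, plus the containing cell index.  Points
#' falling on nodata cells (or outside the extent) are dropped and
#' reported.
#'
#' @param stack an `enm_stack`.
#' @param points either an `enm_occurrences` / data.frame with `lon`,
#'   `lat` columns, or an integer vector of cell indices.
#' @param label value for the `label` column (e.g. 1 presence,
#'   0 background); recycled.
#' @return data.frame with columns `cell`, `label`, then one column per
#'   layer.
#' @export
extract_values <- function(stack, points, label = NA) {
  g <- stack[[1]]
  if (is.numeric(points) && is.null(dim(points)) && !is.data.frame(points)) {
    idx <- as.integer(points)
    if (any(idx < 1 | idx > g$nrows * g$ncols))
      stopf("cell index out of range")
  } else {
    idx <- cell_index(g, points$lon, points$lat)
    if (any(is.na(idx))) {
      message(sprintf("extract_values: dropped %d point(s) outside the extent",
                      sum(is.na(idx))))
      idx <- idx[!is.na(idx)]
    }
  }
  vals <- vapply(unclass(stack), function(l) l$values[idx],
                 numeric(length(idx)))
  if (length(idx) == 1L) vals <- matrix(vals, nrow = 1,
                                        dimnames = list(NULL, stack_names(stack)))
  ok <- stats::complete.cases(vals)
  if (any(!ok))
    message(sprintf("extract_values: dropped %d point(s) on nodata cells",
                    sum(!ok)))
  out <- data.frame(cell = idx[ok], label = rep_len(label, length(idx))[ok])
  cbind(out, as.data.frame(vals[ok, , drop = FALSE]))
}
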
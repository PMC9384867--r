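#' Gridded raster layers
#'
#' An `enm_grid` is a georeferenced lattice of cell values: the spatial
#' substrate for all climate layers, suitability maps and masks in this
#' package.  Values are stored row-major with the first row being the
#' northernmost; missing cells are `NA` internally and serialized as the
#' `nodata` sentinel.  The georeference is the lower-left *corner*
#' (`xll`, `yll`) in decimal degrees; centre-form ESRI headers are
#' converted on read so only one convention exists internally.
#'
#' Cell `(i, j)` (1-based, row 1 = north) covers the half-open box
#' `[xll + (j-1)*cs, xll + j*cs)` in longitude and
#' `[yll + (nrows-i)*cs, yll + (nrows-i+1)*cs)` in latitude, so every
#' point maps to at most one cell.
#'
#' @param values numeric vector of length `nrows * ncols`, row-major,
#'   first row = northernmost; `NA` marks nodata.
#' @param nrows,ncols grid dimensions.
#' @param xll,yll lower-left corner, decimal degrees.
#' @param cellsize cell edge length, decimal degrees.
#' @param nodata sentinel used when writing to disk.
#' @return an object of class `enm_grid`.
#' @export
new_grid <- function(values, nrows, ncols, xll, yll, cellsize,
                     nodata = -9999) {
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (nrows < 1L || ncols < 1L) stopf("grid must have at least one row and column")
  if (cellsize <= 0) stopf("cellsize must be positive")
  values <- as.numeric(values)
  if (length(values) != nrows * ncols)
    stopf("values length %d != nrows*ncols = %d", length(values), nrows * ncols)
  if (any(!is.finite(values) & !is.na(values)))
    stopf("non-finite values must be encoded as NA (nodata)")
  structure(
    list(nrows = nrows, ncols = ncols, xll = xll, yll = yll,
         cellsize = cellsize, nodata = nodata, values = values),
    class = "enm_grid")
}

#' @export
print.enm_grid <- function(x, ...) {
  cat(sprintf("<enm_grid %d x %d, xll=%g yll=%g cellsize=%g, %d nodata>\n",
              x$nrows, x$ncols, x$xll, x$yll, x$cellsize,
              sum(is.na(x$values))))
  invisible(x)
}

grid_geometry <- function(g) g[c("nrows", "ncols", "xll", "yll", "cellsize")]

geom_equal <- function(a, b, tol = 1e-9) {
  ga <- grid_geometry(a); gb <- grid_geometry(b)
  ga$nrows == gb$nrows && ga$ncols == gb$ncols &&
    abs(ga$xll - gb$xll) < tol && abs(ga$yll - gb$yll) < tol &&
    abs(ga$cellsize - gb$cellsize) < tol
}

#' Map coordinates to cell indices
#'
#' Applies the half-open point-in-cell rule: a point on a cell's west or
#' south edge belongs to that cell; points on the grid's extreme north or
#' east edge fall outside.
#'
#' @param grid an `enm_grid` (or anything carrying its geometry fields).
#' @param lon,lat coordinate vectors, decimal degrees.
#' @return integer vector of row-major 1-based cell indices; `NA` for
#'   points outside the extent.
#' @export
cell_index <- function(grid, lon, lat) {
  cs <- grid$cellsize
  j <- floor((lon - grid$xll) / cs)          # 0-based column
  ifloor <- floor((lat - grid$yll) / cs)     # 0-based row from south
  i <- grid$nrows - 1 - ifloor               # 0-based row from north
  ok <- j >= 0 & j < grid$ncols & i >= 0 & i < grid$nrows
  idx <- ifelse(ok, i * grid$ncols + j + 1, NA_integer_)
  as.integer(idx)
}

#' Cell-centre coordinates for row-major cell indices
#' @param grid an `enm_grid`.
#' @param idx integer row-major 1-based indices.
#' @return data.frame with columns `lon`, `lat`.
#' @export
cell_center <- function(grid, idx) {
  i <- (idx - 1L) %/% grid$ncols            # 0-based row from north
  j <- (idx - 1L) %% grid$ncols
  data.frame(
    lon = grid$xll + (j + 0.5) * grid$cellsize,
    lat = grid$yll + (grid$nrows - i - 0.5) * grid$cellsize)
}

#' Read an ESRI ASCII grid
#'
#' Accepts both the corner (`xllcorner`/`yllcorner`) and centre
#' (`xllcenter`/`yllcenter`) header dialects; centre-form origins are
#' converted to the corner convention (`xll = xllcenter - cellsize/2`).
#' Cells equal to the declared `NODATA_value` become `NA`.
#'
#' @param path path to a `.asc` file.
#' @return an `enm_grid`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list(); center_x <- FALSE; center_y <- FALSE
  keys <- c("ncols", "nrows", "xllcorner", "xllcenter", "yllcorner",
            "yllcenter", "cellsize", "nodata_value")
  for (k in 1:6) {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stopf("truncated header at line %d", k)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) != 2 || !(tolower(parts[1]) %in% keys))
      stopf("malformed header line %d: '%s'", k, line)
    key <- tolower(parts[1])
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) stopf("malformed header line %d: '%s'", k, line)
    if (key == "xllcenter") { key <- "xllcorner"; center_x <- TRUE }
    if (key == "yllcenter") { key <- "yllcorner"; center_y <- TRUE }
    hdr[[key]] <- val
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stopf("header missing key(s): %s", paste(miss, collapse = ", "))
  vals <- scan(con, what = numeric(), quiet = TRUE)
  nexp <- hdr$nrows * hdr$ncols
  if (length(vals) != nexp)
    stopf("value count %d != nrows*ncols = %d (truncated or padded file)",
          length(vals), nexp)
  vals[vals == hdr$nodata_value] <- NA_real_
  xll <- hdr$xllcorner - if (center_x) hdr$cellsize / 2 else 0
  yll <- hdr$yllcorner - if (center_y) hdr$cellsize / 2 else 0
  new_grid(vals, hdr$nrows, hdr$ncols, xll, yll, hdr$cellsize,
           nodata = hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' Writes the corner-dialect header (lowercase keys) followed by
#' row-major values, `NA` cells as the grid's nodata sentinel.
#'
#' @param grid an `enm_grid`.
#' @param path output path.
#' @param precision significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, precision = 6) {
  stopifnot(inherits(grid, "enm_grid"))
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  txt <- formatC(vals, digits = precision, format = "g")
  rows <- matrix(txt, nrow = grid$nrows, ncol = grid$ncols, byrow = TRUE)
  body <- apply(rows, 1, paste, collapse = " ")
  hdr <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("nodata_value %.10g", grid$nodata))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Bundle aligned layers into a raster stack
#'
#' @param layers named list of `enm_grid` objects sharing one geometry.
#' @return an `enm_stack` (named list of layers with class attribute).
#' @export
raster_stack <- function(layers) {
  if (length(layers) < 1) stopf("a stack needs at least one layer")
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stopf("layers must have unique non-empty names")
  for (l in layers) stopifnot(inherits(l, "enm_grid"))
  g1 <- layers[[1]]
  for (k in seq_along(layers))
    if (!geom_equal(g1, layers[[k]]))
      stopf("layer '%s' geometry differs from '%s'", nm[k], nm[1])
  structure(layers, class = "enm_stack")
}

#' @export
print.enm_stack <- function(x, ...) {
  g <- x[[1]]
  cat(sprintf("<enm_stack: %d layers (%s) on %d x %d grid>\n",
              length(x), paste(names(x), collapse = ", "),
              g$nrows, g$ncols))
  invisible(x)
}

stack_names <- function(stack) names(unclass(stack))

#' Equally- or explicitly-weighted ensemble mean of raster stacks
#'
#' Averages several aligned stacks (e.g. GCM members of one scenario)
#' layer by layer, cell by cell.  A nodata cell in any member propagates
#' to the output.
#'
#' @param members list of `enm_stack` objects with identical geometry
#'   and layer names.
#' @param weights optional numeric weights, one per member; default
#'   equal.  Normalized to sum to 1.
#' @return an `enm_stack`.
#' @export
ensemble_mean <- function(members, weights = NULL) {
  if (length(members) < 1) stopf("need at least one member")
  nm <- stack_names(members[[1]])
  for (m in members) {
    if (!identical(stack_names(m), nm))
      stopf("members disagree on layer names")
    if (!geom_equal(m[[1]], members[[1]][[1]]))
      stopf("member geometry mismatch")
  }
  if (is.null(weights)) weights <- rep(1, length(members))
  if (length(weights) != length(members) || any(weights < 0) ||
      sum(weights) <= 0)
    stopf("weights must be nonnegative, one per member, with positive sum")
  weights <- weights / sum(weights)
  out <- lapply(nm, function(v) {
    g0 <- members[[1]][[v]]
    acc <- rep(0, length(g0$values))
    bad <- rep(FALSE, length(g0$values))
    for (k in seq_along(members)) {
      vals <- members[[k]][[v]]$values
      bad <- bad | is.na(vals)
      vals[is.na(vals)] <- 0
      acc <- acc + weights[k] * vals
    }
    acc[bad] <- NA_real_
    new_grid(acc, g0$nrows, g0$ncols, g0$xll, g0$yll, g0$cellsize,
             nodata = g0$nodata)
  })
  names(out) <- nm
  raster_stack(out)
}

#' Mark a 0/1 grid as a region mask
#'
#' Mask grids carry a `mask` attribute so that [intersect_mask()] can
#' treat their 0 cells as invalid (0 is a legitimate value in a climate
#' layer but means "outside the region" in a mask).
#'
#' @param grid a 0/1 `enm_grid`.
#' @return the grid with the `mask` attribute set.
#' @export
as_mask <- function(grid) {
  stopifnot(inherits(grid, "enm_grid"))
  attr(grid, "mask") <- TRUE
  grid
}

#' Shared valid-cell mask of grids and stacks
#'
#' Returns a 0/1 `enm_grid` that is 1 exactly where every layer of every
#' input is valid: the common domain on which models are fitted and
#' overlap statistics computed.  A cell is invalid where a layer is
#' nodata, or where a mask input (output of this function, or a grid
#' marked with [as_mask()]) is 0.
#'
#' @param ... `enm_grid` and/or `enm_stack` objects, all aligned.
#' @return an `enm_grid` of 0/1 values (never `NA`), marked as a mask.
#' @export
intersect_mask <- function(...) {
  inputs <- list(...)
  grids <- list()
  for (x in inputs) {
    if (inherits(x, "enm_stack")) grids <- c(grids, unclass(x))
    else if (inherits(x, "enm_grid")) grids <- c(grids, list(x))
    else stopf("intersect_mask accepts enm_grid / enm_stack objects")
  }
  if (!length(grids)) stopf("no inputs")
  g0 <- grids[[1]]
  ok <- rep(TRUE, length(g0$values))
  for (g in grids) {
    if (!geom_equal(g, g0)) stopf("geometry mismatch between mask inputs")
    ok <- ok & !is.na(g$values)
    if (isTRUE(attr(g, "mask"))) ok <- ok & g$values != 0
  }
  as_mask(new_grid(as.numeric(ok), g0$nrows, g0$ncols, g0$xll, g0$yll,
                   g0$cellsize, nodata = g0$nodata))
}

# Indices of mask-true cells (mask = 0/1 enm_grid, or logical vector).
mask_cells <- function(mask) {
  v <- if (inherits(mask, "enm_grid")) mask$values else as.numeric(mask)
  which(!is.na(v) & v != 0)
}

#' Combine two masks (logical AND)
#' @param a,b 0/1 `enm_grid` masks.
#' @return 0/1 `enm_grid`.
#' @export
mask_and <- function(a, b) {
  if (!geom_equal(a, b)) stopf("geometry mismatch")
  v <- as.numeric(!is.na(a$values) & a$values != 0 &
                  !is.na(b$values) & b$values != 0)
  new_grid(v, a$nrows, a$ncols, a$xll, a$yll, a$cellsize, nodata = a$nodata)
}
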
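test_that("ASCII grid parsing maps values to the right cells", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 10", "yllcorner 20",
               "cellsize 0.5", "NODATA_value -9999",
               "1 2", "3 4"), f)
  g <- read_ascii_grid(f)
  expect_equal(g$values[1], 1)   # NW cell
  expect_equal(g$values[4], 4)   # SE cell
  expect_equal(g$xll, 10)
  expect_equal(g$cellsize, 0.5)

  writeLines(c("ncols 2", "nrows 1", "xllcenter 10", "yllcenter 20",
               "cellsize 0.5", "NODATA_value -1",
               "7 -1"), f)
  g2 <- read_ascii_grid(f)
  expect_equal(g2$xll, 10 - 0.25)          # centre converted to corner
  expect_equal(g2$yll, 20 - 0.25)
  expect_true(is.na(g2$values[2]))         # nodata flagged
})

test_that("malformed and truncated ASCII files are rejected with context", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "rows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2 3 4"), f)
  expect_error(read_ascii_grid(f), "header line 2")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2 3"), f)
  expect_error(read_ascii_grid(f), "value count")
})

test_that("read/write round trip preserves values and nodata", {
  set.seed(41)
  vals <- round(runif(100, -5, 5), 4)
  vals[c(3, 77)] <- NA
  g <- tiny_grid(vals, nrows = 10, ncols = 10, xll = -1.25, yll = 40,
                 cellsize = 0.25)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, f, precision = 8)
  g2 <- read_ascii_grid(f)
  expect_equal(g2$values, g$values, tolerance = 1e-7)
  expect_identical(grid_geometry <- g2[c("nrows", "ncols")],
                   g[c("nrows", "ncols")])
  expect_equal(g2$xll, g$xll)
  expect_true(all(is.na(g2$values[c(3, 77)])))
})

test_that("grid invariants are enforced", {
  expect_error(new_grid(1:3, 2, 2, 0, 0, 1), "values length")
  expect_error(new_grid(numeric(0), 0, 1, 0, 0, 1), "at least one")
  expect_error(new_grid(1:4, 2, 2, 0, 0, -1), "cellsize")
  expect_error(new_grid(c(1, Inf, 3, 4), 2, 2, 0, 0, 1), "non-finite")
})

test_that("ensemble_mean averages members with nodata propagation", {
  mk <- function(v) raster_stack(list(a = tiny_grid(v)))
  m <- ensemble_mean(list(mk(rep(10, 4)), mk(rep(20, 4)), mk(rep(30, 4))))
  expect_equal(m$a$values, rep(20, 4))

  w <- ensemble_mean(list(mk(rep(4, 4)), mk(rep(8, 4)), mk(rep(16, 4))),
                     weights = c(0.5, 0.25, 0.25))
  expect_equal(w$a$values, rep(8, 4))

  v2 <- c(1, NA, 3, 4)
  m2 <- ensemble_mean(list(mk(c(5, 6, 7, 8)), mk(v2)))
  expect_true(is.na(m2$a$values[2]))
  expect_equal(m2$a$values[-2], c(3, 5, 6))

  # permutation invariance and single-member identity
  set.seed(5)
  vs <- replicate(3, runif(4), simplify = FALSE)
  e1 <- ensemble_mean(lapply(vs, mk))
  e2 <- ensemble_mean(lapply(rev(vs), mk))
  expect_equal(e1$a$values, e2$a$values)
  expect_equal(ensemble_mean(list(mk(vs[[1]])))$a$values, vs[[1]])

  bad <- raster_stack(list(a = tiny_grid(1:6, nrows = 3, ncols = 2)))
  expect_error(ensemble_mean(list(mk(1:4), bad)), "geometry")
})

test_that("intersect_mask is the intersection, symmetric and idempotent", {
  a <- tiny_grid(c(1, NA, 3, 4))
  b <- tiny_grid(c(NA, 2, 3, 4))
  expect_equal(intersect_mask(tiny_grid(1:4))$values, rep(1, 4))
  m <- intersect_mask(a, b)
  expect_equal(m$values, c(0, 0, 1, 1))
  expect_equal(intersect_mask(b, a)$values, m$values)
  expect_equal(intersect_mask(m, m)$values, m$values)   # idempotent
})

test_that("half-open point-in-cell rule is deterministic at boundaries", {
  g <- tiny_grid(1:4, nrows = 2, ncols = 2, xll = 0, yll = 0, cellsize = 1)
  # cell (row 2, col 1) = index 3 covers [0,1) x [0,1)
  expect_equal(cell_index(g, 0, 0), 3L)          # lower-left corner in cell
  expect_equal(cell_index(g, 1, 0), 4L)          # east edge -> next cell
  expect_equal(cell_index(g, 0, 1), 1L)          # north edge -> row above
  expect_equal(cell_index(g, 1, 1), 2L)
  eps <- 1e-9
  # epsilon inside each corner of the [0,1)x[0,1) cell
  expect_equal(cell_index(g, c(eps, 1 - eps, eps, 1 - eps),
                          c(eps, eps, 1 - eps, 1 - eps)),
               rep(3L, 4))
  # outside the extent
  expect_true(is.na(cell_index(g, 2, 0.5)))
  expect_true(is.na(cell_index(g, 0.5, 2)))
  # cell centres round-trip
  idx <- 1:4
  ctr <- cell_center(g, idx)
  expect_equal(cell_index(g, ctr$lon, ctr$lat), idx)
})
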
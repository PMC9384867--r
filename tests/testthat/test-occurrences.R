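write_occ_csv <- function(df) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, f, row.names = FALSE)
  f
}

test_that("occurrence ingestion cleans duplicates and bad rows", {
  f <- write_occ_csv(data.frame(
    species = "sp", longitude = c(100, 100, 101, 102),
    latitude = c(40, 40, 41, 95)))
  expect_message(expect_message(occ <- read_occurrences(f), "duplicate"),
                 "rejected")
  expect_equal(nrow(occ), 2)
  expect_equal(attr(occ, "n_duplicates"), 1)
  expect_equal(attr(occ, "n_rejected"), 1)

  f2 <- write_occ_csv(data.frame(species = "sp", lon = 1, lat = 2))
  expect_error(read_occurrences(f2), "missing column")
})

test_that("occurrence ingestion is order-invariant", {
  set.seed(9)
  df <- data.frame(species = "sp",
                   longitude = round(runif(30, 90, 110), 3),
                   latitude = round(runif(30, 30, 50), 3))
  f1 <- write_occ_csv(df)
  f2 <- write_occ_csv(df[sample(nrow(df)), ])
  a <- read_occurrences(f1); b <- read_occurrences(f2)
  key <- function(o) sort(paste(o$lon, o$lat))
  expect_identical(key(a), key(b))
})

test_that("spatial rarefaction keeps one record per cell, first wins", {
  g <- tiny_grid(rep(0, 100), nrows = 10, ncols = 10, xll = 0, yll = 0,
                 cellsize = 1)
  occ <- occurrences("sp", c(0.2, 0.7, 3.5), c(0.3, 0.6, 3.5))
  r <- spatial_rarefy(occ, g)
  expect_equal(nrow(r), 2)
  expect_equal(r$lon[1], 0.2)                     # first in file order kept

  occ2 <- occurrences("sp", c(1.5, 2.5, 3.5), c(1.5, 2.5, 3.5))
  expect_equal(nrow(spatial_rarefy(occ2, g)), 3)  # all distinct cells

  occ3 <- occurrences("sp", c(0.5, 50), c(0.5, 50))
  expect_message(r3 <- spatial_rarefy(occ3, g), "outside")
  expect_equal(nrow(r3), 1)
})

test_that("rarefaction matches a brute-force cell-binning oracle and is idempotent", {
  g <- tiny_grid(rep(0, 64), nrows = 8, ncols = 8, xll = 0, yll = 0,
                 cellsize = 0.5)
  for (seed in 1:4) {
    set.seed(seed)
    occ <- occurrences("sp", runif(120, 0, 4), runif(120, 0, 4))
    r <- spatial_rarefy(occ, g)
    # oracle: number of occupied cells by direct binning
    occupied <- unique(paste(floor(occ$lon / 0.5), floor(occ$lat / 0.5)))
    expect_equal(nrow(r), length(occupied))
    r2 <- spatial_rarefy(r, g)
    expect_equal(r2$lon, r$lon)
    expect_lte(nrow(r), nrow(occ))
  }
})

test_that("background sampling is seeded, capped and roughly uniform", {
  msk <- tiny_grid(c(rep(1, 9), NA), nrows = 2, ncols = 5)
  expect_equal(sample_background(msk, 9), which(!is.na(msk$values)))
  expect_warning(b <- sample_background(msk, 20), "only 9 valid")
  expect_equal(length(b), 9)
  expect_identical(sample_background(msk, 4, seed = 7),
                   sample_background(msk, 4, seed = 7))
  expect_error(sample_background(tiny_grid(rep(NA_real_, 4)), 2), "no valid")

  # frequency check: each of 10 cells drawn ~ n/10 of the time
  msk2 <- tiny_grid(rep(1, 10), nrows = 2, ncols = 5)
  counts <- integer(10)
  for (s in 1:400) {
    d <- sample_background(msk2, 3, seed = s)
    counts[d] <- counts[d] + 1
  }
  p <- counts / (400 * 3)
  tol <- 3 * sqrt(0.1 * 0.9 / 1200)
  expect_true(all(abs(p - 0.1) < tol))
})

test_that("value extraction respects the cell rule and drops nodata", {
  vals <- 1:4
  st <- raster_stack(list(a = tiny_grid(vals),
                          b = tiny_grid(vals * 10)))
  ctr <- cell_center(st[[1]], 2L)
  tab <- extract_values(st, data.frame(lon = ctr$lon, lat = ctr$lat),
                        label = 1)
  expect_equal(tab$a, 2); expect_equal(tab$b, 20)
  expect_equal(tab$cell, 2L)

  st2 <- raster_stack(list(a = tiny_grid(c(1, NA, 3, 4))))
  pts <- cell_center(st2[[1]], c(1L, 2L))
  expect_message(t2 <- extract_values(st2, pts), "nodata")
  expect_equal(t2$cell, 1L)
  expect_message(
    t3 <- extract_values(st2, data.frame(lon = c(0.5, 99), lat = c(1.5, 0))),
    "outside")
  expect_equal(nrow(t3), 1)
})
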
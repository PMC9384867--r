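test_that("synthetic climate stacks honor geometry, seed and correlation targets", {
  st <- gen_climate_stack(nrows = 40, ncols = 40, K = 4, range_len = 4,
                          cross_corr = diag(4), seed = 1)
  expect_s3_class(st, "enm_stack")
  expect_length(unclass(st), 4)
  expect_equal(st[[1]]$nrows, 40)
  st2 <- gen_climate_stack(nrows = 40, ncols = 40, K = 4, range_len = 4,
                           cross_corr = diag(4), seed = 1)
  expect_identical(st[[1]]$values, st2[[1]]$values)   # bit-reproducible

  # identity target at the stated desk scale (100 x 100 cells): mean
  # absolute off-diagonal correlation small
  stI <- gen_climate_stack(nrows = 100, ncols = 100, K = 4,
                           range_len = 5, cross_corr = diag(4), seed = 2)
  vals <- sapply(unclass(stI), function(g) g$values)
  cm <- cor(vals)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.1)

  # strong target: r = 0.9 pair lands near 0.9
  cc <- matrix(c(1, 0.9, 0.9, 1), 2)
  st3 <- gen_climate_stack(nrows = 100, ncols = 100, K = 2, range_len = 6,
                           cross_corr = cc, seed = 3)
  r <- cor(st3[[1]]$values, st3[[2]]$values)
  expect_gt(r, 0.8); expect_lt(r, 0.97)

  expect_error(gen_climate_stack(K = 2,
                                 cross_corr = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  # precipitation-like layers are nonnegative
  expect_true(all(st[[4]]$values >= 0))
})

test_that("species truths follow their response specifications", {
  st <- gen_climate_stack(nrows = 25, ncols = 25, K = 3, range_len = 4,
                          seed = 5)
  lin <- gen_species(st, list(list(var = "Bio2", form = "linear",
                                   weight = 2)))
  expect_equal(cor(rank(lin$eta$values), rank(st$Bio2$values)), 1)

  flat <- gen_species(st, list(list(var = "Bio1", form = "linear",
                                    weight = 0)))
  expect_equal(diff(range(flat$suitability$values)), 0)

  hg <- gen_species(st, list(list(var = "Bio1", form = "hinge",
                                  weight = 1, center = 0.5)))
  z <- (st$Bio1$values - mean(st$Bio1$values)) / sd(st$Bio1$values)
  expect_true(all(hg$eta$values[z <= 0.5] == 0))      # flat below the knot
  expect_true(all(hg$eta$values[z > 0.5] > 0))
})

test_that("presence sampling is seeded and tracks the truth surface", {
  st <- gen_climate_stack(nrows = 10, ncols = 10, K = 2, range_len = 2,
                          seed = 8)
  tr <- gen_species(st)
  o1 <- sample_presences(tr, 50, seed = 3)
  o2 <- sample_presences(tr, 50, seed = 3)
  expect_identical(o1$lon, o2$lon)
  expect_error(sample_presences(tr, 0), "at least 1")

  # uniform truth: per-cell counts pass a chi-square GOF at the 1% level
  flat <- gen_species(st, list(list(var = "Bio1", form = "linear",
                                    weight = 0)))
  occ <- sample_presences(flat, 4000, seed = 9)
  cells <- cell_index(st[[1]], occ$lon, occ$lat)
  counts <- tabulate(cells, nbins = 100)
  chi <- sum((counts - 40)^2 / 40)
  expect_lt(chi, qchisq(0.99, df = 99))
})

test_that("future perturbations shift temperature and scale precipitation", {
  st <- gen_climate_stack(nrows = 20, ncols = 20, K = 4, range_len = 3,
                          seed = 11)
  same <- gen_future(st, warming_delta = 0, precip_scale = 1,
                     field_sd = 0, seed = 1)
  for (v in names(same)) expect_equal(same[[v]]$values, st[[v]]$values)

  fut <- gen_future(st, warming_delta = 2, precip_scale = 0.8,
                    field_sd = 0.3, seed = 2)
  tl <- attr(st, "temp_layers")
  d <- mean(fut[[tl[1]]]$values - st[[tl[1]]]$values)
  expect_equal(d, 2, tolerance = 0.31)
  pl <- setdiff(names(st), tl)[1]
  expect_equal(fut[[pl]]$values, pmax(0, st[[pl]]$values * 0.8))
  expect_true(all(fut[[pl]]$values >= 0))
})

test_that("pair generation makes truth overlap decrease with niche offset", {
  st <- gen_climate_stack(nrows = 40, ncols = 40, K = 4, range_len = 5,
                          seed = 21)
  same <- gen_pair(st, offset_delta = 0)
  expect_equal(schoener_d(same$parasite$suitability,
                          same$host$suitability), 1)
  offsets <- c(0, 0.5, 1, 2, 4)
  dvals <- vapply(offsets, function(o) {
    pr <- gen_pair(st, offset_delta = o)
    schoener_d(pr$parasite$suitability, pr$host$suitability)
  }, numeric(1))
  expect_true(all(diff(dvals) <= 1e-12))            # monotone non-increasing
  expect_lt(dvals[length(dvals)], 0.2)              # far offsets barely overlap
})
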
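test_that("fitted coefficients match brute-force optima on small instances", {
  # parameterized over seeds, feature classes and regularization levels
  cases <- expand.grid(seed = 1:3, fc = c("L", "LQ"), rm = c(0.5, 2),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    set.seed(cases$seed[i])
    p <- data.frame(x = runif(6, 0.4, 1))
    b <- data.frame(x = runif(14))
    m <- maxent_fit(p, b, fc = cases$fc[i], rm = cases$rm[i])
    Fp <- feature_matrix(m$features, p)
    Fbg <- feature_matrix(m$features, b)
    star <- oracle_fit(Fp, Fbg, m$lambda)
    expect_equal(unname(m$beta), unname(star), tolerance = 1e-3,
                 label = sprintf("case %d (fc=%s rm=%g)", i,
                                 cases$fc[i], cases$rm[i]))
    expect_lte(oracle_objective(m$beta, Fp, Fbg, m$lambda),
               oracle_objective(star, Fp, Fbg, m$lambda) + 1e-8)
  }
})

test_that("two-variable instances also match the oracle", {
  for (seed in 1:3) {
    set.seed(seed + 100)
    p <- data.frame(x = runif(8, 0.5, 1), y = runif(8, 0, 0.5))
    b <- data.frame(x = runif(12), y = runif(12))
    m <- maxent_fit(p, b, fc = "L", rm = 1)
    Fp <- feature_matrix(m$features, p)
    Fbg <- feature_matrix(m$features, b)
    star <- oracle_fit(Fp, Fbg, m$lambda)
    expect_equal(unname(m$beta), unname(star), tolerance = 1e-3)
  }
})

test_that("overwhelming regularization collapses to the null model", {
  set.seed(4)
  p <- data.frame(x = runif(10, 0.5, 1))
  b <- data.frame(x = runif(30))
  m <- maxent_fit(p, b, fc = "LQH", rm = 1e6)
  expect_true(all(m$beta == 0))
  q <- predict_raw(m, b)
  expect_equal(q, rep(1 / 30, 30))
  expect_equal(predict_logistic(m, b), rep(0.5, 30))   # exact null value
})

test_that("a separating feature ranks presences above background", {
  p <- data.frame(x = rep(1, 5))
  b <- data.frame(x = c(rep(0, 15), rep(1, 5)))
  m <- maxent_fit(p, b, fc = "L", rm = 0.05)
  expect_gt(m$beta[["L:x"]], 0)
  sc <- predict_raw(m, b)
  expect_true(all(sc[16:20] > sc[1:15]))
})

test_that("raw output normalizes over the training background", {
  set.seed(11)
  p <- data.frame(x = runif(20, 0.3, 1), y = runif(20))
  b <- data.frame(x = runif(200), y = runif(200))
  m <- maxent_fit(p, b, fc = "LQ", rm = 1)
  expect_equal(sum(predict_raw(m, b)), 1, tolerance = 1e-9)
  # projecting onto the training background reproduces training q
  expect_identical(predict_raw(m, b), predict_raw(m, b))
  # logistic is a monotone transform of raw: identical rankings
  lg <- predict_logistic(m, b)
  expect_equal(rank(lg), rank(predict_raw(m, b)))
  expect_true(all(lg >= 0 & lg <= 1))
})

test_that("projection clamps out-of-range cells to range-edge predictions", {
  set.seed(12)
  tr <- data.frame(x = runif(30, 0, 1))
  p <- data.frame(x = runif(8, 0.6, 1))
  m <- maxent_fit(p, tr, fc = "LQ", rm = 0.5)
  # the training range is over presences + background combined
  edge <- predict_logistic(m, data.frame(x = max(c(tr$x, p$x))))
  far_clamped <- predict_logistic(m, data.frame(x = 10), clamp = TRUE)
  far_free <- predict_logistic(m, data.frame(x = 10), clamp = FALSE)
  expect_equal(far_clamped, edge)
  expect_false(isTRUE(all.equal(far_free, edge)))

  # grid projection: training stack projection equals direct prediction
  st <- raster_stack(list(x = tiny_grid(c(0.1, 0.4, NA, 0.9))))
  mp <- project_model(m, st)
  direct <- predict_logistic(m, data.frame(x = c(0.1, 0.4, 0.9)),
                             clamp = TRUE)
  expect_equal(mp$values[-3], direct)
  expect_true(is.na(mp$values[3]))                   # nodata propagates
})

test_that("variable contributions are percentages that isolate signal", {
  set.seed(31)
  n <- 300
  x <- runif(n); noise <- runif(n)
  b <- data.frame(x = x, z = noise)
  keep <- which(runif(n) < x^3)                     # presence driven by x
  p <- b[keep[1:40], ]
  m <- maxent_fit(p, b, fc = "LQ", rm = 1)
  vc <- variable_contribution(m, p, b)
  expect_equal(sum(vc$contribution), 100, tolerance = 1e-6)
  expect_true(all(vc$contribution >= 0))
  expect_gt(vc$contribution[["x"]], 80)
  expect_lt(vc$contribution[["z"]], 20)
  expect_named(vc$jackknife,
               c("variable", "gain_full", "gain_without", "gain_with_only"))
  # single-variable model is 100% by construction
  m1 <- maxent_fit(p["x"], b["x"], fc = "LQ", rm = 1)
  vc1 <- variable_contribution(m1, p["x"], b["x"])
  expect_equal(unname(vc1$contribution), 100)
})

test_that("stronger regularization does not grow the support", {
  nnz <- function(m) sum(m$beta != 0)
  tot_lo <- 0; tot_hi <- 0
  for (seed in 1:5) {
    set.seed(seed + 40)
    p <- data.frame(x = runif(25, 0.4, 1), y = runif(25, 0, 0.7))
    b <- data.frame(x = runif(120), y = runif(120))
    f <- build_features(rbind(p, b), "LQH", n_knots = 10)
    # rm = 0.5 on this small sample can be quasi-separable; the
    # safeguard-bound warning is expected there
    lo <- suppressWarnings(maxent_fit(p, b, rm = 0.5, features = f))
    hi <- maxent_fit(p, b, rm = 2, features = f)
    tot_lo <- tot_lo + nnz(lo); tot_hi <- tot_hi + nnz(hi)
  }
  expect_lte(tot_hi, tot_lo)
})
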
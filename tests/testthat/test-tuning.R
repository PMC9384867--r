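test_that("AICc follows the small-sample formula and its guards", {
  set.seed(1)
  p <- data.frame(x = runif(10, 0.5, 1))
  b <- data.frame(x = runif(40))
  m <- maxent_fit(p, b, fc = "L", rm = 1)
  cells <- b
  ic <- model_aicc(m, p, cells)
  # hand computation from the definition
  eta_c <- log(predict_raw(m, cells))
  eta_p <- log(predict_raw(m, p))
  ll <- sum(eta_p - log(sum(exp(eta_c))))
  k <- sum(m$beta != 0)
  expect_equal(ic$loglik, ll, tolerance = 1e-10)
  expect_equal(ic$k, k)
  expect_equal(ic$aicc, 2 * k - 2 * ll + 2 * k * (k + 1) / (10 - k - 1))

  # k >= n-1 guard
  p2 <- p[1:2, , drop = FALSE]
  m2 <- maxent_fit(p2, b, fc = "L", rm = 0.01)
  expect_true(sum(m2$beta != 0) >= 1)
  expect_equal(model_aicc(m2, p2, cells)$aicc, Inf)

  # an all-zero model has k = 0 regardless of feature count
  mz_l <- maxent_fit(p, b, fc = "L", rm = 1e7)
  mz_lq <- maxent_fit(p, b, fc = "LQ", rm = 1e7)
  expect_equal(model_aicc(mz_l, p, cells)$aicc,
               model_aicc(mz_lq, p, cells)$aicc)
})

test_that("tuning selects delta-AICc zero with full candidate table", {
  set.seed(5)
  st <- gen_climate_stack(nrows = 20, ncols = 20, K = 3, range_len = 4,
                          seed = 9)
  truth <- gen_species(st)
  occ <- spatial_rarefy(sample_presences(truth, 70, seed = 2), st[[1]])
  bg <- sample_background(intersect_mask(st), 200, seed = 3)
  pres <- extract_values(st, occ, label = 1)
  bgd <- extract_values(st, bg, label = 0)
  cells <- bgd[, -(1:2)]
  tn <- tune_maxent(pres, bgd, cells, rm_grid = c(0.5, 1, 2),
                    fc_sets = c("L", "LQ"),
                    config = maxent_config(n_knots = 8))
  expect_equal(nrow(tn$candidates), 6)
  expect_equal(min(tn$candidates$delta_aicc), 0)
  sel <- tn$candidates[tn$candidates$fc == tn$selected$fc &
                       tn$candidates$rm == tn$selected$rm, ]
  expect_equal(sel$delta_aicc, 0)
  # single candidate selects trivially
  tn1 <- tune_maxent(pres, bgd, cells, rm_grid = 1, fc_sets = "L")
  expect_equal(tn1$selected, list(fc = "L", rm = 1))
})

test_that("replicate splits are disjoint, sized and frequency-calibrated", {
  sp <- split_replicates(20, frac = 0.75, n_rep = 10, seed = 1)
  for (s in sp) {
    expect_equal(sort(c(s$train, s$test)), 1:20)
    expect_length(s$train, 15)
    expect_length(intersect(s$train, s$test), 0)
  }
  expect_error(split_replicates(10, frac = 1), "empty test")
  expect_identical(split_replicates(9, seed = 4), split_replicates(9, seed = 4))

  counts <- integer(8)
  sp2 <- split_replicates(8, frac = 0.75, n_rep = 1000, seed = 2)
  for (s in sp2) counts[s$train] <- counts[s$train] + 1
  freq <- counts / 1000
  tol <- 3 * sqrt(0.75 * 0.25 / 1000)
  expect_true(all(abs(freq - 0.75) < tol + 1e-9))
})

test_that("AUC matches exhaustive pair counting, with ties", {
  expect_equal(eval_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(eval_auc(rep(1, 5), rep(1, 7)), 0.5)
  for (seed in 1:4) {
    set.seed(seed)
    sp <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)
    sb <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)
    expect_equal(eval_auc(sp, sb), oracle_auc(sp, sb))
  }
})

test_that("TSS maximization matches the exhaustive threshold scan", {
  ts <- eval_tss(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(ts$tss, 1)
  set.seed(8)
  same <- runif(60)
  expect_lt(abs(eval_tss(same[1:30], same[31:60])$tss), 0.35)
  for (seed in 1:4) {
    set.seed(seed)
    sp <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)
    sb <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)
    got <- eval_tss(sp, sb)
    expect_equal(got$tss, oracle_tss(sp, sb))
    # returned threshold attains the maximum
    at <- mean(sp >= got$threshold) + mean(sb < got$threshold) - 1
    expect_equal(at, got$tss)
  }
})

test_that("replicate aggregation averages maps and metrics", {
  g1 <- tiny_grid(c(0.2, 0.4, NA, 0.8))
  g2 <- tiny_grid(c(0.4, 0.6, NA, 0.6))
  mm <- mean_map(list(g1, g2))
  expect_equal(mm$values, c(0.3, 0.5, NA, 0.7))
  expect_equal(mean_map(list(g1, g1))$values, g1$values)
  # mean map bounded by the replicate envelope
  expect_true(all(mm$values >= pmin(g1$values, g2$values), na.rm = TRUE))
  expect_true(all(mm$values <= pmax(g1$values, g2$values), na.rm = TRUE))
})
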
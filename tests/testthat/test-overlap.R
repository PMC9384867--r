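test_that("Schoener's D matches hand computations and limits", {
  a <- tiny_grid(c(0.5, 0.3, 0.2, NA))
  expect_equal(schoener_d(a, a), 1)
  b <- tiny_grid(c(0.2, 0.3, 0.5, NA))
  expect_equal(schoener_d(a, b), 1 - 0.5 * (0.3 + 0 + 0.3))
  # disjoint supports
  x <- tiny_grid(c(1, 1, 0, 0)); y <- tiny_grid(c(0, 0, 1, 1))
  expect_equal(schoener_d(x, y), 0)
  # symmetry and positive-scaling invariance
  set.seed(6)
  u <- tiny_grid(runif(4)); v <- tiny_grid(runif(4))
  expect_equal(schoener_d(u, v), schoener_d(v, u))
  v3 <- tiny_grid(v$values * 3.7)
  expect_equal(schoener_d(u, v3), schoener_d(u, v))
  d <- schoener_d(u, v)
  expect_true(d >= 0 && d <= 1)
  # shared-cell restriction: mismatched nodata
  p <- tiny_grid(c(0.6, NA, 0.4, 0.5)); q <- tiny_grid(c(0.6, 0.1, 0.4, NA))
  dd <- schoener_d(p, q)
  expect_equal(dd, 1)                      # identical on shared cells
  expect_error(schoener_d(tiny_grid(rep(0, 4)), u), "all-zero")
})

test_that("overlap classes follow the five lower-closed bins", {
  expect_equal(overlap_class(0.7316), "high")
  expect_equal(overlap_class(0.2593), "low")
  expect_equal(overlap_class(0.80), "very_high")
  expect_equal(overlap_class(c(0, 0.2, 0.4, 0.6, 1)),
               c("no_or_very_limited", "low", "moderate", "high",
                 "very_high"))
  expect_error(overlap_class(1.2), "0, 1")
})

test_that("pair summaries reproduce the published mean +/- SD", {
  ref <- reference_overlap_d()
  printed <- list(
    "C. songaricum-N. sibirica" = c(0.5142, 0.0066),
    "B. rossica-A. mandshurica" = c(0.7007, 0.0277),
    "C. deserticola-H. ammodendron" = c(0.6677, 0.0096),
    "C. mongolica-T. ramosissima" = c(0.2785, 0.0127))
  for (pr in names(printed)) {
    s <- pair_summary(ref$d[ref$pair == pr])
    expect_equal(s$mean, printed[[pr]][1], label = pr)
    expect_equal(s$sd, printed[[pr]][2], label = pr)
  }
  expect_equal(pair_summary(rep(0.4, 5))$sd, 0)
})

test_that("overlap typology reproduces the published pair labels", {
  ref <- reference_overlap_d()
  labels <- reference_trend_labels()$pairs
  for (i in seq_len(nrow(labels))) {
    d <- ref[ref$pair == labels$pair[i], ]
    cur <- d$d[d$scenario == "current"]
    fut <- d$d[d$scenario != "current"]
    expect_equal(overlap_typology(cur, fut), labels$label[i],
                 label = labels$pair[i])
  }
  expect_equal(overlap_typology(0.5, c(0.4, 0.45, 0.3, 0.2)), "declining")
})

test_that("one-way ANOVA matches its classical identities", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(anova_oneway(g)$F, 0)
  # two groups: F equals the square of the pooled t statistic
  set.seed(10)
  x <- rnorm(8); y <- rnorm(9, 1)
  av <- anova_oneway(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(av$F, unname(tt$statistic)^2)
  expect_equal(av$p, tt$p.value)
  expect_error(anova_oneway(list(a = 1:3)), "2 groups")
  expect_error(anova_oneway(list(a = 1:3, b = 2)), "at least 2 values")
})

test_that("Tamhane T2 reproduces the published letter grouping", {
  ref <- reference_overlap_d()
  groups <- split(ref$d, ref$pair)[unique(ref$pair)]
  res <- tamhane_t2(groups, alpha = 0.01)
  expect_lt(res$p, 0.01)
  lt <- res$letters
  expect_equal(lt[["B. rossica-A. mandshurica"]],
               lt[["C. deserticola-H. ammodendron"]])
  expect_false(lt[["C. songaricum-N. sibirica"]] %in%
                 lt[c("B. rossica-A. mandshurica",
                      "C. mongolica-T. ramosissima")])
  expect_false(lt[["C. mongolica-T. ramosissima"]] ==
                 lt[["B. rossica-A. mandshurica"]])
})

test_that("pairwise decisions match a direct Welch/Sidak recomputation", {
  set.seed(3)
  groups <- list(a = rnorm(5), b = rnorm(6, 2), c = rnorm(4, 2.2),
                 d = rnorm(5, 5))
  res <- tamhane_t2(groups, alpha = 0.05)
  m <- 6
  a_adj <- 1 - (1 - 0.05)^(1 / m)
  for (i in seq_len(nrow(res$pairwise))) {
    r <- res$pairwise[i, ]
    g1 <- groups[[r$group1]]; g2 <- groups[[r$group2]]
    se2 <- var(g1) / length(g1) + var(g2) / length(g2)
    tval <- abs(mean(g1) - mean(g2)) / sqrt(se2)
    df <- se2^2 / ((var(g1) / length(g1))^2 / (length(g1) - 1) +
                   (var(g2) / length(g2))^2 / (length(g2) - 1))
    expect_equal(r$t, tval)
    expect_equal(r$df, df)
    expect_equal(r$significant, tval > qt(1 - a_adj / 2, df))
  }
})

test_that("letters are consistent with pairwise non-significance", {
  # identical groups share a letter
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(length(unique(tamhane_t2(g, alpha = 0.05)$letters)), 1)
  for (seed in 1:6) {
    set.seed(seed)
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(5, sample(0:3, 1)))
    names(groups) <- letters[seq_len(k)]
    res <- tamhane_t2(groups, alpha = 0.05)
    lt <- res$letters
    for (i in seq_len(nrow(res$pairwise))) {
      r <- res$pairwise[i, ]
      share <- any(strsplit(lt[[r$group1]], "")[[1]] %in%
                     strsplit(lt[[r$group2]], "")[[1]])
      expect_equal(share, !r$significant,
                   label = sprintf("seed %d pair %s-%s", seed,
                                   r$group1, r$group2))
    }
  }
})
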
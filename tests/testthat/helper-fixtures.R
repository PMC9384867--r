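# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (loops, exhaustive enumeration) and
# never call the code paths they check.

tiny_grid <- function(values, nrows = 2, ncols = 2, xll = 0, yll = 0,
                      cellsize = 1, nodata = -9999) {
  new_grid(values, nrows, ncols, xll, yll, cellsize, nodata)
}

small_world <- function(seed = 1, nrows = 30, ncols = 30, K = 4,
                        n_presence = 60) {
  simulate_world(nrows = nrows, ncols = ncols, K = K, range_len = 5,
                 n_presence = n_presence, offset_delta = 0.6,
                 n_members = 2, seed = seed)
}

small_config <- function(seed = 1) {
  default_config(seed = seed, n_background = 400, n_replicates = 5,
                 rm_grid = c(1, 2), fc_sets = c("L", "LQ"),
                 maxent = maxent_config(n_knots = 10))
}

# Exhaustive pairwise AUC with half-credit ties.
oracle_auc <- function(sp, sb) {
  tot <- 0
  for (x in sp) for (y in sb)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(sp) * length(sb))
}

# Exhaustive threshold scan for max TSS.
oracle_tss <- function(sp, sb) {
  best <- -Inf
  for (t in sort(unique(c(sp, sb)))) {
    tss <- mean(sp >= t) + mean(sb < t) - 1
    if (tss > best) best <- tss
  }
  best
}

# Penalized maximum-entropy objective (to minimize), straight from the
# definition.
oracle_objective <- function(beta, Fp, Fbg, lambda) {
  eta_p <- as.numeric(Fp %*% beta)
  eta_b <- as.numeric(Fbg %*% beta)
  -mean(eta_p) + log(sum(exp(eta_b))) + sum(lambda * abs(beta))
}

# Brute-force optimum of the penalized objective for 1-2 features:
# coarse grid then Nelder-Mead polish from the best grid point.
oracle_fit <- function(Fp, Fbg, lambda, lim = 12) {
  p <- ncol(Fbg)
  obj <- function(b) oracle_objective(b, Fp, Fbg, lambda)
  if (p == 1) {
    o <- stats::optimize(function(b) obj(b), c(-lim, lim), tol = 1e-12)
    return(o$minimum)
  }
  gr <- seq(-lim, lim, length.out = 41)
  best <- NULL; bestv <- Inf
  for (b1 in gr) for (b2 in gr) {
    v <- obj(c(b1, b2))
    if (v < bestv) { bestv <- v; best <- c(b1, b2) }
  }
  res <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 50000))
  # polish once more from the returned point
  res <- stats::optim(res$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 50000))
  res$par
}

# Independent greedy correlation elimination following the stated
# pair-priority rule.
oracle_select <- function(r, contributions, threshold) {
  vars <- colnames(r)
  keep <- vars
  repeat {
    if (length(keep) < 2) break
    # offending pair with largest |r|, lexicographic tie-break
    pairs <- t(utils::combn(sort(keep), 2))
    if (nrow(pairs) == 0) break
    rv <- apply(pairs, 1, function(pr) abs(r[pr[1], pr[2]]))
    off <- rv > threshold
    if (!any(off)) break
    cand <- which(off)
    cand <- cand[order(-rv[cand], pairs[cand, 1], pairs[cand, 2])]
    a <- pairs[cand[1], 1]; b <- pairs[cand[1], 2]
    drop <- if (contributions[[a]] < contributions[[b]]) a
            else if (contributions[[b]] < contributions[[a]]) b
            else max(a, b)
    keep <- setdiff(keep, drop)
  }
  sort(keep)
}

# Spearman rank correlation without stats::cor shortcuts.
spearman <- function(x, y) stats::cor(rank(x), rank(y))
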
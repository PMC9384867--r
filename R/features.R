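#' Default per-class regularization tables
#'
#' Baseline per-feature penalty scalers as a function of the number of
#' presence records m, interpolated linearly between the tabulated
#' sample sizes and clamped outside them.  These follow the published
#' defaults of the reference maximum-entropy implementation; the
#' regularization multiplier (RM) scales all of them globally.
#'
#' @return list with one `(m, beta)` table per feature class group.
#' @export
default_regularization <- function() {
  list(
    lqp       = list(m = c(10, 30, 100), beta = c(1.0, 0.2, 0.05)),
    hinge     = list(m = c(0, 1),        beta = c(0.5, 0.5)),
    threshold = list(m = c(0, 100),      beta = c(2.0, 1.0)))
}

reg_class_value <- function(kind, m, table = default_regularization()) {
  tab <- switch(kind,
                linear = , quadratic = , product = table$lqp,
                hinge_forward = , hinge_reverse = table$hinge,
                threshold = table$threshold,
                stopf("unknown feature kind '%s'", kind))
  stats::approx(tab$m, tab$beta, xout = m, rule = 2)$y
}

#' Solver and feature-construction settings
#'
#' @param n_knots hinge/threshold knot budget per variable per direction.
#' @param tol KKT stationarity residual at which the solver is
#'   considered converged.
#' @param max_iter iteration cap for the proximal solver.
#' @param kkt_tol slack allowed on the zero-coefficient KKT condition.
#' @param sd_floor lower bound on the presence standard deviation used
#'   in per-feature penalties (features live on a 0-1 scale).  Without
#'   a floor, features that are almost constant over the presences get
#'   a vanishing penalty, which makes quasi-separable fits diverge.
#' @param beta_max box bound on coefficient magnitudes.  A numerical
#'   safeguard only: ordinary fits sit far below it, while completely
#'   separated configurations (whose unpenalized optimum is at
#'   infinity) stop at the bound instead of diverging.
#' @param reg_table per-class regularization tables.
#' @return list of settings.
#' @export
maxent_config <- function(n_knots = 50, tol = 1e-6, max_iter = 5000,
                          kkt_tol = 1e-5, sd_floor = 0.05,
                          beta_max = 200,
                          reg_table = default_regularization()) {
  list(n_knots = n_knots, tol = tol, max_iter = max_iter,
       kkt_tol = kkt_tol, sd_floor = sd_floor, beta_max = beta_max,
       reg_table = reg_table)
}

FC_SETS <- c("L", "H", "LQ", "LQH", "LQHP", "LQHPT")

parse_fc <- function(fc) {
  letters_fc <- strsplit(toupper(fc), "")[[1]]
  bad <- setdiff(letters_fc, c("L", "Q", "H", "P", "T"))
  if (length(bad)) stopf("unknown feature class letter(s): %s",
                         paste(bad, collapse = ""))
  unique(letters_fc)
}

#' Build feature definitions from a training sample
#'
#' Transforms raw climate variables into the model's covariates.  Each
#' variable is min-max scaled to 0-1 on the combined training sample;
#' features are then: linear = scaled value, quadratic = its square,
#' product = pairwise products, forward/reverse hinges and step
#' (threshold) functions with knots at up to `n_knots` empirical
#' quantiles strictly inside the training range.  Variables constant on
#' the sample are skipped, as are degenerate (constant) features.
#'
#' @param samples data.frame of raw variable columns (any `cell` /
#'   `label` columns are ignored); normally presences and background
#'   combined.
#' @param fc feature-class string, e.g. "LQH".
#' @param n_knots knot budget per variable per direction.
#' @return an `enm_features` object: list with `defs` (list of feature
#'   definitions), `scale` (per-variable training min/max), `fc`,
#'   `vars`, `names`.
#' @export
build_features <- function(samples, fc = "LQH", n_knots = 50) {
  x <- samples[, setdiff(names(samples), c("cell", "label")), drop = FALSE]
  x <- as.matrix(x)
  if (nrow(x) == 0) stopf("empty training sample")
  classes <- parse_fc(fc)
  rng <- apply(x, 2, range)
  ok_var <- rng[2, ] > rng[1, ]
  vars <- colnames(x)[ok_var]
  if (!length(vars)) stopf("no variable with at least 2 distinct values")
  scale <- list()
  for (v in vars)
    scale[[v]] <- c(min = unname(rng[1, v]), max = unname(rng[2, v]))
  z <- sapply(vars, function(v)
    (x[, v] - scale[[v]][["min"]]) / (scale[[v]][["max"]] - scale[[v]][["min"]]))
  z <- matrix(z, ncol = length(vars), dimnames = list(NULL, vars))

  mkdef <- function(kind, var, var2 = NA_character_, knot = NA_real_)
    list(kind = kind, var = var, var2 = var2, knot = knot)
  knots_for <- function(v) {
    probs <- seq_len(n_knots) / (n_knots + 1)
    k <- unique(as.numeric(stats::quantile(z[, v], probs, type = 7)))
    k[k > 0 & k < 1]
  }
  groups <- list()
  if ("L" %in% classes)
    groups$L <- lapply(vars, mkdef, kind = "linear")
  if ("Q" %in% classes)
    groups$Q <- lapply(vars, mkdef, kind = "quadratic")
  if ("P" %in% classes && length(vars) >= 2) {
    pr <- utils::combn(vars, 2)
    groups$P <- lapply(seq_len(ncol(pr)), function(i)
      mkdef("product", pr[1, i], pr[2, i]))
  }
  if ("H" %in% classes)
    groups$H <- do.call(c, lapply(vars, function(v)
      do.call(c, lapply(knots_for(v), function(k)
        list(mkdef("hinge_forward", v, knot = k),
             mkdef("hinge_reverse", v, knot = k))))))
  if ("T" %in% classes)
    groups$T <- do.call(c, lapply(vars, function(v)
      lapply(knots_for(v), function(k) mkdef("threshold", v, knot = k))))
  defs <- do.call(c, unname(groups))
  if (!length(defs)) stopf("no features could be constructed from fc='%s'", fc)
  feats <- structure(list(defs = defs, scale = scale, fc = fc,
                          vars = vars),
                     class = "enm_features")
  # drop features constant on the training sample
  M <- feature_matrix(feats, samples)
  keep <- vapply(seq_len(ncol(M)), function(j) {
    cj <- M[, j]
    max(cj) > min(cj)
  }, logical(1))
  feats$defs <- feats$defs[keep]
  feats$names <- feature_names(feats)
  feats
}

feature_names <- function(features) {
  vapply(features$defs, function(d) {
    switch(d$kind,
           linear = paste0("L:", d$var),
           quadratic = paste0("Q:", d$var),
           product = paste0("P:", d$var, "*", d$var2),
           hinge_forward = sprintf("HF:%s@%.6g", d$var, d$knot),
           hinge_reverse = sprintf("HR:%s@%.6g", d$var, d$knot),
           threshold = sprintf("T:%s@%.6g", d$var, d$knot))
  }, character(1))
}

#' Evaluate features on raw data
#'
#' @param features an `enm_features` object.
#' @param data data.frame of raw variable columns.
#' @param clamp clamp raw values to the training range before
#'   transforming (used when projecting onto new climates).
#' @return numeric matrix, one column per feature.
#' @export
feature_matrix <- function(features, data, clamp = FALSE) {
  miss <- setdiff(features$vars, names(data))
  if (length(miss)) stopf("data lacks variable(s): %s",
                          paste(miss, collapse = ", "))
  n <- nrow(data)
  z <- matrix(NA_real_, n, length(features$vars),
              dimnames = list(NULL, features$vars))
  for (v in features$vars) {
    xv <- as.numeric(data[[v]])
    sc <- features$scale[[v]]
    if (clamp) xv <- pmin(pmax(xv, sc[["min"]]), sc[["max"]])
    z[, v] <- (xv - sc[["min"]]) / (sc[["max"]] - sc[["min"]])
  }
  M <- matrix(0, n, length(features$defs))
  for (j in seq_along(features$defs)) {
    d <- features$defs[[j]]
    M[, j] <- switch(d$kind,
      linear = z[, d$var],
      quadratic = z[, d$var]^2,
      product = z[, d$var] * z[, d$var2],
      hinge_forward = pmax(0, (z[, d$var] - d$knot) / (1 - d$knot)),
      hinge_reverse = pmax(0, (d$knot - z[, d$var]) / d$knot),
      threshold = as.numeric(z[, d$var] > d$knot))
  }
  colnames(M) <- features$names %||% feature_names(features)
  M
}

# Indices of features whose parents include variable v.
features_of_var <- function(features, v) {
  which(vapply(features$defs, function(d)
    d$var == v || (!is.na(d$var2) && d$var2 == v), logical(1)))
}
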
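# Penalized maximum-entropy solver.
#
# The model maximizes, over coefficient vector beta,
#   (1/m) sum_presence eta(x) - log sum_background exp(eta(x))
#     - sum_j lambda_j |beta_j|
# with eta(x) = sum_j beta_j f_j(x).  The smooth part is concave, so the
# (negated) problem is convex and the proximal-Newton method in
# src/solver.cpp converges to the global optimum: Newton steps on a
# working set of features, an L1-penalized quadratic subproblem solved
# by coordinate descent, an Armijo line search on the true objective,
# and full KKT checks that pull violating features into the working
# set.

# R-side wrapper around the compiled proximal-Newton core
# (src/solver.cpp).
maxent_solve <- function(Fp, Fbg, lambda, beta0 = NULL, tol = 1e-6,
                         max_iter = 5000, kkt_tol = 1e-5,
                         beta_max = 200) {
  if (is.null(beta0)) beta0 <- rep(0, ncol(Fbg))
  sol <- enm_solve_cpp(Fp, Fbg, as.numeric(lambda), as.numeric(beta0),
                       tol, as.integer(max_iter), kkt_tol, beta_max)
  sol$beta <- as.numeric(sol$beta)
  sol$eta_bg <- as.numeric(sol$eta_bg)
  sol
}

strip_meta <- function(df) {
  df[, setdiff(names(df), c("cell", "label")), drop = FALSE]
}

#' Fit a presence-background maximum-entropy model
#'
#' Fits the penalized maximum-entropy objective (see the package
#' vignette) by a working-set proximal-Newton method.  The
#' per-feature penalty is `rm * r_class(m) * s_j / sqrt(m)` where `m` is
#' the number of presences, `s_j` the feature's standard deviation over
#' the presences (floored at `config$sd_floor`) and `r_class` the
#' class-level table from [default_regularization()].
#'
#' @param presences,background data.frames of raw variable values at
#'   presence and background cells (`cell` / `label` columns ignored).
#' @param fc feature-class string ("L", "H", "LQ", "LQH", "LQHP",
#'   "LQHPT", or any combination of the letters).
#' @param rm regularization multiplier (> 0).
#' @param features optional prebuilt [build_features()] result.
#' @param matrices optional list(Fp, Fbg) of prebuilt feature matrices
#'   matching `features` (used by the tuner to share work).
#' @param warm optional coefficient vector to warm-start from.
#' @param config solver settings from [maxent_config()].
#' @return an `enm_maxent` model: features, named `beta`, penalties,
#'   `logZ` and entropy `H` over the training background, training gain,
#'   and bookkeeping fields.
#' @export
maxent_fit <- function(presences, background, fc = "LQH", rm = 1,
                       features = NULL, matrices = NULL, warm = NULL,
                       config = maxent_config()) {
  p <- strip_meta(as.data.frame(presences))
  b <- strip_meta(as.data.frame(background))
  if (nrow(p) < 1) stopf("need at least one presence")
  if (nrow(b) < 2) stopf("need at least two background points")
  if (rm <= 0) stopf("rm must be positive")
  if (is.null(features))
    features <- build_features(rbind(p, b[names(p)]), fc,
                               n_knots = config$n_knots)
  if (is.null(matrices)) {
    Fp <- feature_matrix(features, p)
    Fbg <- feature_matrix(features, b)
  } else {
    Fp <- matrices$Fp; Fbg <- matrices$Fbg
  }
  if (any(!is.finite(Fp)) || any(!is.finite(Fbg)))
    stopf("non-finite feature values in training data")
  m <- nrow(Fp)
  kinds <- vapply(features$defs, `[[`, character(1), "kind")
  s <- apply(Fp, 2, stats::sd)
  if (m == 1) s <- rep(0, ncol(Fp))
  s <- pmax(s, config$sd_floor)
  rclass <- vapply(kinds, reg_class_value, numeric(1), m = m,
                   table = config$reg_table)
  lambda <- rm * rclass * s / sqrt(m)
  beta0 <- NULL
  if (!is.null(warm)) {
    beta0 <- rep(0, ncol(Fbg))
    common <- intersect(names(warm), features$names)
    beta0[match(common, features$names)] <- warm[common]
  }
  sol <- maxent_solve(Fp, Fbg, lambda, beta0 = beta0, tol = config$tol,
                      max_iter = config$max_iter, kkt_tol = config$kkt_tol,
                      beta_max = config$beta_max %||% 200)
  beta <- sol$beta
  if (any(abs(beta) >= (config$beta_max %||% 200) - 1e-9))
    warnf("coefficients at the +/-%g safeguard bound: data are (quasi-)separable at this regularization",
          config$beta_max %||% 200)
  # exact zeros from soft-thresholding; tidy numerical dust
  beta[abs(beta) < 1e-12] <- 0
  names(beta) <- features$names
  logZ <- logsumexp(sol$eta_bg)
  lq <- sol$eta_bg - logZ
  H <- -sum(exp(lq) * lq)
  null_obj <- log(nrow(Fbg))               # objective at beta = 0
  structure(
    list(features = features, beta = beta, lambda = lambda, rm = rm,
         fc = fc, m = m, n_background = nrow(Fbg), logZ = logZ, H = H,
         objective = sol$objective, gain = null_obj - sol$objective,
         iters = sol$iters),
    class = "enm_maxent")
}

#' @export
print.enm_maxent <- function(x, ...) {
  cat(sprintf(
    "<enm_maxent fc=%s rm=%.2g: %d/%d nonzero features, gain %.4f, H %.4f>\n",
    x$fc, x$rm, sum(x$beta != 0), length(x$beta), x$gain, x$H))
  invisible(x)
}

# Linear predictor on raw data (data.frame).  Only features with
# nonzero coefficients are evaluated.
model_eta <- function(model, data, clamp = FALSE) {
  nz <- which(model$beta != 0)
  if (!length(nz)) return(rep(0, nrow(data)))
  sub <- model$features
  sub$defs <- sub$defs[nz]
  sub$names <- sub$names[nz]
  M <- feature_matrix(sub, data, clamp = clamp)
  as.numeric(M %*% model$beta[nz])
}

#' Raw (relative occurrence rate) prediction
#'
#' `q(x) = exp(eta(x)) / Z` with `Z` the training-background
#' normalizer, so raw values over the model's own background sum to 1.
#'
#' @param model an `enm_maxent`.
#' @param data data.frame of raw variable values.
#' @param clamp clamp variables to the training range first.
#' @return numeric vector of raw probabilities.
#' @export
predict_raw <- function(model, data, clamp = FALSE) {
  exp(model_eta(model, data, clamp = clamp) - model$logZ)
}

#' Logistic habitat-suitability prediction
#'
#' `L(x) = c q(x) / (1 + c q(x))` with `c = exp(H)`, `H` the entropy of
#' the raw distribution over the training background.  A null model
#' (all coefficients zero) scores exactly 0.5 everywhere; values lie in
#' 0-1 and rank cells identically to the raw output.
#'
#' @inheritParams predict_raw
#' @return numeric vector of HSI values in 0-1.
#' @export
predict_logistic <- function(model, data, clamp = FALSE) {
  # c*q = exp(H + eta - logZ); computed on the log scale for stability
  lcq <- model$H + model_eta(model, data, clamp = clamp) - model$logZ
  stats::plogis(lcq)
}

#' Project a model onto a raster stack
#'
#' Evaluates the model at every cell where all layers are valid,
#' clamping variables to the training range by default, and returns a
#' suitability grid (nodata propagates).
#'
#' @param model an `enm_maxent`.
#' @param stack an `enm_stack` holding at least the model's variables.
#' @param clamp clamp to the training range (default TRUE).
#' @param type "logistic" (HSI in 0-1) or "raw".
#' @return an `enm_grid` of suitability values.
#' @export
project_model <- function(model, stack, clamp = TRUE,
                          type = c("logistic", "raw")) {
  type <- match.arg(type)
  g0 <- stack[[1]]
  vars <- model$features$vars
  layer_vals <- lapply(vars, function(v) {
    if (is.null(stack[[v]])) stopf("stack lacks layer '%s'", v)
    stack[[v]]$values
  })
  names(layer_vals) <- vars
  df <- as.data.frame(layer_vals)
  ok <- stats::complete.cases(df)
  out <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    pred <- if (type == "logistic")
      predict_logistic(model, df[ok, , drop = FALSE], clamp = clamp)
    else predict_raw(model, df[ok, , drop = FALSE], clamp = clamp)
    out[ok] <- pred
  }
  new_grid(out, g0$nrows, g0$ncols, g0$xll, g0$yll, g0$cellsize,
           nodata = g0$nodata)
}

#' Variable importance by leave-one-variable-out gain
#'
#' For each variable the model is refit with every feature involving
#' that variable removed (products count for both parents); the
#' variable's contribution is the drop in regularized training gain,
#' floored at zero and normalized to percentages summing to 100.
#' Jackknife companion columns report the gain of the model fitted
#' without the variable and (optionally) with only that variable.
#'
#' @param model a fitted `enm_maxent`.
#' @param presences,background the training data frames.
#' @param with_only also fit single-variable models (slower).
#' @param config solver settings.
#' @return list with `contribution` (named percentages) and `jackknife`
#'   (data.frame: variable, gain_full, gain_without, gain_with_only).
#' @export
variable_contribution <- function(model, presences, background,
                                  with_only = TRUE,
                                  config = maxent_config()) {
  p <- strip_meta(as.data.frame(presences))
  b <- strip_meta(as.data.frame(background))
  feats <- model$features
  Fp <- feature_matrix(feats, p)
  Fbg <- feature_matrix(feats, b)
  vars <- feats$vars
  gain_full <- model$gain
  drop_gain <- numeric(length(vars)); names(drop_gain) <- vars
  gain_without <- drop_gain; gain_with_only <- rep(NA_real_, length(vars))
  names(gain_with_only) <- vars
  for (v in vars) {
    keep <- setdiff(seq_along(feats$defs), features_of_var(feats, v))
    gw <- if (length(keep)) {
      sol <- maxent_solve(Fp[, keep, drop = FALSE],
                          Fbg[, keep, drop = FALSE],
                          model$lambda[keep],
                          beta0 = model$beta[keep],
                          tol = config$tol, max_iter = config$max_iter,
                          kkt_tol = config$kkt_tol,
                          beta_max = config$beta_max %||% 200)
      log(nrow(Fbg)) - sol$objective
    } else 0
    gain_without[v] <- gw
    drop_gain[v] <- max(0, gain_full - gw)
    if (with_only) {
      only <- features_of_var(feats, v)
      only <- only[vapply(feats$defs[only], function(d) is.na(d$var2),
                          logical(1))]   # with-only fits exclude products
      gain_with_only[v] <- if (length(only)) {
        sol <- maxent_solve(Fp[, only, drop = FALSE],
                            Fbg[, only, drop = FALSE],
                            model$lambda[only],
                            tol = config$tol, max_iter = config$max_iter,
                            kkt_tol = config$kkt_tol,
                            beta_max = config$beta_max %||% 200)
        log(nrow(Fbg)) - sol$objective
      } else 0
    }
  }
  tot <- sum(drop_gain)
  pct <- if (tot <= 0) {
    warnf("all leave-one-out gains zero; splitting contribution uniformly")
    rep(100 / length(vars), length(vars))
  } else 100 * drop_gain / tot
  names(pct) <- vars
  list(contribution = pct,
       jackknife = data.frame(variable = vars, gain_full = gain_full,
                              gain_without = as.numeric(gain_without),
                              gain_with_only = as.numeric(gain_with_only)))
}
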
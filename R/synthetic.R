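# Synthetic world generator: spatially autocorrelated, cross-correlated
# climate layers, species with known suitability truth, presence
# samples, smooth scenario perturbations, and parasite-host pairs with
# a tunable niche offset.  Everything is bit-reproducible from a seed.

#' AR(1)-style correlation matrix
#' @param K dimension.
#' @param rho base correlation; entry (i, j) is `rho^|i-j|`.
#' @return K x K positive-definite correlation matrix.
#' @export
ar1_corr <- function(K, rho = 0.6) {
  outer(seq_len(K), seq_len(K), function(i, j) rho^abs(i - j))
}

# Standardized Gaussian random field via FFT kernel smoothing on the
# torus (kernel convolution of white noise; wrap-around edges are an
# accepted artifact at desk scale).
gaussian_field <- function(nrows, ncols, range_len) {
  w <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
  if (range_len <= 0) {
    f <- w
  } else {
    dr <- pmin(0:(nrows - 1), nrows - 0:(nrows - 1))
    dc <- pmin(0:(ncols - 1), ncols - 0:(ncols - 1))
    kern <- exp(-outer(dr^2, dc^2, "+") / (2 * range_len^2))
    kern <- kern / sum(kern)
    f <- Re(stats::fft(stats::fft(w) * stats::fft(kern), inverse = TRUE)) /
      (nrows * ncols)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic climate stack
#'
#' Builds `K` spatially autocorrelated layers by kernel-smoothing white
#' noise to correlation length `range_len` (in cells), mixes them
#' through the Cholesky root of `cross_corr` to impose cross-layer
#' correlations, and rescales the first `ceiling(K/2)` layers to
#' temperature-like units (degrees C) and the rest to
#' precipitation-like units (mm, clamped at 0).  Layer names are
#' "Bio1".."BioK"; the temperature-like subset is recorded in the
#' stack's `temp_layers` attribute.
#'
#' @param nrows,ncols grid size (default 100 x 100: full pipeline runs
#'   in minutes).
#' @param K number of layers (default 8).
#' @param range_len autocorrelation length in cells.
#' @param cross_corr K x K positive-definite correlation target
#'   (default [ar1_corr()] with rho 0.6).
#' @param seed RNG seed.
#' @param xll,yll,cellsize geometry (default a 30 arc-second lattice).
#' @return an `enm_stack` with attribute `temp_layers`.
#' @export
gen_climate_stack <- function(nrows = 100, ncols = 100, K = 8,
                              range_len = 10, cross_corr = NULL,
                              seed = NULL, xll = 95, yll = 40,
                              cellsize = 1 / 120) {
  if (is.null(cross_corr)) cross_corr <- ar1_corr(K, 0.6)
  if (!isTRUE(all.equal(cross_corr, t(cross_corr))) ||
      any(eigen(cross_corr, symmetric = TRUE, only.values = TRUE)$values <= 1e-10))
    stopf("cross_corr must be symmetric positive-definite")
  with_seed(seed, {
    fields <- vapply(seq_len(K),
                     function(k) as.numeric(gaussian_field(nrows, ncols, range_len)),
                     numeric(nrows * ncols))
    # empirical whitening before mixing: smoothing leaves O(1/sqrt(n_eff))
    # sample correlations between fields, which would blur the targets;
    # whitened fields give realized correlations equal to cross_corr
    fields <- scale(fields, center = TRUE, scale = FALSE)
    fields <- fields %*% solve(chol(stats::cov(fields)))
    mixed <- fields %*% chol(cross_corr)
    n_temp <- ceiling(K / 2)
    layers <- vector("list", K)
    for (k in seq_len(K)) {
      f <- mixed[, k]
      vals <- if (k <= n_temp) 8 + 6 * f else pmax(0, 400 + 120 * f)
      # fields come column-major from the matrix; store row-major
      m <- matrix(vals, nrows, ncols)
      layers[[k]] <- new_grid(as.numeric(t(m)), nrows, ncols, xll, yll,
                              cellsize)
    }
    names(layers) <- paste0("Bio", seq_len(K))
    st <- raster_stack(layers)
    attr(st, "temp_layers") <- names(layers)[seq_len(n_temp)]
    st
  })
}

# Standardize a layer over its valid cells.
std_layer <- function(grid) {
  v <- grid$values
  (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
}

#' Default niche response specification
#'
#' Gaussian (quadratic) optima on one temperature-like and one
#' precipitation-like layer: the canonical two-gradient niche.
#'
#' @param stack an `enm_stack` from [gen_climate_stack()].
#' @param centers optima in standardized layer units.
#' @param weight curvature weight.
#' @return response specification list for [gen_species()].
#' @export
default_response <- function(stack, centers = c(0.8, -0.4), weight = 3) {
  tl <- attr(stack, "temp_layers") %||% stack_names(stack)[1]
  pl <- setdiff(stack_names(stack), tl)
  vars <- c(tl[1], if (length(pl)) pl[1] else tl[min(2, length(tl))])
  lapply(seq_along(vars), function(i)
    list(var = vars[i], form = "quadratic", weight = weight,
         center = centers[i]))
}

#' Generate a species with known suitability truth
#'
#' The true linear predictor is a weighted sum of transforms of
#' standardized layers: `linear` = w * z, `quadratic` =
#' -w * (z - center)^2 (a niche optimum), `hinge` = w * max(0, z -
#' center).  True suitability is exp(eta) normalized over valid cells.
#'
#' @param stack an `enm_stack`.
#' @param response_spec list of lists (var, form, weight, center);
#'   default [default_response()].
#' @param species species label.
#' @return an `enm_truth`: `eta` and `suitability` grids,
#'   `response_spec`, `species`.
#' @export
gen_species <- function(stack, response_spec = NULL,
                        species = "synthetic_sp") {
  if (is.null(response_spec)) response_spec <- default_response(stack)
  g0 <- stack[[1]]
  eta <- rep(0, length(g0$values))
  valid <- rep(TRUE, length(g0$values))
  for (l in unclass(stack)) valid <- valid & !is.na(l$values)
  for (rs in response_spec) {
    if (is.null(stack[[rs$var]])) stopf("stack lacks layer '%s'", rs$var)
    z <- std_layer(stack[[rs$var]])
    ctr <- rs$center %||% 0
    eta <- eta + switch(rs$form,
      linear = rs$weight * z,
      quadratic = -rs$weight * (z - ctr)^2,
      hinge = rs$weight * pmax(0, z - ctr),
      stopf("unknown response form '%s'", rs$form))
  }
  eta[!valid] <- NA_real_
  s <- exp(eta - max(eta, na.rm = TRUE))
  s <- s / sum(s, na.rm = TRUE)
  mk <- function(v) new_grid(v, g0$nrows, g0$ncols, g0$xll, g0$yll,
                             g0$cellsize, nodata = g0$nodata)
  structure(list(eta = mk(eta), suitability = mk(s),
                 response_spec = response_spec, species = species),
            class = "enm_truth")
}

#' Sample presence records from a suitability truth
#'
#' Draws `n` cells with probability proportional to true suitability
#' (optionally times a bias surface), with replacement, and jitters
#' each coordinate uniformly within its cell.
#'
#' @param truth an `enm_truth`.
#' @param n number of presences.
#' @param bias optional `enm_grid` of relative sampling effort.
#' @param seed RNG seed.
#' @return an `enm_occurrences` data.frame.
#' @export
sample_presences <- function(truth, n, bias = NULL, seed = NULL) {
  if (n < 1) stopf("n must be at least 1")
  g <- truth$suitability
  w <- g$values
  if (!is.null(bias)) {
    if (!geom_equal(g, bias)) stopf("bias geometry mismatch")
    w <- w * bias$values
  }
  ok <- which(!is.na(w) & w > 0)
  if (!length(ok)) stopf("no cell with positive sampling weight")
  with_seed(seed, {
    cells <- sample(ok, n, replace = TRUE, prob = w[ok])
    ctr <- cell_center(g, cells)
    jx <- stats::runif(n, -0.5, 0.5) * g$cellsize
    jy <- stats::runif(n, -0.5, 0.5) * g$cellsize
    occurrences(truth$species, ctr$lon + jx, ctr$lat + jy)
  })
}

#' Perturb a climate stack into a future scenario
#'
#' Temperature-like layers are shifted by `warming_delta` plus a smooth
#' random field of standard deviation `field_sd`; precipitation-like
#' layers are multiplied by `precip_scale` and clamped at 0.  Geometry
#' is unchanged.
#'
#' @param stack an `enm_stack` (with `temp_layers` attribute, as from
#'   [gen_climate_stack()]).
#' @param warming_delta mean warming, degrees C.
#' @param precip_scale multiplicative precipitation change.
#' @param field_sd SD of the spatially smooth warming anomaly.
#' @param range_len anomaly correlation length, cells.
#' @param seed RNG seed.
#' @return an `enm_stack` with the same `temp_layers` attribute.
#' @export
gen_future <- function(stack, warming_delta = 1.5, precip_scale = 1.05,
                       field_sd = 0.3, range_len = 10, seed = NULL) {
  tl <- attr(stack, "temp_layers") %||% character()
  g0 <- stack[[1]]
  with_seed(seed, {
    out <- lapply(stack_names(stack), function(v) {
      g <- stack[[v]]
      if (v %in% tl) {
        anom <- if (field_sd > 0)
          field_sd * as.numeric(t(matrix(
            gaussian_field(g$nrows, g$ncols, range_len), g$nrows, g$ncols)))
        else 0
        vals <- g$values + warming_delta + anom
      } else {
        vals <- pmax(0, g$values * precip_scale)
      }
      new_grid(vals, g$nrows, g$ncols, g$xll, g$yll, g$cellsize,
               nodata = g$nodata)
    })
    names(out) <- stack_names(stack)
    st <- raster_stack(out)
    attr(st, "temp_layers") <- tl
    st
  })
}

#' Generate a parasite-host pair with a tunable niche offset
#'
#' The host receives Gaussian niche optima on two layers; the parasite
#' gets the same optima shifted by `offset_delta` in standardized
#' environmental units.  Truth-level Schoener's D between the two
#' suitability surfaces decreases monotonically as the offset grows.
#'
#' @param stack an `enm_stack`.
#' @param offset_delta niche offset in standardized units (0 = shared
#'   niche, D = 1).
#' @param centers host optima (standardized units).
#' @param weight niche curvature.
#' @return list with `parasite` and `host` (`enm_truth` objects).
#' @export
gen_pair <- function(stack, offset_delta = 0.5, centers = c(0.8, -0.4),
                     weight = 3) {
  host_spec <- default_response(stack, centers = centers, weight = weight)
  para_spec <- lapply(host_spec, function(rs) {
    rs$center <- rs$center + offset_delta
    rs
  })
  list(parasite = gen_species(stack, para_spec, species = "parasite"),
       host = gen_species(stack, host_spec, species = "host"))
}
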
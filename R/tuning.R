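#' AICc of a fitted maximum-entropy model
#'
#' Information-criterion score in the Warren-Seifert convention used for
#' presence-background tuning: the raw output is renormalized over all
#' valid study cells, the log-likelihood is the sum of log normalized
#' scores at the presences, and k counts nonzero coefficients.  AICc is
#' +Inf when k >= n - 1 (the small-sample correction blows up).
#'
#' @param model an `enm_maxent`.
#' @param presences data.frame of presence variable values (n >= 2 rows).
#' @param cells_data data.frame of variable values at every valid study
#'   cell (the normalization domain).
#' @return list with `loglik`, `k`, `aicc`.
#' @export
model_aicc <- function(model, presences, cells_data) {
  p <- strip_meta(as.data.frame(presences))
  n <- nrow(p)
  if (n < 2) stopf("AICc needs at least 2 presences")
  eta_cells <- model_eta(model, strip_meta(as.data.frame(cells_data)))
  eta_p <- model_eta(model, p)
  logZ_cells <- logsumexp(eta_cells)
  loglik <- sum(eta_p - logZ_cells)
  k <- sum(model$beta != 0)
  aicc <- if (k >= n - 1) Inf
          else 2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
  list(loglik = loglik, k = k, aicc = aicc)
}

#' Tune regularization multiplier and feature classes by AICc
#'
#' Fits every (rm, fc) candidate on ALL presences (tuning uses no data
#' split), scores each by [model_aicc()], and selects the candidate with
#' delta AICc = 0.  Ties are broken by smaller k, then smaller rm, then
#' feature-class order as listed in `fc_sets`.  Within each feature
#' class, candidates are fitted in decreasing-rm order with warm starts.
#'
#' @param presences,background training data frames of variable values.
#' @param cells_data variable values at all valid study cells (AICc
#'   normalization domain).
#' @param rm_grid regularization multipliers (default 0.5 to 4 by 0.5).
#' @param fc_sets feature-class combinations (default the six standard
#'   sets L, H, LQ, LQH, LQHP, LQHPT).
#' @param config solver settings.
#' @return an `enm_tuning`: `candidates` data.frame (fc, rm, loglik, k,
#'   aicc, delta_aicc), `selected` list(fc, rm), and `model`, the
#'   refitted selected model.
#' @export
tune_maxent <- function(presences, background, cells_data,
                        rm_grid = seq(0.5, 4, by = 0.5),
                        fc_sets = FC_SETS,
                        config = maxent_config()) {
  p <- strip_meta(as.data.frame(presences))
  b <- strip_meta(as.data.frame(background))
  rows <- list()
  models <- list()
  # one master feature set covering every candidate class; per-fc
  # candidates reuse column subsets of its matrices
  master_fc <- paste(unique(unlist(strsplit(toupper(fc_sets), ""))),
                     collapse = "")
  master <- build_features(rbind(p, b[names(p)]), master_fc,
                           n_knots = config$n_knots)
  MFp <- feature_matrix(master, p)
  MFbg <- feature_matrix(master, b)
  kind_of <- vapply(master$defs, `[[`, character(1), "kind")
  kinds_for_fc <- function(fc) {
    map <- c(L = "linear", Q = "quadratic", P = "product",
             T = "threshold")
    cls <- parse_fc(fc)
    out <- unname(map[intersect(cls, names(map))])
    if ("H" %in% cls) out <- c(out, "hinge_forward", "hinge_reverse")
    out
  }
  for (fc in fc_sets) {
    cols <- which(kind_of %in% kinds_for_fc(fc))
    feats <- master
    feats$defs <- master$defs[cols]
    feats$names <- master$names[cols]
    feats$fc <- fc
    Fp <- MFp[, cols, drop = FALSE]
    Fbg <- MFbg[, cols, drop = FALSE]
    warm <- NULL
    for (rm in sort(rm_grid, decreasing = TRUE)) {
      mod <- maxent_fit(p, b, fc = fc, rm = rm, features = feats,
                        matrices = list(Fp = Fp, Fbg = Fbg),
                        warm = warm, config = config)
      warm <- mod$beta
      ic <- model_aicc(mod, p, cells_data)
      key <- sprintf("%s_rm%g", fc, rm)
      models[[key]] <- mod
      rows[[key]] <- data.frame(fc = fc, rm = rm, loglik = ic$loglik,
                                k = ic$k, aicc = ic$aicc,
                                stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, rows)
  # present the table in grid order: fc as listed, rm increasing
  cand <- cand[order(match(cand$fc, fc_sets), cand$rm), ]
  rownames(cand) <- NULL
  if (all(!is.finite(cand$aicc))) {
    err <- structure(class = c("enm_tuning_error", "error", "condition"),
                     list(message = "all tuning candidates have infinite AICc",
                          call = NULL, candidates = cand))
    stop(err)
  }
  cand$delta_aicc <- cand$aicc - min(cand$aicc)
  ord <- order(cand$delta_aicc, cand$k, cand$rm, match(cand$fc, fc_sets))
  best <- cand[ord[1], ]
  structure(
    list(candidates = cand,
         selected = list(fc = best$fc, rm = best$rm),
         model = models[[sprintf("%s_rm%g", best$fc, best$rm)]]),
    class = "enm_tuning")
}

#' @export
print.enm_tuning <- function(x, ...) {
  cat(sprintf("<enm_tuning: %d candidates; selected fc=%s rm=%g>\n",
              nrow(x$candidates), x$selected$fc, x$selected$rm))
  invisible(x)
}

#' Random train/test splits of presences
#'
#' Each replicate independently draws `ceiling(frac * n)` presences
#' without replacement as training data; the remainder are the test
#' set.
#'
#' @param n number of presences (or an object with rows).
#' @param frac training fraction (default 0.75).
#' @param n_rep number of replicates (default 15).
#' @param seed RNG seed.
#' @return list of `n_rep` lists with integer `train` and `test`.
#' @export
split_replicates <- function(n, frac = 0.75, n_rep = 15, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1) n <- nrow(n)
  n <- as.integer(n)
  if (frac <= 0 || frac > 1) stopf("frac must be in (0, 1]")
  n_train <- as.integer(ceiling(frac * n))
  if (n_train >= n)
    stopf("training fraction %.2f leaves an empty test set for n = %d",
          frac, n)
  with_seed(seed, lapply(seq_len(n_rep), function(r) {
    tr <- sort(sample.int(n, n_train))
    list(train = tr, test = setdiff(seq_len(n), tr))
  }))
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' Probability that a random presence scores above a random background
#' point, with ties counting one half.
#'
#' @param scores_p presence scores.
#' @param scores_b background scores.
#' @return AUC in 0-1.
#' @export
eval_auc <- function(scores_p, scores_b) {
  np <- length(scores_p); nb <- length(scores_b)
  if (np < 1 || nb < 1) stopf("need scores in both groups")
  r <- rank(c(scores_p, scores_b))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' True skill statistic maximized over thresholds
#'
#' Scans every observed score as a candidate threshold t; sensitivity is
#' the fraction of presences with score >= t, specificity the fraction
#' of background with score < t.  Returns the maximum TSS and its
#' threshold.
#'
#' @inheritParams eval_auc
#' @return list with `tss`, `threshold`, `sensitivity`, `specificity`.
#' @export
eval_tss <- function(scores_p, scores_b) {
  th <- sort(unique(c(scores_p, scores_b)))
  sp <- sort(scores_p); sb <- sort(scores_b)
  np <- length(sp); nb <- length(sb)
  # findInterval with left.open counts elements strictly below each t
  sens <- (np - findInterval(th, sp, left.open = TRUE)) / np
  spec <- findInterval(th, sb, left.open = TRUE) / nb
  tss <- sens + spec - 1
  i <- which.max(tss)
  list(tss = tss[i], threshold = th[i], sensitivity = sens[i],
       specificity = spec[i])
}

#' Fit and evaluate replicate models
#'
#' Fits one model per train/test split at fixed (fc, rm) and scores the
#' held-out presences against the shared background with AUC and max
#' TSS on the logistic output.
#'
#' @param presences,background training data frames.
#' @param fc,rm the tuned feature classes and regularization multiplier.
#' @param splits from [split_replicates()].
#' @param config solver settings.
#' @return an `enm_replicates`: `models` (list), `splits`, `scores`
#'   (data.frame rep, auc, tss, threshold).
#' @export
fit_replicates <- function(presences, background, fc, rm, splits,
                           config = maxent_config()) {
  p <- strip_meta(as.data.frame(presences))
  b <- strip_meta(as.data.frame(background))
  models <- vector("list", length(splits))
  scores <- vector("list", length(splits))
  warm <- NULL
  for (r in seq_along(splits)) {
    tr <- p[splits[[r]]$train, , drop = FALSE]
    te <- p[splits[[r]]$test, , drop = FALSE]
    mod <- maxent_fit(tr, b, fc = fc, rm = rm, warm = warm,
                      config = config)
    warm <- mod$beta
    sp <- predict_logistic(mod, te, clamp = TRUE)
    sb <- predict_logistic(mod, b)
    ts <- eval_tss(sp, sb)
    models[[r]] <- mod
    scores[[r]] <- data.frame(rep = r, auc = eval_auc(sp, sb),
                              tss = ts$tss, threshold = ts$threshold)
  }
  structure(list(models = models, splits = splits,
                 scores = do.call(rbind, scores)),
            class = "enm_replicates")
}

#' Cellwise mean of suitability grids
#'
#' @param maps list of aligned `enm_grid` objects.
#' @return an `enm_grid`; nodata cells are excluded pairwise (a cell is
#'   nodata only where every map is nodata).
#' @export
mean_map <- function(maps) {
  g0 <- maps[[1]]
  for (g in maps) if (!geom_equal(g, g0)) stopf("map geometry mismatch")
  M <- vapply(maps, function(g) g$values, numeric(length(g0$values)))
  if (length(g0$values) == 1L) M <- matrix(M, nrow = 1)
  v <- rowMeans(M, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  new_grid(v, g0$nrows, g0$ncols, g0$xll, g0$yll, g0$cellsize,
           nodata = g0$nodata)
}

#' Aggregate a replicate ensemble over a scenario stack
#'
#' Projects every replicate model onto the stack, averages the logistic
#' maps cellwise, and summarizes the evaluation metrics.
#'
#' @param replicates an `enm_replicates`.
#' @param stack scenario `enm_stack`.
#' @param clamp clamp to training ranges (default TRUE).
#' @return list with `mean_map` (`enm_grid`), `auc_mean`, `auc_sd`,
#'   `tss_mean`, `tss_sd`, `scores`.
#' @export
aggregate_replicates <- function(replicates, stack, clamp = TRUE) {
  maps <- lapply(replicates$models, project_model, stack = stack,
                 clamp = clamp, type = "logistic")
  sc <- replicates$scores
  list(mean_map = mean_map(maps),
       auc_mean = mean(sc$auc), auc_sd = stats::sd(sc$auc),
       tss_mean = mean(sc$tss), tss_sd = stats::sd(sc$tss),
       scores = sc)
}
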
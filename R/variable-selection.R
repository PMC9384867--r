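#' Pairwise Pearson correlation of climate variables
#'
#' Computes the correlation matrix over a chosen sample of rows
#' (presences, presences + background, or all valid cells).  Constant
#' columns get r = 0 against every other variable, with a warning, so
#' they can never trigger an elimination.
#'
#' @param samples data.frame of variable columns (e.g. from
#'   [extract_values()]; `cell` and `label` columns are ignored).
#' @param basis free-text tag recording which rows were correlated.
#' @return an `enm_corr` object: list with `variables`, `r` (symmetric
#'   matrix, unit diagonal), `basis`.
#' @export
pearson_matrix <- function(samples, basis = "presence+background") {
  x <- samples[, setdiff(names(samples), c("cell", "label")), drop = FALSE]
  x <- as.matrix(x)
  if (nrow(x) < 3) stopf("need at least 3 rows to correlate")
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const))
    warnf("constant column(s) %s: correlations set to 0",
          paste(colnames(x)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(x, method = "pearson"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  structure(list(variables = colnames(x), r = r, basis = basis),
            class = "enm_corr")
}

#' Contribution percentages from an all-variables pilot model
#'
#' Fits a single maximum-entropy model on every candidate variable and
#' returns per-variable contribution percentages (leave-one-variable-out
#' gain, normalized to 100).  Used to break correlation ties: of two
#' collinear variables the one contributing less is eliminated.
#'
#' @param presences,background data.frames of variable values (rows at
#'   presence / background cells).
#' @param fc feature classes for the pilot fit (default "LQ": cheap and
#'   stable for ranking purposes).
#' @param rm regularization multiplier for the pilot fit.
#' @return named numeric vector of percentages summing to 100.
#' @export
pilot_contributions <- function(presences, background, fc = "LQ", rm = 1) {
  model <- maxent_fit(presences, background, fc = fc, rm = rm)
  vc <- variable_contribution(model, presences, background,
                              with_only = FALSE)
  vc$contribution
}

#' Correlation-based variable elimination
#'
#' Greedy filter: while any retained pair exceeds the absolute
#' correlation threshold, take the pair with the largest |r| (ties
#' broken lexicographically by the pair's sorted names) and drop its
#' lower-contribution member (contribution ties: the later alphabetical
#' name is dropped).  The result never contains a pair with
#' |r| > threshold.
#'
#' @param report an `enm_corr` from [pearson_matrix()].
#' @param contributions named percentages from [pilot_contributions()].
#' @param threshold absolute correlation above which a pair is collinear
#'   (default 0.7).
#' @return an `enm_selection`: list with `retained`, `dropped`
#'   (data.frame: variable, against, abs_r, contribution), `threshold`,
#'   `contributions`.
#' @export
select_variables <- function(report, contributions, threshold = 0.7) {
  vars <- report$variables
  if (!all(vars %in% names(contributions)))
    stopf("contributions missing for: %s",
          paste(setdiff(vars, names(contributions)), collapse = ", "))
  r <- abs(report$r)
  keep <- vars
  dropped <- list()
  repeat {
    sub <- r[keep, keep, drop = FALSE]
    diag(sub) <- 0
    if (all(sub <= threshold)) break
    # offending pairs, worst first; lexicographic pair-name tie-break
    idx <- which(sub > threshold, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pr <- data.frame(a = keep[idx[, 1]], b = keep[idx[, 2]],
                     r = sub[idx], stringsAsFactors = FALSE)
    key <- paste(pmin(pr$a, pr$b), pmax(pr$a, pr$b))
    pr <- pr[order(-pr$r, key), , drop = FALSE]
    a <- pr$a[1]; b <- pr$b[1]
    ca <- contributions[[a]]; cb <- contributions[[b]]
    drop_var <- if (ca < cb) a
      else if (cb < ca) b
      else max(a, b)                      # equal contribution: later name goes
    other <- if (drop_var == a) b else a
    dropped[[length(dropped) + 1L]] <- data.frame(
      variable = drop_var, against = other, abs_r = pr$r[1],
      contribution = contributions[[drop_var]], stringsAsFactors = FALSE)
    keep <- setdiff(keep, drop_var)
  }
  structure(
    list(retained = keep,
         dropped = if (length(dropped)) do.call(rbind, dropped)
                   else data.frame(variable = character(), against = character(),
                                   abs_r = numeric(), contribution = numeric()),
         threshold = threshold,
         contributions = contributions[vars]),
    class = "enm_selection")
}

#' @export
print.enm_selection <- function(x, ...) {
  cat(sprintf("<enm_selection: %d retained (|r| <= %.2f), %d dropped>\n",
              length(x$retained), x$threshold, nrow(x$dropped)))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
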
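#' Schoener's D niche overlap between two suitability maps
#'
#' Both maps are restricted to their shared valid cells, each is
#' normalized to sum to 1 (giving per-cell occupancy distributions p_X
#' and p_Y), and D = 1 - 0.5 * sum |p_X - p_Y|.  D is 1 for identical
#' distributions, 0 for disjoint support, symmetric, and invariant to
#' rescaling either map by a positive constant.
#'
#' @param map_x,map_y aligned `enm_grid` suitability maps (or plain
#'   numeric vectors of equal length).
#' @return D in 0-1.
#' @export
schoener_d <- function(map_x, map_y) {
  if (inherits(map_x, "enm_grid")) {
    if (!geom_equal(map_x, map_y)) stopf("map geometry mismatch")
    vx <- map_x$values; vy <- map_y$values
  } else {
    vx <- as.numeric(map_x); vy <- as.numeric(map_y)
    if (length(vx) != length(vy)) stopf("length mismatch")
  }
  ok <- !is.na(vx) & !is.na(vy)
  vx <- vx[ok]; vy <- vy[ok]
  if (!length(vx)) stopf("no shared valid cells")
  if (any(vx < 0) || any(vy < 0)) stopf("suitability values must be nonnegative")
  sx <- sum(vx); sy <- sum(vy)
  if (sx == 0 || sy == 0)
    stopf("all-zero suitability map: overlap undefined")
  1 - 0.5 * sum(abs(vx / sx - vy / sy))
}

#' Overlap class of a Schoener's D value
#'
#' Five lower-closed bins: no/very limited 0.00-0.20, low 0.20-0.40,
#' moderate 0.40-0.60, high 0.60-0.80, very high 0.80-1.00 (closed at
#' 1).
#'
#' @param d Schoener's D value(s) in 0-1.
#' @return character vector of class labels.
#' @export
overlap_class <- function(d) {
  if (any(d < 0 | d > 1, na.rm = TRUE)) stopf("D must lie in [0, 1]")
  labels <- c("no_or_very_limited", "low", "moderate", "high", "very_high")
  labels[findInterval(d, c(0.2, 0.4, 0.6, 0.8)) + 1]
}

#' Mean and sample SD of per-scenario overlap values
#'
#' @param d numeric vector of per-scenario D values (current + futures).
#' @param digits decimals for reporting (default 4, matching published
#'   overlap tables).
#' @return list with `mean` and `sd` (sample, n-1 denominator).
#' @export
pair_summary <- function(d, digits = 4) {
  list(mean = round(mean(d), digits), sd = round(stats::sd(d), digits))
}

#' Overlap trend typology
#'
#' Same growing / declining / fluctuating rule as
#' [trend_typology()], applied to per-scenario Schoener's D.
#'
#' @param current_d current-scenario D.
#' @param future_d the four future-scenario D values.
#' @return label string.
#' @export
overlap_typology <- function(current_d, future_d) {
  trend_typology(current_d, future_d)$label
}

#' Classical one-way ANOVA
#'
#' Between/within-group F with (k - 1, N - k) degrees of freedom and
#' upper-tail p-value.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
anova_oneway <- function(groups) {
  k <- length(groups)
  if (k < 2) stopf("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stopf("each group needs at least 2 values")
  all_v <- unlist(groups, use.names = FALSE)
  N <- length(all_v)
  gm <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - gm)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ss_within == 0) {
    Fv <- if (ss_between == 0) 0 else Inf
  } else {
    Fv <- (ss_between / df1) / (ss_within / df2)
  }
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, p = p, df1 = df1, df2 = df2)
}

#' Tamhane T2 pairwise comparisons with compact letter display
#'
#' Unequal-variance post-hoc: for each pair a Welch t statistic with
#' Welch-Satterthwaite degrees of freedom is compared against the
#' two-sided critical value at the Sidak-adjusted per-comparison level
#' alpha' = 1 - (1 - alpha)^(1/m) over the m pairs.  Letters are built
#' by insert-and-absorb over the non-significance graph, ordered by
#' decreasing group mean, so groups sharing a letter are pairwise
#' non-significant.
#'
#' @param groups named list of numeric vectors.
#' @param alpha familywise significance level (default 0.01).
#' @return an `enm_posthoc`: `pairwise` data.frame (group1, group2, t,
#'   df, crit, significant), `letters` named character vector, `F`,
#'   `p` from the companion ANOVA, `alpha`, `alpha_adj`.
#' @export
tamhane_t2 <- function(groups, alpha = 0.01) {
  k <- length(groups)
  av <- anova_oneway(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  ns <- vapply(groups, length, numeric(1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  alpha_adj <- 1 - (1 - alpha)^(1 / m)
  rows <- lapply(seq_len(m), function(pi) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    se2 <- vars[i] / ns[i] + vars[j] / ns[j]
    if (se2 == 0) {
      # both groups constant: significant iff the means differ at all
      return(data.frame(group1 = nm[i], group2 = nm[j],
                        t = if (means[i] == means[j]) 0 else Inf,
                        df = Inf, crit = Inf,
                        significant = means[i] != means[j],
                        stringsAsFactors = FALSE))
    }
    tval <- abs(means[i] - means[j]) / sqrt(se2)
    df <- se2^2 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                   (vars[j] / ns[j])^2 / (ns[j] - 1))
    crit <- stats::qt(1 - alpha_adj / 2, df)
    data.frame(group1 = nm[i], group2 = nm[j], t = tval, df = df,
               crit = crit, significant = tval > crit,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  letters_out <- letter_display(nm, means, pw)
  structure(list(pairwise = pw, letters = letters_out, F = av$F,
                 p = av$p, alpha = alpha, alpha_adj = alpha_adj),
            class = "enm_posthoc")
}

# Insert-and-absorb compact letter display.  `pw` carries the
# significant pairs; columns (sets of group indices) start as one
# all-inclusive set and are split for each significant pair, then
# subset columns are absorbed.  Letters are assigned in order of
# decreasing group mean.
letter_display <- function(nm, means, pw) {
  k <- length(nm)
  cols <- list(seq_len(k))
  sig <- pw[pw$significant, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    i <- match(sig$group1[r], nm); j <- match(sig$group2[r], nm)
    for (ci in seq_along(cols)) {
      if (i %in% cols[[ci]] && j %in% cols[[ci]]) {
        a <- setdiff(cols[[ci]], i)
        b <- setdiff(cols[[ci]], j)
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] %in% cols[[cj]])) keep[ci] <- FALSE
    }
    cols <- cols[keep]
  }
  # deterministic letter order: columns ranked by their best (highest
  # mean) member
  best <- vapply(cols, function(cc) max(means[cc]), numeric(1))
  cols <- cols[order(-best)]
  out <- rep("", k)
  for (ci in seq_along(cols))
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], letters[ci])
  names(out) <- nm
  out
}

#' @export
print.enm_posthoc <- function(x, ...) {
  cat(sprintf("<enm_posthoc: F = %.3f, p = %.3g, alpha = %g>\n",
              x$F, x$p, x$alpha))
  print(data.frame(group = names(x$letters), letter = x$letters,
                   row.names = NULL))
  invisible(x)
}
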
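#' Linear regression summary for parameter-composition relationships
#'
#' Ordinary least squares of `y` on `x` with intercept, reporting the
#' two-sided p-value of the slope, adjusted R-squared
#' `1 - (1 - R^2)(n - 1)/(n - 2)`, the signed Pearson correlation and the
#' significance flag at p < 0.05 used throughout the reporting tables.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite
#' @return object of class `regression_result`: `slope`, `intercept`,
#'   `p`, `r2_adj`, `corr`, `n`, `significant`
#' @export
regress <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("x and y must be finite")
  if (var(x) == 0) stop("zero variance in x")
  if (var(y) == 0) stop("zero variance in y")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p = unname(sm$coefficients[2, 4]),
                 r2_adj = sm$adj.r.squared,
                 corr = unname(stats::cor(x, y)),
                 n = length(x),
                 significant = unname(sm$coefficients[2, 4]) < 0.05),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("n = %d: slope %.4g, p = %.4g, adj R^2 = %.3f, corr = %.3f%s\n",
              x$n, x$slope, x$p, x$r2_adj, x$corr,
              if (x$significant) "" else " (not significant)"))
  invisible(x)
}

#' Two-group comparison (Welch t-test)
#'
#' Used for sheet-thickness contrasts between synthesis-temperature
#' groups.  Unequal variances are assumed.
#'
#' @param a,b numeric vectors, each n >= 2
#' @return two-sided p-value
#' @export
group_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  t.test(a, b)$p.value
}

#' Parameter-composition correlation report
#'
#' One regression row per refined parameter against carbonate content,
#' mirroring the layout of published parameter-correlation tables: p,
#' adjusted R-squared and signed correlation, with non-significant
#' correlations displayed as a dash.  When `group` is given, each group
#' is reported separately.  A Benjamini-Hochberg adjusted p column is
#' emitted alongside for transparency but takes no part in the
#' significance flags.
#'
#' @param param_table data.frame: one row per sample, one numeric column
#'   per parameter
#' @param co3 carbonate concentrations (wt%), one per sample
#' @param group optional factor/character of group labels per sample
#' @return data.frame with columns `parameter`, `group`, `n`, `slope`,
#'   `p`, `p_bh`, `r2_adj`, `corr`, `significant`, `display`
#' @export
build_report <- function(param_table, co3, group = NULL) {
  stopifnot(is.data.frame(param_table))
  if (nrow(param_table) != length(co3))
    stop("param_table and co3 must have one entry per sample")
  if (nrow(param_table) < 3) stop("need at least 3 samples")
  if (is.null(group)) group <- rep("all", nrow(param_table))
  num_cols <- names(param_table)[vapply(param_table, is.numeric, logical(1))]
  # constant columns are parameters that were held fixed: no relationship
  # to estimate, so they are dropped from the report
  num_cols <- num_cols[vapply(param_table[num_cols], function(v)
    isTRUE(var(v[is.finite(v)]) > 0), logical(1))]

  rows <- list()
  for (g in unique(group)) {
    sel <- group == g
    for (cn in num_cols) {
      x <- co3[sel]; y <- param_table[[cn]][sel]
      ok <- is.finite(x) & is.finite(y)
      if (sum(!ok) > 0)
        warning(sprintf("parameter %s, group %s: %d sample(s) missing, excluded",
                        cn, g, sum(!ok)))
      res <- tryCatch(regress(x[ok], y[ok]), error = function(e) NULL)
      if (is.null(res)) {
        warning(sprintf("parameter %s, group %s: regression not estimable, row excluded",
                        cn, g))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        parameter = cn, group = g, n = res$n, slope = res$slope,
        p = res$p, r2_adj = res$r2_adj, corr = res$corr,
        significant = res$significant, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no parameter row could be regressed")
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  for (g in unique(out$group))
    out$p_bh[out$group == g] <- stats::p.adjust(out$p[out$group == g], "BH")
  out$display <- ifelse(out$significant, sprintf("%.2f", out$corr), "-")
  out[, c("parameter", "group", "n", "slope", "p", "p_bh", "r2_adj",
          "corr", "significant", "display")]
}
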
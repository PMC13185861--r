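#' Box-plot summary
#'
#' Median, linear-interpolation quartiles, whiskers at the non-outlier
#' extent and outliers flagged by the 1.5 x IQR rule.
#'
#' @param x Numeric vector.
#' @return A list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
box_summary <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[3L] + 1.5 * iqr
  inl <- x[x >= lo & x <= hi]
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(inl), whisker_high = max(inl),
       outliers = sort(x[x < lo | x > hi]), n = length(x))
}

#' Group comparisons: Kruskal-Wallis/Tukey or one-sample t
#'
#' With two or more groups: non-parametric Kruskal-Wallis omnibus test
#' followed by Tukey HSD pairwise comparisons on the rank-transformed
#' values. With a single numeric vector: one-sample t test against
#' `null_value` (used e.g. to ask whether relative complexity differs from
#' zero).
#'
#' @param values Named list of numeric vectors (>= 2 groups), or a single
#'   numeric vector for the one-sample mode.
#' @param null_value Null mean for the one-sample mode. Default 0.
#' @return A `comparison_report` list: `test`, `statistic`, `df` (where
#'   applicable), `p_value`, `pairwise` (Tukey table or NULL), `summaries`
#'   (per-group [box_summary()]).
#' @export
compare_groups <- function(values, null_value = 0) {
  if (is.numeric(values)) values <- list(sample = values)
  if (length(values) == 1L) {
    x <- values[[1L]]
    if (length(x) < 2L) stop("one-sample t test needs at least 2 values")
    tt <- stats::t.test(x, mu = null_value)
    rep_ <- list(test = "one-sample t", statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 null_value = null_value, pairwise = NULL,
                 summaries = lapply(values, box_summary))
  } else {
    if (is.null(names(values))) names(values) <- paste0("group", seq_along(values))
    v <- unlist(values, use.names = FALSE)
    grp <- factor(rep(names(values), times = vapply(values, length, 1L)))
    kw <- stats::kruskal.test(v, grp)
    tk <- stats::TukeyHSD(stats::aov(rank(v) ~ grp))$grp
    rep_ <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p_value = kw$p.value,
                 pairwise = tk, summaries = lapply(values, box_summary))
  }
  class(rep_) <- "comparison_report"
  rep_
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test, x$statistic, format(x$df), x$p_value))
  invisible(x)
}

#' Pairwise correlation panels with robust linear fits
#'
#' For every pair of numeric variables in a feature table: Pearson r with a
#' two-tailed t test (`t = r * sqrt((n - 2) / (1 - r^2))`), and a robust
#' linear fit by iteratively reweighted least squares with Tukey's bisquare
#' weight (tuning constant 4.685), computed on pairwise-complete rows.
#' Panels with fewer than 3 complete pairs or a constant variable are
#' returned with `NA` estimates and `status` set accordingly.
#'
#' @param ft A data.frame (e.g. a [feature_table()]).
#' @param variables Optional character vector restricting the columns used;
#'   default: all numeric columns.
#' @return A `pairwise_panels` data.frame with columns `var1`, `var2`, `n`,
#'   `r`, `t`, `df`, `p_value`, `slope`, `intercept`, `status`.
#' @export
pairwise_correlations <- function(ft, variables = NULL) {
  d <- as.data.frame(ft)
  num <- names(d)[vapply(d, is.numeric, TRUE)]
  variables <- variables %||% num
  variables <- intersect(variables, num)
  if (length(variables) < 2L) stop("need at least 2 numeric variables")
  pairs <- utils::combn(variables, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    v1 <- pairs[1L, k]; v2 <- pairs[2L, k]
    ok <- stats::complete.cases(d[[v1]], d[[v2]])
    x <- d[[v1]][ok]; y <- d[[v2]][ok]
    n <- length(x)
    base <- data.frame(var1 = v1, var2 = v2, n = n, r = NA_real_,
                       t = NA_real_, df = NA_real_, p_value = NA_real_,
                       slope = NA_real_, intercept = NA_real_,
                       status = "ok", stringsAsFactors = FALSE)
    if (n < 3L) { base$status <- "too few pairs"; return(base) }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      base$status <- "constant variable"; return(base)
    }
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
    base$r <- unname(ct$estimate)
    base$t <- unname(ct$statistic)
    base$df <- unname(ct$parameter)
    base$p_value <- ct$p.value
    base$intercept <- unname(stats::coef(fit)[1L])
    base$slope <- unname(stats::coef(fit)[2L])
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pairwise_panels", "data.frame")
  out
}
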
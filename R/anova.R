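#' Balanced factorial ANOVA with a conservative df adjustment
#'
#' Fits a fully crossed, balanced factorial ANOVA (1 to 3 categorical
#' factors, all interactions) and tests each F ratio against a critical F
#' whose error degrees of freedom may be divided by a conservatism factor.
#' Dividing by 3 implements the adjustment for metacommunity designs in
#' which the three N:P patches within a metacommunity are not independent
#' (they exchange 5% of their volume weekly): F ratios are computed as
#' usual, but significance at `alpha` is decided against
#' `qf(1 - alpha, df_num, df_error / 3)`. Unbalanced designs are rejected
#' rather than reweighted (the distinction between sum-of-squares types is
#' then moot).
#'
#' @param formula Model formula `response ~ A * B * ...`; the response
#'   should already be on the analysis scale (e.g. ln-transformed).
#' @param data Data frame with the response and factor columns.
#' @param df_divisor Divisor applied to the error df when deciding
#'   significance (1 = ordinary ANOVA; 3 = the conservative patch-scale
#'   test). Kept continuous, not rounded.
#' @param alpha Significance level for the critical F.
#' @return An object of class `bef_anova`: a data frame with one row per
#'   term plus the error row, columns `term`, `df`, `sum_sq`, `mean_sq`,
#'   `f`, `df_err_adj`, `f_crit`, `significant`, `p_adj` (the p-value of F
#'   on the adjusted error df).
#' @examples
#' d <- expand.grid(p = factor(1:3), sp = factor(1:6), r = 1:3)
#' d$y <- rnorm(nrow(d)) + as.numeric(d$p)
#' balanced_anova(y ~ p * sp, d)
#' @export
balanced_anova <- function(formula, data, df_divisor = 1, alpha = 0.05) {
  mf <- stats::model.frame(formula, data)
  response <- mf[[1L]]
  factors <- mf[-1L]
  if (length(factors) < 1L || length(factors) > 3L) {
    stop("between 1 and 3 factors are supported")
  }
  factors[] <- lapply(factors, function(x) factor(as.character(x)))
  counts <- table(factors)
  if (any(counts == 0L)) stop("design is not fully crossed (empty cells)")
  if (length(unique(as.vector(counts))) != 1L) {
    stop("design is unbalanced (unequal cell counts); balanced designs only")
  }
  dat <- data.frame(.y = response, factors)
  full <- stats::as.formula(paste(".y ~", paste(names(factors), collapse = " * ")))
  fit <- stats::aov(full, data = dat)
  tab <- summary(fit)[[1L]]
  term <- trimws(rownames(tab))
  is_resid <- term == "Residuals"
  df_err <- tab$Df[is_resid]
  ss_err <- tab$`Sum Sq`[is_resid]
  if (length(df_err) == 0L || df_err <= 0) {
    stop("no residual degrees of freedom (saturated model)")
  }
  df_adj <- df_err / df_divisor
  if (df_adj < 1) stop("adjusted error df < 1: effect untestable")
  res <- data.frame(
    term = gsub(":", " x ", term),
    df = tab$Df,
    sum_sq = tab$`Sum Sq`,
    mean_sq = tab$`Mean Sq`,
    f = tab$`F value`,
    stringsAsFactors = FALSE
  )
  res$df_err_adj <- ifelse(is_resid, NA_real_, df_adj)
  res$f_crit <- ifelse(is_resid, NA_real_,
                       stats::qf(1 - alpha, res$df, df_adj))
  res$significant <- ifelse(is_resid, NA, res$f > res$f_crit)
  res$p_adj <- ifelse(is_resid, NA_real_,
                      stats::pf(res$f, res$df, df_adj, lower.tail = FALSE))
  res$term[is_resid] <- "Error"
  attr(res, "df_err") <- df_err
  attr(res, "ss_err") <- ss_err
  attr(res, "df_divisor") <- df_divisor
  attr(res, "alpha") <- alpha
  attr(res, "n_obs") <- nrow(dat)
  class(res) <- c("bef_anova", "data.frame")
  res
}

#' @export
print.bef_anova <- function(x, ...) {
  cat(sprintf("Balanced factorial ANOVA (alpha = %g, error df divisor = %g)\n",
              attr(x, "alpha"), attr(x, "df_divisor")))
  df <- as.data.frame(x)
  df$sum_sq <- signif(df$sum_sq, 4)
  df$mean_sq <- signif(df$mean_sq, 4)
  df$f <- signif(df$f, 3)
  df$f_crit <- signif(df$f_crit, 3)
  df$p_adj <- signif(df$p_adj, 2)
  df$significant <- ifelse(is.na(df$significant), "",
                           ifelse(df$significant, "*", ""))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Conservative significance decision for one F ratio
#'
#' Given an observed F with numerator df and error df, divides the error df
#' by `divisor` (continuous, not rounded) and declares significance iff the
#' observed F exceeds the upper-`alpha` quantile of F(df_num, df_err /
#' divisor). Because F quantiles decrease in the denominator df, this test
#' is strictly more conservative than the ordinary one.
#'
#' @param f Observed F ratio.
#' @param df_num Numerator degrees of freedom.
#' @param df_err Unadjusted error degrees of freedom (> 0).
#' @param divisor Conservatism divisor (default 3).
#' @param alpha Significance level.
#' @return List with `df_adj`, `f_crit`, `significant`.
#' @examples
#' adjusted_df_test(5.5, 1, 30) # df_adj 10, F_crit 4.96
#' @export
adjusted_df_test <- function(f, df_num, df_err, divisor = 3, alpha = 0.05) {
  if (df_err <= 0) stop("df_err must be > 0")
  df_adj <- df_err / divisor
  if (df_adj < 1) stop("adjusted error df < 1: effect untestable")
  f_crit <- stats::qf(1 - alpha, df_num, df_adj)
  list(df_adj = df_adj, f_crit = f_crit, significant = f > f_crit)
}

#' Treatment residuals from a saturated factorial
#'
#' Subtracts from every observation the mean of its full factorial
#' treatment cell, i.e. the residuals of the saturated model with all
#' factor interactions. Used to ask whether a correlation between two
#' responses persists once treatment effects are removed.
#'
#' @param response Numeric response vector.
#' @param factors Data frame (or list) of factor columns defining the
#'   cells.
#' @return Numeric vector of residuals (summing to zero within each cell).
#' @export
treatment_residuals <- function(response, factors) {
  factors <- as.data.frame(factors)
  cell <- interaction(factors, drop = TRUE)
  if (all(tabulate(cell) <= 1L)) {
    warning("all treatment cells are singletons: residuals are identically 0")
  }
  response - stats::ave(response, cell)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' Standard product-moment correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, nonzero variances).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input: r undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
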
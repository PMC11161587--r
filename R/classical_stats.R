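#' Flag outliers by the 3-standard-deviation rule
#'
#' Indices of values whose absolute distance from the sample mean exceeds
#' three sample standard deviations (mean and SD computed over all values).
#' A zero-variance column yields no flags.
#'
#' @param values Numeric vector with at least 3 finite values.
#' @param k Number of SDs (default 3).
#' @return Integer vector of flagged indices (possibly empty).
#' @export
flag_outliers_3sd <- function(values, k = 3) {
  if (sum(is.finite(values)) < 3L) stop("need at least 3 finite values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(integer(0))
  which(abs(values - mean(values)) > k * s)
}

#' Simulate the Monte-Carlo null distribution of the Lilliefors statistic
#'
#' The null distribution of the Lilliefors-corrected Kolmogorov-Smirnov
#' statistic depends only on the sample size, so it can be computed once and
#' reused across tests of equal-sized samples.
#'
#' @param n Sample size.
#' @param n_mc Number of simulated null samples (default 5000).
#' @param seed Integer seed.
#' @return Numeric vector of `n_mc` null statistics.
#' @export
lilliefors_null_stats <- function(n, n_mc = 5000L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_mc),
         function(i) lilliefors_statistic(stats::rnorm(n)), 0)
}

# sup distance between the empirical CDF and the normal CDF with estimated
# mean and SD (the Lilliefors correction is exactly this estimation step)
lilliefors_statistic <- function(values) {
  n <- length(values)
  z <- sort((values - mean(values)) / stats::sd(values))
  p <- stats::pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Kolmogorov-Smirnov normality test with Lilliefors correction
#'
#' Computes the KS distance between the empirical CDF and a normal CDF with
#' mean and SD estimated from the data, and a Monte-Carlo p-value from
#' `n_mc` simulated normal samples of the same size (the statistic is
#' distribution-free under the null, so a precomputed table from
#' [lilliefors_null_stats()] may be supplied to amortize the simulation).
#'
#' @param values Numeric vector, n >= 5, non-constant.
#' @param n_mc Number of Monte-Carlo null samples (default 5000).
#' @param seed Integer seed for the null simulation.
#' @param null_stats Optional precomputed null statistics for this sample
#'   size.
#' @return List with `statistic`, `p_value`, `n`.
#' @export
lilliefors_ks <- function(values, n_mc = 5000L, seed = 1L,
                          null_stats = NULL) {
  n <- length(values)
  if (n < 5L) stop("need n >= 5")
  if (stats::sd(values) == 0) stop("zero-variance sample")
  d <- lilliefors_statistic(values)
  if (is.null(null_stats)) null_stats <- lilliefors_null_stats(n, n_mc, seed)
  list(statistic = d,
       p_value = (1 + sum(null_stats >= d)) / (length(null_stats) + 1),
       n = n)
}

#' Quantile-quantile normality summary
#'
#' Correlation between the ordered sample and the corresponding theoretical
#' normal quantiles (Blom-type plotting positions); values near 1 indicate a
#' distribution very close to normal. Invariant to affine transforms of the
#' data.
#'
#' @param values Numeric vector, n >= 5.
#' @return List with `correlation` and the paired quantiles
#'   (`sample`, `theoretical`).
#' @export
qq_normality <- function(values) {
  n <- length(values)
  if (n < 5L) stop("need n >= 5")
  s <- sort(values)
  q <- stats::qnorm(stats::ppoints(n))
  list(correlation = stats::cor(s, q), sample = s, theoretical = q)
}

#' Pearson correlation controlled for covariates
#'
#' Classic partial correlation by residualization: both `x` and `y` are
#' regressed (with intercept) on the covariates by least squares, and the
#' Pearson correlation of the residuals is tested on
#' `df = n - 2 - #covariates` degrees of freedom. With no covariates this is
#' the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data.frame or matrix of numeric covariates.
#' @return List with `r`, `p_value`, `df`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  ncov <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    Z <- cbind(1, as.matrix(covariates))
    ncov <- ncol(Z) - 1L
    if (n <= ncov + 2L) stop("need n > #covariates + 2")
    qz <- qr(Z)
    if (qz$rank < ncol(Z))
      warning("collinear covariates; projection uses the column space only")
    x <- qr.resid(qz, x)
    y <- qr.resid(qz, y)
  }
  r <- stats::cor(x, y)
  df <- n - 2L - ncov
  tval <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tval), df)
  list(r = r, p_value = p, df = df)
}

#' Cross-correlation table between behavioral and classical measures
#'
#' Builds the full table of covariate-controlled Pearson correlations
#' between the KDT behavioral variables (rows) and the classical
#' decision-making measures (columns), with significance markers at the
#' 0.05 and 0.01 levels. No multiple-comparison correction is applied.
#'
#' @param cohort Data.frame holding all named columns.
#' @param kdt_vars Row variable names (default [kdt_variables()]).
#' @param classical_vars Column variable names.
#' @param covariates Optional character vector of covariate column names.
#' @param alpha Significance level for the single-star marker (default
#'   0.05; the double-star marker uses `alpha / 5`).
#' @return Object of class `correlation_table`: list of matrices `r`, `p`,
#'   `marker` (`""`, `"*"`, `"**"`).
#' @export
correlation_table <- function(cohort, kdt_vars = kdt_variables(),
                              classical_vars, covariates = NULL,
                              alpha = 0.05) {
  need <- c(kdt_vars, classical_vars, covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cov_df <- if (is.null(covariates)) NULL else cohort[covariates]
  r <- p <- matrix(NA_real_, length(kdt_vars), length(classical_vars),
                   dimnames = list(kdt_vars, classical_vars))
  for (i in kdt_vars) for (j in classical_vars) {
    res <- partial_pearson(cohort[[i]], cohort[[j]], cov_df)
    r[i, j] <- res$r; p[i, j] <- res$p_value
  }
  marker <- ifelse(p < alpha / 5, "**", ifelse(p < alpha, "*", ""))
  structure(list(r = r, p = p, marker = marker, alpha = alpha,
                 covariates = covariates),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  cat("Partial Pearson correlations",
      if (!is.null(x$covariates))
        paste0("(controlled for ", paste(x$covariates, collapse = ", "), ")"),
      "\n")
  out <- matrix(paste0(format(round(x$r, digits)), x$marker),
                nrow = nrow(x$r), dimnames = dimnames(x$r))
  print(out, quote = FALSE)
  cat("* p < ", x$alpha, "; ** p < ", x$alpha / 5, "\n", sep = "")
  invisible(x)
}

#' Write a correlation table as CSV
#'
#' @param x A `correlation_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_table <- function(x, path) {
  df <- data.frame(variable = rownames(x$r),
                   matrix(paste0(round(x$r, 3), x$marker), nrow = nrow(x$r)),
                   check.names = FALSE)
  names(df)[-1] <- colnames(x$r)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
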
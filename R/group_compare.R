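#' MANOVA / MANCOVA across behavioral clusters
#'
#' Multivariate comparison of a set of outcomes across groups, optionally
#' adjusted for covariates entered before the group factor (so the group
#' effect is tested on covariate-adjusted cross-product matrices). Reports
#' Pillai's trace with its standard F approximation, plus per-outcome
#' univariate F tests with partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`) and group means/SDs. With zero
#' covariates and one outcome the univariate branch is classical one-way
#' ANOVA.
#'
#' @param outcomes Data.frame or matrix of numeric outcomes (n x p).
#' @param group Group labels (coerced to factor; >= 2 groups, each with
#'   >= 2 members).
#' @param covariates Optional data.frame of numeric covariates.
#' @param alpha Significance level used by the post hoc letters (default
#'   0.05).
#' @return Object of class `group_comparison`: list with `multivariate`
#'   (Pillai's trace, approximate F, dfs, p), `univariate` (one row per
#'   outcome: F, dfs, p, eta2p), `means`, `sds`, `posthoc` (per-outcome
#'   result of [bonferroni_posthoc()]).
#' @export
mancova <- function(outcomes, group, covariates = NULL, alpha = 0.05) {
  Y <- as.matrix(outcomes)
  g <- factor(group)
  n <- nrow(Y)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(table(g) < 2L)) stop("every group needs >= 2 members")
  ncov <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n <= ncol(Y) + ncov + nlevels(g))
    stop("need n > #outcomes + #covariates + #groups")
  dat <- data.frame(..group = g)
  if (ncov > 0) dat <- cbind(dat, as.data.frame(covariates))
  rhs_cov <- if (ncov > 0)
    paste(setdiff(names(dat), "..group"), collapse = " + ") else "1"
  full <- stats::lm(stats::as.formula(paste("Y ~", rhs_cov, "+ ..group")),
                    data = dat)
  reduced <- stats::lm(stats::as.formula(paste("Y ~", rhs_cov)), data = dat)
  mv <- if (ncol(Y) == 1L) {
    # single outcome: the multivariate test reduces to the univariate F,
    # with Pillai's trace equal to SS_effect / (SS_effect + SS_error)
    a <- stats::anova(full)
    ss_g <- a["..group", "Sum Sq"]; ss_e <- a["Residuals", "Sum Sq"]
    list(pillai = ss_g / (ss_g + ss_e), F = a["..group", "F value"],
         df1 = a["..group", "Df"], df2 = a["Residuals", "Df"],
         p = a["..group", "Pr(>F)"])
  } else tryCatch({
    a <- stats::anova(full, reduced, test = "Pillai")
    list(pillai = a$Pillai[2], F = a$`approx F`[2],
         df1 = a$`num Df`[2], df2 = a$`den Df`[2],
         p = a$`Pr(>F)`[2])
  }, error = function(e) {
    warning("singular error matrix; Pillai computed with a pseudo-inverse")
    E <- crossprod(stats::resid(full))
    H <- crossprod(stats::resid(reduced)) - E
    V <- sum(diag(H %*% MASS::ginv(H + E)))
    list(pillai = V, F = NA_real_, df1 = NA_real_, df2 = NA_real_,
         p = NA_real_)
  })
  out_names <- colnames(Y)
  if (is.null(out_names)) out_names <- paste0("outcome", seq_len(ncol(Y)))
  uni <- do.call(rbind, lapply(seq_len(ncol(Y)), function(j) {
    fit <- stats::lm(stats::as.formula(paste("Y[, j] ~", rhs_cov,
                                             "+ ..group")), data = dat)
    a <- stats::anova(fit)
    ss_g <- a["..group", "Sum Sq"]; ss_e <- a["Residuals", "Sum Sq"]
    data.frame(outcome = out_names[j],
               F = a["..group", "F value"],
               df_between = a["..group", "Df"],
               df_within = a["Residuals", "Df"],
               p = a["..group", "Pr(>F)"],
               eta2p = ss_g / (ss_g + ss_e))
  }))
  means <- vapply(levels(g), function(l)
    colMeans(Y[g == l, , drop = FALSE]), numeric(ncol(Y)))
  sds <- vapply(levels(g), function(l)
    apply(Y[g == l, , drop = FALSE], 2, stats::sd), numeric(ncol(Y)))
  means <- matrix(means, ncol = nlevels(g),
                  dimnames = list(out_names, levels(g)))
  sds <- matrix(sds, ncol = nlevels(g),
                dimnames = list(out_names, levels(g)))
  posthoc <- lapply(stats::setNames(seq_len(ncol(Y)), out_names),
                    function(j) bonferroni_posthoc(Y[, j], g, alpha = alpha))
  structure(list(multivariate = mv, univariate = uni,
                 means = means, sds = sds, posthoc = posthoc,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  mv <- x$multivariate
  cat(sprintf("Pillai = %.4f, F(%s, %s) = %.3f, p = %.4g\n",
              mv$pillai, format(mv$df1), format(mv$df2), mv$F, mv$p))
  print(cbind(x$univariate,
              letters = vapply(x$posthoc, function(ph)
                paste(ph$letters, collapse = "/"), "")),
        row.names = FALSE)
  invisible(x)
}

#' Bonferroni pairwise post hoc comparisons with compact letter display
#'
#' All pairwise two-sample comparisons between groups (pooled-variance t
#' test; Welch fallback with a warning when a group has a single member),
#' with raw p-values multiplied by the number of pairs and capped at 1.
#' Letters are assigned greedily from the lowest-mean group upward so that
#' groups sharing a letter do not differ at `alpha`.
#'
#' @param outcome Numeric vector.
#' @param group Group labels.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `p_adjusted` (symmetric matrix), `letters` (named by
#'   group level), and `n_pairs`.
#' @export
bonferroni_posthoc <- function(outcome, group, alpha = 0.05) {
  g <- factor(group)
  lv <- levels(g)
  if (length(lv) < 2L) stop("need >= 2 groups")
  m <- choose(length(lv), 2)
  padj <- matrix(NA_real_, length(lv), length(lv),
                 dimnames = list(lv, lv))
  diag(padj) <- 1
  for (i in seq_along(lv)) for (j in seq_len(i - 1L)) {
    xi <- outcome[g == lv[i]]; xj <- outcome[g == lv[j]]
    if (length(xi) < 2L || length(xj) < 2L) {
      warning("group of size 1; Welch comparison undefined, p set to 1")
      p <- 1
    } else if (stats::sd(xi) == 0 && stats::sd(xj) == 0) {
      p <- if (mean(xi) == mean(xj)) 1 else 0
    } else {
      p <- stats::t.test(xi, xj, var.equal = TRUE)$p.value
    }
    padj[i, j] <- padj[j, i] <- min(1, p * m)
  }
  ord <- order(vapply(lv, function(l) mean(outcome[g == l]), 0))
  groups <- list()  # each element: indices (into lv) sharing a letter
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (all(padj[i, groups[[k]]] >= alpha)) {
        groups[[k]] <- c(groups[[k]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  lets <- stats::setNames(rep("", length(lv)), lv)
  for (k in seq_along(groups))
    for (i in groups[[k]])
      lets[i] <- paste0(lets[i], letters[k])
  list(p_adjusted = padj, letters = lets, n_pairs = m)
}

#' Write a group comparison as CSV (and optionally JSON)
#'
#' One row per outcome: per-group mean and SD, univariate F, dfs, p,
#' partial eta squared, and the post hoc letters.
#'
#' @param x A `group_comparison` from [mancova()].
#' @param path Output CSV path.
#' @param json_path Optional JSON path.
#' @return `path`, invisibly.
#' @export
write_group_comparison <- function(x, path, json_path = NULL) {
  lv <- colnames(x$means)
  df <- x$univariate
  for (l in lv) {
    df[[paste0("mean_", l)]] <- x$means[, l]
    df[[paste0("sd_", l)]] <- x$sds[, l]
    df[[paste0("letter_", l)]] <- vapply(x$posthoc, function(ph)
      ph$letters[[l]], "")
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(multivariate = x$multivariate,
                              univariate = df),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(path)
}
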
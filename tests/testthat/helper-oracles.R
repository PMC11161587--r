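# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use literal loops and textbook formulas, not the
# package's own code paths.

oracle_loglik <- function(dataset, rho, lambda, mu) {
  total <- 0
  for (i in seq_len(nrow(dataset))) {
    g <- dataset$gain[i]; l <- dataset$loss[i]; c <- dataset$choice[i]
    u <- 0.5 * g^rho + 0.5 * (-lambda * l^rho)
    eta <- mu * u
    # numerically stable branches of log(1/(1+exp(-eta))) and its mirror
    lp_accept <- if (eta >= 0) -log1p(exp(-eta)) else eta - log1p(exp(eta))
    lp_reject <- if (eta >= 0) -eta - log1p(exp(-eta)) else -log1p(exp(eta))
    total <- total + if (c == 1) lp_accept else lp_reject
  }
  total
}

# greedy Ward: at each step merge the pair whose union minimizes the
# increase in total within-cluster sum of squares
oracle_ward <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  sse <- function(rows) {
    cx <- x[rows, , drop = FALSE]
    sum(sweep(cx, 2, colMeans(cx))^2)
  }
  merges <- list(); heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_len(a - 1)) {
      d <- sse(c(clusters[[a]], clusters[[b]])) -
        sse(clusters[[a]]) - sse(clusters[[b]])
      if (is.null(best) || d < best$d) best <- list(a = a, b = b, d = d)
    }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best$a]], clusters[[best$b]]))
    heights <- c(heights, best$d)
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  list(members = merges, heights = heights)
}

# members of each merged cluster from an hclust merge matrix
hclust_members <- function(merge) {
  out <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    mem <- integer(0)
    for (j in merge[k, ]) {
      mem <- c(mem, if (j < 0) -j else out[[j]])
    }
    out[[k]] <- sort(mem)
  }
  out
}

oracle_anova <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ss_b <- 0; ss_w <- 0
  for (l in levels(g)) {
    yl <- y[g == l]
    ss_b <- ss_b + length(yl) * (mean(yl) - grand)^2
    ss_w <- ss_w + sum((yl - mean(yl))^2)
  }
  df_b <- nlevels(g) - 1
  df_w <- length(y) - nlevels(g)
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(F = f, p = 1 - pf(f, df_b, df_w),
       eta2p = ss_b / (ss_b + ss_w), df_b = df_b, df_w = df_w)
}

# partial correlation via explicit normal equations
oracle_partial_r <- function(x, y, Z) {
  Z <- cbind(1, as.matrix(Z))
  bx <- solve(t(Z) %*% Z, t(Z) %*% x)
  by <- solve(t(Z) %*% Z, t(Z) %*% y)
  rx <- x - Z %*% bx
  ry <- y - Z %*% by
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

oracle_split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    h <- length(ch) %/% 2
    halves <- c(halves, list(ch[1:h]), list(ch[(h + 1):(2 * h)]))
  }
  n <- length(halves[[1]])
  W <- mean(sapply(halves, var))
  B <- n * var(sapply(halves, mean))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# small synthetic cluster specs for fast pipeline-level tests
small_test_specs <- function(sizes = c(10, 7, 7)) {
  pub <- kdt_published_clusters()
  mapply(function(sp, n) {
    sp$size <- n
    sp
  }, pub, sizes, SIMPLIFY = FALSE)
}
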
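test_that("generative parameter draws respect bounds and moments", {
  means <- c(rho = 0.61, lambda = 1.87, mu = 0.68)
  sds <- c(rho = 0.018, lambda = 0.48, mu = 0.10)
  d <- draw_pt_params(2000, means, sds, seed = 91)
  expect_true(all(d$rho > 0 & d$rho <= 2))
  expect_true(all(d$lambda > 0 & d$lambda <= 5))
  expect_true(all(d$mu > 0 & d$mu <= 10))
  expect_lt(abs(mean(d$lambda) - 1.87), 4 * 0.48 / sqrt(2000) + 0.01)
  expect_identical(d, draw_pt_params(2000, means, sds, seed = 91))
})

test_that("maximum likelihood recovers rho and lambda from long datasets", {
  gm <- build_gamble_matrix()
  truth <- pt_params(0.8, 1.5, 1)
  big <- do.call(rbind, lapply(1:100, function(r)
    simulate_mgt_choices(truth, gm, seed = r)))
  fit <- fit_pt_mle(big, seed = 92)
  expect_lt(abs(fit$params[["rho"]] - 0.8), 0.1)
  expect_lt(abs(fit$params[["lambda"]] - 1.5), 0.1)
  # mu rides the rho-mu likelihood ridge; only its order of magnitude is
  # pinned down at this design size
  expect_gt(fit$params[["mu"]], 0.3)
  expect_lt(fit$params[["mu"]], 3)
  expect_false(fit$boundary)
  expect_identical(fit$params, fit_pt_mle(big, seed = 92)$params)
})

test_that("estimation error shrinks with trial count", {
  gm <- build_gamble_matrix()
  truth <- pt_params(0.8, 1.5, 1)
  err <- function(n_rep, seed_base) {
    d <- do.call(rbind, lapply(seq_len(n_rep), function(r)
      simulate_mgt_choices(truth, gm, seed = seed_base + r)))
    abs(fit_pt_mle(d, n_restarts = 0, seed = 1)$params[["lambda"]] - 1.5)
  }
  e64 <- vapply(1:12, function(i) err(1, 200 + i * 100), 0)
  e1600 <- vapply(1:12, function(i) err(25, 5000 + i * 100), 0)
  expect_lt(median(e1600), median(e64))
})

test_that("degenerate all-accept data hit the boundary with a flag", {
  gm <- build_gamble_matrix()
  d <- data.frame(gain = gm$gain, loss = gm$loss, choice = 1)
  fit <- fit_pt_mle(d, seed = 93)
  expect_true(fit$boundary)
  expect_error(fit_pt_mle(gm[0, ]), "empty")
})

test_that("split-chain Gelman-Rubin matches its defining formula", {
  expect_warning(r <- gelman_rubin(list(rep(2, 100), rep(2, 100))),
                 "zero-variance")
  expect_equal(unname(r), 1)
  set.seed(94)
  iid <- lapply(1:3, function(i) rnorm(10000))
  expect_true(all(abs(gelman_rubin(iid) - 1) < 0.01))
  far <- list(rnorm(500, 0), rnorm(500, 10))
  expect_gt(gelman_rubin(far), 1.1)
  expect_equal(unname(gelman_rubin(far)), oracle_split_rhat(far),
               tolerance = 1e-12)
  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")
  expect_error(gelman_rubin(list(rnorm(5), rnorm(5))), "too short")
})

test_that("hierarchical fit returns a coherent, reproducible summary", {
  gm <- build_gamble_matrix()
  truth <- draw_pt_params(8, c(rho = 0.61, lambda = 1.87, mu = 0.68),
                          c(rho = 0.018, lambda = 0.48, mu = 0.10),
                          seed = 95)
  ch <- do.call(rbind, lapply(1:8, function(i)
    cbind(subject = i,
          simulate_mgt_choices(pt_params(truth$rho[i], truth$lambda[i],
                                         truth$mu[i]), gm, seed = 95 + i))))
  fit <- fit_pt_hierarchical(ch, chains = 2, n_samples = 150,
                             burn_in = 150, seed = 96)
  expect_s3_class(fit, "pt_hba")
  expect_equal(nrow(fit$subject_summary), 8)
  expect_equal(fit$group_summary$parameter, c("rho", "lambda", "mu"))
  expect_true(all(fit$subject_summary$rho_mean > 0 &
                    fit$subject_summary$rho_mean <= 2))
  expect_true(all(is.finite(fit$rhat)))
  fit2 <- fit_pt_hierarchical(ch, chains = 2, n_samples = 150,
                              burn_in = 150, seed = 96)
  expect_identical(fit$draws, fit2$draws)
  expect_error(fit_pt_hierarchical(ch[ch$subject == 1, ]), "2 subjects")
  expect_error(fit_pt_hierarchical(ch, chains = 1), "2 chains")
})

test_that("partial pooling shrinks subject estimates toward the group", {
  gm <- build_gamble_matrix()
  set.seed(97)
  shared <- pt_params(0.7, 1.8, 0.8)
  ch <- do.call(rbind, lapply(1:10, function(i)
    cbind(subject = i, simulate_mgt_choices(shared, gm, seed = 300 + i))))
  fit <- fit_pt_hierarchical(ch, chains = 2, n_samples = 200,
                             burn_in = 300, seed = 98)
  mles <- vapply(1:10, function(i)
    fit_pt_mle(ch[ch$subject == i, ], n_restarts = 0,
               seed = i)$params[["lambda"]], 0)
  post <- fit$subject_summary$lambda_mean
  center <- mean(post)
  shrunk <- abs(post - center) <= abs(mles - center) + 1e-9
  expect_gte(mean(shrunk), 0.9)
})
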
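test_that("profile generation respects sizes, schema and truncation", {
  co <- generate_profiles(kdt_published_clusters(), seed = 61)
  expect_equal(nrow(co), 81)
  expect_equal(as.vector(table(co$true_cluster)[c(
    "risk_avoidant", "useless_risk", "useful_risk")]), c(39, 21, 21))
  expect_true(all(kdt_variables() %in% names(co)))
  counts <- as.matrix(co[kdt_variables()])
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_false(anyNA(co))
})

test_that("zero-SD specs degenerate to the rounded means", {
  sp <- kdt_published_clusters()$useful_risk
  sp$sds[] <- 0
  sp$pt_means <- NULL
  sp$classical_means <- NULL
  co <- generate_profiles(list(sp), seed = 1)
  for (v in kdt_variables()) {
    expect_true(all(co[[v]] == max(round(sp$means[[v]]), 0)))
  }
})

test_that("sample moments converge to the generative moments", {
  sp <- kdt_published_clusters()$useful_risk
  sp$size <- 10000
  co <- generate_profiles(list(sp), seed = 62)
  # rounding to integers biases the mean by < 0.5/sqrt(12n); 4 SE dominates
  expect_lt(abs(mean(co$total_gains) - 162.9), 4 * 9.46 / sqrt(10000) + 0.01)
  expect_lt(abs(sd(co$total_gains) - 9.46), 0.5)
  # at the published size the mean sits within 3 standard errors
  co21 <- generate_profiles(kdt_published_clusters(), seed = 63)
  g3 <- co21$total_gains[co21$true_cluster == "useful_risk"]
  expect_lt(abs(mean(g3) - 162.9), 3 * 9.46 / sqrt(21))
})

test_that("cohort generation is seed-deterministic", {
  a <- generate_profiles(kdt_published_clusters(), seed = 64)
  b <- generate_profiles(kdt_published_clusters(), seed = 64)
  expect_identical(a, b)
  c2 <- generate_profiles(kdt_published_clusters(), seed = 65)
  expect_false(identical(a, c2))
})

test_that("invalid cluster specs are rejected", {
  sp <- kdt_published_clusters()$useful_risk
  bad <- sp
  bad$sds[1] <- -1
  expect_error(do.call(cluster_spec, bad[c("label", "size", "means",
                                           "sds")]), "non-negative")
  expect_error(cluster_spec("x", 3, sp$means[-1], sp$sds[-1]),
               "18 KDT variables")
  expect_error(generate_profiles(list(), seed = 1), "non-empty")
})

test_that("simulated gamble choices track the model probabilities", {
  gm <- build_gamble_matrix()
  # flat rule accepts half the gambles in the long run
  d <- simulate_mgt_choices(pt_params(1, 1, 0),
                            gm[rep(1:64, 100), ], seed = 66)
  expect_lt(abs(mean(d$choice) - 0.5), 3 * 0.5 / sqrt(6400))
  # extreme loss aversion refuses essentially everything
  d2 <- simulate_mgt_choices(pt_params(0.61, 5, 10),
                             gm[rep(1:64, 20), ], seed = 67)
  expect_lt(mean(d2$choice), 0.01)
  # per-gamble calibration against binomial 99% bounds at 10,000 draws
  p <- pt_params(0.7, 1.8, 0.8)
  one <- gm[29, , drop = FALSE]
  prob <- accept_probability(one, p)
  d3 <- simulate_mgt_choices(p, one[rep(1, 10000), ], seed = 68)
  expect_lt(abs(mean(d3$choice) - prob),
            qnorm(0.995) * sqrt(prob * (1 - prob) / 10000))
  # determinism
  expect_identical(simulate_mgt_choices(p, gm, seed = 69),
                   simulate_mgt_choices(p, gm, seed = 69))
})

test_that("IGT agent follows the delta-rule / softmax contract", {
  ses <- simulate_igt_choices(n_trials = 100, seed = 71)
  expect_equal(nrow(ses), 100)
  expect_true(all(ses$deck %in% c("A", "B", "C", "D")))
  # greedy agent locks onto a strictly dominant deck after learning
  sched <- igt_default_schedule()
  sched$loss_prob <- c(1, 1, 0, 1)
  sched$gain <- c(10, 10, 100, 10)
  greedy <- simulate_igt_choices(list(learning_rate = 0.5, exploration = 0),
                                 sched, n_trials = 60, seed = 72)
  expect_true(all(greedy$deck[21:60] == "C"))
  # zero learning keeps choice probabilities flat across trials
  noisy <- simulate_igt_choices(list(learning_rate = 0, exploration = 50),
                                n_trials = 2000, seed = 73)
  first <- table(factor(noisy$deck[1:1000], c("A", "B", "C", "D")))
  second <- table(factor(noisy$deck[1001:2000], c("A", "B", "C", "D")))
  expect_gt(suppressWarnings(chisq.test(rbind(first, second))$p.value),
            0.01)
  expect_error(simulate_igt_choices(schedule = igt_default_schedule()[1:3, ]),
               "4 decks")
})

test_that("questionnaire totals stay within the legal ranges", {
  co <- generate_profiles(small_test_specs(), seed = 74)
  for (rep in 1:5) {
    q <- simulate_questionnaires(co, seed = rep)
    expect_true(all(q$useq_total >= 6 & q$useq_total <= 30))
    expect_true(all(q$stimulating_risk >= 4 & q$stimulating_risk <= 20))
    expect_true(all(q$instrumental_risk >= 3 & q$instrumental_risk <= 15))
  }
  shifted <- simulate_questionnaires(co, seed = 1,
                                     cluster_shift = c(risk_avoidant = -3,
                                                       useless_risk = 3,
                                                       useful_risk = 0))
  expect_gt(mean(shifted$stimulating_risk[shifted$true_cluster ==
                                            "useless_risk"]),
            mean(shifted$stimulating_risk[shifted$true_cluster ==
                                            "risk_avoidant"]))
})

test_that("cohort CSV round-trips with its JSON sidecar", {
  co <- generate_profiles(small_test_specs(), seed = 75)
  path <- file.path(tempdir(), "cohort_test.csv")
  write_cohort(co, path, config = list(seed = 75))
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(co))
  expect_true(all(kdt_variables() %in% names(back)))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 75)
  unlink(c(path, paste0(path, ".json")))
})
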
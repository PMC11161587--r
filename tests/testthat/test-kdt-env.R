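test_that("environment construction respects configuration and seeds", {
  env <- build_environment(seed = 81)
  ev <- env$events
  expect_equal(nrow(ev), env$config$n_events)
  coins <- ev[ev$kind == "coin", ]
  expect_true(all(coins$value >= 10 & coins$value <= 1000))
  expect_true(all(ev$win_prob >= 0 & ev$win_prob <= 1))
  # safe-zone risk boxes use the four graded win probabilities
  safe_rb <- ev[ev$kind == "risk_box" & ev$zone == "safe", ]
  expect_true(all(safe_rb$win_prob %in% c(0.2, 0.4, 0.6, 0.8)))
  # dangerous-zone boxes are preconfigured to lose on expectation
  dang <- ev[ev$kind %in% c("risk_box", "ambiguous_box") &
               ev$zone == "dangerous", ]
  expect_true(all(dang$win_prob * dang$value -
                    (1 - dang$win_prob) * dang$loss < 0))
  expect_identical(build_environment(seed = 81)$events, ev)
  all_safe <- build_environment(kdt_env_config(
    zone_mix = c(safe = 1, dangerous = 0)), seed = 82)
  expect_true(all(all_safe$events$zone == "safe"))
  expect_error(kdt_env_config(zone_mix = c(safe = 0.7, dangerous = 0.7)),
               "sum to 1")
})

test_that("bank deposits retain exactly half of carried money", {
  cfg <- kdt_env_config(n_events = 1, token_freq = c(
    coin = 0, mixed_coin = 0, ambiguous_box = 0, risk_box = 0, bank = 1,
    watch = 0, shield = 0, danger = 0, vending = 0))
  env <- build_environment(cfg, seed = 83)
  pol <- agent_policy(default_approach = 1, deposit = 1,
                      zone_learning_rate = 0)
  ep <- run_episode(pol, env, step_budget = 1, seed = 1,
                    initial_money = 100)
  expect_equal(ep$banked, 50)
  expect_equal(ep$commissions, 50)
  expect_equal(ep$bank_deposits, 1)
  expect_equal(ep$final_money, 50)
})

test_that("a permanently active shield blocks both losses and gains", {
  env <- build_environment(seed = 84)
  pol <- agent_policy(default_approach = 1, accept_risk = 1,
                      accept_ambiguous = 1)
  ep <- run_episode(pol, env, step_budget = 400, seed = 2,
                    initial_shield_steps = 10000)
  expect_equal(ep$total_losses, 0)
  expect_equal(ep$coins_collected, 0)
  expect_equal(ep$total_gains, 0)
})

test_that("the money ledger balances exactly", {
  env <- build_environment(seed = 85)
  set.seed(86)
  for (rep in 1:10) {
    pol <- agent_policy(default_approach = runif(1),
                        accept_risk = runif(1),
                        accept_ambiguous = runif(1),
                        deposit = runif(1), purchase = runif(1))
    ep <- run_episode(pol, env, step_budget = 500, seed = 100 + rep)
    expect_equal(ep$gains - ep$losses - ep$purchases - ep$commissions,
                 ep$banked + ep$carried, tolerance = 1e-9)
    expect_equal(ep$final_money, ep$banked + ep$carried)
    counts <- unlist(ep[kdt_variables()])
    expect_true(all(counts >= 0))
    expect_lte(ep$risk_boxes_accepted, ep$risk_boxes_touched)
    expect_lte(ep$ambiguous_boxes_accepted, ep$ambiguous_boxes_touched)
    expect_lte(ep$mixed_coins_wins + ep$mixed_coins_losses,
               ep$mixed_coins_collected)
  }
})

test_that("cautious agents lose less; zone learners earn more", {
  env <- build_environment(seed = 87)
  cautious <- agent_policy(default_approach = 0.2, accept_risk = 0.1,
                           accept_ambiguous = 0.1, zone_learning_rate = 0)
  reckless <- agent_policy(default_approach = 1, accept_risk = 0.95,
                           accept_ambiguous = 0.95, zone_learning_rate = 0)
  learner <- agent_policy(default_approach = 0.8, accept_risk = 0.7,
                          accept_ambiguous = 0.7, zone_learning_rate = 0.6)
  blind <- agent_policy(default_approach = 0.8, accept_risk = 0.7,
                        accept_ambiguous = 0.7, zone_learning_rate = 0)
  stats <- vapply(1:200, function(i) {
    c(run_episode(cautious, env, 300, seed = i)$total_losses,
      run_episode(reckless, env, 300, seed = i)$total_losses,
      run_episode(learner, env, 300, seed = 1000 + i)$final_money,
      run_episode(blind, env, 300, seed = 1000 + i)$final_money)
  }, numeric(4))
  expect_lt(mean(stats[1, ]), mean(stats[2, ]))
  expect_gt(mean(stats[3, ]), mean(stats[4, ]))
})

test_that("episodes aggregate into the canonical cohort schema", {
  env <- build_environment(seed = 88)
  pol <- agent_policy()
  eps <- lapply(1:11, function(i) run_episode(pol, env, 150, seed = i))
  tab <- aggregate_outcomes(eps)
  expect_equal(nrow(tab), 11)
  expect_true(all(kdt_variables() %in% names(tab)))
  # same schema as the parametric generator
  co <- generate_profiles(small_test_specs(), seed = 1)
  expect_true(all(kdt_variables() %in% names(co)))
  expect_equal(intersect(kdt_variables(), names(tab)),
               intersect(kdt_variables(), names(co)))
  expect_error(aggregate_outcomes(list()), "non-empty")
  # a token kind that never occurs yields an all-zero column
  cfg <- kdt_env_config(token_freq = c(coin = 1, mixed_coin = 0,
                                       ambiguous_box = 0, risk_box = 0,
                                       bank = 0, watch = 0, shield = 0,
                                       danger = 0, vending = 0))
  ep <- run_episode(pol, build_environment(cfg, seed = 89), 100, seed = 1)
  expect_equal(ep$risk_boxes_touched, 0)
  expect_equal(ep$bank_entrances, 0)
})
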
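#' Default configuration of the abstract KDT environment
#'
#' The simulator is a token-level abstraction of the game: time is
#' discretized into steps (one event per step), the session becomes a step
#' budget, and the 10-second shield becomes a step window. Zones alternate
#' in segments; in dangerous zones boxes are preconfigured to lose and
#' dangers outweigh gains, while safe-zone boxes have positive expectation.
#' Quantities the game does not publish (token frequencies, payoff
#' magnitudes) are configurable defaults.
#'
#' @param n_events Length of the token sequence (default 1000).
#' @param step_budget Steps available per episode (default 600).
#' @param zone_mix Named probabilities `safe`/`dangerous`, must sum to 1.
#' @param segment_len Events per zone segment (default 20).
#' @param token_freq Named sampling probabilities per token kind.
#' @param coin_range Coin value range (default c(10, 1000)).
#' @param shield_steps Shield duration in steps (default 5).
#' @param watch_steps Step bonus per watch (default 20).
#' @param prices Vending prices, named `watch`/`shield`.
#' @return A config list.
#' @export
kdt_env_config <- function(n_events = 1000L, step_budget = 600L,
                           zone_mix = c(safe = 0.6, dangerous = 0.4),
                           segment_len = 20L,
                           token_freq = c(coin = 0.33, mixed_coin = 0.12,
                                          ambiguous_box = 0.10,
                                          risk_box = 0.08, bank = 0.05,
                                          watch = 0.04, shield = 0.05,
                                          danger = 0.13, vending = 0.10),
                           coin_range = c(10, 1000),
                           shield_steps = 5L, watch_steps = 20L,
                           prices = c(watch = 150, shield = 100)) {
  if (abs(sum(zone_mix) - 1) > 1e-8) stop("zone_mix must sum to 1")
  if (abs(sum(token_freq) - 1) > 1e-8) stop("token_freq must sum to 1")
  list(n_events = n_events, step_budget = step_budget, zone_mix = zone_mix,
       segment_len = segment_len, token_freq = token_freq,
       coin_range = coin_range, shield_steps = shield_steps,
       watch_steps = watch_steps, prices = prices)
}

#' Build a token-event sequence for the abstract environment
#'
#' Samples zones in segments and one token event per step. Payoff fields by
#' kind and zone: coins are worth `runif(coin_range)` and are guarded (a
#' guard hit costs money with the stated probability, heavily in dangerous
#' zones); risk boxes carry explicit win probabilities from
#' {0.2, 0.4, 0.6, 0.8} in safe zones but are preconfigured to lose in
#' dangerous ones; ambiguous boxes are positive-expectation in safe zones
#' and negative in dangerous ones; dangers cost more in dangerous zones.
#'
#' @param config A [kdt_env_config()] list.
#' @param seed Integer seed.
#' @return Object of class `kdt_env`: list with `events` (data.frame:
#'   `kind`, `zone`, `value`, `loss`, `win_prob`, `guard_prob`,
#'   `guard_loss`) and `config`.
#' @export
build_environment <- function(config = kdt_env_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_events
  n_seg <- ceiling(n / config$segment_len)
  seg_zone <- sample(names(config$zone_mix), n_seg, replace = TRUE,
                     prob = config$zone_mix)
  zone <- rep(seg_zone, each = config$segment_len)[seq_len(n)]
  kind <- sample(names(config$token_freq), n, replace = TRUE,
                 prob = config$token_freq)
  value <- loss <- win_prob <- guard_prob <- guard_loss <- numeric(n)
  dangerous <- zone == "dangerous"
  ci <- kind == "coin"
  value[ci] <- stats::runif(sum(ci), config$coin_range[1],
                            config$coin_range[2])
  guard_prob[ci] <- ifelse(dangerous[ci], 0.7, 0.1)
  guard_loss[ci] <- ifelse(dangerous[ci],
                           stats::runif(sum(ci), 400, 1200),
                           stats::runif(sum(ci), 10, 50))
  mi <- kind == "mixed_coin"
  value[mi] <- stats::runif(sum(mi), 20, 200)
  loss[mi] <- value[mi]
  win_prob[mi] <- 0.5
  ai <- kind == "ambiguous_box"
  value[ai] <- stats::runif(sum(ai), 50, 300)
  win_prob[ai] <- ifelse(dangerous[ai], 0.10, 0.65)
  loss[ai] <- ifelse(dangerous[ai], stats::runif(sum(ai), 150, 500),
                     stats::runif(sum(ai), 20, 150))
  ri <- kind == "risk_box"
  value[ri] <- stats::runif(sum(ri), 100, 400)
  win_prob[ri] <- ifelse(dangerous[ri], 0.2,
                         sample(c(0.2, 0.4, 0.6, 0.8), sum(ri),
                                replace = TRUE))
  loss[ri] <- ifelse(dangerous[ri], stats::runif(sum(ri), 200, 600),
                     stats::runif(sum(ri), 20, 120))
  di <- kind == "danger"
  loss[di] <- ifelse(dangerous[di], stats::runif(sum(di), 100, 400),
                     stats::runif(sum(di), 10, 50))
  structure(list(events = data.frame(kind = kind, zone = zone, value = value,
                                     loss = loss, win_prob = win_prob,
                                     guard_prob = guard_prob,
                                     guard_loss = guard_loss),
                 config = config),
            class = "kdt_env")
}

#' Parametric agent policy for the abstract environment
#'
#' @param approach Named engagement propensities in [0, 1] per token kind
#'   (missing kinds default to `default_approach`).
#' @param default_approach Fallback approach propensity (default 0.7).
#' @param accept_risk,accept_ambiguous Box-opening propensities in [0, 1].
#' @param zone_learning_rate Delta-rule learning rate in [0, 1] for the
#'   running value of each zone; 0 = zone-blind.
#' @param deposit Probability of depositing when at a bank.
#' @param purchase Probability of buying at a vending machine (given funds).
#' @param shield_activation Probability of activating a held shield when a
#'   danger is encountered.
#' @return Object of class `agent_policy`.
#' @export
agent_policy <- function(approach = c(), default_approach = 0.7,
                         accept_risk = 0.5, accept_ambiguous = 0.5,
                         zone_learning_rate = 0.2, deposit = 0.3,
                         purchase = 0.3, shield_activation = 0.5) {
  kinds <- c("coin", "mixed_coin", "ambiguous_box", "risk_box", "bank",
             "watch", "shield", "danger", "vending")
  ap <- stats::setNames(rep(default_approach, length(kinds)), kinds)
  ap[names(approach)] <- approach
  vals <- c(ap, accept_risk, accept_ambiguous, zone_learning_rate, deposit,
            purchase, shield_activation)
  if (any(vals < 0 | vals > 1)) stop("all propensities must be in [0, 1]")
  structure(list(approach = ap, accept_risk = accept_risk,
                 accept_ambiguous = accept_ambiguous,
                 zone_learning_rate = zone_learning_rate,
                 deposit = deposit, purchase = purchase,
                 shield_activation = shield_activation),
            class = "agent_policy")
}

#' Run one agent episode through the environment
#'
#' The agent traverses the event sequence one step at a time until the step
#' budget (extendable by watches) or the sequence is exhausted. Engagement
#' with an event is gated by a learned zone value (delta rule on scaled
#' monetary outcomes; the gate is `plogis(Q_zone)`, 0.5 for a zone-blind
#' agent). Bank deposits retain exactly 50% of the carried money (the other
#' 50% is the commission). An active shield blocks both losses and gains for
#' its step window. All 18 behavioral variables are tallied, and the exact
#' money ledger `gains - losses - purchases - commissions = banked + carried`
#' holds by construction.
#'
#' @param policy An [agent_policy()].
#' @param env A [build_environment()] result.
#' @param step_budget Steps available (default from the env config).
#' @param seed Integer seed.
#' @param initial_money Starting carried money (default 0).
#' @param initial_shield_steps Shield steps active at episode start
#'   (default 0; set >= budget to keep a shield up the whole episode).
#' @return List (`episode_result`): the 18 KDT variables, plus
#'   `final_money`, `banked`, `carried`, `gains`, `losses`, `purchases`,
#'   `commissions`, `steps_used`.
#' @export
run_episode <- function(policy, env, step_budget = env$config$step_budget,
                        seed = 1L, initial_money = 0,
                        initial_shield_steps = 0L) {
  if (step_budget < 1L) stop("step_budget must be >= 1")
  ev <- env$events   # force the env argument before seeding: a lazily
  cfg <- env$config  # built environment would otherwise reset the RNG
  force(policy)
  set.seed(seed)
  v <- stats::setNames(numeric(length(kdt_variables())), kdt_variables())
  gains <- losses <- purchases <- commissions <- banked <- 0
  carried <- initial_money
  shield_active <- initial_shield_steps
  shields_held <- 0
  Q <- c(safe = 0, dangerous = 0)
  budget <- step_budget
  steps <- 0L
  i <- 0L
  gain <- function(a) { gains <<- gains + a; carried <<- carried + a }
  lose <- function(a) { losses <<- losses + a; carried <<- carried - a }
  learn <- function(z, outcome) {
    Q[z] <<- Q[z] + policy$zone_learning_rate * (outcome / 200 - Q[z])
  }
  while (steps < budget && i < nrow(ev)) {
    i <- i + 1L
    steps <- steps + 1L
    blocked <- shield_active > 0
    if (shield_active > 0) shield_active <- shield_active - 1L
    e <- ev[i, ]
    if (stats::runif(1) >= stats::plogis(Q[[e$zone]])) next  # zone gate
    if (stats::runif(1) >= policy$approach[[e$kind]] &&
        e$kind != "danger") next
    switch(e$kind,
      coin = {
        if (!blocked) {
          v["coins_collected"] <- v["coins_collected"] + 1
          v["total_gains"] <- v["total_gains"] + 1
          gain(e$value)
          net <- e$value
          if (stats::runif(1) < e$guard_prob) {
            v["dangers_suffered"] <- v["dangers_suffered"] + 1
            v["total_losses"] <- v["total_losses"] + 1
            lose(e$guard_loss)
            net <- net - e$guard_loss
          }
          learn(e$zone, net)
        }
      },
      mixed_coin = {
        if (!blocked) {
          v["mixed_coins_collected"] <- v["mixed_coins_collected"] + 1
          if (stats::runif(1) < e$win_prob) {
            v["mixed_coins_wins"] <- v["mixed_coins_wins"] + 1
            v["total_gains"] <- v["total_gains"] + 1
            gain(e$value); learn(e$zone, e$value)
          } else {
            v["mixed_coins_losses"] <- v["mixed_coins_losses"] + 1
            v["total_losses"] <- v["total_losses"] + 1
            lose(e$loss); learn(e$zone, -e$loss)
          }
        }
      },
      ambiguous_box = ,
      risk_box = {
        if (!blocked) {
          risk <- e$kind == "risk_box"
          tv <- if (risk) "risk_boxes_touched" else "ambiguous_boxes_touched"
          av <- if (risk) "risk_boxes_accepted" else "ambiguous_boxes_accepted"
          acc <- if (risk) policy$accept_risk else policy$accept_ambiguous
          v[tv] <- v[tv] + 1
          if (stats::runif(1) < acc) {
            v[av] <- v[av] + 1
            if (stats::runif(1) < e$win_prob) {
              v["total_gains"] <- v["total_gains"] + 1
              gain(e$value); learn(e$zone, e$value)
            } else {
              v["total_losses"] <- v["total_losses"] + 1
              lose(e$loss); learn(e$zone, -e$loss)
            }
          }
        }
      },
      bank = {
        v["bank_entrances"] <- v["bank_entrances"] + 1
        if (carried > 0 && stats::runif(1) < policy$deposit) {
          v["bank_deposits"] <- v["bank_deposits"] + 1
          banked <- banked + carried / 2
          commissions <- commissions + carried / 2
          carried <- 0
        }
      },
      watch = {
        v["watches_collected"] <- v["watches_collected"] + 1
        budget <- budget + cfg$watch_steps
      },
      shield = {
        v["shields_collected"] <- v["shields_collected"] + 1
        shields_held <- shields_held + 1
      },
      vending = {
        if (stats::runif(1) < policy$purchase) {
          item <- sample(c("watch", "shield"), 1)
          price <- cfg$prices[[item]]
          if (carried >= price) {
            purchases <- purchases + price
            carried <- carried - price
            if (item == "watch") {
              v["watches_purchased"] <- v["watches_purchased"] + 1
              budget <- budget + cfg$watch_steps
            } else {
              v["shields_purchased"] <- v["shields_purchased"] + 1
              shields_held <- shields_held + 1
            }
          }
        }
      },
      danger = {
        if (!blocked) {
          if (shields_held > 0 &&
              stats::runif(1) < policy$shield_activation) {
            shields_held <- shields_held - 1
            v["shields_activated"] <- v["shields_activated"] + 1
            shield_active <- cfg$shield_steps
          } else {
            v["dangers_suffered"] <- v["dangers_suffered"] + 1
            v["total_losses"] <- v["total_losses"] + 1
            lose(e$loss); learn(e$zone, -e$loss)
          }
        }
      })
  }
  c(as.list(v),
    list(final_money = banked + carried, banked = banked, carried = carried,
         gains = gains, losses = losses, purchases = purchases,
         commissions = commissions, steps_used = steps))
}

#' Aggregate episode results into a cohort table
#'
#' @param episodes Non-empty list of [run_episode()] results.
#' @return Data.frame with `participant`, the 18 KDT variables (same schema
#'   as [generate_profiles()]), and `final_money`.
#' @export
aggregate_outcomes <- function(episodes) {
  if (length(episodes) == 0L) stop("episodes must be non-empty")
  rows <- lapply(episodes, function(ep)
    as.data.frame(ep[c(kdt_variables(), "final_money")]))
  out <- do.call(rbind, rows)
  data.frame(participant = seq_len(nrow(out)), out)
}
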
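#' Generative specification of a behavioral cluster
#'
#' @param label Cluster name.
#' @param size Number of participants to generate.
#' @param means,sds Named numeric vectors over exactly the 18 variables of
#'   [kdt_variables()]; `sds` must be non-negative.
#' @param pt_means,pt_sds Optional generative means/SDs for the
#'   prospect-theory parameters (`rho`, `lambda`, `mu`).
#' @param classical_means,classical_sds Optional generative moments for
#'   classical measures (IG index, questionnaire subscales).
#' @return Object of class `cluster_spec`.
#' @export
cluster_spec <- function(label, size, means, sds,
                         pt_means = NULL, pt_sds = NULL,
                         classical_means = NULL, classical_sds = NULL) {
  v <- kdt_variables()
  if (!setequal(names(means), v) || !setequal(names(sds), v))
    stop("means/sds must cover exactly the 18 KDT variables")
  if (any(!is.finite(sds[v])) || any(sds[v] < 0))
    stop("all SDs must be finite and non-negative")
  if (size < 1L) stop("size must be >= 1")
  structure(list(label = label, size = as.integer(size),
                 means = means[v], sds = sds[v],
                 pt_means = pt_means, pt_sds = pt_sds,
                 classical_means = classical_means,
                 classical_sds = classical_sds),
            class = "cluster_spec")
}

#' Generate a synthetic behavioral cohort from cluster specifications
#'
#' For each specification, draws `size` participants with each of the 18
#' behavioral variables sampled independently from a normal with the spec's
#' mean and SD, rounded half-to-even to integers and floored at 0 (all 18
#' variables are event counts). The generative cluster label is retained as
#' the column `true_cluster`. When the specs carry prospect-theory and
#' classical-measure moments, per-participant values are drawn the same way
#' (untruncated for the IG index, which may be negative; PT parameters
#' truncated to their bounds).
#'
#' @param specs List of [cluster_spec()] objects (non-empty).
#' @param seed Integer seed.
#' @return A data.frame (`CohortTable`): `participant`, `true_cluster`, the
#'   18 behavioral count variables, and any generative PT/classical columns.
#' @export
generate_profiles <- function(specs, seed = 1L) {
  if (length(specs) == 0L) stop("specs must be non-empty")
  if (inherits(specs, "cluster_spec")) specs <- list(specs)
  lapply(specs, force)   # force before seeding
  set.seed(seed)
  v <- kdt_variables()
  rows <- lapply(specs, function(sp) {
    x <- vapply(v, function(nm)
      pmax(round(stats::rnorm(sp$size, sp$means[[nm]], sp$sds[[nm]])), 0),
      numeric(sp$size))
    x <- matrix(x, nrow = sp$size, dimnames = list(NULL, v))
    out <- data.frame(true_cluster = rep(sp$label, sp$size), x,
                      check.names = FALSE)
    if (!is.null(sp$pt_means)) {
      b <- pt_bounds()
      for (p in c("rho", "lambda", "mu")) {
        y <- stats::rnorm(sp$size, sp$pt_means[[p]], sp$pt_sds[[p]])
        bad <- y <= 0 | y > b[[p]]
        while (any(bad)) {
          y[bad] <- stats::rnorm(sum(bad), sp$pt_means[[p]], sp$pt_sds[[p]])
          bad <- y <= 0 | y > b[[p]]
        }
        out[[paste0("true_", p)]] <- y
      }
    }
    if (!is.null(sp$classical_means)) {
      for (p in names(sp$classical_means))
        out[[p]] <- stats::rnorm(sp$size, sp$classical_means[[p]],
                                 sp$classical_sds[[p]])
    }
    out
  })
  out <- do.call(rbind, rows)
  data.frame(participant = seq_len(nrow(out)), out, check.names = FALSE)
}

#' Simulate mixed-gamble choices under the prospect-theory model
#'
#' One accept/reject draw per gamble with acceptance probability from
#' [accept_probability()]. Trial order is the row order of `gambles`.
#'
#' @param params A [pt_params()] object.
#' @param gambles Data.frame of gambles (columns `gain`, `loss`), e.g.
#'   [build_gamble_matrix()].
#' @param seed Integer seed.
#' @return Data.frame with columns `trial`, `gain`, `loss`, `choice`.
#' @export
simulate_mgt_choices <- function(params, gambles, seed = 1L) {
  if (nrow(gambles) == 0L) stop("gambles must be non-empty")
  p <- accept_probability(gambles, params)  # forces arguments pre-seeding
  set.seed(seed)
  data.frame(trial = seq_len(nrow(gambles)),
             gain = gambles$gain, loss = gambles$loss,
             choice = stats::rbinom(nrow(gambles), 1, p))
}

#' Classic four-deck payoff schedule for the Iowa Gambling Task
#'
#' Decks A and B pay large immediate gains (100 per card) but lose on net
#' (expected -250 per 10 cards): A loses 150-350 on half the cards, B loses
#' 1250 on one card in ten. Decks C and D pay small gains (50 per card) and
#' win on net (+250 per 10 cards): C loses 25-75 on half the cards, D loses
#' 250 on one card in ten.
#'
#' @return Data.frame with one row per deck: `deck`, `gain`, `loss_prob`,
#'   `loss_mean` (loss values are drawn uniformly from
#'   `loss_mean * c(0.6, 0.8, 1, 1.2, 1.4)` for the frequent-loss decks and
#'   are fixed for the rare-loss decks).
#' @export
igt_default_schedule <- function() {
  data.frame(deck = c("A", "B", "C", "D"),
             gain = c(100, 100, 50, 50),
             loss_prob = c(0.5, 0.1, 0.5, 0.1),
             loss_mean = c(250, 1250, 50, 250),
             spread = c(TRUE, FALSE, TRUE, FALSE))
}

#' Simulate an Iowa Gambling Task session with a delta-rule learner
#'
#' A stand-in generative agent (the task analytics only consume the choice
#' sequence): the agent keeps a running expectancy per deck, updated after
#' each outcome by `Q <- Q + learning_rate * (outcome - Q)`, and picks decks
#' through a softmax with temperature `exploration` (in outcome currency
#' units; 0 = greedy on expectancy with random tie-breaks, large = uniform
#' random).
#'
#' @param agent List with `learning_rate` in [0, 1] and `exploration` >= 0.
#' @param schedule Deck payoff schedule, see [igt_default_schedule()]
#'   (requires >= 4 decks).
#' @param n_trials Number of decisions (default 100).
#' @param seed Integer seed.
#' @return Data.frame with columns `trial`, `deck`, `outcome` (net currency
#'   for that pick).
#' @export
simulate_igt_choices <- function(agent = list(learning_rate = 0.1,
                                              exploration = 50),
                                 schedule = igt_default_schedule(),
                                 n_trials = 100L, seed = 1L) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (nrow(schedule) < 4L) stop("schedule must define 4 decks")
  force(agent)
  set.seed(seed)
  k <- nrow(schedule)
  Q <- rep(0, k)
  deck <- character(n_trials); outcome <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    w <- if (agent$exploration <= 0) {
      as.numeric(Q == max(Q))              # greedy, ties broken at random
    } else {
      exp((Q - max(Q)) / agent$exploration)
    }
    pick <- sample.int(k, 1, prob = w / sum(w))
    loss <- 0
    if (stats::runif(1) < schedule$loss_prob[pick]) {
      loss <- if (isTRUE(schedule$spread[pick]))
        schedule$loss_mean[pick] * sample(c(0.6, 0.8, 1, 1.2, 1.4), 1)
      else schedule$loss_mean[pick]
    }
    out <- schedule$gain[pick] - loss
    Q[pick] <- Q[pick] + agent$learning_rate * (out - Q[pick])
    deck[t] <- schedule$deck[pick]; outcome[t] <- out
  }
  data.frame(trial = seq_len(n_trials), deck = deck, outcome = outcome)
}

#' Add questionnaire totals to a cohort
#'
#' Draws USEQ (user satisfaction, 6-30), stimulating-risk (4-20) and
#' instrumental-risk (3-15) totals uniformly within their legal ranges, with
#' an optional per-cluster shift (`cluster_shift`, added to the
#' stimulating-risk draw mean before clamping) to induce association with
#' the generative cluster label.
#'
#' @param cohort A CohortTable (see [generate_profiles()]).
#' @param seed Integer seed.
#' @param cluster_shift Named numeric vector of shifts by cluster label
#'   (default `NULL`: totals independent of cluster).
#' @param fields Which totals to draw (default all three).
#' @return The cohort with columns `useq_total`, `stimulating_risk`,
#'   `instrumental_risk` added (existing columns of those names are
#'   overwritten).
#' @export
simulate_questionnaires <- function(cohort, seed = 1L, cluster_shift = NULL,
                                    fields = c("useq_total",
                                               "stimulating_risk",
                                               "instrumental_risk")) {
  if (nrow(cohort) == 0L) stop("cohort must be non-empty")
  n <- nrow(cohort)
  set.seed(seed)
  draw_total <- function(lo, hi, shift = 0) {
    mid <- (lo + hi) / 2 + shift
    pmin(pmax(round(stats::rnorm(n, mid, (hi - lo) / 6)), lo), hi)
  }
  shift <- rep(0, n)
  if (!is.null(cluster_shift) && "true_cluster" %in% names(cohort))
    shift <- unname(cluster_shift[as.character(cohort$true_cluster)])
  if ("useq_total" %in% fields) cohort$useq_total <- draw_total(6, 30)
  if ("stimulating_risk" %in% fields)
    cohort$stimulating_risk <- draw_total(4, 20, shift)
  if ("instrumental_risk" %in% fields)
    cohort$instrumental_risk <- draw_total(3, 15)
  cohort
}

#' Write a cohort table as CSV with a JSON configuration sidecar
#'
#' @param cohort Data.frame to write.
#' @param path Output CSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param config List recorded in the sidecar (should include the seed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = list()) {
  utils::write.csv(cohort, path, row.names = FALSE)
  jsonlite::write_json(config, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
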
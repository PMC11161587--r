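#' Canonical mixed-gamble matrix
#'
#' Builds the full crossing of the 8 x 8 gain/loss design used by the mixed
#' gamble task: gains 100 to 380 in steps of 40, losses 50 to 190 in steps
#' of 20, each pair exactly once, win probability fixed at 0.5. Losses are
#' stored as positive magnitudes.
#'
#' @return A data.frame with 64 rows and columns `gain`, `loss`, `p_win`.
#' @export
build_gamble_matrix <- function() {
  g <- expand.grid(gain = seq(100, 380, by = 40),
                   loss = seq(50, 190, by = 20))
  g$p_win <- 0.5
  g
}

#' Prospect-theory parameter set
#'
#' Bundles the three parameters of the prospect-theory choice model:
#' `rho` (risk attitude, the curvature of the utility function; 1 = risk
#' neutral, smaller = more risk averse), `lambda` (loss aversion; 1 = gains
#' and losses weighted equally), and `mu` (consistency, the softmax inverse
#' temperature; higher = more deterministic choices).
#'
#' @param rho Risk attitude, in (0, 2].
#' @param lambda Loss aversion, in (0, 5].
#' @param mu Consistency, in [0, 10]. `mu = 0` gives uniformly random choice
#'   and is allowed for degenerate checks.
#' @return An object of class `pt_params` (named numeric vector).
#' @export
pt_params <- function(rho, lambda, mu) {
  b <- pt_bounds()
  stopifnot(is.finite(rho), is.finite(lambda), is.finite(mu))
  if (rho <= 0 || rho > b["rho"]) stop("rho must be in (0, ", b["rho"], "]")
  if (lambda <= 0 || lambda > b["lambda"])
    stop("lambda must be in (0, ", b["lambda"], "]")
  if (mu < 0 || mu > b["mu"]) stop("mu must be in [0, ", b["mu"], "]")
  structure(c(rho = rho, lambda = lambda, mu = mu), class = "pt_params")
}

#' Default parameter bounds of the prospect-theory model
#'
#' Upper bounds of the open-below intervals used for validation and for the
#' logit-scaled sampling transforms: rho in (0, 2], lambda in (0, 5],
#' mu in (0, 10].
#'
#' @return Named numeric vector with elements `rho`, `lambda`, `mu`.
#' @export
pt_bounds <- function() c(rho = 2, lambda = 5, mu = 10)

#' Prospect-theory utility of a signed amount
#'
#' Power utility for gains, `u(x) = x^rho`; mirrored, loss-aversion-scaled
#' power utility for losses, `u(x) = -lambda * (-x)^rho`; `u(0) = 0`.
#'
#' @param amount Signed currency amount(s); negative values are losses.
#' @param params A [pt_params()] object (or named vector with `rho`,
#'   `lambda`).
#' @return Utility value(s), same length as `amount`.
#' @export
pt_utility <- function(amount, params) {
  rho <- params[["rho"]]; lambda <- params[["lambda"]]
  ifelse(amount >= 0, amount^rho, -lambda * (-amount)^rho)
}

#' Probability of accepting a mixed gamble
#'
#' Softmax (logistic) choice rule over the utility difference between
#' accepting and rejecting:
#' `P(accept) = 1 / (1 + exp(-mu * (U_accept - U_reject)))`, with
#' `U_accept = 0.5 * u(gain) + 0.5 * u(-loss)` and `U_reject = 0`
#' (the status quo; the task endowment is framing only).
#'
#' @param gamble A data.frame with columns `gain` and `loss` (loss as a
#'   positive magnitude), one row per gamble.
#' @param params A [pt_params()] object.
#' @return Acceptance probabilities in (0, 1), one per gamble row.
#' @export
accept_probability <- function(gamble, params) {
  du <- 0.5 * pt_utility(gamble$gain, params) +
    0.5 * pt_utility(-gamble$loss, params)
  stats::plogis(params[["mu"]] * du)
}

#' Log-likelihood of a mixed-gamble choice dataset
#'
#' Bernoulli log-likelihood of observed accept/reject choices under the
#' prospect-theory softmax model.
#'
#' @param dataset A data.frame with columns `gain`, `loss`, and `choice`
#'   (1 = accept, 0 = reject).
#' @param params A [pt_params()] object.
#' @return The summed log-probability of the observed choices.
#' @export
pt_log_likelihood <- function(dataset, params) {
  if (nrow(dataset) == 0L) stop("empty choice dataset")
  if (!all(dataset$choice %in% c(0, 1))) stop("choice must be 0/1")
  du <- 0.5 * pt_utility(dataset$gain, params) +
    0.5 * pt_utility(-dataset$loss, params)
  eta <- params[["mu"]] * du
  # log probabilities computed on the linear predictor to stay finite when
  # plogis saturates in double precision
  sum(dataset$choice * stats::plogis(eta, log.p = TRUE) +
        (1 - dataset$choice) * stats::plogis(-eta, log.p = TRUE))
}

# internal vectorized likelihood machinery shared by the fitters -----------

# natural-scale parameters from the unconstrained (probit) sampling scale;
# probit is the convention for this model family and keeps typical values
# of all three parameters in the bulk of a standard-normal group prior
pt_from_z <- function(z, bounds = pt_bounds()) {
  c(rho = bounds[["rho"]] * stats::pnorm(z[1]),
    lambda = bounds[["lambda"]] * stats::pnorm(z[2]),
    mu = bounds[["mu"]] * stats::pnorm(z[3]))
}

pt_to_z <- function(p, bounds = pt_bounds()) {
  c(stats::qnorm(p[["rho"]] / bounds[["rho"]]),
    stats::qnorm(p[["lambda"]] / bounds[["lambda"]]),
    stats::qnorm(p[["mu"]] / bounds[["mu"]]))
}

# log-likelihood for n subjects at once. G, L, C, W are n x T matrices of
# gains, loss magnitudes, choices and trial-validity weights; rho, lambda,
# mu are length-n vectors. Returns a length-n vector.
pt_ll_matrix <- function(rho, lambda, mu, G, L, C, W) {
  du <- 0.5 * exp(rho * log(G)) - 0.5 * lambda * exp(rho * log(L))
  eta <- mu * du
  # log P(accept) = -log1p(exp(-eta)); log P(reject) = -log1p(exp(eta))
  lp <- C * stats::plogis(eta, log.p = TRUE) +
    (1 - C) * stats::plogis(-eta, log.p = TRUE)
  rowSums(lp * W)
}

# pack a long choice data.frame (subject, gain, loss, choice) into padded
# matrices usable by pt_ll_matrix
pt_pack_choices <- function(choices) {
  need <- c("subject", "gain", "loss", "choice")
  if (!all(need %in% names(choices)))
    stop("choice data must have columns: ", paste(need, collapse = ", "))
  subjects <- unique(choices$subject)
  n <- length(subjects)
  lens <- table(factor(choices$subject, levels = subjects))
  Tmax <- max(lens)
  G <- matrix(1, n, Tmax); L <- matrix(1, n, Tmax)
  C <- matrix(0, n, Tmax); W <- matrix(0, n, Tmax)
  for (i in seq_len(n)) {
    d <- choices[choices$subject == subjects[i], ]
    k <- nrow(d)
    G[i, seq_len(k)] <- d$gain
    L[i, seq_len(k)] <- d$loss
    C[i, seq_len(k)] <- d$choice
    W[i, seq_len(k)] <- 1
  }
  list(subjects = subjects, G = G, L = L, C = C, W = W)
}
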
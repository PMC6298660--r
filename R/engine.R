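# Continuous-time ministep engine.  Actors receive change opportunities at
# rates (lambda_net, lambda_beh) per unit time over a period of length 1; at
# each opportunity the actor makes a multinomial-logit choice among single-tie
# toggles (plus keeping the current network) or feasible one-category
# behavior steps, weighted by exp of the evaluation-function change.

as_adj <- function(x) { x <- as.matrix(x); storage.mode(x) <- "integer"; x }

#' Ministep choice probabilities over network alternatives
#'
#' For an actor with a change opportunity in the network function: the
#' probability of toggling the tie to each other actor, plus keeping the
#' current network (the entry at the actor's own index).
#'
#' @param spec an [effect_spec()].
#' @param theta_net network coefficients in spec order.
#' @param x adjacency matrix; `z` centered behavior; `covs` covariate matrix.
#' @param actor the actor choosing.
#' @return numeric vector of length n summing to 1.
#' @export
network_choice_probs <- function(spec, theta_net, x, z = NULL, covs = NULL,
                                 actor) {
  x <- as_adj(x)
  n <- nrow(x)
  if (is.null(covs)) covs <- empty_covs(n)
  if (is.null(z)) z <- rep(0, n)
  if (length(theta_net) != nrow(spec$network)) stop("coefficient length mismatch")
  sc <- spec_codes(spec, covs)
  M <- net_change_stats_cpp(x, z, covs, sc$net_code, sc$net_covi, actor)
  u <- as.vector(M %*% theta_net)
  if (any(!is.finite(u))) stop("non-finite objective value")
  e <- exp(u - max(u))
  e / sum(e)
}

#' Ministep choice probabilities over behavior steps
#'
#' For an actor with a behavior change opportunity: probabilities over the
#' feasible subset of a one-category decrease, no change, and a one-category
#' increase (steps leaving the 1..n_categories range are excluded).
#'
#' @inheritParams network_choice_probs
#' @param theta_beh behavior coefficients in spec order.
#' @param scale a [behavior_scale()]; `z` is centered by
#'   `scale$centering_constant`.
#' @param sim_center similarity centering constant.
#' @return named numeric vector (subset of `c("-1","0","1")`) summing to 1.
#' @export
behavior_choice_probs <- function(spec, theta_beh, x, z, actor,
                                  scale = behavior_scale(), covs = NULL,
                                  sim_center = 0) {
  x <- as_adj(x)
  if (is.na(z[actor])) stop("actor ", actor, " has missing behavior")
  code <- z[actor] + scale$centering_constant
  deltas <- c(-1, 0, 1)
  feasible <- code + deltas >= 1 - 1e-9 & code + deltas <= scale$n_categories + 1e-9
  deltas <- deltas[feasible]
  M <- beh_change_stats_cpp(x, z, unname(BEH_EFFECTS[spec$behavior$name]),
                            actor, deltas, scale$range, sim_center)
  u <- as.vector(M %*% theta_beh)
  e <- exp(u - max(u))
  p <- e / sum(e)
  names(p) <- as.character(deltas)
  p
}

#' Simulate one observation period of the co-evolution process
#'
#' Runs the exponential-clock ministep process from a start state over a unit
#' time interval.  Waiting times are exponential at total intensity
#' `n_active * (rate_net + rate_beh)`; each event draws an actor uniformly
#' among active actors and the function proportionally to the two rates.
#' Deterministic given the RNG state (use `set.seed()` before calling, or
#' pass `seed`).
#'
#' @param spec an [effect_spec()].
#' @param theta list with `net` and `beh` coefficient vectors.
#' @param rates length-2 numeric `c(net, beh)`, both >= 0.
#' @param x start adjacency; `z_codes` start behavior category codes (1..K;
#'   NA actors are held at the scale midpoint and should be inactive).
#' @param covs covariate matrix; `scale` a [behavior_scale()].
#' @param active logical per actor; only active actors receive opportunities.
#' @param sim_center similarity centering constant.
#' @param seed optional integer seed.
#' @param scores also accumulate the per-coefficient log-choice-probability
#'   gradients (used by the derivative estimator in estimation).
#' @return list with `x`, `z_codes`, `n_net_steps`, `n_beh_steps`,
#'   `n_active`, and (when `scores`) `score_net`, `score_beh`.
#' @export
simulate_period <- function(spec, theta, rates, x, z_codes, covs = NULL,
                            scale = behavior_scale(), active = NULL,
                            sim_center = 0, seed = NULL, scores = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  x <- as_adj(x)
  n <- nrow(x)
  if (is.null(covs)) covs <- empty_covs(n)
  if (is.null(active)) active <- rep(TRUE, n)
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (length(theta$net) != nrow(spec$network) ||
      length(theta$beh) != nrow(spec$behavior))
    stop("coefficient length mismatch")
  if ("avg_similarity" %in% spec$behavior$name && scale$range <= 0)
    stop("the average similarity effect needs a positive behavior range")
  cc <- scale$centering_constant
  z <- ifelse(is.na(z_codes), (1 + scale$n_categories) / 2, z_codes) - cc
  sc <- spec_codes(spec, covs)
  res <- simulate_period_cpp(x, z, active, rates[1], rates[2],
                             sc$net_code, sc$net_covi, theta$net,
                             sc$beh_code, theta$beh, covs,
                             1 - cc, scale$n_categories - cc,
                             scale$range, sim_center, scores)
  out <- list(x = res$x, z_codes = as.integer(round(res$z + cc)),
              n_net_steps = res$n_net_steps, n_beh_steps = res$n_beh_steps,
              n_active = res$n_active)
  out$z_codes[is.na(z_codes)] <- NA_integer_
  if (scores) {
    out$score_net <- res$score_net
    out$score_beh <- res$score_beh
  }
  out
}

#' Simulate a multi-wave panel forward from an initial wave
#'
#' Chains [simulate_period()]: wave m+1 is simulated conditional on the
#' simulated wave m.  Actors with missing behavior at the start hold the
#' scale midpoint and are treated as inactive.
#'
#' @inheritParams simulate_period
#' @param rates 2 x n_periods matrix (rows net, beh) or length-2 vector
#'   recycled over periods.
#' @param n_periods number of periods (waves returned = n_periods + 1).
#' @return a [wave_panel()] of `n_periods + 1` waves.
#' @export
simulate_panel <- function(spec, theta, rates, x, z_codes, covs = NULL,
                           scale = behavior_scale(), active = NULL,
                           sim_center = 0, n_periods = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.vector(rates) && length(rates) == 2)
    rates <- matrix(rates, 2, n_periods)
  stopifnot(ncol(rates) == n_periods)
  if (is.null(active)) active <- !is.na(z_codes)
  waves <- vector("list", n_periods + 1)
  waves[[1]] <- list(adjacency = as_adj(x), behavior = z_codes,
                     participating = active)
  for (m in seq_len(n_periods)) {
    st <- simulate_period(spec, theta, rates[, m], waves[[m]]$adjacency,
                          waves[[m]]$behavior, covs, scale, active,
                          sim_center)
    waves[[m + 1]] <- list(adjacency = st$x, behavior = st$z_codes,
                           participating = active)
  }
  wave_panel(waves, n_categories = scale$n_categories)
}
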
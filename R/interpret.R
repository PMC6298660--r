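# Interpretation layer: evaluation-function contrasts expressed as odds
# ratios, the alter-selection curve over BMI categories, ego-alter selection
# tables, and Monte Carlo bootstrap confidence intervals.

#' Convert an evaluation-function coefficient to an odds ratio
#'
#' @param beta coefficient (finite).
#' @param digits optional rounding for display (e.g. 1 for network odds
#'   ratios); NULL keeps full precision.
#' @return exp(beta), optionally rounded.
#' @examples
#' or_from_coefficient(0.441, digits = 1)  # 1.6
#' @export
or_from_coefficient <- function(beta, digits = NULL) {
  if (any(!is.finite(beta))) stop("coefficient must be finite")
  or <- exp(beta)
  if (!is.null(digits)) or <- round(or, digits)
  or
}

#' Alter-selection curve over BMI categories
#'
#' The contribution `g(v) = beta_alter * v + beta_alter_sq * v^2` of an
#' alter's centered BMI category to the tendency to be nominated as a friend,
#' evaluated at each category, plus the continuous vertex
#' `v* = -beta_alter / (2 beta_alter_sq)` when the quadratic opens downward.
#'
#' @param beta_alter,beta_alter_sq the linear and squared alter coefficients.
#' @param scale a [behavior_scale()] giving the centering constant.
#' @return list with `curve` (data frame: category, label, centered value,
#'   contribution), `vertex` (centered value of the maximum, or NA when
#'   `beta_alter_sq >= 0`), `peak_category` (category with the largest
#'   contribution).
#' @export
alter_selection_curve <- function(beta_alter, beta_alter_sq, scale) {
  v <- seq_len(scale$n_categories) - scale$centering_constant
  g <- beta_alter * v + beta_alter_sq * v^2
  vertex <- if (beta_alter_sq < 0) -beta_alter / (2 * beta_alter_sq)
            else NA_real_
  list(curve = data.frame(category = seq_len(scale$n_categories),
                          label = bmi_category_labels()[seq_len(scale$n_categories)],
                          centered = v, contribution = g),
       vertex = vertex,
       peak_category = which.max(g))
}

#' Ego-alter selection table
#'
#' The network evaluation-function contribution of a tie from an ego with
#' centered behavior `v_e` to an alter with centered behavior `v_a`:
#' `b_ego v_e + b_ego_sq v_e^2 + b_alt v_a + b_alt_sq v_a^2 + b_ea v_e v_a`.
#'
#' @param beta named vector or list with (any of) `ego`, `ego_sq`, `alter`,
#'   `alter_sq`, `ego_x_alter`; absent entries count as 0.
#' @param ego_values,alter_values centered behavior grids.
#' @param scale optional [behavior_scale()]; grid values outside the scale's
#'   span trigger a warning.
#' @return matrix (ego values x alter values) of contributions.
#' @export
ego_alter_table <- function(beta, ego_values, alter_values, scale = NULL) {
  beta <- as.list(beta)
  b <- function(nm) if (is.null(beta[[nm]]) || is.na(beta[[nm]])) 0 else beta[[nm]]
  if (!is.null(scale)) {
    lim <- c(1, scale$n_categories) - scale$centering_constant
    if (any(c(ego_values, alter_values) < lim[1] - 1e-9) ||
        any(c(ego_values, alter_values) > lim[2] + 1e-9))
      warning("grid values fall outside the behavior scale range")
  }
  out <- outer(ego_values, alter_values, function(ve, va)
    b("ego") * ve + b("ego_sq") * ve^2 + b("alter") * va +
      b("alter_sq") * va^2 + b("ego_x_alter") * ve * va)
  dimnames(out) <- list(ego = format(ego_values),
                        alter = format(alter_values))
  out
}

#' Scenario contrast for behavior-change odds
#'
#' Describes two ego-and-friends configurations whose odds of a one-category
#' BMI step (versus staying) are compared: an ego at `ego_category`
#' (centered) whose friends all sit `offset_a` categories away versus
#' `offset_b` categories away.
#'
#' @param step +1 or -1 category move.
#' @param offset_a,offset_b friend-minus-ego category offsets for the two
#'   scenarios.  The canonical defaults contrast friends one category above
#'   the ego against friends one category below: the comparison of
#'   "friends with a higher BMI" against "friends with the same or a lower
#'   BMI", with the reference resolved to the lower side so that the
#'   increase and decrease odds ratios are exact inverses of one another.
#'   Because the shape terms cancel and average similarity enters the
#'   objective change linearly in the friend offset, the +1-step odds ratio
#'   under these defaults equals the closed form
#'   `exp(2 * beta_avg_similarity / range)`.
#' @param ego_category ego's centered behavior value.
#' @param n_friends number of friends in both scenarios.
#' @return object of class `scenario_contrast`.
#' @export
scenario_contrast <- function(step = 1, offset_a = 1, offset_b = -1,
                              ego_category = 0, n_friends = 1) {
  if (!(step %in% c(-1, 1))) stop("step must be +1 or -1")
  structure(list(step = step, offset_a = offset_a, offset_b = offset_b,
                 ego_category = ego_category, n_friends = n_friends),
            class = "scenario_contrast")
}

# Behavior objective change for a one-category step of an ego whose friends
# all sit `offset` categories away.
beh_step_objective <- function(beta, step, offset, ego_category, n_friends,
                               range) {
  beta <- as.list(beta)
  b <- function(nm) if (is.null(beta[[nm]]) || is.na(beta[[nm]])) 0 else beta[[nm]]
  z0 <- ego_category
  z1 <- ego_category + step
  d_lin <- z1 - z0
  d_quad <- z1^2 - z0^2
  # friends fixed at z0 + offset; similarity centering cancels in the change
  d_sim <- (-abs(z1 - (z0 + offset)) + abs(z0 - (z0 + offset))) / range
  b("linear") * d_lin + b("quadratic") * d_quad + b("avg_similarity") * d_sim
}

#' Odds ratio for a behavior step under a scenario contrast
#'
#' Computes, for each of the two friend configurations, the odds of making
#' the one-category step versus staying (exp of the behavior
#' evaluation-function change), and returns their ratio.  For the canonical
#' contrast (see [scenario_contrast()]) the shape terms cancel and the
#' +1-step odds ratio reduces to the closed form
#' `exp(2 * beta_avg_similarity / range)`, with the -1-step ratio its exact
#' inverse.
#'
#' @param beta named vector/list of behavior coefficients (`linear`,
#'   `quadratic`, `avg_similarity`; absent entries count as 0).
#' @param contrast a [scenario_contrast()].
#' @param scale a [behavior_scale()]; its `range` scales the similarity.
#' @param digits optional display rounding.
#' @return the odds ratio.
#' @examples
#' sc <- behavior_scale(11, 6.25, 10)
#' behavior_change_or(c(avg_similarity = 5.233), scenario_contrast(), sc,
#'                    digits = 2)  # 2.85
#' @export
behavior_change_or <- function(beta, contrast = scenario_contrast(),
                               scale, digits = NULL) {
  stopifnot(inherits(contrast, "scenario_contrast"))
  lim <- c(1, scale$n_categories) - scale$centering_constant
  if (contrast$ego_category + contrast$step < lim[1] - 1e-9 ||
      contrast$ego_category + contrast$step > lim[2] + 1e-9)
    stop("the step is infeasible at the scale bounds for this ego category")
  da <- beh_step_objective(beta, contrast$step, contrast$offset_a,
                           contrast$ego_category, contrast$n_friends,
                           scale$range)
  db <- beh_step_objective(beta, contrast$step, contrast$offset_b,
                           contrast$ego_category, contrast$n_friends,
                           scale$range)
  or <- exp(da - db)
  if (!is.null(digits)) or <- round(or, digits)
  or
}

#' Odds ratio per unit of the ego's own BMI category
#'
#' The multiplicative change in the increase-versus-stay odds contributed by
#' the shape terms for each one-category increase of the ego's own centered
#' category: `exp(2 * beta_quadratic)`.
#'
#' @param beta_quadratic the quadratic shape coefficient.
#' @param digits optional display rounding.
#' @return the per-unit odds ratio.
#' @examples
#' own_category_or(0.041, digits = 2)  # 1.09
#' @export
own_category_or <- function(beta_quadratic, digits = NULL) {
  or <- exp(2 * beta_quadratic)
  if (!is.null(digits)) or <- round(or, digits)
  or
}

#' Monte Carlo bootstrap confidence interval for a parameter functional
#'
#' Draws parameter vectors from the multivariate normal with mean
#' `theta_hat` and the given covariance, applies the functional to each draw
#' and returns the 2.5th and 97.5th percentiles (or another level).
#'
#' @param theta_hat parameter vector.
#' @param covariance parameter covariance matrix (positive semidefinite).
#' @param functional function mapping a parameter vector to a scalar.
#' @param n_draws number of draws (at least 100).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return numeric `c(lo, hi)`.
#' @export
mc_bootstrap_ci <- function(theta_hat, covariance, functional,
                            n_draws = 1e5, level = 0.95, seed = NULL) {
  if (n_draws < 100) stop("n_draws must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  p <- length(theta_hat)
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop("covariance is not positive semidefinite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  draws <- matrix(rnorm(n_draws * p), n_draws, p) %*% t(L)
  draws <- sweep(draws, 2, theta_hat, "+")
  colnames(draws) <- names(theta_hat)
  vals <- apply(draws, 1, functional)
  unname(quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2)))
}
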
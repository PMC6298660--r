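# Synthetic residence-hall study generator.  Defaults emulate the study
# conditions: 276 actors over four waves of one academic year, wave
# participation 239/241/218/192, ~71% female, ~52% non-White, ~93%
# first-year, mean within-hall out-degree ~3.3 at the first wave, and the
# first-wave BMI category distribution.  Co-evolution is simulated forward
# with the published model coefficients as the default truth.

# First-wave BMI category frequencies (counts among 239 participants).
T1_CATEGORY_COUNTS <- c(12, 15, 31, 34, 22, 24, 16, 18, 28, 21, 18)

default_true_theta <- function() {
  list(rates = matrix(c(4.250, 2.221, 3.310,     # network, periods 1..3
                        1.059, 0.738, 0.892),    # behavior
                      nrow = 2, byrow = TRUE,
                      dimnames = list(c("net", "beh"), NULL)),
       net = c(outdegree = -2.341, reciprocity = 4.248,
               transitive_triplets = 1.002,
               transitive_recip_triplets = -0.666,
               outdegree_activity = -0.149, indegree_activity = -0.221,
               alter.behavior = 0.021, alter_sq.behavior = -0.021,
               ego.behavior = 0.003, ego_sq.behavior = 0.002,
               ego_x_alter.behavior = 0.005),
       beh = c(linear = 0.310, quadratic = 0.041, avg_similarity = 5.205))
}

#' Configuration of a synthetic residence-hall study
#'
#' @param n_actors number of actors (default 276).
#' @param n_waves number of observation waves (default 4).
#' @param female_fraction,race_fractions,first_year_fraction covariate
#'   marginals; `race_fractions` is a named vector over White, Black,
#'   Hispanic, Other summing to 1.
#' @param n_floors number of residence floors (assigned uniformly).
#' @param mean_outdegree target mean within-hall out-degree of the initial
#'   network.
#' @param same_floor_multiplier odds multiplier on ties within a floor.
#' @param recip_boost odds multiplier on the mutual-dyad configuration.
#' @param spec the [effect_spec()] the true model uses (default
#'   [bmi_effect_spec()] without demographics).
#' @param theta true parameters: list with `rates` (2 x periods), `net`,
#'   `beh` (defaults: the published no-demographics estimates).
#' @param participation per-wave participation counts (default
#'   239, 241, 218, 192).
#' @param sim_center similarity centering constant used in simulation.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_actors = 276L, n_waves = 4L,
                         female_fraction = 0.71,
                         race_fractions = c(White = 0.49, Black = 0.105,
                                            Hispanic = 0.272, Other = 0.134),
                         first_year_fraction = 0.931,
                         n_floors = 6L,
                         mean_outdegree = 3.3,
                         same_floor_multiplier = 2.0,
                         recip_boost = 5.0,
                         spec = bmi_effect_spec(),
                         theta = default_true_theta(),
                         participation = c(239L, 241L, 218L, 192L),
                         sim_center = 0) {
  stopifnot(female_fraction >= 0, female_fraction <= 1,
            first_year_fraction >= 0, first_year_fraction <= 1,
            abs(sum(race_fractions) - 1) < 0.01,  # printed percentages round
            all(race_fractions >= 0),
            length(participation) == n_waves,
            all(participation <= n_actors),
            mean_outdegree < n_actors - 1)
  if (is.vector(theta$rates))
    theta$rates <- matrix(theta$rates, 2, n_waves - 1)
  stopifnot(ncol(theta$rates) == n_waves - 1,
            length(theta$net) == nrow(spec$network),
            length(theta$beh) == nrow(spec$behavior))
  structure(list(n_actors = as.integer(n_actors),
                 n_waves = as.integer(n_waves),
                 female_fraction = female_fraction,
                 race_fractions = race_fractions / sum(race_fractions),
                 first_year_fraction = first_year_fraction,
                 n_floors = as.integer(n_floors),
                 mean_outdegree = mean_outdegree,
                 same_floor_multiplier = same_floor_multiplier,
                 recip_boost = recip_boost,
                 spec = spec, theta = theta,
                 participation = as.integer(participation),
                 sim_center = sim_center),
            class = "study_config")
}

#' Draw a covariate table matching the study marginals
#'
#' Independent Bernoulli/multinomial draws for sex, race/ethnicity and
#' first-year status; floors assigned uniformly at random.
#'
#' @param config a [study_config()].
#' @param seed optional integer seed.
#' @return a [covariate_table()].
#' @export
gen_covariates <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_actors
  covariate_table(
    id = sprintf("a%03d", seq_len(n)),
    male = rbinom(n, 1, 1 - config$female_fraction),
    race = sample(names(config$race_fractions), n, replace = TRUE,
                  prob = config$race_fractions),
    first_year = rbinom(n, 1, config$first_year_fraction),
    floor = sample(seq_len(config$n_floors), n, replace = TRUE))
}

#' Draw the first-wave network and behavior
#'
#' Ties are drawn dyad by dyad from a four-state distribution (null,
#' asymmetric either way, mutual) with odds weight `w` per tie, multiplied
#' by the same-floor multiplier for within-floor pairs and by the
#' reciprocation boost for the mutual configuration; `w` is calibrated by
#' root finding so the expected mean out-degree hits the target.  Behavior
#' codes are drawn from the first-wave category frequency table.
#'
#' @param covariates a [covariate_table()].
#' @param config a [study_config()].
#' @param seed optional integer seed.
#' @return list with `x` (adjacency) and `z_codes`.
#' @export
gen_initial_state <- function(covariates, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_actors
  floors <- as.integer(covariates$floor)
  same <- outer(floors, floors, "==")
  f_same <- mean(same[upper.tri(same)])
  rho <- config$recip_boost

  p_tie <- function(w) (w + w^2 * rho) / (1 + 2 * w + w^2 * rho)
  expected_od <- function(w) {
    (n - 1) * (f_same * p_tie(w * config$same_floor_multiplier) +
               (1 - f_same) * p_tie(w))
  }
  w <- uniroot(function(w) expected_od(w) - config$mean_outdegree,
               c(1e-8, 10), tol = 1e-10)$root

  x <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      wij <- if (same[i, j]) w * config$same_floor_multiplier else w
      pr <- c(1, wij, wij, wij^2 * rho)
      st <- sample.int(4, 1, prob = pr)
      if (st == 2L || st == 4L) x[i, j] <- 1L
      if (st == 3L || st == 4L) x[j, i] <- 1L
    }
  }
  z <- sample.int(11, n, replace = TRUE,
                  prob = T1_CATEGORY_COUNTS / sum(T1_CATEGORY_COUNTS))
  list(x = x, z_codes = z)
}

#' Impose wave-specific participation on a complete panel
#'
#' Samples which actors are unobserved at each wave so that the per-wave
#' participation counts are matched exactly while every actor remains
#' observed at two or more waves (missing completely at random).  Behavior
#' codes of non-participants are set missing and their outgoing ties zeroed.
#'
#' @param panel a [wave_panel()] with full participation.
#' @param participation per-wave participation counts.
#' @param seed optional integer seed.
#' @return the panel with missingness applied.
#' @export
apply_missingness <- function(panel, participation, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- panel$n_actors
  M <- length(panel$waves)
  stopifnot(length(participation) == M, all(participation <= n))
  n_missing <- n - participation
  max_missing_per_actor <- M - 2L
  if (sum(n_missing) > n * max_missing_per_actor)
    stop("participation counts are incompatible with every actor being ",
         "observed at two or more waves")
  for (attempt in 1:100) {
    dropped <- matrix(FALSE, n, M)
    ok <- TRUE
    for (m in order(n_missing, decreasing = TRUE)) {
      pool <- which(rowSums(dropped) < max_missing_per_actor)
      if (length(pool) < n_missing[m]) { ok <- FALSE; break }
      sel <- if (n_missing[m] > 0) sample(pool, n_missing[m]) else integer()
      dropped[sel, m] <- TRUE
    }
    if (ok) break
  }
  if (!ok) stop("could not find a feasible participation pattern")
  waves <- lapply(seq_len(M), function(m) {
    w <- panel$waves[[m]]
    out <- dropped[, m]
    w$behavior[out] <- NA_integer_
    if (!is.null(w$bmi)) w$bmi[out] <- NA_real_
    w$adjacency[out, ] <- 0L
    w$participating <- !out
    w
  })
  wave_panel(waves, actor_ids = panel$actor_ids,
             n_categories = panel$n_categories)
}

#' Generate a complete synthetic study
#'
#' Composes [gen_covariates()], [gen_initial_state()], forward co-evolution
#' simulation under the configured true parameters, and
#' [apply_missingness()]; optionally writes the three CSVs plus a JSON
#' manifest recording the configuration and seed.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @param out_dir optional directory to write `Links_all.csv`, `BMI.csv`,
#'   `covariates.csv` and `manifest.json` into.
#' @return list with `panel`, `covariates`, `scale`, `config`, `seed`.
#' @export
gen_study <- function(config = study_config(), seed = 1L, out_dir = NULL) {
  set.seed(seed)
  covariates <- gen_covariates(config)
  init <- gen_initial_state(covariates, config)
  cb <- center_behavior(init$z_codes)
  scale <- behavior_scale(11L, cb$scale$centering_constant, 10)
  covs <- covariate_matrix(covariates)
  panel <- simulate_panel(config$spec,
                          list(net = unname(config$theta$net),
                               beh = unname(config$theta$beh)),
                          config$theta$rates, init$x, init$z_codes,
                          covs, scale, sim_center = config$sim_center,
                          n_periods = config$n_waves - 1L)
  panel <- wave_panel(panel$waves, actor_ids = covariates$id)
  panel <- apply_missingness(panel, config$participation)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_panel(panel, file.path(out_dir, "Links_all.csv"),
                file.path(out_dir, "BMI.csv"))
    write_covariates(covariates, file.path(out_dir, "covariates.csv"))
    manifest <- list(seed = seed, n_actors = config$n_actors,
                     n_waves = config$n_waves,
                     participation = config$participation,
                     mean_outdegree = config$mean_outdegree,
                     theta = config$theta)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(panel = panel, covariates = covariates, scale = scale,
       config = config, seed = seed)
}
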
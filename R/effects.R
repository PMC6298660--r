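# Effect statistics for the two evaluation (objective) functions.
#
# Network effects (statistic of actor i on directed adjacency x, covariate v):
#   outdegree                  sum_j x_ij
#   reciprocity                sum_j x_ij x_ji
#   transitive_triplets        sum_{j,h} x_ij x_ih x_hj   (i->j closing i->h->j)
#   transitive_recip_triplets  sum_{j,h} x_ij x_ji x_ih x_hj
#   outdegree_activity         (sum_j x_ij)^2
#   indegree_activity          (sum_j x_ij)(sum_j x_ji)
#   alter                      sum_j x_ij v_j          alter_sq   sum_j x_ij v_j^2
#   ego                        v_i sum_j x_ij          ego_sq     v_i^2 sum_j x_ij
#   ego_x_alter                v_i sum_j x_ij v_j
#   same                       sum_j x_ij 1[v_i = v_j]
#
# Behavior effects (statistic of actor i on centered behavior z):
#   linear  z_i     quadratic  z_i^2
#   avg_similarity  (1/out_i) sum_j x_ij (sim_ij - sim_center),
#                   sim_ij = 1 - |z_i - z_j| / range; 0 for isolates.

NET_EFFECTS <- c(outdegree = 1L, reciprocity = 2L, transitive_triplets = 3L,
                 transitive_recip_triplets = 4L, outdegree_activity = 5L,
                 indegree_activity = 6L, alter = 7L, alter_sq = 8L,
                 ego = 9L, ego_sq = 10L, ego_x_alter = 11L, same = 12L)
BEH_EFFECTS <- c(linear = 1L, quadratic = 2L, avg_similarity = 3L)
NET_COV_EFFECTS <- names(NET_EFFECTS)[NET_EFFECTS >= 7L]
SAME_ONLY_COVS <- c("floor_cat", "white_cat", "year_cat")

#' Specify the effects entering the two evaluation functions
#'
#' An effect specification fixes the ordered list of network and behavior
#' effects, and thereby the coefficient layout of a parameter vector.
#' Network covariate effects (`alter`, `alter_sq`, `ego`, `ego_sq`,
#' `ego_x_alter`, `same`) name the covariate they use: either `"behavior"`
#' (the dynamic centered BMI category) or a column of [covariate_matrix()].
#'
#' @param network data frame with columns `name` and (optionally) `covariate`,
#'   or a character vector of structural effect names.
#' @param behavior character vector of behavior effect names among `linear`,
#'   `quadratic`, `avg_similarity`.
#' @return object of class `effect_spec` with components `network` and
#'   `behavior` (data frames with `name`, `covariate`, `label`).
#' @examples
#' effect_spec(network = c("outdegree", "reciprocity"),
#'             behavior = c("linear", "avg_similarity"))
#' @export
effect_spec <- function(network, behavior = character()) {
  if (is.character(network))
    network <- data.frame(name = network, covariate = NA_character_)
  if (is.null(network$covariate)) network$covariate <- NA_character_
  network$name <- as.character(network$name)
  network$covariate <- as.character(network$covariate)
  bad <- setdiff(network$name, names(NET_EFFECTS))
  if (length(bad)) stop("unknown network effect(s): ", paste(bad, collapse = ", "))
  needs_cov <- network$name %in% NET_COV_EFFECTS
  if (any(needs_cov & is.na(network$covariate)))
    stop("covariate effects must name a covariate")
  if (any(!needs_cov & !is.na(network$covariate)))
    stop("structural effects take no covariate")
  numeric_only <- setdiff(NET_COV_EFFECTS, "same")
  misuse <- network$name %in% numeric_only &
    network$covariate %in% SAME_ONLY_COVS
  if (any(misuse))
    stop("categorical identity covariates (", paste(SAME_ONLY_COVS, collapse = ", "),
         ") can only be used with the 'same' effect")
  network$label <- ifelse(is.na(network$covariate), network$name,
                          paste0(network$name, ".", network$covariate))
  if (anyDuplicated(network$label)) stop("duplicated network effects")

  behavior <- as.character(behavior)
  bad <- setdiff(behavior, names(BEH_EFFECTS))
  if (length(bad)) stop("unknown behavior effect(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(behavior)) stop("duplicated behavior effects")
  structure(list(network = network,
                 behavior = data.frame(name = behavior,
                                       label = behavior,
                                       stringsAsFactors = FALSE)),
            class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("effect_spec:\n  network: ", paste(x$network$label, collapse = ", "),
      "\n  behavior: ", paste(x$behavior$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The study's friendship-and-BMI model specification
#'
#' The network function holds the structural controls (outdegree, reciprocity,
#' transitive and transitive reciprocated triplets, out- and indegree
#' activity) plus the BMI selection terms (alter, alter squared, ego, ego
#' squared, ego x alter on the dynamic behavior); with `demographics = TRUE`
#' the demographic selection terms retained in the adjusted model (male
#' alter, White alter, first-year alter, Hispanic ego, same floor, same White,
#' same year) are added.  The behavior function holds the linear and
#' quadratic shape terms and average similarity (peer influence).
#'
#' @param demographics include the demographic selection effects.
#' @return an [effect_spec()].
#' @export
bmi_effect_spec <- function(demographics = FALSE) {
  net <- data.frame(
    name = c("outdegree", "reciprocity", "transitive_triplets",
             "transitive_recip_triplets", "outdegree_activity",
             "indegree_activity"),
    covariate = NA_character_)
  if (demographics) {
    net <- rbind(net, data.frame(
      name = c("alter", "alter", "alter", "ego", "same", "same", "same"),
      covariate = c("male", "white", "first_year", "hispanic",
                    "floor_cat", "white_cat", "year_cat")))
  }
  net <- rbind(net, data.frame(
    name = c("alter", "alter_sq", "ego", "ego_sq", "ego_x_alter"),
    covariate = "behavior"))
  effect_spec(network = net,
              behavior = c("linear", "quadratic", "avg_similarity"))
}

resolve_cov <- function(covariate, z, covs) {
  if (is.na(covariate) || covariate == "") return(NULL)
  if (covariate %in% c("behavior", "bmi")) return(z)
  if (is.null(covs) || !(covariate %in% colnames(covs)))
    stop("covariate '", covariate, "' not found in the covariate matrix")
  covs[, covariate]
}

# Integer coding of a spec for the C++ core.
spec_codes <- function(spec, covs) {
  covi <- vapply(seq_len(nrow(spec$network)), function(k) {
    cv <- spec$network$covariate[k]
    if (is.na(cv)) -1L
    else if (cv %in% c("behavior", "bmi")) 0L
    else {
      j <- match(cv, colnames(covs))
      if (is.na(j)) stop("covariate '", cv, "' not found in the covariate matrix")
      j
    }
  }, integer(1))
  list(net_code = unname(NET_EFFECTS[spec$network$name]),
       net_covi = covi,
       beh_code = unname(BEH_EFFECTS[spec$behavior$name]))
}

empty_covs <- function(n) matrix(0, n, 0)

#' Network effect statistic for one actor
#'
#' Full (non-incremental) computation of a named network effect statistic.
#'
#' @param name effect name (see [effect_spec()]).
#' @param x binary directed adjacency matrix.
#' @param actor actor index (1-based).
#' @param v covariate vector for covariate effects (centered for numeric
#'   covariates; raw codes for `same`).
#' @return the statistic value for `actor`.
#' @export
network_statistic <- function(name, x, actor, v = NULL) {
  if (!(name %in% names(NET_EFFECTS))) stop("unknown network effect: ", name)
  if (name %in% NET_COV_EFFECTS && is.null(v))
    stop("effect '", name, "' needs a covariate vector")
  i <- actor
  xi <- x[i, ]
  switch(name,
    outdegree = sum(xi),
    reciprocity = sum(xi * x[, i]),
    transitive_triplets = sum(xi * (xi %*% x)),
    transitive_recip_triplets = sum(xi * x[, i] * (xi %*% x)),
    outdegree_activity = sum(xi)^2,
    indegree_activity = sum(xi) * sum(x[, i]),
    alter = sum(xi * v),
    alter_sq = sum(xi * v^2),
    ego = v[i] * sum(xi),
    ego_sq = v[i]^2 * sum(xi),
    ego_x_alter = v[i] * sum(xi * v),
    same = sum(xi * (v == v[i])))
}

#' Behavior effect statistic for one actor
#'
#' @param name one of `linear`, `quadratic`, `avg_similarity`.
#' @param z centered behavior values.
#' @param x binary directed adjacency matrix (used by `avg_similarity`).
#' @param actor actor index.
#' @param range behavior range scaling the similarity score.
#' @param sim_center similarity centering constant subtracted from each
#'   dyadic similarity (0 by default).
#' @return the statistic value for `actor`; average similarity of an actor
#'   without outgoing ties is 0 by convention.
#' @export
behavior_statistic <- function(name, z, x, actor, range = 10,
                               sim_center = 0) {
  if (!(name %in% names(BEH_EFFECTS))) stop("unknown behavior effect: ", name)
  i <- actor
  if (is.na(z[i])) stop("actor ", i, " has missing behavior")
  if (range <= 0) stop("behavior range must be positive")
  switch(name,
    linear = z[i],
    quadratic = z[i]^2,
    avg_similarity = {
      friends <- which(x[i, ] == 1L)
      if (!length(friends)) 0
      else mean(1 - abs(z[i] - z[friends]) / range - sim_center)
    })
}

# All-actor statistic vectors (vectorized full recomputation); used for
# moment targets and simulated statistics.
network_statistic_all <- function(name, x, v = NULL) {
  od <- rowSums(x)
  switch(name,
    outdegree = od,
    reciprocity = rowSums(x * t(x)),
    transitive_triplets = rowSums(x * (x %*% x)),
    transitive_recip_triplets = rowSums(x * t(x) * (x %*% x)),
    outdegree_activity = od^2,
    indegree_activity = od * colSums(x),
    alter = as.vector(x %*% v),
    alter_sq = as.vector(x %*% v^2),
    ego = v * od,
    ego_sq = v^2 * od,
    ego_x_alter = v * as.vector(x %*% v),
    same = rowSums(x * outer(v, v, "==")))
}

behavior_statistic_all <- function(name, z, x, range, sim_center = 0) {
  switch(name,
    linear = z,
    quadratic = z^2,
    avg_similarity = {
      od <- rowSums(x)
      sim <- 1 - abs(outer(z, z, "-")) / range - sim_center
      s <- rowSums(x * sim)
      ifelse(od > 0, s / pmax(od, 1), 0)
    })
}

#' Evaluation (objective) function value for one actor
#'
#' The linear combination `sum_k beta_k s_ik` of effect statistics that
#' exponentiates into an actor's multinomial choice weights.
#'
#' @param fun `"network"` or `"behavior"`.
#' @param spec an [effect_spec()].
#' @param theta coefficient vector, one per effect of the chosen function, in
#'   spec order.
#' @param x adjacency matrix; `z` centered behavior; `covs` covariate matrix
#'   from [covariate_matrix()] (may be NULL when unused).
#' @param actor actor index.
#' @param range,sim_center similarity scaling, see [behavior_statistic()].
#' @return scalar objective value.
#' @export
objective_value <- function(fun = c("network", "behavior"), spec, theta,
                            x, z = NULL, covs = NULL, actor,
                            range = 10, sim_center = 0) {
  fun <- match.arg(fun)
  eff <- if (fun == "network") spec$network else spec$behavior
  if (length(theta) != nrow(eff))
    stop("theta has length ", length(theta), " but the ", fun,
         " function has ", nrow(eff), " effects")
  s <- vapply(seq_len(nrow(eff)), function(k) {
    if (fun == "network") {
      v <- resolve_cov(eff$covariate[k], z, covs)
      network_statistic(eff$name[k], x, actor, v)
    } else {
      behavior_statistic(eff$name[k], z, x, actor, range, sim_center)
    }
  }, numeric(1))
  sum(theta * s)
}

#' Change statistic for a single ministep alternative
#'
#' The exact difference `s_ik(after) - s_ik(before)` in actor `actor`'s
#' effect statistics when one tie is toggled or the behavior moves one
#' category, computed incrementally.
#'
#' @param spec an [effect_spec()].
#' @param x adjacency matrix; `z` centered behavior; `covs` covariate matrix.
#' @param actor the actor making the change.
#' @param change for a tie change, `list(type = "tie", alter = j)`; for a
#'   behavior step, `list(type = "behavior", delta = +1 or -1)`.
#' @param scale a [behavior_scale()] (needed for behavior changes and for
#'   similarity scaling).
#' @param sim_center similarity centering constant.
#' @return named vector of deltas, one per effect of the relevant function.
#' @export
change_statistic <- function(spec, x, z = NULL, covs = NULL, actor, change,
                             scale = behavior_scale(), sim_center = 0) {
  storage.mode(x) <- "integer"
  if (is.null(covs)) covs <- empty_covs(nrow(x))
  if (is.null(z)) z <- rep(0, nrow(x))
  if (change$type == "tie") {
    sc <- spec_codes(spec, covs)
    M <- net_change_stats_cpp(x, z, covs, sc$net_code, sc$net_covi, actor)
    d <- M[change$alter, ]
    names(d) <- spec$network$label
  } else if (change$type == "behavior") {
    if (!(change$delta %in% c(-1, 1))) stop("behavior step must be +1 or -1")
    code <- z[actor] + scale$centering_constant
    if (code + change$delta < 1 || code + change$delta > scale$n_categories)
      stop("behavior step leaves the category range 1..", scale$n_categories)
    d <- beh_change_stats_cpp(x, z, unname(BEH_EFFECTS[spec$behavior$name]),
                              actor, change$delta, scale$range, sim_center)[1, ]
    names(d) <- spec$behavior$label
  } else stop("change$type must be 'tie' or 'behavior'")
  d
}

#' Write / read an effect specification as YAML
#'
#' @param spec an [effect_spec()].
#' @param file path.
#' @return `write_effect_spec` returns the path invisibly;
#'   `read_effect_spec` returns the [effect_spec()].
#' @export
write_effect_spec <- function(spec, file) {
  obj <- list(
    network = lapply(seq_len(nrow(spec$network)), function(k) {
      e <- list(name = spec$network$name[k])
      if (!is.na(spec$network$covariate[k]))
        e$covariate <- spec$network$covariate[k]
      e
    }),
    behavior = as.list(spec$behavior$name))
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' @rdname write_effect_spec
#' @export
read_effect_spec <- function(file) {
  obj <- yaml::read_yaml(file)
  net <- data.frame(
    name = vapply(obj$network, `[[`, "", "name"),
    covariate = vapply(obj$network, function(e)
      if (is.null(e$covariate)) NA_character_ else e$covariate, ""))
  effect_spec(network = net, behavior = unlist(obj$behavior))
}
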
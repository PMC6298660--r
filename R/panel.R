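#' Code a measured BMI into the 11-level ordinal category scheme
#'
#' BMI values (kg/m^2) are mapped onto an 11-point ordinal scale: category 1
#' for BMI below 19; integer-truncated BMI for values in \[19, 26) (categories
#' 2 through 8 for truncated values 19 through 25); category 9 for \[26, 28);
#' 10 for \[28, 31); and 11 for BMI of 31 or more.  The mapping is total on the
#' positive reals and weakly monotone.
#'
#' @param bmi numeric vector of BMI values in kg/m^2; must be finite and
#'   positive (NA is propagated).
#' @return integer vector of category codes in 1..11.
#' @examples
#' code_bmi(c(18.9, 24.5, 25.99, 26, 31))
#' @export
code_bmi <- function(bmi) {
  ok <- is.na(bmi) | (is.finite(bmi) & bmi > 0)
  if (!all(ok)) {
    stop("BMI values must be positive and finite; offending values: ",
         paste(utils::head(bmi[!ok], 5), collapse = ", "))
  }
  code <- rep(NA_integer_, length(bmi))
  idx <- !is.na(bmi)
  b <- bmi[idx]
  k <- ifelse(b < 19, 1L,
       ifelse(b < 26, as.integer(floor(b)) - 17L,
       ifelse(b < 28, 9L,
       ifelse(b < 31, 10L, 11L))))
  code[idx] <- k
  code
}

#' Upper-open BMI bin labels for the 11 categories
#'
#' @return character vector of length 11 giving the kg/m^2 range each ordinal
#'   category covers.
#' @export
bmi_category_labels <- function() {
  c("<19", "19 to 19.99", "20 to 20.99", "21 to 21.99", "22 to 22.99",
    "23 to 23.99", "24 to 24.99", "25 to 25.99", "26 to 27.99",
    "28 to 30.99", ">=31")
}

#' Mean-center ordinal behavior codes
#'
#' Computes a single centering constant as the mean of all non-missing codes
#' pooled across actors and waves, and returns the centered values together
#' with a behavior scale record.  With the study's category distribution the
#' centered values span roughly -5.25 to 4.75.
#'
#' @param codes integer matrix (actors x waves) or vector of category codes in
#'   1..n_categories; NA allowed and propagated.
#' @param n_categories number of ordinal categories (default 11).
#' @return list with elements `scale` (a `behavior_scale`: `n_categories`,
#'   `centering_constant`, `range` = observed max minus min code) and
#'   `centered` (same shape as `codes`).
#' @examples
#' center_behavior(matrix(c(1, 6, 11, 2, 7, 10), nrow = 3))
#' @export
center_behavior <- function(codes, n_categories = 11L) {
  v <- as.vector(codes)
  if (all(is.na(v))) stop("all behavior codes are missing; cannot center")
  bad <- !is.na(v) & (v < 1 | v > n_categories | v != round(v))
  if (any(bad)) stop("behavior codes must be integers in 1..", n_categories)
  cc <- mean(v, na.rm = TRUE)
  rng <- diff(range(v, na.rm = TRUE))
  scale <- behavior_scale(n_categories = n_categories,
                          centering_constant = cc, range = rng)
  list(scale = scale, centered = codes - cc)
}

#' Construct a behavior scale record
#'
#' @param n_categories number of ordinal categories.
#' @param centering_constant value subtracted from codes to center them.
#' @param range observed behavior range (max minus min code); used to scale
#'   similarity statistics.
#' @return object of class `behavior_scale`.
#' @export
behavior_scale <- function(n_categories = 11L, centering_constant = 0,
                           range = n_categories - 1) {
  if (range < 0) stop("behavior scale range must be nonnegative")
  structure(list(n_categories = as.integer(n_categories),
                 centering_constant = centering_constant,
                 range = range),
            class = "behavior_scale")
}

#' @export
print.behavior_scale <- function(x, ...) {
  cat(sprintf("behavior scale: %d categories, centering constant %.4g, range %.4g\n",
              x$n_categories, x$centering_constant, x$range))
  invisible(x)
}

#' Construct a longitudinal network-behavior panel
#'
#' A `wave_panel` holds, for each observation wave, a binary directed
#' adjacency matrix (no self-ties), an integer behavior code per actor (NA for
#' unobserved), an optional raw BMI value per actor, and a participation flag.
#' At least two waves are required.
#'
#' @param waves list of wave records; each a list with `adjacency` (n x n
#'   binary matrix), `behavior` (integer codes or NA), optional `bmi` (raw
#'   kg/m^2) and optional `participating` (logical; defaults to
#'   `!is.na(behavior)`).
#' @param actor_ids character vector of actor identifiers (defaults to
#'   rownames of the first adjacency or "a1".."an").
#' @param n_categories number of behavior categories.
#' @return object of class `wave_panel`.
#' @export
wave_panel <- function(waves, actor_ids = NULL, n_categories = 11L) {
  if (length(waves) < 2) stop("a panel needs at least two waves")
  n <- nrow(waves[[1]]$adjacency)
  if (is.null(actor_ids)) {
    actor_ids <- rownames(waves[[1]]$adjacency)
    if (is.null(actor_ids)) actor_ids <- paste0("a", seq_len(n))
  }
  waves <- lapply(waves, function(w) {
    adj <- as.matrix(w$adjacency)
    storage.mode(adj) <- "integer"
    dimnames(adj) <- list(actor_ids, actor_ids)
    beh <- w$behavior
    if (is.null(beh)) beh <- rep(NA_integer_, n)
    part <- w$participating
    if (is.null(part)) part <- !is.na(beh)
    list(adjacency = adj, behavior = as.integer(beh),
         bmi = w$bmi, participating = as.logical(part))
  })
  p <- structure(list(n_actors = n, actor_ids = actor_ids,
                      n_categories = as.integer(n_categories),
                      waves = waves),
                 class = "wave_panel")
  validate_wave_panel(p)
  p
}

#' Validate a wave panel's invariants
#'
#' Checks: adjacency matrices are square, binary, with zero diagonal; behavior
#' codes lie in 1..n_categories when present; participation flags have one
#' entry per actor; at least two waves.
#'
#' @param panel a `wave_panel`.
#' @return the panel, invisibly; errors on violation.
#' @export
validate_wave_panel <- function(panel) {
  stopifnot(inherits(panel, "wave_panel"))
  n <- panel$n_actors
  if (length(panel$waves) < 2) stop("a panel needs at least two waves")
  for (m in seq_along(panel$waves)) {
    w <- panel$waves[[m]]
    a <- w$adjacency
    if (!is.matrix(a) || nrow(a) != n || ncol(a) != n)
      stop("wave ", m, ": adjacency must be ", n, " x ", n)
    if (any(is.na(a)) || !all(a %in% c(0L, 1L)))
      stop("wave ", m, ": adjacency must be binary")
    if (any(diag(a) != 0L))
      stop("wave ", m, ": self-ties are not allowed")
    b <- w$behavior
    if (length(b) != n) stop("wave ", m, ": behavior must have one code per actor")
    bad <- !is.na(b) & (b < 1L | b > panel$n_categories)
    if (any(bad))
      stop("wave ", m, ": behavior codes must lie in 1..", panel$n_categories)
    if (length(w$participating) != n)
      stop("wave ", m, ": participation flag must have one entry per actor")
  }
  invisible(panel)
}

#' @export
print.wave_panel <- function(x, ...) {
  cat(sprintf("wave_panel: %d actors, %d waves, %d behavior categories\n",
              x$n_actors, length(x$waves), x$n_categories))
  for (m in seq_along(x$waves)) {
    w <- x$waves[[m]]
    cat(sprintf("  wave %d: %d ties, %d participating, mean code %.2f\n",
                m, sum(w$adjacency), sum(w$participating),
                mean(w$behavior, na.rm = TRUE)))
  }
  invisible(x)
}

#' Construct an actor covariate table
#'
#' Constant actor attributes for the study design: sex, race/ethnicity
#' (White / Black / Hispanic / Other), first-year status and residence floor.
#'
#' @param id character actor identifiers.
#' @param male binary indicator (1 = male).
#' @param race character/factor with levels among White, Black, Hispanic,
#'   Other.
#' @param first_year binary indicator (1 = first-year student).
#' @param floor residence-floor label (coerced to factor).
#' @return object of class `covariate_table` (a data frame).
#' @export
covariate_table <- function(id, male, race, first_year, floor) {
  race <- factor(as.character(race),
                 levels = c("White", "Black", "Hispanic", "Other"))
  if (any(is.na(race))) stop("race must be one of White, Black, Hispanic, Other")
  stopifnot(all(male %in% 0:1), all(first_year %in% 0:1))
  d <- data.frame(id = as.character(id), male = as.integer(male),
                  race = race, first_year = as.integer(first_year),
                  floor = factor(floor), stringsAsFactors = FALSE)
  class(d) <- c("covariate_table", "data.frame")
  d
}

#' Build the numeric covariate matrix used by effect statistics
#'
#' Numeric/binary attributes are returned mean-centered (columns `male`,
#' `white`, `black`, `hispanic`, `other`, `first_year`); categorical identity
#' columns for matching ("same") effects are returned as raw integer codes
#' (`floor_cat`, `white_cat`, `year_cat`).  Centered columns have mean zero
#' over the actors included.
#'
#' @param covariates a `covariate_table`.
#' @return numeric matrix, one row per actor, with a `centers` attribute
#'   recording the subtracted means.
#' @export
covariate_matrix <- function(covariates) {
  stopifnot(inherits(covariates, "covariate_table"))
  raw <- cbind(male = covariates$male,
               white = as.integer(covariates$race == "White"),
               black = as.integer(covariates$race == "Black"),
               hispanic = as.integer(covariates$race == "Hispanic"),
               other = as.integer(covariates$race == "Other"),
               first_year = covariates$first_year)
  centers <- colMeans(raw)
  centered <- sweep(raw, 2, centers)
  out <- cbind(centered,
               floor_cat = as.integer(covariates$floor),
               white_cat = as.integer(covariates$race == "White"),
               year_cat = covariates$first_year)
  rownames(out) <- covariates$id
  attr(out, "centers") <- centers
  out
}
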
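# Method-of-moments estimation.  Parameters are chosen so that the expected
# statistics of forward-simulated periods match the observed target
# statistics; the root is found by three-phase Robbins-Monro stochastic
# approximation (phase 1: derivative matrix; phase 2: iterative updates with
# halving gain; phase 3: diagnostics, covariance and standard errors at the
# solution).

# Internal bundle of everything estimation needs per panel.
prepare_estimation <- function(panel, spec, covariates = NULL,
                               sim_center = "data") {
  validate_wave_panel(panel)
  n <- panel$n_actors
  M <- length(panel$waves) - 1L
  covs <- if (is.null(covariates)) empty_covs(n) else covariate_matrix(covariates)

  zobs <- sapply(panel$waves, function(w) w$behavior)       # n x (M+1), NA = missing
  cb <- center_behavior(zobs, n_categories = panel$n_categories)
  scale <- cb$scale
  part <- sapply(panel$waves, function(w) w$participating)

  # carry-forward (then carry-backward) imputation for simulation starts;
  # imputed actor-waves are excluded from the targets' ego sums, and the
  # simulated values at missing observations are reset to the imputed values
  # so that unobserved entries cancel from the moment comparison
  zimp <- zobs
  for (m in 2:(M + 1))
    zimp[, m] <- ifelse(is.na(zimp[, m]), zimp[, m - 1], zimp[, m])
  for (m in M:1)
    zimp[, m] <- ifelse(is.na(zimp[, m]), zimp[, m + 1], zimp[, m])
  if (any(is.na(zimp)))
    zimp[is.na(zimp)] <- round((1 + panel$n_categories) / 2)

  # same for the network: a non-participant's outgoing ties are imputed by
  # their last observed row (kept zero before the first observation, which
  # coincides with the recorded data)
  ximp <- lapply(panel$waves, function(w) w$adjacency)
  for (m in seq_len(M + 1)) {
    for (i in which(!part[, m])) {
      prev <- rev(which(part[i, seq_len(m)]))
      if (length(prev))
        ximp[[m]][i, ] <- panel$waves[[prev[1]]]$adjacency[i, ]
    }
  }

  if (identical(sim_center, "data") && scale$range <= 0) sim_center <- 0
  if (identical(sim_center, "data")) {
    sims <- unlist(lapply(seq_len(M + 1), function(m) {
      z <- zobs[, m]
      ok <- which(!is.na(z))
      if (length(ok) < 2) return(NULL)
      d <- abs(outer(z[ok], z[ok], "-"))
      1 - d[row(d) != col(d)] / scale$range
    }))
    sim_center <- mean(sims)
  }

  if ("avg_similarity" %in% spec$behavior$name && scale$range <= 0)
    stop("the average similarity effect needs behavior variation in the panel")
  ego_net <- lapply(seq_len(M), function(m) which(part[, m] & part[, m + 1]))
  ego_beh <- lapply(seq_len(M), function(m)
    which(part[, m] & part[, m + 1] & !is.na(zobs[, m]) & !is.na(zobs[, m + 1])))
  # every actor is active in simulation (the latent process does not pause
  # for non-response); unobserved states are imputed above
  active <- lapply(seq_len(M), function(m) rep(TRUE, n))
  if (n == 0) stop("a period has no active actors")

  pN <- nrow(spec$network); pB <- nrow(spec$behavior)
  par_names <- c(paste0("rate.net.", seq_len(M)), paste0("rate.beh.", seq_len(M)),
                 if (pN) paste0("net.", spec$network$label),
                 if (pB) paste0("beh.", spec$behavior$label))
  list(panel = panel, spec = spec, covs = covs, scale = scale,
       sim_center = sim_center, n = n, M = M, part = part, zobs = zobs,
       zimp = zimp, ximp = ximp, ego_net = ego_net, ego_beh = ego_beh,
       active = active,
       pN = pN, pB = pB, par_names = par_names,
       npar = 2 * M + pN + pB)
}

# Effect-statistic sums over the given ego sets for one end state.
eval_stat_sums <- function(prep, x, z_codes) {
  zc <- z_codes - prep$scale$centering_constant
  sN <- vapply(seq_len(prep$pN), function(k) {
    v <- resolve_cov(prep$spec$network$covariate[k], zc, prep$covs)
    network_statistic_all(prep$spec$network$name[k], x, v)
  }, numeric(prep$n))
  sB <- vapply(seq_len(prep$pB), function(k)
    behavior_statistic_all(prep$spec$behavior$name[k], zc, x,
                           prep$scale$range, prep$sim_center),
    numeric(prep$n))
  list(net = sN, beh = sB)
}

#' Observed target statistics for method-of-moments estimation
#'
#' For each rate parameter: the observed amount of change in its period (the
#' network Hamming distance over dyads whose ego participates at both waves;
#' the summed absolute category change over actors observed at both waves).
#' For each effect coefficient: the effect-statistic sum over periods,
#' evaluated on each period's end wave over the same ego sets, with entries
#' unobserved at that wave imputed from their nearest observed wave (the
#' simulated counterparts are reset to the same imputed values during
#' estimation, so unobserved entries cancel from the moment comparison).
#'
#' @param panel a [wave_panel()].
#' @param spec an [effect_spec()].
#' @param covariates optional [covariate_table()].
#' @param sim_center `"data"` (mean observed dyadic similarity) or a number.
#' @return named numeric vector (rates, then network effects, then behavior
#'   effects).
#' @export
target_statistics <- function(panel, spec, covariates = NULL,
                              sim_center = "data") {
  prep <- prepare_estimation(panel, spec, covariates, sim_center)
  compute_targets(prep)
}

compute_targets <- function(prep) {
  M <- prep$M
  rateN <- rateB <- numeric(M)
  effN <- numeric(prep$pN); effB <- numeric(prep$pB)
  for (m in seq_len(M)) {
    x0 <- prep$ximp[[m]]
    x1 <- prep$ximp[[m + 1]]
    iN <- prep$ego_net[[m]]; iB <- prep$ego_beh[[m]]
    rateN[m] <- sum(abs(x1[iN, , drop = FALSE] - x0[iN, , drop = FALSE]))
    rateB[m] <- sum(abs(prep$zobs[iB, m + 1] - prep$zobs[iB, m]))
    s <- eval_stat_sums(prep, x1, prep$zimp[, m + 1])
    if (prep$pN) effN <- effN + colSums(s$net[iN, , drop = FALSE])
    if (prep$pB) effB <- effB + colSums(s$beh[iB, , drop = FALSE])
  }
  stats <- c(rateN, rateB, effN, effB)
  names(stats) <- prep$par_names
  stats
}

# One Monte Carlo realization of the simulated statistics (and scores) at
# theta; each period starts from the observed start wave.
simulate_moments <- function(prep, theta, scores = TRUE) {
  M <- prep$M
  lamN <- theta[seq_len(M)]
  lamB <- theta[M + seq_len(M)]
  thN <- theta[2 * M + seq_len(prep$pN)]
  thB <- theta[2 * M + prep$pN + seq_len(prep$pB)]
  stat <- numeric(prep$npar)
  score <- numeric(prep$npar)
  for (m in seq_len(M)) {
    x0 <- prep$ximp[[m]]
    res <- simulate_period(prep$spec, list(net = thN, beh = thB),
                           c(lamN[m], lamB[m]), x0, prep$zimp[, m],
                           prep$covs, prep$scale, prep$active[[m]],
                           prep$sim_center, scores = scores)
    # entries unobserved at the period's end cancel from the moment
    # comparison: reset them to the imputed end-wave values
    x_end <- res$x
    z_end <- res$z_codes
    out <- !prep$part[, m + 1]
    if (any(out)) {
      x_end[out, ] <- prep$ximp[[m + 1]][out, ]
      z_end[out] <- prep$zimp[out, m + 1]
    }
    miss_z <- is.na(prep$zobs[, m + 1])
    z_end[miss_z] <- prep$zimp[miss_z, m + 1]
    iN <- prep$ego_net[[m]]; iB <- prep$ego_beh[[m]]
    stat[m] <- sum(abs(x_end[iN, , drop = FALSE] - x0[iN, , drop = FALSE]))
    stat[M + m] <- sum(abs(z_end[iB] - prep$zimp[iB, m]))
    s <- eval_stat_sums(prep, x_end, z_end)
    if (prep$pN)
      stat[2 * M + seq_len(prep$pN)] <- stat[2 * M + seq_len(prep$pN)] +
        colSums(s$net[iN, , drop = FALSE])
    if (prep$pB)
      stat[2 * M + prep$pN + seq_len(prep$pB)] <-
        stat[2 * M + prep$pN + seq_len(prep$pB)] +
        colSums(s$beh[iB, , drop = FALSE])
    if (scores) {
      nact <- res$n_active
      score[m] <- -nact + res$n_net_steps / lamN[m]
      score[M + m] <- -nact + res$n_beh_steps / lamB[m]
      if (prep$pN)
        score[2 * M + seq_len(prep$pN)] <-
          score[2 * M + seq_len(prep$pN)] + res$score_net
      if (prep$pB)
        score[2 * M + prep$pN + seq_len(prep$pB)] <-
          score[2 * M + prep$pN + seq_len(prep$pB)] + res$score_beh
    }
  }
  list(stat = stat, score = score)
}

# Inversion with two-sided diagonal equilibration: moment statistics live on
# very different scales (per-period change counts vs summed squared degrees),
# which alone can push the raw reciprocal condition number below solver
# tolerance.  A small scaled ridge is added if the equilibrated matrix is
# still ill-conditioned; only genuine singularity aborts.
solve_equilibrated <- function(D, what = "derivative matrix", sv_floor = 0) {
  r <- sqrt(apply(abs(D), 1, max))
  c <- sqrt(apply(abs(D), 2, max))
  r[r == 0] <- 1; c[c == 0] <- 1
  Ds <- D / outer(r, c)
  if (sv_floor > 0) {
    # damped pseudo-inverse: floor the singular values so weakly identified
    # directions get bounded (not exploding) update steps
    sv <- svd(Ds)
    d <- pmax(sv$d, sv_floor * max(sv$d))
    return((sv$v %*% (t(sv$u) / d)) / outer(c, r))
  }
  rc <- rcond(Ds)
  if (!is.finite(rc) || rc < 1e-14)
    stop(what, " is singular (equilibrated rcond = ", signif(rc, 3),
         "); cannot proceed")
  if (rc < 1e-8) {
    warning(what, " is ill-conditioned (equilibrated rcond = ",
            signif(rc, 3), "); adding a small ridge")
    Ds <- Ds + diag(1e-6, nrow(Ds))
  }
  solve(Ds) / outer(c, r)
}

# Likelihood-ratio (score-function) estimate of D = d E[stat] / d theta from
# a batch of simulations: D[k, l] = cov(stat_k, score_l).
score_derivative <- function(stats, scores) {
  S <- nrow(stats)
  cs <- scale(stats, scale = FALSE)
  cq <- scale(scores, scale = FALSE)
  crossprod(cs, cq) / (S - 1)
}

fd_derivative <- function(prep, theta, h = 0.15, reps = 10) {
  p <- prep$npar
  D <- matrix(0, p, p)
  base <- sample.int(.Machine$integer.max %/% 2, 1)
  for (l in seq_len(p)) {
    hl <- h * max(1, abs(theta[l]))
    for (r in seq_len(reps)) {
      tp <- theta; tp[l] <- tp[l] + hl
      tm <- theta; tm[l] <- max(tm[l] - hl,
                                if (l <= 2 * prep$M) 0.01 else -Inf)
      d <- tp[l] - tm[l]
      set.seed(base + r)
      sp <- simulate_moments(prep, tp, scores = FALSE)$stat
      set.seed(base + r)
      sm <- simulate_moments(prep, tm, scores = FALSE)$stat
      D[, l] <- D[, l] + (sp - sm) / (d * reps)
    }
  }
  D
}

initial_theta <- function(prep, targets) {
  M <- prep$M
  theta <- numeric(prep$npar)
  names(theta) <- prep$par_names
  for (m in seq_len(M)) {
    nN <- max(1, length(prep$ego_net[[m]]))
    nB <- max(1, length(prep$ego_beh[[m]]))
    theta[m] <- targets[m] / nN * 1.5 + 0.1
    theta[M + m] <- targets[M + m] / nB * 1.5 + 0.1
  }
  k <- match("outdegree", prep$spec$network$name)
  if (!is.na(k)) {
    dens <- mean(vapply(prep$panel$waves, function(w) {
      i <- which(w$participating)
      sum(w$adjacency[i, ]) / (length(i) * (prep$n - 1))
    }, 0))
    dens <- min(max(dens, 1e-4), 0.5)
    theta[2 * M + k] <- log(dens / (1 - dens))
  }
  theta
}

#' Estimate a co-evolution model by the method of moments
#'
#' Three-phase Robbins-Monro stochastic approximation.  Phase 1 estimates the
#' derivative matrix of expected statistics with respect to the parameters
#' (likelihood-ratio score estimator, or finite differences with common
#' random numbers).  Phase 2 iterates
#' `theta <- theta - a * solve(D, sim_stats - targets)` over `n_sub`
#' subphases, halving the gain `a` each subphase and re-starting each
#' subphase from the average of the previous subphase's iterates.  Phase 3
#' simulates `n3` panels at the solution to compute per-parameter convergence
#' t-ratios, the overall convergence ratio (the Mahalanobis norm of the
#' mean deviation, debiased by its p/n3 simulation-noise floor), the parameter
#' covariance `D^-1 Sigma D^-T` and standard errors.
#'
#' @param panel a [wave_panel()].
#' @param spec an [effect_spec()].
#' @param covariates optional [covariate_table()].
#' @param options list overriding any of: `n_sub` (4), `n2start` (40), `n3`
#'   (500), `gain0` (0.2), `n1` (7 + 3p), `restarts` (2, number of passes
#'   through phases 1-2, each re-starting from the previous answer),
#'   `sv_floor` (0.005, relative singular-value floor of the damped
#'   pseudo-inverse used for phase-2 updates), `dev_trunc` (5, phase-2
#'   deviations are truncated at this many phase-1 standard deviations),
#'   `deriv` ("score" or "fd"),
#'   `fd_reps` (10), `diagonalize` (0.2, weight on the diagonal of D used
#'   for phase-2 updates), `max_step` (2), `t_threshold` (0.1),
#'   `overall_threshold` (0.25), `sim_center` ("data"), `seed`.
#' @return object of class `saom_fit`: `theta`, `se`, `covariance`, `t_conv`,
#'   `overall_conv`, `converged`, `p_values`, `targets`, `sim_means`,
#'   `n_phase3`, `seed`, `options`, `spec`, `scale`, `sim_center`.
#' @export
saom_estimate <- function(panel, spec, covariates = NULL, options = list()) {
  opt <- utils::modifyList(list(
    n_sub = 4L, n2start = 40L, n3 = 500L, gain0 = 0.2, n1 = NULL,
    restarts = 2L, sv_floor = 0.005, dev_trunc = 5, diag_first = 0.8,
    deriv = "score", fd_reps = 10L, diagonalize = 0.2, max_step = 2,
    t_threshold = 0.1, overall_threshold = 0.25, sim_center = "data",
    seed = NULL), options)
  stopifnot(opt$n_sub >= 1, opt$n2start >= 1, opt$n3 >= 2, opt$gain0 > 0)
  if (!is.null(opt$seed)) set.seed(opt$seed)

  prep <- prepare_estimation(panel, spec, covariates, opt$sim_center)
  p <- prep$npar
  if (is.null(opt$n1)) opt$n1 <- 7L + 3L * p
  targets <- compute_targets(prep)
  theta <- initial_theta(prep, targets)
  M <- prep$M
  rate_idx <- seq_len(2 * M)

  derivative_at <- function(th, nsims) {
    stats <- matrix(0, nsims, p); scores <- matrix(0, nsims, p)
    for (s in seq_len(nsims)) {
      r <- simulate_moments(prep, th)
      stats[s, ] <- r$stat; scores[s, ] <- r$score
    }
    D <- if (opt$deriv == "fd") fd_derivative(prep, th, reps = opt$fd_reps)
         else score_derivative(stats, scores)
    list(D = D, sd = apply(stats, 2, sd))
  }
  stabilize <- function(D, w = opt$diagonalize) {
    dg <- diag(D)
    if (any(!is.finite(dg)))
      stop("derivative matrix is not finite; the model may be unidentified ",
           "at the current parameters")
    bad <- dg <= 0
    if (all(bad))
      stop("derivative matrix has no positive diagonal entries; the model ",
           "appears unidentified (diag = ",
           paste(signif(dg, 3), collapse = ", "), ")")
    if (any(bad)) {
      # Monte Carlo noise can flip a weakly identified diagonal entry; fall
      # back to a small positive proxy rather than aborting phase 2
      warning("replacing ", sum(bad), " non-positive derivative diagonal ",
              "entr", if (sum(bad) == 1) "y" else "ies",
              " with a positive proxy")
      dg[bad] <- 0.1 * mean(dg[!bad])
      diag(D) <- dg
    }
    Du <- (1 - w) * D + w * diag(dg, p)
    solve_equilibrated(Du, sv_floor = opt$sv_floor)
  }

  # phases 1 and 2, optionally repeated from the previous answer.  The first
  # pass updates along the (sign-safe) diagonal of D only: with p in the
  # tens, the off-diagonal score-covariance estimates from a phase-1 batch
  # are noisy enough that a full inverse can steer the search into the
  # degenerate (dense-network) region; later passes, started near the root
  # where D is re-estimated, use the blended full inverse.
  for (pass in seq_len(opt$restarts)) {
    d1 <- derivative_at(theta, opt$n1)
    Dinv2 <- stabilize(d1$D, w = if (pass == 1 && opt$restarts > 1)
      max(opt$diagonalize, opt$diag_first) else opt$diagonalize)
    # truncate extreme deviations (a standard guard: one bad realization, or
    # a transiently degenerate state, must not throw the iteration off)
    dev_cap <- opt$dev_trunc * pmax(d1$sd, 1e-8)
    pass_start <- theta
    capped_run <- 0
    for (sub in seq_len(opt$n_sub)) {
      a <- opt$gain0 / 2^(sub - 1)
      n_it <- ceiling(opt$n2start * 1.5^(sub - 1))
      acc <- matrix(0, n_it, p)
      for (it in seq_len(n_it)) {
        dev <- simulate_moments(prep, theta, scores = FALSE)$stat - targets
        at_cap <- mean(abs(dev) >= dev_cap * 0.999)
        dev <- pmin(pmax(dev, -dev_cap), dev_cap)
        capped_run <- if (at_cap > 0.5) capped_run + 1 else 0
        if (capped_run >= 5) {
          # the state has saturated: pull back to the pass start and shrink
          # the gain rather than walking further into the degenerate region
          theta <- pass_start
          a <- a / 4
          capped_run <- 0
        }
        step <- a * drop(Dinv2 %*% dev)
        mx <- max(abs(step))
        if (mx > opt$max_step) step <- step * opt$max_step / mx
        theta <- theta - step
        theta[rate_idx] <- pmax(theta[rate_idx], 0.01)
        acc[it, ] <- theta
      }
      theta <- colMeans(acc)
      names(theta) <- prep$par_names
    }
  }

  # phase 3
  stats <- matrix(0, opt$n3, p); scores <- matrix(0, opt$n3, p)
  for (s in seq_len(opt$n3)) {
    r <- simulate_moments(prep, theta)
    stats[s, ] <- r$stat; scores[s, ] <- r$score
  }
  dev <- sweep(stats, 2, targets)
  mdev <- colMeans(dev)
  sdev <- apply(dev, 2, sd)
  t_conv <- ifelse(sdev > 0, mdev / sdev, ifelse(mdev == 0, 0, Inf))
  Sigma <- cov(stats)
  D3 <- if (opt$deriv == "fd") fd_derivative(prep, theta, reps = opt$fd_reps)
        else score_derivative(stats, scores)
  Dinv <- solve_equilibrated(D3, "derivative matrix at the solution")
  covariance <- Dinv %*% Sigma %*% t(Dinv)
  covariance <- (covariance + t(covariance)) / 2
  se <- sqrt(pmax(diag(covariance), 0))
  # Mahalanobis norm of the mean deviation, debiased for simulation noise:
  # at an exact solution the raw quadratic form has expectation p/n3
  overall <- tryCatch({
    q <- drop(t(mdev) %*% solve_equilibrated(Sigma, "statistic covariance") %*%
                mdev)
    sqrt(max(0, q - p / opt$n3))
  }, error = function(e) max(abs(t_conv)), warning = function(w) max(abs(t_conv)))
  converged <- max(abs(t_conv)) < opt$t_threshold &&
    overall < opt$overall_threshold
  if (!converged)
    warning("estimation has not converged (max |t_conv| = ",
            signif(max(abs(t_conv)), 3), ", overall = ", signif(overall, 3),
            "); consider more phase-2 iterations or a restart")
  z <- ifelse(se > 0, theta / se, NA_real_)
  pv <- 2 * pnorm(-abs(z))
  dimnames(covariance) <- list(prep$par_names, prep$par_names)
  names(se) <- names(t_conv) <- names(pv) <- prep$par_names
  sim_means <- colMeans(stats); names(sim_means) <- prep$par_names

  structure(list(theta = theta, se = se, covariance = covariance,
                 t_conv = t_conv, overall_conv = overall,
                 converged = converged, p_values = pv, targets = targets,
                 sim_means = sim_means, n_phase3 = opt$n3,
                 seed = opt$seed, options = opt, spec = spec,
                 scale = prep$scale, sim_center = prep$sim_center,
                 n_actors = prep$n, n_periods = M),
            class = "saom_fit")
}

#' Wald tests for the parameters of a fitted model
#'
#' @param fit a `saom_fit`.
#' @return data frame with estimate, standard error, z = estimate/se and the
#'   two-sided normal p-value per parameter (NA where se is 0).
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "saom_fit"))
  z <- ifelse(fit$se > 0, fit$theta / fit$se, NA_real_)
  data.frame(parameter = names(fit$theta), estimate = fit$theta,
             se = fit$se, z = z, p_value = 2 * pnorm(-abs(z)),
             row.names = NULL)
}

#' @export
print.saom_fit <- function(x, ...) {
  cat(sprintf("saom_fit: %d actors, %d periods; %sconverged (max |t| = %.3f, overall = %.3f)\n",
              x$n_actors, x$n_periods, if (x$converged) "" else "NOT ",
              max(abs(x$t_conv)), x$overall_conv))
  tab <- wald_tests(x)
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$z <- round(tab$z, 2)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
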
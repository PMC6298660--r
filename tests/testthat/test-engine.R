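test_that("choice probabilities are uniform when all coefficients are zero", {
  sp <- effect_spec("outdegree", behavior = "linear")
  p <- network_choice_probs(sp, 0, matrix(0L, 4, 4), actor = 2)
  expect_equal(p, rep(0.25, 4))
  scale <- behavior_scale(11, 6, 10)
  pb <- behavior_choice_probs(sp, 0, matrix(0L, 4, 4), c(0, 0, 0, 0), 1, scale)
  expect_equal(unname(pb), rep(1 / 3, 3))
})

test_that("behavior choices at the scale boundary are restricted to feasible steps", {
  sp <- effect_spec("outdegree", behavior = "linear")
  scale <- behavior_scale(11, 6, 10)
  z <- c(11, 1, 5) - 6
  p_top <- behavior_choice_probs(sp, 0, matrix(0L, 3, 3), z, 1, scale)
  expect_equal(p_top, c("-1" = 0.5, "0" = 0.5))
  p_bot <- behavior_choice_probs(sp, 0, matrix(0L, 3, 3), z, 2, scale)
  expect_equal(p_bot, c("0" = 0.5, "1" = 0.5))
})

test_that("an outdegree-only model gives odds exp(beta) for each tie creation", {
  sp2 <- effect_spec("outdegree", behavior = character())
  for (beta in c(-2, -0.5, 1)) {
    p <- network_choice_probs(sp2, beta, matrix(0L, 5, 5), actor = 3)
    expect_equal(p[-3] / p[3], rep(exp(beta), 4), tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("a large positive linear coefficient drives the increase probability to 1", {
  sp <- effect_spec("outdegree", behavior = "linear")
  scale <- behavior_scale(11, 6, 10)
  p <- behavior_choice_probs(sp, 50, matrix(0L, 2, 2), c(0, 0), 1, scale)
  expect_gt(p["1"], 1 - 1e-10)
})

test_that("choice probabilities normalize and are logit-shift invariant on random states", {
  spec <- effect_spec(network = all_net_effect_rows(),
                      behavior = c("linear", "quadratic", "avg_similarity"))
  set.seed(21)
  for (r in 1:10) {
    n <- sample(4:7, 1)
    x <- random_digraph(n, 0.4)
    z <- round(runif(n, -4, 4), 1)
    th <- runif(nrow(spec$network), -1, 1)
    p <- network_choice_probs(spec, th, x, z, actor = 1)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    # adding a constant to all objective values leaves the choice unchanged:
    # realized through the outdegree effect shifting every toggle equally is
    # not constant, so instead verify directly via softmax recomputation
    u <- log(p) - log(p[1])
    expect_equal(exp(u + 5) / sum(exp(u + 5)), unname(p), tolerance = 1e-9)
  }
})

test_that("zero rates leave the state untouched and same seed gives same trace", {
  sp <- effect_spec(c("outdegree", "reciprocity"), behavior = "linear")
  scale <- behavior_scale(11, 6, 10)
  x <- random_digraph(8, 0.2)
  z <- sample.int(11, 8, replace = TRUE)
  r0 <- simulate_period(sp, list(net = c(-1, 1), beh = 0.1), c(0, 0), x, z,
                        scale = scale)
  expect_identical(r0$x, x)
  expect_identical(r0$z_codes, z)
  expect_identical(r0$n_net_steps + r0$n_beh_steps, 0L)

  r1 <- simulate_period(sp, list(net = c(-1, 1), beh = 0.1), c(3, 1), x, z,
                        scale = scale, seed = 31, scores = TRUE)
  r2 <- simulate_period(sp, list(net = c(-1, 1), beh = 0.1), c(3, 1), x, z,
                        scale = scale, seed = 31, scores = TRUE)
  expect_identical(r1, r2)
})

test_that("simulated trajectories keep networks binary and behavior in range", {
  sp <- effect_spec(c("outdegree", "reciprocity"),
                    behavior = c("linear", "avg_similarity"))
  scale <- behavior_scale(11, 6, 10)
  set.seed(5)
  x <- random_digraph(12, 0.15)
  z <- sample.int(11, 12, replace = TRUE)
  pan <- simulate_panel(sp, list(net = c(-1.5, 1), beh = c(0.3, 2)),
                        c(4, 2), x, z, scale = scale, n_periods = 3)
  expect_length(pan$waves, 4)
  for (w in pan$waves) {
    expect_true(all(w$adjacency %in% 0:1))
    expect_true(all(diag(w$adjacency) == 0))
    expect_true(all(w$behavior >= 1 & w$behavior <= 11))
  }
})

test_that("ministep counts follow the Poisson law of the exponential clock", {
  sp <- effect_spec("outdegree", behavior = "linear")
  scale <- behavior_scale(11, 6, 10)
  n <- 30; lamN <- 3; lamB <- 1
  x <- matrix(0L, n, n)
  z <- rep(6L, n)
  set.seed(77)
  reps <- 400
  counts <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    s <- simulate_period(sp, list(net = 0, beh = 0), c(lamN, lamB), x, z,
                         scale = scale)
    counts[r, ] <- c(s$n_net_steps, s$n_beh_steps)
  }
  for (k in 1:2) {
    lam <- n * c(lamN, lamB)[k]
    expect_lt(abs(mean(counts[, k]) - lam), 3 * sqrt(lam / reps))
    # index of dispersion ~ 1 for Poisson; chi-square bounds at reps draws
    disp <- var(counts[, k]) / mean(counts[, k])
    expect_gt(disp, 0.8)
    expect_lt(disp, 1.25)
  }
})

test_that("under zero coefficients the long-run tie density approaches one half", {
  sp <- effect_spec("outdegree", behavior = character())
  scale <- behavior_scale(11, 6, 10)
  n <- 6
  set.seed(13)
  x <- matrix(0L, n, n)
  dens <- numeric(60)
  for (r in seq_len(60)) {
    s <- simulate_period(sp, list(net = 0, beh = numeric()), c(40, 0), x,
                         rep(6L, n), scale = scale)
    dens[r] <- sum(s$x) / (n * (n - 1))
  }
  expect_lt(abs(mean(dens) - 0.5), 0.05)
})

test_that("stronger reciprocity yields more mutual dyads in expectation", {
  sp <- effect_spec(c("outdegree", "reciprocity"), behavior = character())
  scale <- behavior_scale(11, 6, 10)
  n <- 15
  mutuals <- function(beta_r, seed) {
    set.seed(seed)
    m <- 0
    for (r in 1:20) {
      s <- simulate_period(sp, list(net = c(-1.5, beta_r), beh = numeric()),
                           c(6, 0), matrix(0L, n, n), rep(6L, n),
                           scale = scale)
      m <- m + sum(s$x * t(s$x)) / 2
    }
    m / 20
  }
  expect_gt(mutuals(2.5, 41), mutuals(0, 41))
})

test_that("a period with no active actors is an error", {
  sp <- effect_spec("outdegree", behavior = "linear")
  expect_error(simulate_period(sp, list(net = 0, beh = 0), c(1, 1),
                               matrix(0L, 3, 3), c(5L, 5L, 5L),
                               active = rep(FALSE, 3),
                               scale = behavior_scale(11, 6, 10)),
               "active")
})
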
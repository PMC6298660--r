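test_that("network statistics match hand counts on toy graphs", {
  x <- toy_adj(3, list(c(1, 2), c(2, 1), c(1, 3)))
  expect_equal(network_statistic("reciprocity", x, 1), 1)
  expect_equal(network_statistic("outdegree", x, 1), 2)
  expect_equal(network_statistic("outdegree_activity", x, 1), 4)
  expect_equal(network_statistic("indegree_activity", x, 1), 2)

  x2 <- toy_adj(3, list(c(1, 2), c(2, 3), c(1, 3)))
  # the only ordered pair (j, h) with 1->j, 1->h, h->j is (3, 2)
  expect_equal(network_statistic("transitive_triplets", x2, 1), 1)
  expect_equal(network_statistic("transitive_triplets", x2, 2), 0)

  v <- c(0, 0.5, -1.5)
  x3 <- toy_adj(3, list(c(1, 2), c(1, 3)))
  expect_equal(network_statistic("alter", x3, 1, v), -1.0)
  expect_equal(network_statistic("alter_sq", x3, 1, v), 2.5)
  expect_equal(network_statistic("ego_x_alter", x3, 1, v), v[1] * -1.0)
  expect_equal(network_statistic("same", x3, 1, c(1, 1, 2)), 1)
  expect_error(network_statistic("alter", x3, 1), "covariate")
  expect_error(network_statistic("nonsense", x3, 1), "unknown")
})

test_that("transitive triplets on a complete digraph equal (n-1)(n-2) per actor", {
  for (n in 3:6) {
    x <- matrix(1L, n, n); diag(x) <- 0L
    expect_equal(network_statistic("transitive_triplets", x, 1),
                 (n - 1) * (n - 2))
  }
})

test_that("behavior statistics match the similarity formula", {
  expect_equal(behavior_statistic("linear", c(2, 0), matrix(0L, 2, 2), 1), 2)
  expect_equal(behavior_statistic("quadratic", c(2, 0), matrix(0L, 2, 2), 1), 4)

  x <- toy_adj(3, list(c(1, 2), c(1, 3)))
  z <- c(0, 1, -1)
  expect_equal(behavior_statistic("avg_similarity", z, x, 1, range = 10), 0.9)
  # isolate convention
  expect_equal(behavior_statistic("avg_similarity", z, x, 2, range = 10), 0)
  expect_error(behavior_statistic("avg_similarity", c(NA, 1, 0), x, 1, 10),
               "missing")
  expect_error(behavior_statistic("linear", z, x, 1, range = 0), "positive")
})

test_that("average similarity stays within [-1, 1] for in-range inputs", {
  set.seed(4)
  for (r in 1:20) {
    n <- sample(3:7, 1)
    x <- random_digraph(n, 0.5)
    z <- runif(n, -5, 5)
    simc <- runif(1)
    s <- vapply(seq_len(n), function(i)
      behavior_statistic("avg_similarity", z, x, i, range = 10,
                         sim_center = simc), 0)
    expect_true(all(s >= -1 - 1e-12 & s <= 1 + 1e-12))
  }
})

test_that("count-based network statistics are nonnegative integers", {
  set.seed(9)
  for (r in 1:10) {
    x <- random_digraph(5, 0.4)
    for (nm in c("outdegree", "reciprocity", "transitive_triplets",
                 "transitive_recip_triplets", "outdegree_activity",
                 "indegree_activity")) {
      s <- network_statistic(nm, x, sample(5, 1))
      expect_true(s >= 0 && s == round(s))
    }
  }
})

test_that("objective value is the coefficient-weighted sum of statistics", {
  x <- toy_adj(3, list(c(1, 2), c(2, 1), c(1, 3)))
  sp <- effect_spec(c("outdegree", "reciprocity"))
  expect_equal(objective_value("network", sp, c(0, 0), x, actor = 1), 0)
  sp1 <- effect_spec("outdegree")
  expect_equal(objective_value("network", sp1, -2.341, x, actor = 1),
               -2.341 * 2)
  # invariant to permuting effects with matching coefficients
  spa <- effect_spec(c("outdegree", "reciprocity", "indegree_activity"))
  spb <- effect_spec(c("reciprocity", "indegree_activity", "outdegree"))
  th <- c(0.3, -1.1, 0.7)
  expect_equal(objective_value("network", spa, th, x, actor = 1),
               objective_value("network", spb, th[c(2, 3, 1)], x, actor = 1))
  expect_error(objective_value("network", spa, c(1, 2), x, actor = 1),
               "effects")
})

test_that("tie change statistics equal full recomputation for every effect and toggle", {
  spec <- effect_spec(network = all_net_effect_rows())
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    x <- random_digraph(n, runif(1, 0.2, 0.6))
    z <- round(runif(n, -5, 5), 2)
    for (i in seq_len(n)) {
      for (j in seq_len(n)[-i]) {
        d <- change_statistic(spec, x, z, actor = i,
                              change = list(type = "tie", alter = j))
        x2 <- x; x2[i, j] <- 1L - x2[i, j]
        full <- vapply(seq_len(nrow(spec$network)), function(k) {
          nm <- spec$network$name[k]
          v <- if (is.na(spec$network$covariate[k])) NULL else z
          network_statistic(nm, x2, i, v) - network_statistic(nm, x, i, v)
        }, 0)
        expect_equal(unname(d), full, tolerance = 1e-12)
      }
    }
  }
})

test_that("behavior change statistics equal full recomputation for both steps", {
  spec <- effect_spec("outdegree",
                      behavior = c("linear", "quadratic", "avg_similarity"))
  scale <- behavior_scale(11, 6, 10)
  set.seed(12)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    x <- random_digraph(n, 0.4)
    codes <- sample(2:10, n, replace = TRUE)
    z <- codes - scale$centering_constant
    for (i in seq_len(n)) {
      for (delta in c(-1, 1)) {
        d <- change_statistic(spec, x, z, actor = i,
                              change = list(type = "behavior", delta = delta),
                              scale = scale)
        z2 <- z; z2[i] <- z2[i] + delta
        full <- vapply(c("linear", "quadratic", "avg_similarity"), function(nm)
          behavior_statistic(nm, z2, x, i, scale$range) -
            behavior_statistic(nm, z, x, i, scale$range), 0)
        expect_equal(unname(d), unname(full), tolerance = 1e-12)
      }
    }
  }
})

test_that("behavior steps leaving the category range are rejected", {
  spec <- effect_spec("outdegree", behavior = "linear")
  scale <- behavior_scale(11, 6, 10)
  x <- matrix(0L, 2, 2)
  expect_error(change_statistic(spec, x, c(11 - 6, 0), actor = 1,
                                change = list(type = "behavior", delta = 1),
                                scale = scale), "range")
  expect_error(change_statistic(spec, x, c(1 - 6, 0), actor = 1,
                                change = list(type = "behavior", delta = -1),
                                scale = scale), "range")
})

test_that("a +1 step toward uniformly higher friends raises similarity by 1/range", {
  spec <- effect_spec("outdegree", behavior = "avg_similarity")
  scale <- behavior_scale(11, 6, 10)
  x <- toy_adj(4, list(c(1, 2), c(1, 3), c(1, 4)))
  z <- c(3, 8, 8, 8) - scale$centering_constant
  d <- change_statistic(spec, x, z, actor = 1,
                        change = list(type = "behavior", delta = 1),
                        scale = scale)
  expect_equal(unname(d), 1 / scale$range)
})

test_that("effect specifications validate names and covariates", {
  expect_error(effect_spec("foo"), "unknown")
  expect_error(effect_spec(data.frame(name = "alter", covariate = NA)),
               "covariate")
  expect_error(effect_spec(data.frame(name = "outdegree", covariate = "male")),
               "structural")
  expect_error(effect_spec(data.frame(name = "alter", covariate = "floor_cat")),
               "identity")
  expect_error(effect_spec("outdegree", behavior = c("linear", "linear")),
               "duplicated")
})

test_that("effect specifications round-trip through YAML", {
  sp <- bmi_effect_spec(demographics = TRUE)
  f <- tempfile(fileext = ".yaml")
  write_effect_spec(sp, f)
  rt <- read_effect_spec(f)
  expect_identical(rt$network$name, sp$network$name)
  expect_identical(rt$network$covariate, sp$network$covariate)
  expect_identical(rt$behavior$name, sp$behavior$name)
})
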
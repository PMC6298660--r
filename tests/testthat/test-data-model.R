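test_that("BMI coding maps measured values onto the 11 ordinal categories", {
  expect_identical(code_bmi(18.9), 1L)
  expect_identical(code_bmi(24.5), 7L)
  expect_identical(code_bmi(31.0), 11L)
  expect_identical(code_bmi(25.99), 8L)
  expect_identical(code_bmi(26.0), 9L)
  # cut points 19, 20, ..., 26, 28, 31 partition the line
  cuts <- c(19:26, 28, 31)
  expect_identical(code_bmi(cuts), 2:11)
  expect_identical(code_bmi(cuts - 1e-9), 1:10)
  expect_error(code_bmi(-1), "positive")
  expect_error(code_bmi(Inf), "positive")
  expect_true(is.na(code_bmi(NA)))
})

test_that("BMI coding is total and weakly monotone on a dense grid", {
  b <- seq(10, 45, by = 0.01)
  k <- code_bmi(b)
  expect_true(all(k %in% 1:11))
  expect_true(all(diff(k) >= 0))
  expect_setequal(unique(k), 1:11)
})

test_that("behavior centering pools all waves and reproduces the study range", {
  # pooled mean 6.25 with both extreme categories present
  codes <- c(rep(1, 1), rep(11, 1), rep(6, 6))  # mean = 6
  codes <- c(1, 11, 4, 5, 6, 7, 5, 11)          # mean 6.25
  cb <- center_behavior(codes)
  expect_equal(cb$scale$centering_constant, 6.25)
  expect_equal(min(cb$centered), -5.25)
  expect_equal(max(cb$centered), 4.75)
  expect_equal(cb$scale$range, 10)

  cb2 <- center_behavior(c(5, 5, 5))
  expect_true(all(cb2$centered == 0))
  expect_equal(cb2$scale$range, 0)

  cb3 <- center_behavior(c(1, 11))
  expect_equal(as.vector(cb3$centered), c(-5, 5))
  expect_equal(cb3$scale$range, 10)

  m <- matrix(c(1, 5, NA, 9, 2, NA), 3, 2)
  cbm <- center_behavior(m)
  expect_equal(sum(cbm$centered, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_identical(is.na(cbm$centered), is.na(m))
  expect_error(center_behavior(c(NA, NA)), "missing")
  expect_error(center_behavior(c(0, 5)), "1..11")
})

test_that("panel construction enforces the invariants", {
  x <- toy_adj(3, list(c(1, 2)))
  w <- list(adjacency = x, behavior = c(3L, 4L, 5L))
  expect_error(wave_panel(list(w)), "two waves")
  xb <- x; xb[1, 1] <- 1L
  expect_error(wave_panel(list(list(adjacency = xb, behavior = c(3L, 4L, 5L)), w)),
               "self-ties")
  expect_error(wave_panel(list(list(adjacency = x, behavior = c(0L, 4L, 5L)), w)),
               "1..11")
  xn <- x; xn[1, 2] <- 2L
  expect_error(wave_panel(list(list(adjacency = xn, behavior = c(3L, 4L, 5L)), w)),
               "binary")
  p <- wave_panel(list(w, w))
  expect_s3_class(p, "wave_panel")
  expect_identical(p$waves[[1]]$participating, rep(TRUE, 3))
})

test_that("covariate matrix centers numeric covariates to mean zero", {
  ct <- covariate_table(id = paste0("s", 1:8),
                        male = c(1, 0, 0, 0, 1, 0, 0, 1),
                        race = c("White", "Black", "Hispanic", "Other",
                                 "White", "White", "Hispanic", "Black"),
                        first_year = c(1, 1, 1, 0, 1, 1, 1, 1),
                        floor = c(1, 1, 2, 2, 3, 3, 1, 2))
  cm <- covariate_matrix(ct)
  for (col in c("male", "white", "black", "hispanic", "other", "first_year"))
    expect_equal(mean(cm[, col]), 0, tolerance = 1e-9)
  expect_setequal(unique(cm[, "floor_cat"]), 1:3)
  expect_identical(unname(cm[, "white_cat"]), as.double(ct$race == "White"))
  expect_error(covariate_table("a", 1, "Martian", 1, 1), "race")
})

test_that("panels round-trip exactly through the CSV layout", {
  p <- toy_panel(n = 6, seed = 3, waves = 4)
  # make one actor non-participating with missing behavior at wave 2
  p$waves[[2]]$behavior[4] <- NA_integer_
  p$waves[[2]]$adjacency[4, ] <- 0L
  p$waves[[2]]$participating[4] <- FALSE
  lf <- tempfile(fileext = ".csv"); bf <- tempfile(fileext = ".csv")
  write_panel(p, lf, bf)
  rt <- read_panel(lf, bf)$panel
  expect_identical(rt$actor_ids, p$actor_ids)
  for (m in seq_along(p$waves)) {
    expect_identical(unname(rt$waves[[m]]$adjacency),
                     unname(p$waves[[m]]$adjacency))
    expect_identical(rt$waves[[m]]$behavior, p$waves[[m]]$behavior)
    expect_identical(rt$waves[[m]]$participating, p$waves[[m]]$participating)
  }
})

test_that("reader deduplicates edges, drops self-ties and rejects unknown ids", {
  bf <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("A", "B", "C"), T1 = c(3, 4, 5), T2 = c(3, 5, 5)),
            bf, row.names = FALSE)
  lf <- tempfile(fileext = ".csv")
  write.csv(data.frame(ego_id = c("A", "A", "A", "B"),
                       alter_id = c("B", "B", "A", "C"),
                       wave = c(1, 1, 1, 2)),
            lf, row.names = FALSE)
  expect_warning(expect_warning(res <- read_panel(lf, bf), "self-nomination"),
                 "duplicated")
  expect_identical(sum(res$panel$waves[[1]]$adjacency), 1L)
  # identical to the file without the duplicate row
  lf2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(ego_id = c("A", "B"), alter_id = c("B", "C"),
                       wave = c(1, 2)), lf2, row.names = FALSE)
  res2 <- read_panel(lf2, bf)
  expect_identical(res$panel$waves[[1]]$adjacency,
                   res2$panel$waves[[1]]$adjacency)

  lf3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(ego_id = "A", alter_id = "Z", wave = 1), lf3,
            row.names = FALSE)
  expect_error(read_panel(lf3, bf), "absent")
})

test_that("raw kg/m2 behavior files are coded onto the category scale", {
  bf <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("A", "B"), T1 = c(18.2, 24.5), T2 = c(26.0, NA)),
            bf, row.names = FALSE)
  lf <- tempfile(fileext = ".csv")
  write.csv(data.frame(ego_id = "A", alter_id = "B", wave = 1), lf,
            row.names = FALSE)
  res <- read_panel(lf, bf)
  expect_identical(res$panel$waves[[1]]$behavior, c(1L, 7L))
  expect_identical(res$panel$waves[[2]]$behavior, c(9L, NA))
  expect_false(res$panel$waves[[2]]$participating[2])
  expect_equal(res$panel$waves[[1]]$bmi, c(18.2, 24.5))
})

test_that("descriptives report degree, BMI and the endpoint category split", {
  w1 <- list(adjacency = toy_adj(2, list(c(1, 2))), behavior = c(3L, 5L))
  w2 <- list(adjacency = toy_adj(2, list(c(1, 2), c(2, 1))), behavior = c(4L, 5L))
  d <- panel_descriptives(wave_panel(list(w1, w2)))
  expect_equal(unname(d$transition), c(50, 50, 0))
  expect_equal(sum(d$transition), 100)
  expect_equal(d$per_wave$outdegree_mean, c(0.5, 1))
  expect_equal(d$per_wave$n_participating, c(2, 2))
  expect_equal(d$category_counts["<19", "T1"], 0)
})

test_that("transition percentages always sum to 100 over jointly observed actors", {
  for (seed in 1:5) {
    p <- toy_panel(n = 8, seed = seed, waves = 3)
    p$waves[[1]]$behavior[seed %% 8 + 1] <- NA_integer_
    p$waves[[1]]$participating <- !is.na(p$waves[[1]]$behavior)
    d <- panel_descriptives(p)
    expect_equal(sum(d$transition), 100)
  }
})
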
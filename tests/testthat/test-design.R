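test_that("quantile knot vectors obey the knots-minus-4 law", {
  set.seed(11)
  v <- runif(300)
  for (nb in c(2, 3, 4, 5, 6, 8, 12)) {
    k <- quantile_knots(v, nb)
    expect_length(k, nb + 4)
    expect_false(is.unsorted(k))
    expect_equal(k[1], min(v))
    expect_equal(k[length(k)], max(v))
  }
  # n_basis = 2: only repeated boundary knots
  k2 <- quantile_knots(v, 2)
  expect_setequal(unique(k2), range(v))
})

test_that("quantile knots sit on empirical quantiles (oracle check)", {
  set.seed(12)
  v <- rnorm(500)
  nb <- 7
  k <- quantile_knots(v, nb)
  core <- k[4:(length(k) - 3)]          # strip the 3 padding repeats per side
  levels <- seq(0, 1, length.out = nb - 2)
  expect_equal(core, vapply(levels, function(p) quantile_oracle(v, p), 0),
               tolerance = 1e-12)
})

test_that("degenerate predictors are rejected", {
  expect_error(quantile_knots(rep(1, 50), 4), "degenerate")
  expect_error(quantile_knots(c(1, 2, 3), 5), "degenerate")
})

test_that("cubic B-spline basis matches an independent Cox-de Boor oracle", {
  set.seed(13)
  for (trial in 1:100) {
    nb <- sample(4:10, 1)
    core <- sort(runif(nb - 2))
    knots <- c(rep(core[1], 3), core, rep(core[length(core)], 3))
    lo <- core[1]; hi <- core[length(core)]
    x <- runif(20, lo + 1e-9, hi - 1e-9)
    B <- bspline_basis(x, knots)
    O <- coxdeboor_oracle(x, knots)
    expect_lt(max(abs(B - O)), 1e-10)
  }
})

test_that("B-spline basis is a partition of unity with clamped ends", {
  set.seed(14)
  v <- rnorm(200)
  k <- quantile_knots(v, 6)
  x <- seq(min(v), max(v), length.out = 101)
  B <- bspline_basis(x, k)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-9)
  # at most 4 nonzero entries per interior point
  expect_lte(max(rowSums(B[-c(1, 101), ] > 1e-12)), 4)
  # boundary values: clamped end conditions
  expect_equal(as.numeric(bspline_basis(min(v), k)),
               c(1, rep(0, 5)), tolerance = 1e-12)
  expect_equal(as.numeric(bspline_basis(max(v), k)),
               c(rep(0, 5), 1), tolerance = 1e-12)
  # out-of-range values are clamped to the boundary
  expect_equal(as.numeric(bspline_basis(min(v) - 10, k)),
               as.numeric(bspline_basis(min(v), k)))
})

test_that("cyclic spline basis is periodic, shift-invariant, sums to one", {
  x <- seq(-400, 800, by = 7)
  B <- cyclic_spline_basis(x, 5, 0, 360)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-9)
  expect_equal(cyclic_spline_basis(0, 5, 0, 360),
               cyclic_spline_basis(360, 5, 0, 360), tolerance = 1e-9,
               ignore_attr = TRUE)
  # shifting by one knot spacing rotates the columns
  d <- 360 / 5
  g <- seq(0, 360 - d, length.out = 37)
  B1 <- cyclic_spline_basis(g, 5, 0, 360)
  B2 <- cyclic_spline_basis(g + d, 5, 0, 360)
  expect_lt(max(abs(B2 - B1[, c(5, 1:4)])), 1e-9)
  expect_error(cyclic_spline_basis(x, 2, 0, 360), "n_basis >= 3")
})

test_that("tensor spline basis has n^2 columns and sums to one", {
  set.seed(15)
  a <- runif(40); b <- rnorm(40)
  expect_equal(ncol(tensor_spline_basis(a, b, 10)), 100)
  expect_equal(ncol(tensor_spline_basis(a, b, 4)), 16)
  Tb <- tensor_spline_basis(a, b, 5)
  expect_lt(max(abs(rowSums(Tb) - 1)), 1e-9)
  expect_error(tensor_spline_basis(a, b[-1], 5), "equal length")
})

test_that("build_design codes factors, splines and interactions correctly", {
  set.seed(16)
  n <- 60
  ev <- data.frame(onset = sort(runif(n, 0, 50)), type = "stim",
                   cond = sample(c("a", "b", "c"), n, TRUE),
                   lum = runif(n, 10, 100),
                   x = rnorm(n))
  # 3-level factor, treatment coding: 2 columns + intercept
  d1 <- build_design(ev, model_spec("stim", "y ~ 1 + cat(cond)", c(0, 0.2)))
  expect_equal(ncol(d1$values), 3)
  expect_true(all(d1$values[, 1] == 1))
  expect_equal(sort(unique(as.numeric(d1$values[, 2:3]))), c(0, 1))
  # reference = alphabetically first: rows with cond == "a" are all zero
  expect_true(all(d1$values[ev[order(ev$onset), ]$cond == "a", 2:3] == 0))

  # spline identifiability: 1 + (5 - 1) columns, and the full basis plus
  # intercept has rank 5 (one basis column is redundant)
  d2 <- build_design(ev, model_spec("stim", "y ~ 1 + spl(x,5)", c(0, 0.2)))
  expect_equal(ncol(d2$values), 5)
  full_B <- bspline_basis(d2$events$x, d2$term_meta[["spl(x,5)"]]$knots)
  expect_equal(qr(cbind(1, full_B))$rank, 5)

  # the hypothetical face/house model: 3 columns
  ev$is_face <- sample(c("face", "house"), n, TRUE)
  d3 <- build_design(ev, model_spec("stim", "y ~ 1 + cat(is_face) + lum",
                                    c(0, 0.2)))
  expect_equal(ncol(d3$values), 3)
  # continuous predictors pass through uncentered
  expect_equal(d3$values[, 3], d3$events$lum, ignore_attr = TRUE)

  # interaction columns are products of the parents' coded columns
  d4 <- build_design(ev, model_spec("stim", "y ~ 1 + cat(is_face)*lum",
                                    c(0, 0.2)))
  expect_equal(ncol(d4$values), 4)
  expect_equal(d4$values[, 4], d4$values[, 2] * d4$values[, 3],
               ignore_attr = TRUE)
})

test_that("treatment and effects coding span the same column space", {
  set.seed(17)
  n <- 40
  ev <- data.frame(onset = sort(runif(n, 0, 50)), type = "stim",
                   cond = sample(c("a", "b", "c"), n, TRUE))
  Xt <- build_design(ev, model_spec("stim", "y ~ 1 + cat(cond)", c(0, 0.2),
                                    coding = "treatment"))$values
  Xe <- build_design(ev, model_spec("stim", "y ~ 1 + cat(cond)", c(0, 0.2),
                                    coding = "effects"))$values
  P <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  expect_lt(max(abs(P(Xt) - P(Xe))), 1e-9)
  # effects coding: rows of the alphabetically last level are -1
  ev_sorted <- ev[order(ev$onset), ]
  expect_true(all(Xe[ev_sorted$cond == "c", 2:3] == -1))
})

test_that("reference levels can be overridden per predictor", {
  ev <- data.frame(onset = c(0.1, 0.2, 0.3, 0.4), type = "stim",
                   cond = c("a", "b", "a", "b"))
  d <- build_design(ev, model_spec("stim", "y ~ 1 + cat(cond)", c(0, 0.1),
                                   ref_levels = list(cond = "b")))
  # with reference "b", rows with cond == "b" are zero
  expect_true(all(d$values[d$events$cond == "b", 2] == 0))
  expect_true(all(d$values[d$events$cond == "a", 2] == 1))
})

test_that("imputation fills or drops missing predictor values", {
  ev <- data.frame(onset = c(0.1, 0.2, 0.3), type = "stim",
                   x = c(1, NA, 3))
  expect_equal(impute_missing(ev, "mean")$x, c(1, 2, 3))
  expect_equal(impute_missing(ev, "median")$x, c(1, 2, 3))
  expect_warning(dropped <- impute_missing(ev, "drop"), "overlap")
  expect_equal(nrow(dropped), 2)
  # marginal draws come from the observed values and are seed-reproducible
  ev2 <- data.frame(onset = seq(0.1, 2, by = 0.1), type = "stim",
                    x = c(NA, runif(18), NA))
  m1 <- impute_missing(ev2, "marginal", seed = 42)
  m2 <- impute_missing(ev2, "marginal", seed = 42)
  expect_identical(m1, m2)
  expect_true(all(m1$x[c(1, 20)] %in% ev2$x[2:19]))
  expect_error(impute_missing(ev2, "marginal"), "seed")
  ev3 <- data.frame(onset = c(0.1, 0.2), type = "stim", x = c(NA, NA))
  expect_error(impute_missing(ev3, "mean"), "cannot impute")
})

test_that("event tables are sorted with the original order retained", {
  ev <- data.frame(onset = c(0.5, 0.1, 0.3), type = "stim")
  out <- as_event_table(ev)
  expect_equal(out$onset, c(0.1, 0.3, 0.5))
  expect_equal(out$.orig_index, c(2, 3, 1))
  expect_error(as_event_table(data.frame(onset = -1, type = "a")), ">= 0")
  expect_error(as_event_table(data.frame(onset = 3, type = "a"),
                              duration = 2), "duration")
})
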
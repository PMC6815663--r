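test_that("stick-basis conversion is a pure reshape of the coefficients", {
  fx <- sim_fixture("fig10_boxcar", seed = 61)
  fit <- fit_lsmr(fx$X, fx$sim$data)
  erps <- extract_erps(fit)
  cp <- erps$components[["stim::1"]]
  expect_equal(as.numeric(cp$beta[, 1, 1]), fit$coefficients[1, ],
               tolerance = 0)
  expect_equal(cp$times, local_window(0, 0.8, fx$sc$srate)$times)
})

test_that("a band-limited kernel survives a truncated Fourier fit", {
  # kernel built from harmonics <= 3 of the window length; K = 5 keeps them
  srate <- 100; n <- 1500
  grid <- local_window(0, 0.8, srate)
  j <- seq_len(grid$n_local) - 1
  kern <- 0.8 * sin(2 * pi * 1 * j / grid$n_local) +
          0.5 * cos(2 * pi * 3 * j / grid$n_local) - 0.5
  set.seed(62)
  onsets <- sort(runif(30, 0.2, (n - 100) / srate))
  y <- numeric(n)
  for (o in onsets) {
    idx <- round(o * srate) + seq_along(kern)
    keep <- idx <= n
    y[idx[keep]] <- y[idx[keep]] + kern[keep]
  }
  ev <- data.frame(onset = onsets, type = "A")
  sp <- model_spec("A", "y ~ 1", c(0, 0.8),
                   basis = temporal_basis("fourier", K = 5))
  X <- expand_model(ev, sp, n, srate)
  fit <- fit_lsmr(X, y, tol = 1e-12)
  erps <- extract_erps(fit)
  rec <- as.numeric(erps$components[["A::1"]]$beta[, 1, 1])
  expect_lt(max(abs(rec - kern)), 1e-3)
  # low-pass property: no spectral energy above the truncation harmonic
  sp_energy <- Mod(fft(rec))^2
  hi <- sp_energy[(5 + 2):(length(rec) - 5)]   # bins above harmonic K
  expect_lt(sum(hi) / sum(sp_energy), 1e-10)
})

test_that("temporal splines smooth the estimate relative to sticks", {
  sc <- preset("fig7", seed = 63)
  sim <- simulate_scenario(sc)
  sp_stick <- model_spec("stim", "y ~ 1", c(0, 0.8))
  sp_spl <- model_spec("stim", "y ~ 1", c(0, 0.8),
                       basis = temporal_basis("spline", n_basis = 20))
  Xs <- expand_model(sim$events, sp_stick, sim$n_samples, sc$srate)
  Xp <- expand_model(sim$events, sp_spl, sim$n_samples, sc$srate)
  f_s <- fit_lsmr(Xs, sim$data)
  f_p <- fit_lsmr(Xp, sim$data)
  jump <- function(f) max(abs(diff(
    as.numeric(extract_erps(f)$components[["stim::1"]]$beta[, 1, 1]))))
  expect_lt(jump(f_p), jump(f_s))
})

test_that("baseline correction subtracts the window mean and is idempotent", {
  fx <- sim_fixture("fig10_erp", seed = 64)
  fit <- fit_lsmr(fx$X, fx$sim$data)
  erps <- extract_erps(fit)
  bl <- baseline_correct(erps, c(0.6, 0.8))
  cp <- bl$components[["stim::1"]]
  sel <- cp$times >= 0.6 & cp$times <= 0.8
  expect_equal(mean(cp$beta[sel, 1, 1]), 0, tolerance = 1e-12)
  bl2 <- baseline_correct(bl, c(0.6, 0.8))
  expect_equal(bl2$components[["stim::1"]]$beta, cp$beta, tolerance = 1e-12)
  # a constant time-course becomes all zero
  erps_const <- erps
  erps_const$components[["stim::1"]]$beta[] <- 5
  z <- baseline_correct(erps_const, c(0, 0.8))
  expect_true(all(z$components[["stim::1"]]$beta == 0))
  expect_error(baseline_correct(erps, c(5, 6)), "no samples")
})

test_that("long-format export round-trips and has the documented shape", {
  fx <- sim_fixture("fig10_boxcar", seed = 65)
  fit <- fit_lsmr(fx$X, rbind(fx$sim$data, fx$sim$data))
  erps <- extract_erps(fit)
  p <- tempfile(fileext = ".csv")
  export_long(erps, p)
  d <- read_erps_long(p)
  n_local <- local_window(0, 0.8, fx$sc$srate)$n_local
  expect_equal(nrow(d), 2 * 1 * n_local)   # channels x effect cols x times
  expect_named(d, c("channel", "event_type", "term", "effect", "time_s",
                    "beta"))
  expect_equal(d$beta[d$channel == 1],
               as.numeric(erps$components[["stim::1"]]$beta[, 1, 1]),
               tolerance = 1e-11)
  expect_equal(sort(unique(d$channel)), 1:2)
})

test_that("spline effects are zero at the model reference point", {
  set.seed(66)
  sc <- preset("fig1", seed = 66)
  sim <- simulate_scenario(sc)
  sp <- model_spec("stimulus", "y ~ 1 + cat(is_face) + spl(luminance,5)",
                   c(0, 0.6))
  X <- expand_model(sim$events, sp, sim$n_samples, sc$srate)
  fit <- fit_lsmr(X, sim$data)
  erps <- extract_erps(fit)
  meta <- erps$components[["stimulus::spl(luminance,5)"]]$meta
  eff <- evaluate_spline_effect(erps, "luminance", meta$ref_x)
  expect_lt(max(abs(eff)), 1e-9)
})

test_that("spline fit of a linear effect yields a monotone effect curve", {
  set.seed(67)
  srate <- 100; n <- 6000
  kern <- make_kernel("auditory_erp", srate = srate, duration = 0.4)
  onsets <- sort(runif(150, 0.2, (n - 60) / srate))
  x <- runif(150, 0, 2)
  y <- numeric(n)
  for (i in seq_along(onsets)) {
    idx <- round(onsets[i] * srate) + seq_along(kern$x)
    keep <- idx <= n
    y[idx[keep]] <- y[idx[keep]] + (1 + 0.8 * x[i]) * kern$x[keep]
  }
  ev <- data.frame(onset = onsets, type = "A", x = x)
  sp <- model_spec("A", "y ~ 1 + spl(x,5)", c(0, 0.4))
  X <- expand_model(ev, sp, n, srate)
  fit <- fit_lsmr(X, y, tol = 1e-12)
  erps <- extract_erps(fit)
  # at the kernel's (negative) N1 peak the effect must be monotone in x
  peak_tau <- which.min(kern$x)
  vals <- seq(0.1, 1.9, length.out = 9)
  eff <- evaluate_spline_effect(erps, "x", vals)
  expect_true(all(diff(eff[peak_tau, ]) < 0))  # more x -> more negative N1
  # and the fitted effect curve is essentially the linear truth
  truth <- 0.8 * (vals - erps$components[["A::spl(x,5)"]]$meta$ref_x) *
    kern$x[peak_tau]
  expect_gt(summary(lm(eff[peak_tau, ] ~ truth))$r.squared, 0.99)
})

test_that("unknown predictors are rejected by effect evaluation", {
  fx <- sim_fixture("fig10_boxcar", seed = 68)
  fit <- fit_lsmr(fx$X, fx$sim$data)
  erps <- extract_erps(fit)
  expect_error(evaluate_spline_effect(erps, "nope", 1), "no spline term")
})

test_that("the fitted signal reconstructs noise-free recordings", {
  fx <- sim_fixture("fig10_pink", seed = 69)
  fit <- fit_lsmr(fx$X, fx$sim$data, tol = 1e-12)
  yhat <- fitted_signal(fit)
  y <- fx$sim$data
  expect_lt(sqrt(sum((yhat - y)^2)) / sqrt(sum(y^2)), 1e-6)
})

test_that("deconvolution plus spline modeling removes spurious differences", {
  sc <- preset("fig1", seed = 70)
  sim <- simulate_scenario(sc)
  srate <- sc$srate
  grid <- local_window(0, 0.6, srate)
  stim <- sim$events[sim$events$type == "stimulus", ]
  # naive condition difference: epoch averages face minus house
  ep <- cut_epochs(sim$data, onsets_to_samples(stim$onset, srate), grid)
  kept <- attr(ep, "kept")
  face <- stim$is_face[kept] == "face"
  naive_diff <- apply(ep[1, face, , drop = FALSE], 3, mean) -
    apply(ep[1, !face, , drop = FALSE], 3, mean)
  # deconvolution with luminance spline + button-press model
  specs <- list(
    model_spec("stimulus", "y ~ 1 + cat(is_face) + spl(luminance,5)",
               c(0, 0.6), ref_levels = list(is_face = "house")),
    model_spec("button", "y ~ 1", c(-0.3, 0.3)))
  X <- expand_model(sim$events, specs, sim$n_samples, srate)
  fit <- fit_lsmr(X, sim$data, tol = 1e-12)
  erps <- extract_erps(fit)
  # with reference level "house", the factor coefficient is face - house
  model_diff <- as.numeric(
    erps$components[["stimulus::cat(is_face)"]]$beta[, 1, 1])
  # ground truth: the face condition adds exactly the N170 component
  n170 <- sc$event_types$stimulus$components[[2]]$kernel$x
  true_n170_win <- abs(n170) > 0.05 * max(abs(n170))
  # outside the true N170 window, the naive difference shows large spurious
  # structure; the model difference does not
  spurious_naive <- max(abs(naive_diff[!true_n170_win]))
  spurious_model <- max(abs(model_diff[!true_n170_win]))
  expect_gt(spurious_naive, 0.1 * max(abs(n170)))
  expect_lt(spurious_model, 0.1 * spurious_naive)
  # and the modeled difference matches the true component closely
  expect_gt(cor(model_diff, n170), 0.99)
})

test_that("the log-luminance modulation is recovered by the spline term", {
  sc <- preset("fig1", seed = 71)
  sim <- simulate_scenario(sc)
  specs <- list(
    model_spec("stimulus", "y ~ 1 + cat(is_face) + spl(luminance,5)",
               c(0, 0.6)),
    model_spec("button", "y ~ 1", c(-0.3, 0.3)))
  X <- expand_model(sim$events, specs, sim$n_samples, sc$srate)
  fit <- fit_lsmr(X, sim$data, tol = 1e-12)
  erps <- extract_erps(fit)
  p1 <- sc$event_types$stimulus$components[[3]]
  stim <- sim$events[sim$events$type == "stimulus", ]
  lo <- quantile(stim$luminance, 0.1); hi <- quantile(stim$luminance, 0.9)
  eff <- evaluate_spline_effect(erps, "luminance", c(lo, hi))
  got <- eff[, 2] - eff[, 1]
  want <- p1$beta * (log(hi) - log(lo)) * p1$kernel$x
  expect_gt(cor(got, want), 0.95)
})
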
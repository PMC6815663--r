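test_that("onset-to-sample conversion rounds half to even", {
  expect_equal(onsets_to_samples(0, 500), 0L)
  expect_equal(onsets_to_samples(0.25, 500), 125L)
  expect_equal(onsets_to_samples(1.0005, 1000), 1000L)  # tie -> even
  expect_equal(onsets_to_samples(1.0015, 1000), 1002L)  # tie -> even
})

test_that("local window grids have the documented sample counts", {
  g <- local_window(-0.1, 0.5, 100)
  expect_equal(g$n_local, 61)
  expect_equal(range(g$k), c(-10, 50))
  expect_equal(local_window(0, 0.004, 1000)$n_local, 5)
  expect_equal(local_window(-1.5, 1.0, 200)$n_local, 501)
  expect_equal(g$times, g$k / 100)
  expect_error(local_window(0.5, 0.1, 100), "tau_min < tau_max")
  expect_error(local_window(0, 0.004, 100), "fewer than 2")
})

test_that("temporal basis transforms have the specified structure", {
  expect_identical(basis_transform(temporal_basis("stick"), 10), diag(10))
  # Fourier: 2K+1 pairwise-orthonormal columns
  Tf <- basis_transform(temporal_basis("fourier", K = 2), 100)
  expect_equal(dim(Tf), c(100, 5))
  expect_lt(max(abs(crossprod(Tf) - diag(5))), 1e-10)
  # temporal splines: partition of unity across the window
  Ts <- basis_transform(temporal_basis("spline", n_basis = 45), 500)
  expect_equal(dim(Ts), c(500, 45))
  expect_lt(max(abs(rowSums(Ts) - 1)), 1e-9)
  expect_error(basis_transform(temporal_basis("fourier", K = 10), 12),
               "2K \\+ 1")
  expect_error(basis_transform(temporal_basis("spline", n_basis = 20), 15),
               "n_basis < n_local")
})

test_that("time expansion reproduces the worked toy example", {
  # events of type A at samples 21 and 25, type B at 22; stick basis;
  # 5-sample window starting at onset
  ev <- data.frame(onset = c(21, 25, 22) / 100, type = c("A", "A", "B"))
  X <- expand_model(ev, list(model_spec("A", "y ~ 1", c(0, 0.04)),
                             model_spec("B", "y ~ 1", c(0, 0.04))),
                    n_samples = 40, srate = 100)
  row25 <- X$X[26, ]                    # 0-based sample 25
  nz <- which(row25 != 0)
  expect_length(nz, 3)
  expect_true(all(row25[nz] == 1))
  got <- X$colmap[nz, c("event_type", "local_sample")]
  expect_equal(got$event_type, c("A", "A", "B"))
  expect_setequal(paste(got$event_type, got$local_sample),
                  c("A 4", "B 3", "A 0"))
})

test_that("a single event's stick expansion is the identity on its window", {
  ev <- data.frame(onset = 0.05, type = "A")
  X <- expand_model(ev, model_spec("A", "y ~ 1", c(0, 0.04)), 20, 100)
  expect_equal(as.matrix(X$X[6:10, ]), diag(5), ignore_attr = TRUE)
})

test_that("same-cell collisions are summed", {
  ev <- data.frame(onset = c(0.05, 0.05), type = "A")
  X <- expand_model(ev, model_spec("A", "y ~ 1", c(0, 0.04)), 20, 100)
  expect_equal(as.matrix(X$X[6:10, ]), 2 * diag(5), ignore_attr = TRUE)
})

test_that("stick expansion satisfies the convolution identity exactly", {
  set.seed(21)
  for (trial in 1:3) {
    srate <- 100; n <- 600
    types <- c("A", "B")
    # integer-valued kernels so both sides sum exactly
    kern <- list(A = as.numeric(sample(-5:5, 31, TRUE)),
                 B = as.numeric(sample(-5:5, 31, TRUE)))
    ev <- data.frame(
      onset = sort(runif(25, 0.2, (n - 40) / srate)),
      type = sample(types, 25, TRUE))
    specs <- lapply(types, function(tp)
      model_spec(tp, "y ~ 1", c(0, 0.3)))
    X <- expand_model(ev, specs, n, srate)
    beta <- c(kern$A, kern$B)
    got <- as.numeric(X$X %*% beta)
    # independent construction: place kernels at onsets and sum
    want <- numeric(n)
    for (i in seq_len(nrow(ev))) {
      s <- round(ev$onset[i] * srate)
      idx <- s + seq_len(31)
      keep <- idx <= n
      want[idx[keep]] <- want[idx[keep]] + kern[[ev$type[i]]][keep]
    }
    expect_identical(got, want)
  }
})

test_that("stick sparsity equals events x window x predictors without truncation", {
  set.seed(22)
  ev <- data.frame(onset = sort(runif(12, 0.5, 3)), type = "A",
                   x = rnorm(12))
  X <- expand_model(ev, model_spec("A", "y ~ 0 + x", c(0, 0.2)), 500, 100)
  # x values are continuous so no exact collisions; nnz = 12 * 21 * 1
  expect_equal(Matrix::nnzero(X$X), 12 * 21)
})

test_that("partial windows at the recording edges are truncated", {
  ev <- data.frame(onset = c(0.0, 0.18), type = "A")
  X <- expand_model(ev, model_spec("A", "y ~ 1", c(-0.05, 0.05)), 20, 100)
  expect_equal(nrow(X$X), 20)
  # first event keeps 6 of 11 samples (pre-onset part cut), second keeps 7
  expect_equal(Matrix::nnzero(X$X), 6 + 7)
})

test_that("assemble concatenates blocks along columns", {
  ev <- data.frame(onset = c(0.05, 0.1), type = c("A", "B"))
  bA <- time_expand(build_design(ev, model_spec("A", "y ~ 1", c(0, 0.04))),
                    30, 100)
  bB <- time_expand(build_design(ev, model_spec("B", "y ~ 1", c(0, 0.06))),
                    30, 100)
  both <- assemble(list(bA, bB))
  expect_equal(ncol(both$X), ncol(bA$X) + ncol(bB$X))
  expect_equal(nrow(both$colmap), ncol(both$X))
  expect_identical(assemble(list(bA))$X, bA$X)
  expect_error(assemble(list()), "at least one")
  bC <- time_expand(build_design(ev, model_spec("B", "y ~ 1", c(0, 0.06))),
                    40, 100)
  expect_error(assemble(list(bA, bC)), "row counts")
})

test_that("continuous covariates append a single untransformed column", {
  ev <- data.frame(onset = 0.05, type = "A")
  X <- expand_model(ev, model_spec("A", "y ~ 1", c(0, 0.04)), 200, 100)
  X0 <- add_continuous_covariate(X, rep(0, 200), "flat")
  expect_equal(ncol(X0$X), ncol(X$X) + 1)
  expect_equal(sum(abs(X0$X[, ncol(X0$X)])), 0)
  expect_error(add_continuous_covariate(X, rep(0, 100), "short"), "length")
  expect_error(add_continuous_covariate(X, c(NaN, rep(0, 199)), "bad"),
               "finite")
  # fitting y = 2 * signal with no event overlap recovers beta = 2 exactly
  set.seed(23)
  sig <- rnorm(200)
  Xs <- add_continuous_covariate(X, sig, "env")
  y <- 2 * sig
  fit <- fit_lsmr(Xs, y, tol = 1e-12)
  expect_equal(fit$coefficients[1, ncol(Xs$X)], 2, tolerance = 1e-8)
})

test_that("expanded designs round-trip through Matrix Market + JSON", {
  ev <- data.frame(onset = c(0.05, 0.12), type = "A", x = c(1.5, -2))
  X <- expand_model(ev, model_spec("A", "y ~ 1 + x", c(0, 0.04)), 30, 100)
  base <- file.path(tempdir(), "xdc_test")
  write_expanded(X, base)
  back <- read_expanded_mtx(base)
  expect_equal(as.matrix(back$X), as.matrix(X$X), ignore_attr = TRUE)
  expect_equal(back$srate, X$srate)
  expect_equal(back$colmap$local_sample, X$colmap$local_sample)
})

test_that("events outside the recording are excluded with a warning", {
  ev <- data.frame(onset = c(0.05, 5.0), type = "A")
  expect_warning(
    X <- time_expand(build_design(ev, model_spec("A", "y ~ 1", c(0, 0.04))),
                     30, 100),
    "outside the recording")
  expect_equal(Matrix::nnzero(X$X), 5)
})
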
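# Independent oracles used to validate the implementation. These are kept
# deliberately naive (textbook recursions, brute-force enumeration) and
# share no code with the package internals.

# textbook Cox-de Boor recursion for B-spline bases of order `ord`
coxdeboor_oracle <- function(x, knots, ord = 4) {
  nb <- length(knots) - ord
  B <- vapply(seq_len(length(knots) - 1), function(i)
    as.numeric(knots[i] <= x & x < knots[i + 1]), numeric(length(x)))
  B <- matrix(B, nrow = length(x))
  for (k in 2:ord) {
    Bk <- matrix(0, length(x), length(knots) - k)
    for (i in seq_len(length(knots) - k)) {
      d1 <- knots[i + k - 1] - knots[i]
      d2 <- knots[i + k] - knots[i + 1]
      t1 <- if (d1 > 0) (x - knots[i]) / d1 * B[, i] else 0
      t2 <- if (d2 > 0) (knots[i + k] - x) / d2 * B[, i + 1] else 0
      Bk[, i] <- t1 + t2
    }
    B <- Bk
  }
  B[, seq_len(nb), drop = FALSE]
}

# linear-interpolation empirical quantile, written out by hand
quantile_oracle <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# brute-force moving-window peak-to-peak detection over explicit positions
peak2peak_oracle <- function(data, threshold, wl, st) {
  n <- ncol(data)
  if (wl >= n) {
    any_bad <- any(apply(data, 1, function(ch) diff(range(ch))) > threshold)
    return(if (any_bad) cbind(0L, n) else cbind(integer(), integer()))
  }
  starts <- seq.int(0L, n - wl, by = st)
  if (tail(starts, 1) + wl < n) starts <- c(starts, n - wl)
  flag <- logical(length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    for (ch in seq_len(nrow(data))) {
      seg <- data[ch, (s + 1):(s + wl)]
      if (max(seg) - min(seg) > threshold) flag[k] <- TRUE
    }
  }
  if (!any(flag)) return(cbind(integer(), integer()))
  # merge
  ss <- starts[flag]; ee <- ss + wl
  ms <- ss[1]; me <- ee[1]; out <- NULL
  for (i in seq_along(ss)[-1]) {
    if (ss[i] <= me) me <- max(me, ee[i])
    else { out <- rbind(out, c(ms, me)); ms <- ss[i]; me <- ee[i] }
  }
  rbind(out, c(ms, me))
}

# dense direct least-squares solve
dense_ls_oracle <- function(X, y) qr.coef(qr(as.matrix(X)), y)

# wrap an arbitrary matrix as a minimal expanded design for solver tests
fake_expanded <- function(X, srate = 100) {
  X <- methods::as(methods::as(Matrix::Matrix(X), "generalMatrix"),
                   "CsparseMatrix")
  structure(list(X = X, colmap = data.frame(col = seq_len(ncol(X))),
                 srate = srate, n_samples = nrow(X), blocks = list(),
                 blanked = NULL),
            class = "erp_expanded")
}

# standard small simulated fixture: one event type, intercept-only model
sim_fixture <- function(preset_name = "fig10_boxcar", seed = 7,
                        formula = "y ~ 1") {
  sc <- preset(preset_name, seed = seed)
  sim <- simulate_scenario(sc)
  sp <- model_spec(names(sc$event_types)[1], formula, c(0, 0.8))
  X <- expand_model(sim$events, sp, sim$n_samples, sc$srate)
  list(sc = sc, sim = sim, spec = sp, X = X)
}
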
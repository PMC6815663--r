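# ---------------------------------------------------------------------------
# Synthetic continuous recordings with known ground truth.
#
# The simulator produces the validation scenarios used throughout the test
# suite: event trains with normally distributed inter-event intervals,
# fixed response kernels per event type (boxcar, Dirac, parametric ERP,
# pink noise), additive linear / logarithmic covariate modulations of
# individual response components, correlated covariates, and additive
# Gaussian noise. Every scenario returns its exact noiseless kernels so
# recovery error is computable without re-derivation.
# ---------------------------------------------------------------------------

#' Construct a response kernel
#'
#' Kernel shapes: `boxcar` is 1 on `[t_on, t_off)` and 0 elsewhere;
#' `dirac` is a single unit sample at `at` seconds; `auditory_erp` is a
#' parametric ERP-like waveform, the sum of three Gaussian components
#' (positive P1, negative N1, positive P2) with configurable amplitudes,
#' latencies and widths; `pinknoise` is a seeded 1/f-shaped noise segment
#' normalized to unit peak; `custom` takes `params$values` directly.
#'
#' Defaults: boxcar `t_on = 0.1`, `t_off = 0.4`; dirac `at = 0.1`;
#' auditory ERP components (amplitude, latency s, width s) = P1 (0.5, 0.05,
#' 0.015), N1 (-1, 0.1, 0.025), P2 (0.8, 0.2, 0.045); pink noise
#' `seed = 1`.
#'
#' @param name one of `"boxcar"`, `"dirac"`, `"auditory_erp"`,
#'   `"pinknoise"`, `"custom"`.
#' @param params named list of shape parameters (see Details).
#' @param srate sampling rate in Hz.
#' @param duration kernel support in seconds (default 0.8); the kernel has
#'   `local_window(0, duration, srate)$n_local` samples.
#' @return an object of class `erp_kernel` with elements `name`, `x`
#'   (sample vector), `times`, `srate`, `params`.
#' @export
make_kernel <- function(name = c("boxcar", "dirac", "auditory_erp",
                                 "pinknoise", "custom"),
                        params = list(), srate, duration = 0.8) {
  name <- match.arg(name)
  stopifnot(srate > 0, duration > 0)
  grid <- local_window(0, duration, srate)
  tt <- grid$times
  x <- switch(name,
    boxcar = {
      t_on <- params$t_on %||% 0.1
      t_off <- params$t_off %||% 0.4
      if (!(t_on < t_off)) stop("boxcar needs t_on < t_off")
      as.numeric(tt >= t_on & tt < t_off)
    },
    dirac = {
      at <- params$at %||% 0.1
      v <- numeric(grid$n_local)
      idx <- which.min(abs(tt - at))
      v[idx] <- 1
      v
    },
    auditory_erp = {
      comps <- params$components %||% list(
        c(amp = 0.5, lat = 0.05, width = 0.015),
        c(amp = -1.0, lat = 0.10, width = 0.025),
        c(amp = 0.8, lat = 0.20, width = 0.045))
      Reduce(`+`, lapply(comps, function(cmp)
        cmp[["amp"]] * exp(-0.5 * ((tt - cmp[["lat"]]) / cmp[["width"]])^2)))
    },
    pinknoise = {
      seed <- params$seed %||% 1
      rng <- local_rng(seed); on.exit(rng(), add = TRUE)
      n <- grid$n_local
      nf <- floor(n / 2)
      spec <- complex(real = rnorm(nf), imaginary = rnorm(nf)) /
        sqrt(seq_len(nf))                      # amplitude ~ 1/sqrt(f)
      full <- complex(length.out = n)
      full[2:(nf + 1)] <- spec
      if (n %% 2 == 0) full[nf + 1] <- complex(real = Re(full[nf + 1]))
      if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
      v <- Re(fft(full, inverse = TRUE)) / n
      v / max(abs(v))
    },
    custom = {
      v <- params$values
      if (is.null(v) || length(v) != grid$n_local)
        stop("custom kernel needs params$values of length ", grid$n_local)
      as.numeric(v)
    })
  if (any(!is.finite(x))) stop("kernel contains non-finite values")
  structure(list(name = name, x = x, times = tt, srate = srate,
                 duration = duration, params = params),
            class = "erp_kernel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.erp_kernel <- function(x, ...) {
  cat(sprintf("<kernel> %s: %d samples @ %g Hz, peak %.3g\n", x$name,
              length(x$x), x$srate, max(abs(x$x))))
  invisible(x)
}

#' Define a simulation scenario
#'
#' @param srate sampling rate in Hz.
#' @param duration recording duration in seconds.
#' @param event_types named list; each element describes one event type
#'   with fields: `isi_mean`, `isi_sd` (seconds; inter-event intervals are
#'   drawn from a normal distribution truncated below at 2 samples),
#'   optional `n_events` (stop after this many events instead of at
#'   `duration`), optional `derived_from` + `delay` (onsets = parent onsets
#'   plus a per-event normal delay, e.g. button presses at stimulus +
#'   reaction time; `delay = list(mean, sd)` or `list(by, means, sd)` with
#'   per-level means keyed by the values of covariate `by`), and
#'   `components`: list of response components, each
#'   `list(kernel, covariate = NULL, effect = "none"|"linear"|"log"|"level",
#'   beta = 1, level = NULL)`. A component contributes
#'   `beta * g(x_i) * kernel` to each event `i`, with `g` = 1 (none), `x`
#'   (linear), `log(x)` (log), or `x == level` (level).
#' @param covariates named list of per-event covariate specs:
#'   `list(dist = "normal"|"uniform"|"factor", par = c(...),
#'   levels =, prob =, shift = list(by, level, delta))`. `shift` adds
#'   `delta` when factor covariate `by` equals `level` (condition-dependent
#'   confounds).
#' @param covariate_corr optional `list(pair = c(name_a, name_b), r = ...)`:
#'   the two covariates are drawn from a Gaussian copula with the given
#'   target Pearson correlation.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed mandatory integer seed.
#' @return an object of class `erp_scenario`.
#' @export
sim_scenario <- function(srate, duration, event_types, covariates = list(),
                         covariate_corr = NULL, noise_sd = 0, seed) {
  if (missing(seed)) stop("scenario seed is mandatory")
  for (et in names(event_types)) {
    e <- event_types[[et]]
    if (is.null(e$derived_from)) {
      if (is.null(e$isi_mean) || e$isi_mean <= 0)
        stop("event type '", et, "': isi_mean must be > 0")
    }
    if (!length(e$components))
      stop("event type '", et, "' has no response components")
  }
  structure(list(srate = srate, duration = duration,
                 event_types = event_types, covariates = covariates,
                 covariate_corr = covariate_corr, noise_sd = noise_sd,
                 seed = seed),
            class = "erp_scenario")
}

# truncated-normal ISI draws (lower bound = 2 samples)
draw_isis <- function(n, mean, sd, lower) {
  if (mean <= lower)
    stop("infeasible ISI spec: mean must exceed the 2-sample lower bound")
  out <- numeric(0)
  while (length(out) < n) {
    cand <- rnorm(n, mean, sd)
    out <- c(out, cand[cand >= lower])
  }
  out[seq_len(n)]
}

draw_covariate_values <- function(spec, n, z = NULL) {
  # z: standard-normal column (Gaussian copula) or NULL for a fresh draw
  switch(spec$dist %||% "normal",
    normal = {
      par <- spec$par %||% c(0, 1)
      zz <- z %||% rnorm(n)
      par[1] + par[2] * zz
    },
    uniform = {
      par <- spec$par %||% c(0, 1)
      u <- if (is.null(z)) runif(n) else stats::pnorm(z)
      par[1] + (par[2] - par[1]) * u
    },
    factor = {
      lev <- spec$levels %||% c("a", "b")
      prob <- spec$prob %||% rep(1 / length(lev), length(lev))
      u <- if (is.null(z)) runif(n) else stats::pnorm(z)
      lev[findInterval(u, cumsum(prob), rightmost.closed = TRUE) + 1L]
    },
    stop("unknown covariate distribution '", spec$dist, "'"))
}

#' Draw the event table of a scenario
#'
#' Event onsets are cumulative sums of truncated-normal inter-event
#' intervals, from time 0 until the duration (or `n_events`) is reached;
#' derived event types are placed at their parent's onset plus a drawn
#' delay. Covariates are drawn per their specs; a correlated pair is drawn
#' through a Gaussian copula so the sample Pearson correlation approaches
#' the target. Reproducible under the seed.
#'
#' @param scenario an `erp_scenario`.
#' @param seed seed override; defaults to the scenario's seed.
#' @return an event table (see [as_event_table()]).
#' @export
draw_events <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "erp_scenario"))
  rng <- local_rng(seed); on.exit(rng(), add = TRUE)
  lower <- 2 / scenario$srate
  tabs <- list()
  for (et in names(scenario$event_types)) {
    e <- scenario$event_types[[et]]
    if (!is.null(e$derived_from)) next
    if (!is.null(e$n_events)) {
      isis <- draw_isis(e$n_events, e$isi_mean, e$isi_sd, lower)
      onsets <- cumsum(isis)
      if (utils::tail(onsets, 1) >= scenario$duration)
        stop("event type '", et, "': ", e$n_events,
             " events do not fit into the duration")
    } else {
      n_guess <- ceiling(scenario$duration / e$isi_mean * 1.5) + 10
      onsets <- cumsum(draw_isis(n_guess, e$isi_mean, e$isi_sd, lower))
      onsets <- onsets[onsets < scenario$duration]
    }
    tabs[[et]] <- data.frame(onset = onsets, type = et,
                             stringsAsFactors = FALSE)
    # covariates for this event type
    n <- nrow(tabs[[et]])
    cov_names <- names(scenario$covariates)
    zs <- list()
    if (!is.null(scenario$covariate_corr)) {
      r <- scenario$covariate_corr$r
      pair <- scenario$covariate_corr$pair
      z1 <- rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
      zs[[pair[1]]] <- z1; zs[[pair[2]]] <- z2
    }
    for (cv in cov_names) {
      sp <- scenario$covariates[[cv]]
      tabs[[et]][[cv]] <- draw_covariate_values(sp, n, zs[[cv]])
    }
    for (cv in cov_names) {       # condition-dependent shifts after all draws
      sp <- scenario$covariates[[cv]]
      if (!is.null(sp$shift))
        tabs[[et]][[cv]] <- tabs[[et]][[cv]] +
          sp$shift$delta * (tabs[[et]][[sp$shift$by]] == sp$shift$level)
    }
  }
  for (et in names(scenario$event_types)) {
    e <- scenario$event_types[[et]]
    if (is.null(e$derived_from)) next
    parent <- tabs[[e$derived_from]]
    if (is.null(parent)) stop("derived event type '", et,
                              "': unknown parent '", e$derived_from, "'")
    n <- nrow(parent)
    d <- e$delay
    mu <- if (!is.null(d$by)) unname(d$means[as.character(parent[[d$by]])])
          else rep(d$mean, n)
    delay <- pmax(lower, rnorm(n, mu, d$sd))
    tabs[[et]] <- data.frame(onset = parent$onset + delay, type = et,
                             stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, lapply(tabs, function(d) {
    for (cl in setdiff(unique(unlist(lapply(tabs, names))), names(d)))
      d[[cl]] <- NA
    d
  }))
  ev <- ev[ev$onset >= 0 & ev$onset < scenario$duration, , drop = FALSE]
  rownames(ev) <- NULL
  as_event_table(ev, duration = scenario$duration)
}

component_scale <- function(comp, ev_rows) {
  beta <- comp$beta %||% 1
  switch(comp$effect %||% "none",
    none = rep(beta, nrow(ev_rows)),
    linear = beta * as.numeric(ev_rows[[comp$covariate]]),
    log = beta * log(as.numeric(ev_rows[[comp$covariate]])),
    level = beta * as.numeric(ev_rows[[comp$covariate]] == comp$level),
    stop("unknown effect '", comp$effect, "'"))
}

#' Render the continuous recording of a scenario
#'
#' Sums, for every event, each response component scaled by its covariate
#' effect, at the event's onset (overlapping responses add up linearly),
#' truncating at the recording edges, then adds Gaussian noise.
#'
#' @param events event table (from [draw_events()]).
#' @param scenario the `erp_scenario`.
#' @param seed seed override for the noise draw; defaults to
#'   `scenario$seed + 1`.
#' @return list with `data` (1 x samples matrix), `clean` (noiseless
#'   signal), `truth` (per event type: the noiseless kernel components and
#'   the summed fixed-effect kernel `kernel`, i.e. what an intercept-only
#'   deconvolution should recover), `srate`, `n_samples`.
#' @export
render_continuous <- function(events, scenario, seed = scenario$seed + 1) {
  stopifnot(inherits(scenario, "erp_scenario"))
  n <- round(scenario$duration * scenario$srate)
  y <- numeric(n)
  truth <- list()
  for (et in names(scenario$event_types)) {
    e <- scenario$event_types[[et]]
    rows <- events[events$type == et, , drop = FALSE]
    onset_s <- onsets_to_samples(rows$onset, scenario$srate)
    fixed <- NULL
    for (comp in e$components) {
      kx <- comp$kernel$x
      scales <- component_scale(comp, rows)
      for (i in seq_len(nrow(rows))) {
        idx <- onset_s[i] + seq_along(kx)       # 1-based rows, onset at k=0
        keep <- idx >= 1 & idx <= n
        y[idx[keep]] <- y[idx[keep]] + scales[i] * kx[keep]
      }
      if ((comp$effect %||% "none") == "none") {
        contrib <- (comp$beta %||% 1) * kx
        fixed <- if (is.null(fixed)) contrib else fixed + contrib
      }
    }
    if (is.null(fixed)) fixed <- numeric(length(e$components[[1]]$kernel$x))
    truth[[et]] <- list(kernel = fixed,
                        times = e$components[[1]]$kernel$times,
                        components = e$components)
  }
  clean <- y
  if (scenario$noise_sd > 0) {
    rng <- local_rng(seed); on.exit(rng(), add = TRUE)
    y <- y + rnorm(n, 0, scenario$noise_sd)
  }
  list(data = matrix(y, nrow = 1, dimnames = list("ch1", NULL)),
       clean = clean, truth = truth, srate = scenario$srate, n_samples = n)
}

#' Simulate a scenario end to end
#'
#' @param scenario an `erp_scenario`.
#' @param seed seed override.
#' @return list with `events`, plus everything [render_continuous()]
#'   returns.
#' @export
simulate_scenario <- function(scenario, seed = scenario$seed) {
  events <- draw_events(scenario, seed)
  out <- render_continuous(events, scenario, seed + 1)
  out$events <- events
  out$scenario <- scenario
  out
}

#' Preset validation scenarios
#'
#' Fully parameterized scenarios used for validation:
#' * `fig10_boxcar`, `fig10_dirac`, `fig10_erp`, `fig10_pink`: 5 s of
#'   noise-free continuous data, one event type, inter-event intervals
#'   normal(0.25 s, 0.05 s), one of the four kernel shapes; an
#'   intercept-only deconvolution must recover the kernel exactly.
#' * `fig7`: 38 events with an ERP-like kernel, a linear covariate effect
#'   plus a second, truly null covariate correlated r = 0.85 with the
#'   first, additive Gaussian noise of SD 1 (the regularization
#'   demonstration).
#' * `fig1`: a stimulus-discrimination experiment: stimulus events with a
#'   condition effect (extra N170-like negativity for faces), a
#'   logarithmic luminance effect on the P1 component (luminance slightly
#'   higher for faces), and button-press events at stimulus onset plus a
#'   condition-dependent reaction time -- the scenario in which naive
#'   averaging shows spurious condition differences that deconvolution
#'   plus spline modeling removes.
#'
#' Sampling rates, effect sizes, and reaction-time distributions not fixed
#' by the scenario definitions above are package defaults (see the methods
#' vignette).
#'
#' @param name preset name.
#' @param seed scenario seed (default 1001).
#' @return an `erp_scenario`.
#' @export
preset <- function(name = c("fig10_boxcar", "fig10_dirac", "fig10_erp",
                            "fig10_pink", "fig7", "fig1"), seed = 1001) {
  name <- match.arg(name)
  srate <- if (name == "fig1") 100 else 200
  if (startsWith(name, "fig10")) {
    kname <- switch(name, fig10_boxcar = "boxcar", fig10_dirac = "dirac",
                    fig10_erp = "auditory_erp", fig10_pink = "pinknoise")
    k <- make_kernel(kname, srate = srate, duration = 0.8)
    return(sim_scenario(
      srate = srate, duration = 5,
      event_types = list(stim = list(isi_mean = 0.25, isi_sd = 0.05,
                                     components = list(list(kernel = k)))),
      noise_sd = 0, seed = seed))
  }
  if (name == "fig7") {
    srate <- 100
    k <- make_kernel("auditory_erp", srate = srate, duration = 0.8)
    return(sim_scenario(
      srate = srate, duration = 12,
      event_types = list(stim = list(
        isi_mean = 0.25, isi_sd = 0.05, n_events = 38,
        components = list(
          list(kernel = k),
          list(kernel = k, covariate = "covariate", effect = "linear",
               beta = 0.5)))),
      covariates = list(covariate = list(dist = "normal", par = c(0, 1)),
                        random_covariate = list(dist = "normal",
                                                par = c(0, 1))),
      covariate_corr = list(pair = c("covariate", "random_covariate"),
                            r = 0.85),
      noise_sd = 1, seed = seed))
  }
  # fig1: faces/houses with luminance confound and overlapping button press
  base <- make_kernel("auditory_erp", srate = srate, duration = 0.6,
                      params = list(components = list(
                        c(amp = 1, lat = 0.1, width = 0.02),
                        c(amp = -0.6, lat = 0.25, width = 0.04),
                        c(amp = 0.4, lat = 0.4, width = 0.06))))
  p1 <- make_kernel("auditory_erp", srate = srate, duration = 0.6,
                    params = list(components = list(
                      c(amp = 1, lat = 0.1, width = 0.02))))
  n170 <- make_kernel("auditory_erp", srate = srate, duration = 0.6,
                      params = list(components = list(
                        c(amp = -1, lat = 0.17, width = 0.025))))
  motor <- make_kernel("auditory_erp", srate = srate, duration = 0.6,
                       params = list(components = list(
                         c(amp = -0.8, lat = 0.05, width = 0.05),
                         c(amp = 1.2, lat = 0.25, width = 0.08))))
  sim_scenario(
    srate = srate, duration = 80,
    event_types = list(
      stimulus = list(
        isi_mean = 1.0, isi_sd = 0.15,
        components = list(
          list(kernel = base),
          list(kernel = n170, covariate = "is_face", effect = "level",
               level = "face", beta = 1),
          list(kernel = p1, covariate = "luminance", effect = "log",
               beta = 0.25))),
      button = list(
        derived_from = "stimulus",
        delay = list(by = "is_face", means = c(face = 0.38, house = 0.48),
                     sd = 0.06),
        components = list(list(kernel = motor)))),
    covariates = list(
      is_face = list(dist = "factor", levels = c("face", "house"),
                     prob = c(0.5, 0.5)),
      luminance = list(dist = "uniform", par = c(10, 100),
                       shift = list(by = "is_face", level = "face",
                                    delta = 15))),
    noise_sd = 0, seed = seed)
}
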
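# ---------------------------------------------------------------------------
# From coefficients to regression-ERP waveforms
# ---------------------------------------------------------------------------

#' Convert fitted coefficients to rERP time-courses
#'
#' Groups the coefficient vector by (event type, term), applies the
#' temporal-basis transform to turn basis coefficients into local-time
#' courses (for the stick basis this is a pure reshape), and returns a set
#' of per-term waveforms. With treatment coding the intercept time-course is
#' the reference-condition response and the other terms are partial effects
#' (difference waves).
#'
#' @param fit an `erp_fit`.
#' @return an object of class `erp_set`: list of components, each with
#'   `event_type`, `term`, `kind`, `times` (seconds), `labels` (effect
#'   columns), `beta` (array n_local x n_effects x n_channels), and `meta`
#'   (spline basis bookkeeping for [evaluate_spline_effect()]).
#' @export
extract_erps <- function(fit) {
  stopifnot(inherits(fit, "erp_fit"))
  comps <- list()
  offset <- 0L                       # blocks occupy consecutive column runs
  for (blk in fit$blocks) {
    TT <- blk$transform
    n_b <- ncol(TT)
    dsgn <- blk$design
    blk_cols <- offset + seq_len(blk$n_pred * n_b)
    offset <- offset + blk$n_pred * n_b
    for (tm in unique(dsgn$colmap$term)) {
      pred_cols <- dsgn$colmap$col[dsgn$colmap$term == tm]
      n_eff <- length(pred_cols)
      n_chan <- nrow(fit$coefficients)
      arr <- array(0, c(blk$grid$n_local, n_eff, n_chan))
      for (e in seq_len(n_eff)) {
        cols <- blk_cols[(pred_cols[e] - 1L) * n_b + seq_len(n_b)]
        arr[, e, ] <- TT %*% t(fit$coefficients[, cols, drop = FALSE])
      }
      comps[[paste(blk$event_type, tm, sep = "::")]] <- list(
        event_type = blk$event_type, term = tm,
        kind = dsgn$colmap$kind[dsgn$colmap$term == tm][1],
        times = blk$grid$times,
        labels = dsgn$colmap$label[dsgn$colmap$term == tm],
        beta = arr, meta = dsgn$term_meta[[tm]])
    }
  }
  cc <- which(fit$colmap$kind == "continuous_covariate")
  for (i in cc) {
    comps[[paste("(continuous)", fit$colmap$term[i], sep = "::")]] <- list(
      event_type = "(continuous)", term = fit$colmap$term[i],
      kind = "continuous_covariate", times = 0,
      labels = fit$colmap$pred_label[i],
      beta = array(fit$coefficients[, fit$colmap$col[i]], c(1, 1,
                   nrow(fit$coefficients))),
      meta = NULL)
  }
  structure(list(components = comps, srate = fit$srate,
                 n_channels = nrow(fit$coefficients),
                 method = fit$info$method),
            class = "erp_set")
}

#' @export
print.erp_set <- function(x, ...) {
  cat(sprintf("<erp set> %d component(s), %d channel(s) [%s]\n",
              length(x$components), x$n_channels, x$method))
  for (nm in names(x$components)) {
    cp <- x$components[[nm]]
    cat(sprintf("  %-30s %d effect column(s) x %d time point(s)\n", nm,
                dim(cp$beta)[2], dim(cp$beta)[1]))
  }
  invisible(x)
}

find_component <- function(erps, predictor, event_type = NULL) {
  hits <- Filter(function(cp) {
    if (!cp$kind %in% c("spline", "circspline", "spline2d")) return(FALSE)
    if (!is.null(event_type) && cp$event_type != event_type) return(FALSE)
    grepl(paste0("(^|[(,])", predictor, "([,)])"), cp$term)
  }, erps$components)
  if (!length(hits))
    stop("no spline term for predictor '", predictor, "' in this model")
  hits[[1]]
}

#' Evaluate a non-linear (spline) effect at chosen predictor values
#'
#' Computes the partial effect time-course of a spline-modeled predictor at
#' given values, using the same basis (same knots, same dropped column) as
#' at fitting time. The effect is expressed relative to the model's
#' reference point (the location of the basis function dropped for
#' identifiability), so evaluating at that point gives zero for all time
#' points. Out-of-range values are clamped to the boundary knots.
#'
#' @param erps an `erp_set`.
#' @param predictor predictor name (for a 2D spline, either margin name
#'   selects the term and `values` must be a two-column matrix).
#' @param values numeric vector of evaluation values (two-column matrix for
#'   a 2D spline).
#' @param event_type optional event type to disambiguate.
#' @param channel channel index, default 1.
#' @return matrix n_local x n_values of effect amplitudes.
#' @export
evaluate_spline_effect <- function(erps, predictor, values,
                                   event_type = NULL, channel = 1L) {
  stopifnot(inherits(erps, "erp_set"))
  cp <- find_component(erps, predictor, event_type)
  meta <- cp$meta
  B_of <- function(v) {
    switch(cp$kind,
      spline = bspline_basis(v, meta$knots),
      circspline = {
        cb <- meta$cycle_bounds
        cyclic_spline_basis(v, meta$n_basis, cb[1], cb[2])
      },
      spline2d = {
        if (!is.matrix(v) || ncol(v) != 2)
          stop("2D spline terms need a two-column matrix of values")
        tensor_spline_basis(v[, 1], v[, 2], meta$n_basis,
                            meta$knots_a, meta$knots_b)
      })
  }
  B <- B_of(if (cp$kind == "spline2d") as.matrix(values)
            else as.numeric(values))
  Bref <- if (!is.na(meta$dropped[1])) {
    rv <- if (cp$kind == "spline2d") matrix(meta$ref_x, 1, 2) else meta$ref_x
    B_of(rv)
  } else matrix(0, 1, ncol(B))
  Bc <- sweep(B, 2, as.numeric(Bref), "-")
  if (!is.na(meta$dropped[1])) Bc <- Bc[, -meta$dropped, drop = FALSE]
  beta <- cp$beta[, , channel, drop = FALSE]       # n_local x n_eff
  dim(beta) <- dim(cp$beta)[1:2]
  beta %*% t(Bc)
}

#' Baseline-correct rERP time-courses
#'
#' Subtracts, from every effect time-course, its mean over the baseline
#' window. Applied to the converted waveforms (after [extract_erps()]), as
#' is appropriate for overlap-corrected estimates.
#'
#' @param erps an `erp_set`.
#' @param window `c(b0, b1)` seconds, inside the model window.
#' @return the corrected `erp_set`.
#' @export
baseline_correct <- function(erps, window) {
  stopifnot(inherits(erps, "erp_set"), length(window) == 2)
  for (nm in names(erps$components)) {
    cp <- erps$components[[nm]]
    if (cp$kind == "continuous_covariate") next
    sel <- cp$times >= window[1] & cp$times <= window[2]
    if (!any(sel))
      stop("baseline window [", window[1], ", ", window[2],
           "] contains no samples of component ", nm)
    mean_b <- apply(cp$beta[sel, , , drop = FALSE], c(2, 3), mean)
    erps$components[[nm]]$beta <-
      sweep(cp$beta, c(2, 3), mean_b, "-")
  }
  erps
}

#' Export rERP waveforms as long-format CSV
#'
#' One row per (channel, event type, term, effect column, time point) with
#' the coefficient amplitude, written with 12 significant digits so a
#' read-back reproduces the set to float precision.
#'
#' @param erps an `erp_set`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_long <- function(erps, path) {
  stopifnot(inherits(erps, "erp_set"))
  rows <- lapply(names(erps$components), function(nm) {
    cp <- erps$components[[nm]]
    d <- dim(cp$beta)
    data.frame(
      channel = rep(seq_len(d[3]), each = d[1] * d[2]),
      event_type = cp$event_type,
      term = cp$term,
      effect = rep(rep(cp$labels, each = d[1]), d[3]),
      time_s = rep(cp$times, d[2] * d[3]),
      beta = as.numeric(cp$beta),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(channel = integer(), event_type = character(),
                      term = character(), effect = character(),
                      time_s = numeric(), beta = numeric())
  out$time_s <- sprintf("%.12g", out$time_s)
  out$beta <- sprintf("%.12g", out$beta)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a long-format rERP export
#'
#' @param path CSV written by [export_long()].
#' @return data.frame with numeric `time_s` and `beta`.
#' @export
read_erps_long <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$channel <- as.integer(d$channel)
  d$time_s <- as.numeric(d$time_s)
  d$beta <- as.numeric(d$beta)
  d
}
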
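# ---------------------------------------------------------------------------
# Time expansion: instance-level design -> sparse continuous-time design
# ---------------------------------------------------------------------------

#' Describe a temporal basis for time expansion
#'
#' The temporal basis maps basis coefficients to local-time courses within
#' the estimation window. `stick` (FIR) uses one indicator per local time
#' sample (the default and the recommended choice); `spline` uses `n_basis`
#' cubic B-splines on equally spaced knots across the window, smoothing
#' neighbouring time points; `fourier` uses a truncated Fourier set
#' (constant plus `K` cosine/sine harmonic pairs), which acts as a low-pass
#' filter on the estimated response.
#'
#' @param kind `"stick"`, `"spline"`, or `"fourier"`.
#' @param n_basis number of temporal splines (spline kind only).
#' @param K number of harmonic pairs (fourier kind only); yields `2K + 1`
#'   columns.
#' @return an object of class `erp_temporal_basis`.
#' @export
temporal_basis <- function(kind = c("stick", "spline", "fourier"),
                           n_basis = NULL, K = NULL) {
  kind <- match.arg(kind)
  if (kind == "spline") {
    if (is.null(n_basis) || n_basis < 4)
      stop("temporal spline basis needs n_basis >= 4")
    n_basis <- as.integer(n_basis)
  }
  if (kind == "fourier") {
    if (is.null(K) || K < 1) stop("fourier basis needs K >= 1")
    K <- as.integer(K)
  }
  structure(list(kind = kind, n_basis = n_basis, K = K),
            class = "erp_temporal_basis")
}

#' Temporal-basis transform matrix
#'
#' Builds the `n_local x n_cols` matrix `T` mapping basis coefficients to a
#' local-time course. Stick: identity. Spline: cubic B-splines on equally
#' spaced knots over the window (no column is removed; there is no intercept
#' in local time). Fourier: a constant column `1/sqrt(n_local)` followed by
#' `cos(2 pi k j / n_local)` and `sin(2 pi k j / n_local)` for `k = 1..K`,
#' `j = 0..n_local - 1`, each column l2-normalized.
#'
#' @param basis an `erp_temporal_basis`.
#' @param n_local number of samples in the local window.
#' @return the transform matrix.
#' @export
basis_transform <- function(basis, n_local) {
  stopifnot(inherits(basis, "erp_temporal_basis"), n_local >= 2)
  n_local <- as.integer(n_local)
  switch(basis$kind,
    stick = diag(n_local),
    spline = {
      nb <- basis$n_basis
      if (nb >= n_local)
        stop("temporal spline basis needs n_basis < n_local")
      core <- seq(0, n_local - 1, length.out = nb - 2)
      knots <- c(rep(core[1], 3), core, rep(core[length(core)], 3))
      bspline_basis(seq_len(n_local) - 1, knots)
    },
    fourier = {
      K <- basis$K
      if (2L * K + 1L > n_local)
        stop("fourier basis needs 2K + 1 <= n_local")
      j <- seq_len(n_local) - 1L
      cols <- matrix(0, n_local, 2L * K + 1L)
      cols[, 1] <- 1 / sqrt(n_local)
      for (k in seq_len(K)) {
        ck <- cos(2 * pi * k * j / n_local)
        sk <- sin(2 * pi * k * j / n_local)
        cols[, 2L * k] <- ck / sqrt(sum(ck^2))
        cols[, 2L * k + 1L] <- sk / sqrt(sum(sk^2))
      }
      cols
    }
  )
}

#' Convert event onsets from seconds to sample indices
#'
#' `sample = round(onset * srate)` with half-to-even (banker's) rounding,
#' 0-based.
#'
#' @param onsets numeric vector of onsets in seconds.
#' @param srate sampling rate in Hz.
#' @return integer vector of 0-based sample indices.
#' @export
onsets_to_samples <- function(onsets, srate) {
  stopifnot(srate > 0)
  as.integer(round(onsets * srate))
}

#' Local sample grid for an estimation window
#'
#' @param tau_min,tau_max window bounds in seconds relative to event onset,
#'   `tau_min < tau_max`.
#' @param srate sampling rate in Hz.
#' @return list with `k` (0-based local sample offsets,
#'   `round(tau_min * srate) .. round(tau_max * srate)` inclusive), `times`
#'   (`k / srate`, seconds), and `n_local`.
#' @export
local_window <- function(tau_min, tau_max, srate) {
  if (!(tau_min < tau_max)) stop("window must satisfy tau_min < tau_max")
  stopifnot(srate > 0)
  k <- seq.int(round(tau_min * srate), round(tau_max * srate))
  if (length(k) < 2) stop("window contains fewer than 2 samples")
  list(k = as.integer(k), times = k / srate, n_local = length(k))
}

#' Time-expand an instance-level design matrix
#'
#' Builds the sparse continuous-time design block for one event type: for
#' each instance `i`, predictor column `c`, and local sample `k` within the
#' window, row `onset_i + k` receives the contribution
#' `x[i, c] * T[k, b]` in column `(c, b)` for every temporal-basis column
#' `b`. Contributions of different instances landing in the same cell are
#' summed (that is what models the overlap). Rows outside the recording are
#' truncated (partial windows near the edges), and events whose onset sample
#' itself lies outside the recording are excluded with a warning.
#'
#' @param design an `erp_design` from [build_design()].
#' @param n_samples total number of samples in the continuous recording.
#' @param srate sampling rate in Hz.
#' @param window optional `c(tau_min, tau_max)` seconds; defaults to the
#'   spec's window.
#' @param basis optional `erp_temporal_basis`; defaults to the spec's basis.
#' @return an object of class `erp_expanded`: sparse matrix `X`
#'   (`n_samples` x `n_pred * n_cols_basis`), `colmap`, sampling metadata,
#'   and per-event-type block descriptors.
#' @export
time_expand <- function(design, n_samples, srate, window = NULL,
                        basis = NULL) {
  stopifnot(inherits(design, "erp_design"))
  if (ncol(design$values) == 0 || nrow(design$values) == 0)
    stop("empty design matrix")
  if (any(is.na(design$values))) stop("design matrix contains missing values")
  if (is.null(window)) window <- design$spec$window
  if (is.null(basis)) basis <- design$spec$basis
  n_samples <- as.integer(n_samples)
  grid <- local_window(window[1], window[2], srate)
  TT <- basis_transform(basis, grid$n_local)
  n_b <- ncol(TT)
  X <- design$values
  n_pred <- ncol(X)
  onset_s <- onsets_to_samples(design$onsets, srate)
  oob <- onset_s < 0L | onset_s >= n_samples
  if (any(oob)) {
    warning(sum(oob), " event(s) with onset outside the recording excluded")
    onset_s <- onset_s[!oob]
    X <- X[!oob, , drop = FALSE]
  }
  n_inst <- length(onset_s)
  inst_rep <- rep(seq_len(n_inst), each = grid$n_local)
  j_rep <- rep(seq_len(grid$n_local), n_inst)
  rows <- onset_s[inst_rep] + grid$k[j_rep]
  valid <- rows >= 0L & rows < n_samples
  ii <- jj <- integer(0); xx <- numeric(0)
  stick <- basis$kind == "stick"
  for (c_ in seq_len(n_pred)) {
    if (stick) {
      ii <- c(ii, rows[valid] + 1L)
      jj <- c(jj, (c_ - 1L) * n_b + j_rep[valid])
      xx <- c(xx, X[inst_rep[valid], c_])
    } else {
      for (b in seq_len(n_b)) {
        v <- X[inst_rep[valid], c_] * TT[j_rep[valid], b]
        nz <- v != 0
        ii <- c(ii, rows[valid][nz] + 1L)
        jj <- c(jj, rep.int((c_ - 1L) * n_b + b, sum(nz)))
        xx <- c(xx, v[nz])
      }
    }
  }
  Xdc <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(n_samples, n_pred * n_b))
  colmap <- data.frame(
    event_type = design$spec$event_type,
    term = design$colmap$term[rep(seq_len(n_pred), each = n_b)],
    kind = design$colmap$kind[rep(seq_len(n_pred), each = n_b)],
    pred_label = design$colmap$label[rep(seq_len(n_pred), each = n_b)],
    pred_col = rep(seq_len(n_pred), each = n_b),
    basis_col = rep(seq_len(n_b), n_pred),
    local_sample = if (stick) rep(grid$k, n_pred) else NA_integer_,
    stringsAsFactors = FALSE)
  colmap$col <- seq_len(nrow(colmap))
  out <- structure(list(
    X = Xdc, colmap = colmap, srate = srate, n_samples = n_samples,
    blocks = list(list(event_type = design$spec$event_type, grid = grid,
                       basis = basis, transform = TT, n_pred = n_pred,
                       design = design))),
    class = "erp_expanded")
  if (ncol(Xdc) > n_samples)
    warning("expanded design has more columns than rows (underdetermined)")
  out
}

#' @export
print.erp_expanded <- function(x, ...) {
  cat(sprintf("<expanded design> %d samples x %d columns (%d event type(s), %.3g%% nonzero)\n",
              x$n_samples, ncol(x$X), length(x$blocks),
              100 * Matrix::nnzero(x$X) / prod(dim(x$X))))
  invisible(x)
}

#' Concatenate time-expanded blocks of several event types
#'
#' Horizontal concatenation of per-event-type expanded designs into the
#' full continuous-time design matrix.
#'
#' @param event_blocks non-empty list of `erp_expanded` objects with
#'   identical row counts and sampling rates.
#' @return a single `erp_expanded`.
#' @export
assemble <- function(event_blocks) {
  if (!length(event_blocks)) stop("assemble() needs at least one block")
  stopifnot(all(vapply(event_blocks, inherits, TRUE, "erp_expanded")))
  ns <- vapply(event_blocks, function(b) b$n_samples, 1L)
  if (length(unique(ns)) != 1) stop("mismatched row counts across blocks")
  sr <- vapply(event_blocks, function(b) b$srate, 1)
  if (length(unique(sr)) != 1) stop("mismatched sampling rates across blocks")
  if (length(event_blocks) == 1) return(event_blocks[[1]])
  X <- do.call(cbind, lapply(event_blocks, `[[`, "X"))
  colmap <- do.call(rbind, lapply(event_blocks, `[[`, "colmap"))
  colmap$col <- seq_len(nrow(colmap))
  structure(list(X = X, colmap = colmap, srate = sr[1], n_samples = ns[1],
                 blocks = do.call(c, lapply(event_blocks, `[[`, "blocks"))),
            class = "erp_expanded")
}

#' Append a time-continuous covariate column
#'
#' Adds one per-sample signal (e.g. a stimulus envelope) as a single dense
#' column of the expanded design, with no time expansion.
#'
#' @param X an `erp_expanded`.
#' @param signal numeric vector, one value per recording sample; must be
#'   finite (clean or blank beforehand).
#' @param name column name.
#' @return the augmented `erp_expanded`.
#' @export
add_continuous_covariate <- function(X, signal, name) {
  stopifnot(inherits(X, "erp_expanded"))
  if (length(signal) != X$n_samples)
    stop("signal length must equal the number of recording samples")
  if (any(!is.finite(signal)))
    stop("signal contains non-finite values; clean or blank it first")
  X$X <- cbind(X$X, Matrix::Matrix(signal, ncol = 1, sparse = TRUE))
  row <- data.frame(event_type = NA_character_, term = name,
                    kind = "continuous_covariate", pred_label = name,
                    pred_col = NA_integer_, basis_col = NA_integer_,
                    local_sample = NA_integer_,
                    col = nrow(X$colmap) + 1L, stringsAsFactors = FALSE)
  X$colmap <- rbind(X$colmap, row)
  X
}

#' Time-expand all model specs against a recording
#'
#' Convenience wrapper: builds the per-event-type designs, time-expands
#' each, and assembles the full sparse design matrix.
#'
#' @param events event table.
#' @param specs a single `erp_model_spec` or a list of them (one per event
#'   type).
#' @param n_samples,srate recording geometry.
#' @return an `erp_expanded`.
#' @export
expand_model <- function(events, specs, n_samples, srate) {
  if (inherits(specs, "erp_model_spec")) specs <- list(specs)
  blocks <- lapply(specs, function(sp)
    time_expand(build_design(events, sp), n_samples, srate))
  assemble(blocks)
}

#' Write / read an expanded design as Matrix Market plus JSON column map
#'
#' @param X an `erp_expanded`.
#' @param path base path; writes `<path>.mtx` and `<path>.json`.
#' @return `write_expanded`: the base path, invisibly. `read_expanded_mtx`:
#'   a list with the sparse matrix and the column map (inspection /
#'   cross-language checking; block metadata is not round-tripped).
#' @export
write_expanded <- function(X, path) {
  stopifnot(inherits(X, "erp_expanded"))
  Matrix::writeMM(as(X$X, "generalMatrix"), paste0(path, ".mtx"))
  jsonlite::write_json(
    list(srate = X$srate, n_samples = X$n_samples, colmap = X$colmap),
    paste0(path, ".json"), dataframe = "columns", auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' @rdname write_expanded
#' @export
read_expanded_mtx <- function(path) {
  M <- methods::as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(X = M, colmap = as.data.frame(meta$colmap), srate = meta$srate,
       n_samples = meta$n_samples)
}
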
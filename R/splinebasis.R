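# ---------------------------------------------------------------------------
# Spline basis construction for non-linear (GAM) covariate terms.
#
# Cubic B-splines: full knot vector has the boundary values at multiplicity 4
# so the basis is clamped (value (1,0,...,0) at the left boundary) and forms a
# partition of unity over the whole predictor range. With m proper interior
# knots this gives m + 4 basis functions, i.e. n_basis = length(knots) - 4.
# ---------------------------------------------------------------------------

#' Quantile-based knot vector for a cubic B-spline basis
#'
#' Places knots on the empirical quantiles of the observed predictor values:
#' `n_basis - 2` quantile levels spread evenly over \[0, 1\] (the outermost
#' two being the minimum and maximum), with each boundary value repeated to
#' multiplicity 4. The resulting full knot vector has `n_basis + 4` entries,
#' so the number of basis functions equals the knot count minus 4.
#' Quantiles use the standard linear-interpolation definition
#' (`stats::quantile` type 7).
#'
#' @param values numeric vector of observed predictor values.
#' @param n_basis requested number of basis functions (>= 2; cubic
#'   evaluation via [bspline_basis()] additionally requires >= 4).
#' @return nondecreasing numeric knot vector of length `n_basis + 4`.
#' @export
quantile_knots <- function(values, n_basis) {
  stopifnot(is.numeric(values), length(n_basis) == 1)
  n_basis <- as.integer(n_basis)
  if (n_basis < 2) stop("n_basis must be >= 2")
  v <- values[is.finite(values)]
  if (length(unique(v)) < n_basis)
    stop("degenerate predictor: need at least n_basis distinct finite values")
  if (n_basis >= 4) {
    core <- unname(quantile(v, seq(0, 1, length.out = n_basis - 2), type = 7))
    pad <- 3L
  } else if (n_basis == 3) {
    core <- unname(quantile(v, c(0, 0.5, 1), type = 7))
    pad <- 2L
  } else {
    core <- range(v)
    pad <- 2L
  }
  knots <- c(rep(core[1], pad), core, rep(core[length(core)], pad))
  if (is.unsorted(knots)) stop("internal error: knots not nondecreasing")
  if (length(knots) != n_basis + 4L)
    stop("internal error: knot count != n_basis + 4")
  knots
}

#' Evaluate a cubic B-spline basis
#'
#' Cox--de Boor cubic B-spline evaluation (via [splines::splineDesign()]) on
#' a full knot vector as produced by [quantile_knots()] (or user-supplied,
#' nondecreasing, boundary multiplicity 4). Values outside the boundary
#' knots are clamped to the nearest boundary rather than extrapolated.
#'
#' @param values numeric vector of evaluation points.
#' @param knots full nondecreasing knot vector (length = n_basis + 4).
#' @return matrix `length(values)` x `n_basis`; rows sum to 1 inside the
#'   boundaries. The knot vector is attached as attribute `"knots"`.
#' @export
bspline_basis <- function(values, knots) {
  stopifnot(is.numeric(values), is.numeric(knots))
  if (is.unsorted(knots)) stop("knots must be nondecreasing")
  n_basis <- length(knots) - 4L
  if (n_basis < 4)
    stop("cubic B-spline evaluation needs n_basis >= 4 (knot vector length >= 8)")
  lo <- knots[1]; hi <- knots[length(knots)]
  x <- pmin(pmax(values, lo), hi)
  B <- splines::splineDesign(knots, x, ord = 4)
  dimnames(B) <- NULL
  attr(B, "knots") <- knots
  B
}

#' Evaluate a cyclic (periodic) cubic B-spline basis
#'
#' Wrapped cubic B-splines on uniform knots over `[lo, hi]`, following the
#' cyclic construction of Wood (implemented by [mgcv::cSplineDes()]). Values
#' are mapped into `[lo, hi)` by modular wrapping, so `basis(lo)` equals
#' `basis(hi)` row-wise and the basis forms a partition of unity.
#'
#' @param values numeric vector (any real; wrapped modulo the cycle).
#' @param n_basis number of basis functions (>= 3).
#' @param lo,hi cycle bounds, `lo < hi` (e.g. 0 and 360 degrees).
#' @return matrix `length(values)` x `n_basis`.
#' @export
cyclic_spline_basis <- function(values, n_basis, lo, hi) {
  stopifnot(is.numeric(values), length(lo) == 1, length(hi) == 1)
  n_basis <- as.integer(n_basis)
  if (n_basis < 3) stop("cyclic cubic spline basis needs n_basis >= 3")
  if (!(lo < hi)) stop("cycle bounds must satisfy lo < hi")
  x <- lo + (values - lo) %% (hi - lo)
  knots <- seq(lo, hi, length.out = n_basis + 1L)
  B <- mgcv::cSplineDes(x, knots, ord = 4)
  dimnames(B) <- NULL
  attr(B, "knots") <- knots
  attr(B, "cycle_bounds") <- c(lo, hi)
  B
}

#' Evaluate a two-dimensional tensor-product spline basis
#'
#' Pairwise products of two one-dimensional cubic B-spline bases (each built
#' on quantile knots of its own margin), used for non-linear interactions
#' between two continuous predictors. With `n_basis` functions per margin
#' the result has `n_basis^2` columns; column `(j, k)` (column-major in the
#' first margin) is the elementwise product of basis column `j` of the first
#' margin and column `k` of the second.
#'
#' @param values_a,values_b equal-length numeric vectors.
#' @param n_basis basis functions per margin (>= 4 for cubic evaluation).
#' @param knots_a,knots_b optional precomputed knot vectors; default
#'   quantile knots from the supplied values.
#' @return matrix `length(values_a)` x `n_basis^2`.
#' @export
tensor_spline_basis <- function(values_a, values_b, n_basis,
                                knots_a = NULL, knots_b = NULL) {
  if (length(values_a) != length(values_b))
    stop("values_a and values_b must have equal length")
  if (is.null(knots_a)) knots_a <- quantile_knots(values_a, n_basis)
  if (is.null(knots_b)) knots_b <- quantile_knots(values_b, n_basis)
  Ba <- bspline_basis(values_a, knots_a)
  Bb <- bspline_basis(values_b, knots_b)
  n <- ncol(Ba)
  stopifnot(ncol(Bb) == n)
  out <- matrix(0, nrow(Ba), n * n)
  for (k in seq_len(n))
    out[, (k - 1L) * n + seq_len(n)] <- Ba * Bb[, k]
  attr(out, "knots_a") <- knots_a
  attr(out, "knots_b") <- knots_b
  out
}

# peak location of each basis function, by evaluation on a fine grid over
# the boundary-knot range; used to pick the column dropped for
# identifiability and as the reference point of spline effects
bspline_peaks <- function(knots, n_grid = 2001L) {
  lo <- knots[1]; hi <- knots[length(knots)]
  g <- seq(lo, hi, length.out = n_grid)
  B <- bspline_basis(g, knots)
  g[apply(B, 2, which.max)]
}
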
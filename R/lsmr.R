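# ---------------------------------------------------------------------------
# LSMR: iterative solver for sparse least-squares problems
# min ||A x - b||_2  (optionally damped), after Fong & Saunders (2011).
# Based on Golub-Kahan bidiagonalization; algebraically equivalent to MINRES
# applied to the normal equations, with monotone ||A'r||.
# ---------------------------------------------------------------------------

#' Iterative sparse least-squares (LSMR)
#'
#' Solves `min ||A x - b||` for a (typically sparse, tall) matrix `A`
#' without forming the normal equations.
#'
#' @param A numeric matrix or `Matrix` sparse matrix (m x n).
#' @param b numeric right-hand side of length m.
#' @param damp damping parameter (>= 0); 0 gives plain least squares.
#' @param atol,btol stopping tolerances on the normal-equation residual and
#'   the data residual.
#' @param conlim stop when the condition-number estimate exceeds this.
#' @param max_iter iteration cap; default `max(100, 5 n)`.
#' @return list with `x` (solution), `itn` (iterations used), `istop`
#'   (stopping reason code: 0 trivial, 1 residual small, 2 normal-equation
#'   residual small, 3 condition limit, 7 iteration cap), and `converged`.
#' @export
lsmr <- function(A, b, damp = 0, atol = 1e-10, btol = 1e-10, conlim = 1e10,
                 max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  if (is.null(max_iter)) max_iter <- max(100L, 5L * n)
  Av  <- function(v) as.numeric(A %*% v)
  Atu <- function(u) as.numeric(Matrix::crossprod(A, u))

  u <- b
  normb <- sqrt(sum(b * b))
  x <- numeric(n)
  beta <- normb
  if (beta > 0) u <- u / beta
  v <- if (beta > 0) Atu(u) else numeric(n)
  alpha <- sqrt(sum(v * v))
  if (alpha > 0) v <- v / alpha

  zetabar <- alpha * beta
  alphabar <- alpha
  rho <- 1; rhobar <- 1; cbar <- 1; sbar <- 0
  h <- v; hbar <- numeric(n)

  betadd <- beta; betad <- 0
  rhodold <- 1; tautildeold <- 0; thetatilde <- 0; zeta <- 0; d <- 0
  normA2 <- alpha^2
  maxrbar <- 0; minrbar <- 1e+100
  normar <- alpha * beta
  if (normar == 0)
    return(list(x = x, itn = 0L, istop = 0L, converged = TRUE))

  istop <- 7L; itn <- 0L
  while (itn < max_iter) {
    itn <- itn + 1L
    u <- Av(v) - alpha * u
    beta <- sqrt(sum(u * u))
    if (beta > 0) {
      u <- u / beta
      v <- Atu(u) - beta * v
      alpha <- sqrt(sum(v * v))
      if (alpha > 0) v <- v / alpha
    }

    if (damp > 0) {
      alphahat <- sqrt(alphabar^2 + damp^2)
      chat <- alphabar / alphahat
      shat <- damp / alphahat
    } else {
      alphahat <- alphabar; chat <- 1; shat <- 0
    }

    rhoold <- rho
    rho <- sqrt(alphahat^2 + beta^2)
    c_ <- alphahat / rho
    s_ <- beta / rho
    thetanew <- s_ * alpha
    alphabar <- c_ * alpha

    rhobarold <- rhobar
    zetaold <- zeta
    thetabar <- sbar * rho
    rhotemp <- cbar * rho
    rhobar <- sqrt((cbar * rho)^2 + thetanew^2)
    cbar <- cbar * rho / rhobar
    sbar <- thetanew / rhobar
    zeta <- cbar * zetabar
    zetabar <- -sbar * zetabar

    hbar <- h - (thetabar * rho / (rhoold * rhobarold)) * hbar
    x <- x + (zeta / (rho * rhobar)) * hbar
    h <- v - (thetanew / rho) * h

    # residual-norm estimates
    betaacute <- chat * betadd
    betacheck <- -shat * betadd
    betahat <- c_ * betaacute
    betadd <- -s_ * betaacute

    thetatildeold <- thetatilde
    rhotildeold <- sqrt(rhodold^2 + thetabar^2)
    ctildeold <- rhodold / rhotildeold
    stildeold <- thetabar / rhotildeold
    thetatilde <- stildeold * rhobar
    rhodold <- ctildeold * rhobar
    betad <- -stildeold * betad + ctildeold * betahat

    tautildeold <- (zetaold - thetatildeold * tautildeold) / rhotildeold
    taud <- (zeta - thetatilde * tautildeold) / rhodold
    d <- d + betacheck^2
    normr <- sqrt(d + (betad - taud)^2 + betadd^2)

    normA2 <- normA2 + beta^2
    normA <- sqrt(normA2)
    normA2 <- normA2 + alpha^2

    maxrbar <- max(maxrbar, rhobarold)
    if (itn > 1L) minrbar <- min(minrbar, rhobarold)
    condA <- max(maxrbar, rhotemp) / min(minrbar, rhotemp)

    normar <- abs(zetabar)
    normx <- sqrt(sum(x * x))

    test1 <- normr / normb
    test2 <- if (normA * normr != 0) normar / (normA * normr) else Inf
    test3 <- 1 / condA
    rtol <- btol + atol * normA * normx / normb
    if (1 + test3 <= 1 || test3 <= 1 / conlim) { istop <- 3L; break }
    if (1 + test2 <= 1 || test2 <= atol)       { istop <- 2L; break }
    if (1 + test1 <= 1 || test1 <= rtol)       { istop <- 1L; break }
  }
  list(x = x, itn = itn, istop = istop, converged = istop < 7L)
}
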
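#' Principal branch of the Lambert W function
#'
#' Vectorised evaluation of \eqn{W_0(x)}, the inverse of \eqn{w e^w} on
#' \eqn{w \ge -1}, for arguments \eqn{x \ge -1/e}. The closed-form spike-time
#' solution and its derivatives evaluate \eqn{W_0} once per candidate
#' threshold crossing, so this is the numerical workhorse of the package and
#' must accept whole vectors/matrices of arguments at once.
#'
#' Arguments within `branch_tol` below \eqn{-1/e} are clamped to the branch
#' point (treated as a tangency); anything further below is an error.
#'
#' @param x numeric vector (or matrix) of arguments, each `>= -1/e` up to
#'   `branch_tol`.
#' @param branch_tol tolerance below `-1/e` within which arguments are
#'   clamped to the branch point.
#' @return numeric object of the same shape as `x` with `W0(x)`.
#' @examples
#' lambert_w0(0)            # 0
#' lambert_w0(exp(1))       # 1
#' lambert_w0(-exp(-1))     # -1 (branch point)
#' @export
lambert_w0 <- function(x, branch_tol = 1e-12) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  dims <- dim(x)
  x <- as.numeric(x)
  bad <- !is.na(x) & (x < -exp(-1) - branch_tol)
  if (any(bad)) {
    stop("lambert_w0: argument below the branch point -1/e: ",
         format(min(x[bad])))
  }
  x <- pmax(x, -exp(-1))
  w <- numeric(length(x))
  w[is.na(x)] <- NA_real_
  ok <- !is.na(x)

  # initial guesses: series around the branch point for x near -1/e,
  # w ~ x for small |x|, log-based for large x
  p <- sqrt(2 * (exp(1) * x + 1))
  near <- ok & (x < -0.25)
  w[near] <- -1 + p[near] - p[near]^2 / 3 + 11 / 72 * p[near]^3
  mid <- ok & !near & (x < exp(1))
  w[mid] <- log1p(x[mid])   # crude but in the Halley basin everywhere here
  big <- ok & !near & !mid
  if (any(big)) {
    lx <- log(x[big])
    w[big] <- lx - log(lx)
  }

  # Halley iteration; quartic-ish convergence from these seeds
  for (iter in 1:20) {
    ew <- exp(w)
    f <- w * ew - x
    wp1 <- w + 1
    # guard the branch point where wp1 -> 0
    denom <- ew * wp1 - (w + 2) * f / (2 * wp1)
    denom[!is.finite(denom) | denom == 0] <- .Machine$double.eps
    dw <- f / denom
    dw[!ok] <- 0
    w <- w - dw
    if (isTRUE(all(abs(dw) <= 1e-14 * (1 + abs(w))))) break
  }
  w[ok & x == -exp(-1)] <- -1
  if (!is.null(dims)) dim(w) <- dims
  w
}
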
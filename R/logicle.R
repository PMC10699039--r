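## Logicle (biexponential) display transform, Parks-Roederer-Moore
## parameterization. Display coordinate y is normalized so that y = 1 maps
## to the top of scale T; the forward transform is obtained by numerically
## inverting the biexponential.

#' Logicle parameters
#'
#' @param T top of scale (fluorescence units), > 0.
#' @param W linearization width in decades, `0 <= W <= M/2`.
#' @param M total display decades (default 4.5).
#' @param A additional negative decades (default 0), `A >= -W`.
#' @return an object of class `LogicleParams`.
#' @export
logicleParams <- function(T, W, M = 4.5, A = 0) {
  stopifnot(is.finite(T), is.finite(W), is.finite(M), is.finite(A))
  if (T <= 0) stop("T must be > 0")
  if (M <= 0) stop("M must be > 0")
  if (W < 0 || W > M / 2) stop("W must lie in [0, M/2]")
  if (A < -W) stop("A must be >= -W")
  structure(list(T = T, W = W, M = M, A = A), class = "LogicleParams")
}

#' @export
print.LogicleParams <- function(x, ...) {
  cat(sprintf("LogicleParams: T = %g, M = %g, W = %.4f, A = %g\n",
              x$T, x$M, x$W, x$A))
  invisible(x)
}

#' Automatic logicle parameter estimation
#'
#' Chooses display parameters from the data: `T` is the largest observed
#' value, `M = 4.5` decades, `A = 0`, and the linearization width is set
#' from the 5th percentile `r` of the negative events as
#' `W = max(0, (M - log10(T/|r|)) / 2)`; with no negative events
#' `W = 0.5`.
#'
#' @param values numeric vector of fluorescence values (>= 10 finite).
#' @param M display decades (default 4.5).
#' @return a `LogicleParams` object.
#' @export
autoLogicleParams <- function(values, M = 4.5) {
  values <- values[is.finite(values)]
  if (length(values) < 10) stop("need at least 10 finite values")
  if (length(unique(values)) == 1)
    stop("degenerate input: all values identical")
  T <- max(values)
  if (T <= 0) stop("top of scale must be positive")
  neg <- values[values < 0]
  if (length(neg) == 0) {
    W <- 0.5
  } else {
    r <- quantile(neg, 0.05, names = FALSE, type = 7)
    W <- max(0, (M - log10(T / abs(r))) / 2)
    W <- min(W, M / 2)
  }
  logicleParams(T = T, W = W, M = M, A = 0)
}

## Biexponential coefficients for normalized display y in [0, 1].
.logicleCoef <- function(p) {
  tot <- p$M + p$A
  w  <- p$W / tot
  x2 <- p$A / tot
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b  <- tot * log(10)
  if (w <= .Machine$double.eps) {
    d <- b
  } else {
    ## d solves 2 ln(b/d) = w (b + d), 0 < d < b
    f <- function(d) 2 * log(b / d) - w * (b + d)
    d <- uniroot(f, c(1e-12 * b, b * (1 - 1e-12)), tol = 1e-14)$root
  }
  ca <- exp(x0 * (b + d))
  fa <- exp(b * x1) - ca * exp(-d * x1)
  a  <- p$T / (exp(b) - ca * exp(-d) - fa)
  list(a = a, b = b, c = ca * a, d = d, f = fa * a, x1 = x1, w = w)
}

#' Biexponential (inverse logicle)
#'
#' Maps display coordinates back to fluorescence; the branch below the
#' linearization midpoint is the negative reflection of the branch above,
#' making the function strictly increasing and smooth through zero.
#'
#' @param y numeric display coordinates.
#' @param p a `LogicleParams` object.
#' @return fluorescence values on the original scale.
#' @export
inverseLogicle <- function(y, p) {
  stopifnot(inherits(p, "LogicleParams"))
  cf <- .logicleCoef(p)
  pos <- y >= cf$x1
  out <- numeric(length(y))
  yy <- ifelse(pos, y, 2 * cf$x1 - y)
  s <- cf$a * exp(cf$b * yy) - cf$c * exp(-cf$d * yy) - cf$f
  out[pos] <- s[pos]
  out[!pos] <- -s[!pos]
  out
}

#' Logicle transform
#'
#' Forward logicle display transform: the strictly monotone inverse of the
#' biexponential, computed by vectorized bisection refined past 1e-10 in
#' display units. `logicleTransform(T) == 1`; values above `T` map above 1.
#'
#' @param x numeric fluorescence values (finite).
#' @param p a `LogicleParams` object.
#' @return display coordinates, approximately in `[0, 1]`.
#' @export
logicleTransform <- function(x, p) {
  stopifnot(inherits(p, "LogicleParams"))
  if (any(!is.finite(x))) stop("non-finite input to logicleTransform")
  n <- length(x)
  lo <- rep(-1.5, n)
  hi <- rep(2, n)
  ## widen bounds if needed (values far beyond the display range)
  while (any(inverseLogicle(lo, p) > x)) lo <- lo - 1
  while (any(inverseLogicle(hi, p) < x)) hi <- hi + 1
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    fm <- inverseLogicle(mid, p)
    below <- fm < x
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}
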
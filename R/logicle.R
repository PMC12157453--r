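#' Logicle (biexponential) display transform
#'
#' The logicle scale is the standard flow-cytometry display transform:
#' approximately linear around zero (so negative, background-subtracted
#' values remain visible) and logarithmic at scale. It is the inverse of
#' the biexponential
#' \deqn{B(y) = a e^{by} - c e^{-dy} + f,}
#' parameterized by the full-scale value `T`, the number of displayed
#' decades `M`, the linearization width `W` (decades) and `A` additional
#' negative decades. `B` maps display position `y` (0 at the bottom of the
#' scale, 1 at `T`) to a data value; the forward transform solves
#' `B(y) = x` for `y`, which is well defined because `B` is strictly
#' increasing. Used for histogram display only, never for metric
#' computation.
#'
#' `logicle(0)` equals `(A + W) / (M + A)`, the display position of data
#' zero.
#'
#' @param values Numeric data values (may be negative).
#' @param T_top Full-scale data value (> 0).
#' @param W Linearization width in decades (>= 0). `NULL` estimates it from
#'   the 5th percentile of the negative values via [logicle_w()].
#' @param M Total display decades (default 4.5).
#' @param A Additional negative display decades (default 0).
#' @return `logicle()`: display positions (0 to 1 over the nominal range;
#'   values outside the range map outside \[0, 1\] monotonically).
#'   `logicle_inverse()`: data values.
#' @export
logicle <- function(values, T_top, W = NULL, M = 4.5, A = 0) {
  if (is.null(W)) W <- logicle_w(values, T_top, M)
  p <- logicle_params(T_top, W, M, A)
  vapply(values, .logicle_forward, numeric(1), p = p)
}

#' @rdname logicle
#' @param y Display positions.
#' @export
logicle_inverse <- function(y, T_top, W, M = 4.5, A = 0) {
  p <- logicle_params(T_top, W, M, A)
  .biexp(y, p)
}

#' @rdname logicle
#' @export
logicle_w <- function(values, T_top, M = 4.5) {
  neg <- values[!is.na(values) & values < 0]
  if (length(neg) == 0) return(0)
  r <- stats::quantile(neg, 0.05, names = FALSE)
  w <- (M - log10(T_top / abs(r))) / 2
  min(max(w, 0), M / 2)
}

# Derived biexponential parameters; see Parks, Roederer & Moore's logicle
# construction. d solves 2(ln d - ln b) + w(b + d) = 0 on (0, b].
logicle_params <- function(T_top, W, M, A) {
  if (!is.numeric(T_top) || length(T_top) != 1 || T_top <= 0) {
    stop("T_top must be a single positive number")
  }
  if (M <= 0) stop("M must be positive")
  if (W < 0) stop("W must be non-negative")
  if (A < 0) stop("A must be non-negative")
  if (W > M / 2) stop("W must not exceed M/2")
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b <- (M + A) * log(10)
  d <- if (w == 0) b else
    stats::uniroot(function(d) 2 * (log(d) - log(b)) + w * (b + d),
                   lower = b * 1e-12, upper = b, tol = 1e-14)$root
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a / exp(d * x1)
  a <- T_top / ((exp(b) - mf_a) - c_a / exp(d))
  cc <- c_a * a
  f <- -(a * exp(b * x1) - cc * exp(-d * x1))
  list(a = a, b = b, c = cc, d = d, f = f, x1 = x1, T_top = T_top,
       W = W, M = M, A = A)
}

.biexp <- function(y, p) {
  p$a * exp(p$b * y) - p$c * exp(-p$d * y) + p$f
}

.biexp_deriv <- function(y, p) {
  p$a * p$b * exp(p$b * y) + p$c * p$d * exp(-p$d * y)
}

# Bracketed root-find then Newton polish; B is strictly increasing so the
# root is unique. Newton alone can overflow from a far-off start because B
# grows doubly-exponentially in y.
.logicle_forward <- function(x, p) {
  if (is.na(x)) return(NA_real_)
  lo <- -1; hi <- 2
  while (.biexp(lo, p) > x) lo <- lo * 2
  while (.biexp(hi, p) < x) hi <- hi * 2
  y <- stats::uniroot(function(y) .biexp(y, p) - x, lower = lo, upper = hi,
                      tol = 1e-12)$root
  for (i in 1:3) {
    step <- (.biexp(y, p) - x) / .biexp_deriv(y, p)
    if (!is.finite(step)) break
    y <- y - step
  }
  y
}

#' Logicle-scaled histogram counts
#'
#' Histogram of intensity values on the logicle display scale — the form in
#' which per-cell FPcell/Abcell distributions are visualized.
#'
#' @inheritParams logicle
#' @param n_breaks Number of histogram bins on the display scale.
#' @return `data.frame` with `mid` (display position), `value` (data value
#'   at the bin midpoint) and `count`.
#' @export
logicle_histogram <- function(values, T_top = NULL, W = NULL, M = 4.5, A = 0,
                              n_breaks = 64) {
  if (is.null(T_top)) T_top <- max(values, na.rm = TRUE)
  if (is.null(W)) W <- logicle_w(values, T_top, M)
  y <- logicle(values, T_top, W, M, A)
  breaks <- seq(min(0, min(y, na.rm = TRUE)),
                max(1, max(y, na.rm = TRUE)), length.out = n_breaks + 1)
  h <- graphics::hist(y, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids,
             value = logicle_inverse(h$mids, T_top, W, M, A),
             count = h$counts)
}
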
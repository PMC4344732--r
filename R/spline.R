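#' Not-a-knot cubic spline with exact piecewise-polynomial integral
#'
#' The volume estimator's cubic interpolant is the classical C^2 cubic
#' spline with the not-a-knot end condition (the third derivative is
#' continuous across the first and last interior knots), the default of
#' MATLAB's `spline`. Because each segment is an explicit cubic, its
#' antiderivative is evaluated segment by segment, so the integral carries
#' no quadrature error.
#'
#' `notaknot_spline()` degrades gracefully at the point counts that coarse
#' slice spacings produce: with 3 points it returns the unique parabola
#' through them, with 2 the straight line.
#'
#' @param x Strictly increasing knot positions (length >= 2).
#' @param y Values at the knots.
#' @return A list of class `icv_spline` with knots and per-segment
#'   coefficients: on segment `i`, `S(x) = y_i + b_i*t + c_i*t^2 + d_i*t^3`
#'   with `t = x - x_i`.
#' @examples
#' sp <- notaknot_spline(c(0, 1, 2, 4, 7), c(0, 2, 1, 5, 3))
#' spline_value(sp, 3)
#' spline_integral(sp)
#' @export
notaknot_spline <- function(x, y) {
  m <- length(x)
  if (m < 2L || length(y) != m) {
    abort("need at least 2 points with equal-length `x` and `y`.")
  }
  if (any(diff(x) <= 0)) abort("`x` must be strictly increasing.")
  h <- diff(x)
  slope <- diff(y) / h

  if (m == 2L) {
    coef <- cbind(b = slope, c = 0, d = 0)
  } else if (m == 3L) {
    # unique parabola through the 3 points (not-a-knot is degenerate here)
    c2 <- (slope[2] - slope[1]) / (h[1] + h[2])
    coef <- cbind(
      b = c(slope[1] - c2 * h[1], slope[2] - c2 * h[2]),
      c = c(c2, c2),
      d = c(0, 0)
    )
  } else {
    # second-derivative (M) formulation: tridiagonal interior equations with
    # not-a-knot corner rows demanding d^3 continuity at x[2] and x[m-1]
    A <- matrix(0, m, m)
    rhs <- numeric(m)
    A[1, 1:3] <- c(h[2], -(h[1] + h[2]), h[1])
    for (i in 2:(m - 1)) {
      A[i, (i - 1):(i + 1)] <- c(h[i - 1], 2 * (h[i - 1] + h[i]), h[i])
      rhs[i] <- 6 * (slope[i] - slope[i - 1])
    }
    A[m, (m - 2):m] <- c(h[m - 1], -(h[m - 2] + h[m - 1]), h[m - 2])
    M <- solve(A, rhs)
    i <- seq_len(m - 1)
    coef <- cbind(
      b = slope - h * (2 * M[i] + M[i + 1]) / 6,
      c = M[i] / 2,
      d = (M[i + 1] - M[i]) / (6 * h)
    )
  }
  dimnames(coef) <- list(NULL, c("b", "c", "d"))
  structure(list(x = unname(x), y = unname(y), coef = coef),
            class = "icv_spline")
}

#' @rdname notaknot_spline
#' @param sp An `icv_spline`.
#' @param xout Positions at which to evaluate (extrapolation uses the end
#'   segments' cubics, as MATLAB `ppval` would).
#' @export
spline_value <- function(sp, xout) {
  i <- pmin(pmax(findInterval(xout, sp$x), 1L), length(sp$x) - 1L)
  t <- xout - sp$x[i]
  unname(sp$y[i] + sp$coef[i, "b"] * t + sp$coef[i, "c"] * t^2 +
           sp$coef[i, "d"] * t^3)
}

#' @rdname notaknot_spline
#' @param from,to Integration bounds; default the full knot span.
#' @export
spline_integral <- function(sp, from = NULL, to = NULL) {
  x <- sp$x
  if (is.null(from)) from <- x[1]
  if (is.null(to)) to <- x[length(x)]
  if (to < from) return(-spline_integral(sp, to, from))
  # antiderivative of segment i from its left knot to local coordinate t
  seg_int <- function(i, t) {
    sp$y[i] * t + sp$coef[i, "b"] * t^2 / 2 +
      sp$coef[i, "c"] * t^3 / 3 + sp$coef[i, "d"] * t^4 / 4
  }
  n_seg <- length(x) - 1L
  i0 <- pmin(pmax(findInterval(from, x), 1L), n_seg)
  i1 <- pmin(pmax(findInterval(to, x), 1L), n_seg)
  if (i0 == i1) {
    return(unname(seg_int(i0, to - x[i0]) - seg_int(i0, from - x[i0])))
  }
  total <- seg_int(i0, x[i0 + 1L] - x[i0]) - seg_int(i0, from - x[i0])
  if (i1 > i0 + 1L) {
    mid <- (i0 + 1L):(i1 - 1L)
    h <- x[mid + 1L] - x[mid]
    total <- total + sum(sp$y[mid] * h + sp$coef[mid, "b"] * h^2 / 2 +
                         sp$coef[mid, "c"] * h^3 / 3 + sp$coef[mid, "d"] * h^4 / 4)
  }
  unname(total + seg_int(i1, to - x[i1]))
}

# minimum of the spline over its full span: segment endpoints plus interior
# roots of each segment's derivative; used to flag negative lobes
spline_min <- function(sp) {
  n_seg <- length(sp$x) - 1L
  best <- min(sp$y)
  for (i in seq_len(n_seg)) {
    b <- sp$coef[i, "b"]; cc <- sp$coef[i, "c"]; d <- sp$coef[i, "d"]
    h <- sp$x[i + 1L] - sp$x[i]
    crit <- if (abs(d) > 1e-300) {
      disc <- 4 * cc^2 - 12 * d * b
      if (disc >= 0) (-2 * cc + c(-1, 1) * sqrt(disc)) / (6 * d) else numeric()
    } else if (abs(cc) > 1e-300) {
      -b / (2 * cc)
    } else {
      numeric()
    }
    crit <- crit[crit > 0 & crit < h]
    if (length(crit)) {
      vals <- sp$y[i] + b * crit + cc * crit^2 + d * crit^3
      best <- min(best, vals)
    }
  }
  best
}
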
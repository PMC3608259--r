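#' B-spline curves in 3D
#'
#' Constructs a polynomial B-spline curve from an ordered set of control
#' points. Open curves use a clamped knot vector (the curve interpolates its
#' first and last control points); closed curves use a periodic uniform knot
#' vector obtained by wrapping the first \code{degree} control points, which
#' gives C^(degree-1) continuity across the seam.
#'
#' All coordinates are interpreted in millimetres. Rational weights are not
#' supported: uniform-weight NURBS reduce exactly to the polynomial B-splines
#' implemented here.
#'
#' @param control_points numeric matrix, one row per control point. 2-column
#'   input is promoted to 3D with z = 0.
#' @param degree polynomial degree (>= 1). Defaults to cubic, lowered to
#'   \code{nrow(control_points) - 1} when fewer than 4 points are given.
#' @param closed logical; evaluate periodically?
#' @return an object of class \code{bspline_curve}.
#' @examples
#' sq <- bspline_curve(rbind(c(0, 0, 0), c(2, 0, 0)), degree = 1)
#' evaluate_curve(sq, 0.5)  # (1, 0, 0)
#' @export
bspline_curve <- function(control_points, degree = NULL, closed = FALSE) {
  control_points <- as_points3(control_points)
  n <- nrow(control_points)
  if (is.null(degree)) degree <- min(3L, n - 1L)
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1")
  if (n < degree + 1L) {
    stop(sprintf("need at least degree + 1 = %d control points, got %d",
                 degree + 1L, n))
  }
  if (closed) {
    # periodic uniform knots over the wrapped control net
    knots <- (seq_len(n + 2L * degree + 1L) - 1L - degree) / n
  } else {
    n_int <- n - degree - 1L
    internal <- if (n_int > 0L) seq_len(n_int) / (n_int + 1L) else numeric(0)
    knots <- c(rep(0, degree + 1L), internal, rep(1, degree + 1L))
  }
  structure(
    list(control_points = control_points, degree = degree,
         closed = closed, knots = knots),
    class = "bspline_curve"
  )
}

#' @export
print.bspline_curve <- function(x, ...) {
  cat(sprintf("<bspline_curve: degree %d, %d control points, %s>\n",
              x$degree, nrow(x$control_points),
              if (x$closed) "closed (periodic)" else "open (clamped)"))
  invisible(x)
}

as_points3 <- function(p) {
  p <- as.matrix(p)
  if (!is.numeric(p)) stop("points must be numeric")
  if (ncol(p) == 2L) p <- cbind(p, 0)
  if (ncol(p) != 3L) stop("points must have 2 or 3 columns")
  if (anyNA(p) || any(!is.finite(p))) stop("points must be finite")
  storage.mode(p) <- "double"
  p
}

# Cox-de Boor basis matrix: length(t) x n_basis, 0/0 treated as 0.
bspline_basis <- function(t, knots, degree) {
  nb <- length(knots) - degree - 1L
  m <- length(t)
  # degree-0 indicators over every span; clamp the right end of the
  # evaluation domain onto the last non-empty span so t = domain max works
  tmax <- knots[nb + 1L]
  t_adj <- t
  t_adj[t_adj >= tmax] <- tmax - 1e-12
  n0 <- length(knots) - 1L
  N <- matrix(0, m, n0)
  for (j in seq_len(n0)) {
    if (knots[j + 1L] > knots[j]) {
      N[, j] <- as.numeric(t_adj >= knots[j] & t_adj < knots[j + 1L])
    }
  }
  if (degree == 0L) return(N[, seq_len(nb), drop = FALSE])
  for (k in seq_len(degree)) {
    nk <- length(knots) - k - 1L
    N_new <- matrix(0, m, nk)
    for (j in seq_len(nk)) {
      d1 <- knots[j + k] - knots[j]
      d2 <- knots[j + k + 1L] - knots[j + 1L]
      a <- if (d1 > 0) (t - knots[j]) / d1 * N[, j] else 0
      b <- if (d2 > 0) (knots[j + k + 1L] - t) / d2 * N[, j + 1L] else 0
      N_new[, j] <- a + b
    }
    N <- N_new
  }
  N
}

#' Evaluate a B-spline curve
#'
#' @param curve a \code{bspline_curve}.
#' @param t numeric vector of parameter values. Open curves require
#'   t in \[0, 1\]; closed curves are periodic (t is taken modulo 1).
#' @return numeric matrix \code{length(t)} x 3 of points (mm).
#' @export
evaluate_curve <- function(curve, t) {
  stopifnot(inherits(curve, "bspline_curve"))
  t <- as.numeric(t)
  if (anyNA(t)) stop("t must not contain NA")
  d <- curve$degree
  P <- curve$control_points
  if (curve$closed) {
    t <- t - floor(t)
    Pe <- rbind(P, P[seq_len(d), , drop = FALSE])
    N <- bspline_basis(t, curve$knots, d)
    return(N %*% Pe)
  }
  if (any(t < -1e-12 | t > 1 + 1e-12)) {
    stop("t outside [0, 1] for an open curve")
  }
  t <- pmin(pmax(t, 0), 1)
  N <- bspline_basis(t, curve$knots, d)
  N %*% P
}

#' Reverse the orientation of a B-spline curve
#' @param curve a \code{bspline_curve}
#' @return the curve traversed in the opposite direction.
#' @export
reverse_curve <- function(curve) {
  bspline_curve(curve$control_points[rev(seq_len(nrow(curve$control_points))), ,
                                     drop = FALSE],
                degree = curve$degree, closed = curve$closed)
}

#' Interpolating B-spline through data points
#'
#' Solves the global interpolation problem: returns a B-spline curve that
#' passes exactly through the given points, with chord-length
#' parameterisation. Used wherever a modelled feature must hit a measured
#' dimension exactly (e.g. a root profile reaching its prescribed width at
#' half root length).
#'
#' @param points matrix of points to interpolate (rows).
#' @param degree spline degree; lowered automatically for few points.
#' @param closed logical; fit a periodic curve through a closed loop?
#' @return a \code{bspline_curve} passing through \code{points} (for closed
#'   curves, through every point with periodic continuity).
#' @export
interpolate_bspline <- function(points, degree = 3L, closed = FALSE) {
  Q <- as_points3(points)
  n <- nrow(Q)
  if (!closed) {
    degree <- as.integer(min(degree, n - 1L))
    # chord-length parameters
    seg <- sqrt(rowSums((Q[-1, , drop = FALSE] - Q[-n, , drop = FALSE])^2))
    if (any(seg == 0)) seg[seg == 0] <- 1e-9
    u <- c(0, cumsum(seg)) / sum(seg)
    # knot averaging (standard global interpolation)
    n_int <- n - degree - 1L
    internal <- if (n_int > 0L) {
      vapply(seq_len(n_int), function(j) mean(u[(j + 1L):(j + degree)]),
             numeric(1))
    } else numeric(0)
    knots <- c(rep(0, degree + 1L), internal, rep(1, degree + 1L))
    N <- bspline_basis(u, knots, degree)
    P <- solve(N, Q)
    crv <- bspline_curve(P, degree = degree, closed = FALSE)
    crv$knots <- knots
    return(crv)
  }
  degree <- as.integer(min(degree, n - 1L))
  # periodic fit: n unknown control points, wrapped basis folded modulo n
  seg <- sqrt(rowSums((rbind(Q[-1, , drop = FALSE], Q[1, , drop = FALSE]) - Q)^2))
  if (any(seg == 0)) seg[seg == 0] <- 1e-9
  u <- c(0, cumsum(seg))[seq_len(n)] / sum(seg)
  knots <- (seq_len(n + 2L * degree + 1L) - 1L - degree) / n
  Nfull <- bspline_basis(u, knots, degree)     # n x (n + degree)
  N <- Nfull[, seq_len(n), drop = FALSE]
  for (j in seq_len(degree)) N[, j] <- N[, j] + Nfull[, n + j]
  P <- solve(N, Q)
  crv <- bspline_curve(P, degree = degree, closed = TRUE)
  crv
}

# Dense polyline sampling of a curve (helper used for calibration/oracles).
sample_curve <- function(curve, n = 512L) {
  if (curve$closed) {
    evaluate_curve(curve, (seq_len(n) - 1L) / n)
  } else {
    evaluate_curve(curve, seq(0, 1, length.out = n))
  }
}
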
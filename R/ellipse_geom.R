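#' Direct least-squares ellipse fit
#'
#' Fits the conic `A x^2 + B x y + C y^2 + D x + E y + F = 0` to a set of
#' boundary points by minimising the algebraic residual subject to the
#' ellipse-specific constraint `4AC - B^2 = 1`, using the numerically stable
#' partitioned eigen-system formulation.  Points are centred before fitting
#' for conditioning and the conic is mapped back afterwards.  The returned
#' coefficient vector is normalised so `4AC - B^2 = 1` and `A > 0`.
#'
#' @param points data.frame or matrix with columns `x`, `y` (>= 6 points, not
#'   collinear).
#' @return named numeric vector `A..F`, class `conic_params`.
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 6L)
    stop("fit-failure: at least 6 points are required", call. = FALSE)
  if (qr(cbind(pts, 1))$rank < 3L)
    stop("fit-failure: points are collinear", call. = FALSE)
  mx <- mean(pts[, 1L]); my <- mean(pts[, 2L])
  x <- pts[, 1L] - mx; y <- pts[, 2L] - my

  D1 <- cbind(x * x, x * y, y * y)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) stop("fit-failure: degenerate point set",
                                          call. = FALSE))
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C1), C1 the constraint matrix of 4AC - B^2
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1L, ] * vec[3L, ] - vec[2L, ]^2
  ok <- which(cond > 0 & abs(Im(ev$values)) < 1e-8)
  if (!length(ok))
    stop("fit-failure: no ellipse solution for these points", call. = FALSE)
  a1 <- vec[, ok[1L]]
  theta <- c(a1, as.vector(Tm %*% a1))

  # undo the centring: substitute x -> x - mx, y -> y - my
  A <- theta[1L]; B <- theta[2L]; C <- theta[3L]
  D <- theta[4L]; E <- theta[5L]; F <- theta[6L]
  Dn <- D - 2 * A * mx - B * my
  En <- E - B * mx - 2 * C * my
  Fn <- F + A * mx^2 + B * mx * my + C * my^2 - D * mx - E * my
  as_conic(c(A, B, C, Dn, En, Fn))
}

# Normalise conic coefficients so 4AC - B^2 = 1 and A > 0; reject non-ellipses.
as_conic <- function(v) {
  v <- as.numeric(v)
  disc <- 4 * v[1L] * v[3L] - v[2L]^2
  if (!is.finite(disc) || disc <= 0)
    stop("fit-failure: conic is not an ellipse (4AC - B^2 <= 0)", call. = FALSE)
  v <- v / sqrt(disc)
  if (v[1L] < 0) v <- -v
  names(v) <- c("A", "B", "C", "D", "E", "F")
  structure(v, class = "conic_params")
}

#' @export
print.conic_params <- function(x, ...) {
  cat("Conic (4AC - B^2 = 1):\n")
  print(unclass(round(x, 6)))
  invisible(x)
}

# Evaluate the conic at points (x, y); near zero on the curve.
conic_residual <- function(conic, x, y) {
  conic[1L] * x^2 + conic[2L] * x * y + conic[3L] * y^2 +
    conic[4L] * x + conic[5L] * y + conic[6L]
}

#' Recover ellipse geometry from conic coefficients
#'
#' Computes the centre `(x0, y0)` from the gradient zero of the quadratic
#' form, the semi-axes `Rmax >= Rmin` from the eigenvalues of
#' `[[A, B/2], [B/2, C]]`, the centre-to-focus distance
#' `L = sqrt(Rmax^2 - Rmin^2)`, and the signed rotation angle `beta`:
#' the angle between the vector from the centre to the upper major-axis
#' endpoint and the vertical image axis, positive (clockwise) when the top
#' point lies left of the centre (`xt < x0`), negative when right, zero for a
#' circle or an upright ellipse.  `K` reports the normalising constant of the
#' centred quadratic form.  The major/minor axis endpoints (`top_point`,
#' `left_minor_point`) come from the parametric form and always satisfy the
#' conic equation.
#'
#' @param conic `conic_params` vector.
#' @return list of class `ellipse_geometry` with fields `center`, `Rmax`,
#'   `Rmin`, `L`, `K`, `beta` (radians), `top_point`, `left_minor_point`,
#'   `major_dir`, `minor_dir`, `conic`.
#' @export
conic_to_geometry <- function(conic) {
  if (!inherits(conic, "conic_params")) conic <- as_conic(conic)
  A <- conic[[1L]]; B <- conic[[2L]]; C <- conic[[3L]]
  D <- conic[[4L]]; E <- conic[[5L]]; F <- conic[[6L]]
  disc <- 4 * A * C - B^2
  x0 <- (B * E - 2 * C * D) / disc
  y0 <- (B * D - 2 * A * E) / disc
  F0 <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2L)
  eg <- eigen(Q, symmetric = TRUE)
  if (any(eg$values <= 0) || F0 >= 0)
    stop("geometry error: conic does not bound a real ellipse", call. = FALSE)
  # eigen returns decreasing eigenvalues: values[1] (largest) -> minor axis
  Rmin <- sqrt(-F0 / eg$values[1L])
  Rmax <- sqrt(-F0 / eg$values[2L])
  circle <- (Rmax - Rmin) / Rmax < 1e-12

  eps <- 1e-9
  if (circle) {
    major <- c(0, -1)                    # convention: straight up, beta = 0
  } else {
    major <- eg$vectors[, 2L]
    # orient toward the image top (smaller y); tie (horizontal axis): leftward
    if (major[2L] > eps || (abs(major[2L]) <= eps && major[1L] > 0))
      major <- -major
  }
  minor <- c(-major[2L], major[1L])      # perpendicular
  if (minor[1L] > eps || (abs(minor[1L]) <= eps && minor[2L] > 0))
    minor <- -minor                      # point leftward (tie: upward)

  center <- c(x = x0, y = y0)
  top_point <- center + Rmax * major
  left_minor_point <- center + Rmin * minor

  u <- top_point - center
  cosb <- min(1, max(-1, sum(u * c(0, -1)) / sqrt(sum(u^2))))
  beta <- acos(cosb)
  # sign rule: clockwise rotation (top point left of the centre) is positive
  dx <- top_point[[1L]] - x0
  if (abs(dx) < 1e-9) beta <- 0 else if (dx > 0) beta <- -beta

  structure(list(
    center = center,
    Rmax = Rmax, Rmin = Rmin,
    L = sqrt(max(Rmax^2 - Rmin^2, 0)),
    K = -F0,
    beta = beta,
    top_point = c(x = top_point[[1L]], y = top_point[[2L]]),
    left_minor_point = c(x = left_minor_point[[1L]], y = left_minor_point[[2L]]),
    major_dir = major, minor_dir = minor,
    conic = conic
  ), class = "ellipse_geometry")
}

#' Construct ellipse geometry from explicit parameters
#'
#' Builds the same `ellipse_geometry` object as [conic_to_geometry()] from
#' centre, semi-axes and signed rotation angle (positive = clockwise, i.e.
#' top point left of centre).  Used by the phantom generator and in tests.
#'
#' @param center numeric `(x, y)` in pixels.
#' @param Rmax,Rmin semi-axes in pixels, `Rmax >= Rmin > 0`.
#' @param beta rotation angle in radians, `|beta| <= pi/2`.
#' @return `ellipse_geometry` object.
#' @export
make_ellipse_geometry <- function(center, Rmax, Rmin, beta = 0) {
  stopifnot(Rmax >= Rmin, Rmin > 0, abs(beta) <= pi / 2 + 1e-12)
  major <- c(-sin(beta), -cos(beta))     # unit vector to the upper endpoint
  # conic from the quadratic form with semi-axes along major/minor
  minor <- c(-major[2L], major[1L])
  if (minor[1L] > 0 || (minor[1L] == 0 && minor[2L] > 0)) minor <- -minor
  R <- cbind(major, minor)
  Q <- R %*% diag(c(1 / Rmax^2, 1 / Rmin^2)) %*% t(R)
  A <- Q[1L, 1L]; B <- 2 * Q[1L, 2L]; C <- Q[2L, 2L]
  x0 <- center[[1L]]; y0 <- center[[2L]]
  D <- -(2 * A * x0 + B * y0)
  E <- -(B * x0 + 2 * C * y0)
  F <- A * x0^2 + B * x0 * y0 + C * y0^2 - 1
  conic_to_geometry(as_conic(c(A, B, C, D, E, F)))
}

#' @export
print.ellipse_geometry <- function(x, ...) {
  cat(sprintf(
    "Ellipse: center (%.2f, %.2f), Rmax %.2f px, Rmin %.2f px, L %.2f px, beta %.2f deg\n",
    x$center[[1L]], x$center[[2L]], x$Rmax, x$Rmin, x$L, x$beta * 180 / pi))
  invisible(x)
}

#' Sample points on an ellipse boundary
#'
#' Exact parametric samples `center + Rmax cos(t) major + Rmin sin(t) minor`.
#'
#' @param geom `ellipse_geometry`.
#' @param n number of points.
#' @return data.frame with columns `x`, `y`.
#' @export
ellipse_points <- function(geom, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  px <- geom$center[[1L]] + geom$Rmax * cos(t) * geom$major_dir[1L] +
    geom$Rmin * sin(t) * geom$minor_dir[1L]
  py <- geom$center[[2L]] + geom$Rmax * cos(t) * geom$major_dir[2L] +
    geom$Rmin * sin(t) * geom$minor_dir[2L]
  data.frame(x = px, y = py)
}

#' Rasterize the ellipse interior
#'
#' @param geom `ellipse_geometry`.
#' @param dim image dimensions `c(rows, cols)`.
#' @return mask matrix with 255 inside the ellipse.
#' @export
rasterize_ellipse <- function(geom, dim) {
  nr <- dim[1L]; nc <- dim[2L]
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  dx <- xs - geom$center[[1L]]; dy <- ys - geom$center[[2L]]
  u <- dx * geom$major_dir[1L] + dy * geom$major_dir[2L]
  v <- dx * geom$minor_dir[1L] + dy * geom$minor_dir[2L]
  inside <- (u / geom$Rmax)^2 + (v / geom$Rmin)^2 <= 1
  out <- matrix(0L, nr, nc)
  out[inside] <- 255L
  out
}

# Build a cut line in normalised implicit form a x + b y + c = 0 with the
# keep side anchored at a reference point (strictly positive sign there).
make_cut_line <- function(direction, through, keep_point) {
  n <- unname(c(-direction[[2L]], direction[[1L]]))
  n <- n / sqrt(sum(n^2))
  cc <- -sum(n * through)
  s <- sum(n * keep_point) + cc
  if (abs(s) < 1e-12)
    stop("degenerate cut line: reference point lies on the line", call. = FALSE)
  if (s < 0) { n <- -n; cc <- -cc }
  slope <- if (abs(n[2L]) > 1e-12) -n[1L] / n[2L] else NA_real_
  intercept <- if (is.na(slope)) NA_real_ else -cc / n[2L]
  structure(list(a = n[1L], b = n[2L], c = cc,
                 m = slope, b_intercept = intercept),
            class = "cut_line")
}

#' Minor-axis cut line of an ellipse
#'
#' The line through the centre and the left minor-axis endpoint; the kept
#' half-plane is the one containing the upper major-axis endpoint, i.e. the
#' upper half of the ellipse in raster coordinates.
#'
#' @param geom `ellipse_geometry`.
#' @return list of class `cut_line` with normalised implicit coefficients
#'   `a, b, c` (keep side: `a x + b y + c > 0`) and slope/intercept views
#'   `m`, `b_intercept` (`NA` for a vertical line).
#' @export
minor_axis_line <- function(geom) {
  make_cut_line(geom$left_minor_point - geom$center, geom$center,
                geom$top_point)
}

#' Cut a mask by a half-plane
#'
#' Retains pixels strictly on the keep side of the line (`a x + b y + c > 0`);
#' pixels on the line or beyond are set to zero.
#'
#' @param mask matrix with entries in \{0, 255\}.
#' @param line `cut_line`.
#' @return cut mask.
#' @export
cut_halfplane <- function(mask, line) {
  assert_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  keep <- line$a * xs + line$b * ys + line$c > 0
  out <- mask
  out[!keep] <- 0L
  if (!any(out != 0L))
    stop("empty-region: half-plane cut removed every pixel", call. = FALSE)
  out
}
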
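#' Specification of a synthetic thermal head phantom
#'
#' Describes a simulated thermal frame: a cool uniform background, a warm
#' elliptical head, two hotter eye disks (or colder glasses-lens disks),
#' optional cold occluders (breathing mask, beard patch) and additive
#' Gaussian sensor noise.  Defaults emulate the target camera (140 x 120 px)
#' and physiologically plausible skin temperatures: background 25 degC
#' (room), face 34 degC, eyes 36.5 degC (the warmest facial points), lenses
#' 28 degC (low-emissivity glass), noise sd 0.2 degC (a conservative bound
#' for an 80 mK NETD detector).
#'
#' @param frame_shape `(rows, cols)` of the frame.
#' @param background_c,face_c,eye_c,lens_c temperatures, degC.
#' @param head_center ellipse centre `(x, y)` px.
#' @param head_axes `(Rmax, Rmin)` semi-axes, px.
#' @param beta_deg in-plane head rotation, degrees in \[-60, 60\]
#'   (positive = clockwise, top of the head toward smaller x).
#' @param has_glasses render lens disks instead of eye disks.
#' @param eye_radius,lens_radius disk radii, px.
#' @param occluders list of `list(shape = "disc"|"rect", center = c(x, y),
#'   size = radius or c(halfwidth, halfheight), temp_c = ...)` stamped over
#'   the head.
#' @param noise_sd_c additive Gaussian noise sd, degC.
#' @param seed integer RNG seed; the phantom is deterministic given the seed.
#' @return validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(frame_shape = c(120L, 140L),
                         background_c = 25, face_c = 34, eye_c = 36.5,
                         lens_c = 28,
                         head_center = c(70, 58), head_axes = c(38, 27),
                         beta_deg = 0, has_glasses = FALSE,
                         eye_radius = 5, lens_radius = 7,
                         occluders = list(), noise_sd_c = 0.2, seed = 1L) {
  spec <- list(frame_shape = as.integer(frame_shape),
               background_c = background_c, face_c = face_c, eye_c = eye_c,
               lens_c = lens_c, head_center = as.numeric(head_center),
               head_axes = as.numeric(head_axes), beta_deg = beta_deg,
               has_glasses = isTRUE(has_glasses), eye_radius = eye_radius,
               lens_radius = lens_radius, occluders = occluders,
               noise_sd_c = noise_sd_c, seed = as.integer(seed))
  temps <- c(background_c, face_c, eye_c, lens_c,
             vapply(occluders, function(o) o$temp_c, numeric(1)))
  if (any(temps < SENSOR_MIN_C | temps > SENSOR_MAX_C))
    stop("phantom temperatures must lie in the sensor range", call. = FALSE)
  if (!(eye_c > face_c && face_c > background_c && lens_c < face_c))
    stop("need eye_c > face_c > background_c and lens_c < face_c",
         call. = FALSE)
  if (abs(beta_deg) > 60)
    stop("beta_deg must be within [-60, 60]", call. = FALSE)
  if (spec$head_axes[1L] < spec$head_axes[2L])
    stop("head_axes must be (Rmax, Rmin) with Rmax >= Rmin", call. = FALSE)
  b <- beta_deg * pi / 180
  wx <- sqrt((spec$head_axes[1L] * sin(b))^2 + (spec$head_axes[2L] * cos(b))^2)
  wy <- sqrt((spec$head_axes[1L] * cos(b))^2 + (spec$head_axes[2L] * sin(b))^2)
  if (spec$head_center[1L] - wx < 1.5 ||
      spec$head_center[1L] + wx > spec$frame_shape[2L] - 0.5 ||
      spec$head_center[2L] - wy < 1.5 ||
      spec$head_center[2L] + wy > spec$frame_shape[1L] - 0.5)
    stop("head ellipse leaves the frame", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

stamp_disc <- function(frame, center, radius, temp) {
  nr <- nrow(frame); nc <- ncol(frame)
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  hit <- (xs - center[1L])^2 + (ys - center[2L])^2 <= radius^2
  frame[hit] <- temp
  frame
}

# Flattened disc in the head frame: semi-axis `rx` along the head's minor
# direction (lens width), `ry` along the major direction (lens height).
stamp_lens <- function(frame, center, side, up, rx, ry, temp) {
  nr <- nrow(frame); nc <- ncol(frame)
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  dx <- xs - center[1L]; dy <- ys - center[2L]
  u <- dx * side[1L] + dy * side[2L]
  v <- dx * up[1L] + dy * up[2L]
  frame[(u / rx)^2 + (v / ry)^2 <= 1] <- temp
  frame
}

stamp_rect <- function(frame, center, half, temp) {
  nr <- nrow(frame); nc <- ncol(frame)
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  hit <- abs(xs - center[1L]) <= half[1L] & abs(ys - center[2L]) <= half[2L]
  frame[hit] <- temp
  frame
}

#' Generate a synthetic thermal head frame with ground truth
#'
#' Renders the phantom described by `spec` and computes analytic ground
#' truth: the head ellipse geometry, the true eye/lens centres (at half of
#' each semi-axis from the centre, in the upper half), and the forehead mask
#' defined by the same geometric rule the pipeline targets — the ellipse
#' interior strictly above the line parallel to the minor axis through the
#' 20%-shifted midpoint of the true eye centres.
#'
#' @param spec a [phantom_spec()].
#' @return list with `frame` (thermal frame) and `truth` (list with
#'   `forehead_mask`, `geometry`, `eye_centers` 2 x 2 matrix, `eye_mask`,
#'   `spec`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  nr <- spec$frame_shape[1L]; nc <- spec$frame_shape[2L]
  beta <- spec$beta_deg * pi / 180
  geom <- make_ellipse_geometry(spec$head_center, spec$head_axes[1L],
                                spec$head_axes[2L], beta)

  frame <- matrix(spec$background_c, nr, nc)
  head <- rasterize_ellipse(geom, c(nr, nc)) != 0L
  frame[head] <- spec$face_c

  up <- geom$major_dir
  side <- geom$minor_dir
  e1 <- spec$head_center + (spec$head_axes[1L] / 2) * up -
    (spec$head_axes[2L] / 2) * side
  e2 <- spec$head_center + (spec$head_axes[1L] / 2) * up +
    (spec$head_axes[2L] / 2) * side
  eye_centers <- rbind(c1 = e1, c2 = e2)
  colnames(eye_centers) <- c("x", "y")
  if (eye_centers[1L, 1L] > eye_centers[2L, 1L])
    eye_centers <- eye_centers[2:1, , drop = FALSE]

  eye_mask <- matrix(0L, nr, nc)
  if (spec$has_glasses) {
    # spectacle lenses are wider than tall: flattened discs in the head frame
    for (k in 1:2) {
      frame <- stamp_lens(frame, eye_centers[k, ], side, up,
                          spec$lens_radius, 0.6 * spec$lens_radius,
                          spec$lens_c)
      eye_mask <- stamp_lens(eye_mask, eye_centers[k, ], side, up,
                             spec$lens_radius, 0.6 * spec$lens_radius, 255L)
    }
  } else {
    for (k in 1:2) {
      frame <- stamp_disc(frame, eye_centers[k, ], spec$eye_radius,
                          spec$eye_c)
      eye_mask <- stamp_disc(eye_mask, eye_centers[k, ], spec$eye_radius,
                             255L)
    }
  }
  storage.mode(eye_mask) <- "integer"

  for (oc in spec$occluders) {
    frame <- switch(oc$shape,
      disc = stamp_disc(frame, oc$center, oc$size, oc$temp_c),
      rect = stamp_rect(frame, oc$center, oc$size, oc$temp_c),
      stop("unknown occluder shape: ", oc$shape, call. = FALSE))
  }

  if (spec$noise_sd_c > 0) {
    set.seed(spec$seed)
    frame <- frame + stats::rnorm(nr * nc, 0, spec$noise_sd_c)
  }
  frame <- pmin(pmax(frame, SENSOR_MIN_C), SENSOR_MAX_C)

  # analytic ground-truth forehead: ellipse interior strictly above the
  # minor-axis-parallel line through the shifted true-eye midpoint
  mp <- colMeans(eye_centers)
  sm <- mp + 0.20 * (geom$top_point - mp)
  n <- c(-side[2L], side[1L]); n <- n / sqrt(sum(n^2))
  cc <- -sum(n * sm)
  if (sum(n * geom$top_point) + cc < 0) { n <- -n; cc <- -cc }
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  fh <- head & (n[1L] * xs + n[2L] * ys + cc > 0)
  forehead_mask <- matrix(0L, nr, nc); forehead_mask[fh] <- 255L

  list(frame = as_thermal_frame(frame),
       truth = list(forehead_mask = forehead_mask, geometry = geom,
                    eye_centers = eye_centers, eye_mask = eye_mask,
                    spec = spec))
}

default_occluders <- function(type, geom, spec) {
  down <- -geom$major_dir
  side <- geom$minor_dir
  ctr <- geom$center
  Rmax <- spec$head_axes[1L]; Rmin <- spec$head_axes[2L]
  switch(type,
    mask = list(list(shape = "disc",
                     center = ctr + 0.55 * Rmax * down,
                     size = 0.45 * Rmin, temp_c = 29.5)),
    beard = list(
      list(shape = "disc", center = ctr + 0.62 * Rmax * down,
           size = 0.3 * Rmin, temp_c = 31.5),
      list(shape = "disc", center = ctr + 0.5 * Rmax * down + 0.45 * Rmin * side,
           size = 0.2 * Rmin, temp_c = 31.5),
      list(shape = "disc", center = ctr + 0.5 * Rmax * down - 0.45 * Rmin * side,
           size = 0.2 * Rmin, temp_c = 31.5)),
    list())
}

#' Generate a reproducible suite of phantoms
#'
#' Samples `n` phantom specifications from the declared ranges — head
#' rotation uniform in `beta_range`, glasses with probability
#' `glasses_prob`, a lower-face occluder (breathing mask or beard patches)
#' with probability `occluder_prob`, mild jitter of the head centre and
#' axes — and renders them.  Fully reproducible from `master_seed`.
#'
#' @param n number of phantoms.
#' @param master_seed integer seed driving all sampling.
#' @param beta_range rotation range in degrees.
#' @param glasses_prob,occluder_prob Bernoulli probabilities.
#' @param noise_sd_c sensor noise sd, degC.
#' @param frame_shape `(rows, cols)`.
#' @param manifest_csv optional path; if given the manifest is written there.
#' @return list with `phantoms` (list of [generate_phantom()] results) and
#'   `manifest` (data.frame: frame_id, seed, beta_deg, has_glasses,
#'   occluder, head geometry columns).
#' @export
generate_suite <- function(n, master_seed = 1L, beta_range = c(-20, 20),
                           glasses_prob = 0.5, occluder_prob = 0.3,
                           noise_sd_c = 0.2, frame_shape = c(120L, 140L),
                           manifest_csv = NULL) {
  stopifnot(n >= 1)
  set.seed(master_seed)
  betas <- stats::runif(n, beta_range[1L], beta_range[2L])
  glasses <- stats::runif(n) < glasses_prob
  occl <- ifelse(stats::runif(n) < occluder_prob,
                 sample(c("mask", "beard"), n, replace = TRUE), "none")
  cx <- stats::runif(n, 64, 76)
  cy <- stats::runif(n, 54, 62)
  rmax <- stats::runif(n, 34, 40)
  rmin <- stats::runif(n, 24, 29)
  seeds <- sample.int(.Machine$integer.max - 1L, n)

  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(frame_shape = frame_shape,
                         head_center = c(cx[i], cy[i]),
                         head_axes = c(rmax[i], rmin[i]),
                         beta_deg = betas[i], has_glasses = glasses[i],
                         noise_sd_c = noise_sd_c, seed = seeds[i])
    if (occl[i] != "none") {
      geom <- make_ellipse_geometry(spec$head_center, rmax[i], rmin[i],
                                    betas[i] * pi / 180)
      spec$occluders <- default_occluders(occl[i], geom, spec)
    }
    phantoms[[i]] <- generate_phantom(spec)
  }
  manifest <- data.frame(
    frame_id = sprintf("phantom_%04d", seq_len(n)), seed = seeds,
    beta_deg = betas, has_glasses = glasses, occluder = occl,
    center_x = cx, center_y = cy, Rmax = rmax, Rmin = rmin,
    stringsAsFactors = FALSE)
  if (!is.null(manifest_csv))
    utils::write.csv(manifest, manifest_csv, row.names = FALSE)
  list(phantoms = phantoms, manifest = manifest)
}
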
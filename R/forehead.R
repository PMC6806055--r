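#' Shifted eye midpoint
#'
#' The midpoint `Mp` of the two detected eye (or lens) centres is moved 20%
#' of the way toward the upper major-axis endpoint of the ellipse, so the
#' forehead cut clears the eyebrows and glasses frames:
#' `shifted = Mp + shift_fraction * (top_point - Mp)`.
#'
#' @param eyes `cluster_pair` of detected centres.
#' @param geom `ellipse_geometry`.
#' @param shift_fraction fraction in \[0, 1\]; default 0.20 (1 returns the
#'   apex itself).
#' @return named numeric `(x, y)`.
#' @export
shifted_midpoint <- function(eyes, geom, shift_fraction = 0.20) {
  if (shift_fraction < 0 || shift_fraction > 1)
    stop("shift_fraction must be in [0, 1]", call. = FALSE)
  if (all(eyes$c1 == eyes$c2))
    stop("degenerate-landmark: identical eye centres", call. = FALSE)
  mp <- (eyes$c1 + eyes$c2) / 2
  p <- mp + shift_fraction * (geom$top_point - mp)
  c(x = p[[1L]], y = p[[2L]])
}

#' Segment the forehead above the shifted midpoint
#'
#' Cuts the upper-half-ellipse mask by the line through the shifted midpoint
#' parallel to the minor axis, keeping the side that contains the ellipse
#' apex (the upper major-axis endpoint).
#'
#' @param upper_mask upper-half-ellipse mask (entries in \{0, 255\}).
#' @param geom `ellipse_geometry`.
#' @param xsm_ysm shifted midpoint `(x, y)`.
#' @return forehead mask.
#' @export
segment_forehead <- function(upper_mask, geom, xsm_ysm) {
  # the shifted midpoint must lie strictly between the centre line and the
  # apex; at or beyond the apex the forehead region is empty by construction
  proj <- sum((xsm_ysm - geom$center) * geom$major_dir)
  if (proj >= geom$Rmax)
    stop(sprintf(
      "empty-forehead: shifted midpoint (%.1f, %.1f) lies at or beyond the apex",
      xsm_ysm[[1L]], xsm_ysm[[2L]]), call. = FALSE)
  line <- make_cut_line(geom$left_minor_point - geom$center, xsm_ysm,
                        geom$top_point)
  out <- tryCatch(cut_halfplane(upper_mask, line), error = function(e)
    stop(sprintf(paste0(
      "empty-forehead: no pixels above the cut line ",
      "(shifted midpoint (%.1f, %.1f), apex (%.1f, %.1f))"),
      xsm_ysm[[1L]], xsm_ysm[[2L]], geom$top_point[[1L]],
      geom$top_point[[2L]]), call. = FALSE))
  out
}

#' Mean forehead temperature
#'
#' Average of the raw temperatures under the nonzero pixels of the mask
#' (mask values are 0/255, so the 255-weighted mean reduces to the plain
#' mean); `w` is the nonzero pixel count.
#'
#' @param raw thermal frame matrix.
#' @param mask forehead mask.
#' @return list with `mean_temp_c` and `w`.
#' @export
mean_forehead_temperature <- function(raw, mask) {
  assert_mask(mask)
  if (!all(dim(raw) == dim(mask)))
    stop("frame and mask dimensions differ", call. = FALSE)
  sel <- mask != 0L
  w <- sum(sel)
  if (w == 0L) stop("empty-mask: no forehead pixels", call. = FALSE)
  list(mean_temp_c = mean(unclass(raw)[sel]), w = w)
}

stage_error <- function(stage, e) {
  stop(structure(class = c("thermoface_stage_error", "error", "condition"),
                 list(message = sprintf("[stage %s] %s", stage,
                                        conditionMessage(e)),
                      call = NULL, stage = stage)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, thermoface_stage_error = function(e) stop(e),
           error = function(e) stage_error(stage, e))
}

#' Segment the forehead and extract its mean temperature
#'
#' Runs the full pipeline on a raw thermal frame: grayscale conversion, Otsu
#' threshold and contrast stretch, binarisation, largest-component filtering,
#' boundary extraction, direct least-squares ellipse fit, upper-half-ellipse
#' cut at the minor axis, two-cluster K-means eye/lens detection, forehead
#' cut above the shifted eye midpoint, and the mean-temperature readout.
#' Any stage failure surfaces as an error tagged with the stage name; no
#' partial result is returned.
#'
#' After the fit, the head component is checked against the rasterised
#' ellipse (Jaccard overlap >= `ellipse_gate`, centre inside the frame), so
#' frames without a plausible head (e.g. pure background noise) fail at the
#' ellipse stage instead of producing a meaningless mask.
#'
#' @param raw thermal frame matrix (see [as_thermal_frame()]).
#' @param has_glasses logical; `TRUE` switches landmark detection from the
#'   warmest (eyes) to the coldest (lenses) pixels.
#' @param shift_fraction forehead cut shift, default 0.20.
#' @param quantile candidate-pixel fraction for landmark detection.
#' @param ellipse_gate minimum head-mask/ellipse Jaccard overlap.
#' @param boundary_offset compensation, in pixels, added to both fitted
#'   semi-axes before the region cuts: the erosion+XOR contour is the inner
#'   pixel boundary, whose pixel centres sit about half a pixel inside the
#'   continuous region edge, so the raw fit underestimates the head ellipse
#'   by roughly that amount.  Default 0.5 px; set to 0 to disable.
#' @return object of class `forehead_segmentation`: the forehead `mask`,
#'   `mean_temp_c`, `pixel_count_w`, eye centres, ellipse `geometry`,
#'   midpoints and per-stage diagnostics.
#' @seealso [generate_phantom()] to simulate input frames with ground truth.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' fit <- forehead_segment(ph$frame)
#' fit
#' coef(fit)
#' @export
forehead_segment <- function(raw, has_glasses = FALSE, shift_fraction = 0.20,
                             quantile = 0.10, ellipse_gate = 0.6,
                             boundary_offset = 0.5) {
  raw <- as_thermal_frame(unclass(raw))
  gray <- run_stage("grayscale", to_grayscale(raw))
  ot <- run_stage("threshold", otsu_threshold(gray))
  thresholded <- run_stage("threshold",
                           stretch_threshold(gray, ot$threshold_M))
  head_component <- run_stage("binarize",
                              largest_component(binarize(thresholded)))
  head_mask <- run_stage("binarize", fill_holes(head_component))
  boundary <- run_stage("boundary", extract_boundary(head_mask))
  geom_fit <- run_stage("ellipse", conic_to_geometry(fit_ellipse(boundary)))
  run_stage("ellipse", {
    ctr <- geom_fit$center
    if (ctr[[1L]] < 1 || ctr[[1L]] > ncol(raw) ||
        ctr[[2L]] < 1 || ctr[[2L]] > nrow(raw))
      stop("fitted ellipse centre outside the frame", call. = FALSE)
  })
  geom <- if (boundary_offset != 0)
    make_ellipse_geometry(geom_fit$center, geom_fit$Rmax + boundary_offset,
                          geom_fit$Rmin + boundary_offset, geom_fit$beta)
  else geom_fit
  ellipse_mask <- rasterize_ellipse(geom, dim(raw))
  run_stage("ellipse", {
    # plausibility gate on the un-filled component: a background-noise blob
    # is porous and cannot match its own fitted ellipse
    overlap <- jaccard(head_component, ellipse_mask)
    if (overlap < ellipse_gate)
      stop(sprintf(
        "head region is not elliptical (mask/ellipse overlap %.2f < %.2f)",
        overlap, ellipse_gate), call. = FALSE)
  })
  upper_mask <- run_stage("upper_half",
                          cut_halfplane(ellipse_mask, minor_axis_line(geom)))
  eyes <- run_stage("landmarks",
                    detect_eye_regions(thresholded, raw, upper_mask, geom,
                                       has_glasses, quantile))
  sm <- run_stage("forehead", shifted_midpoint(eyes, geom, shift_fraction))
  fh_mask <- run_stage("forehead", segment_forehead(upper_mask, geom, sm))
  temp <- run_stage("temperature", mean_forehead_temperature(raw, fh_mask))

  structure(list(
    mask = fh_mask,
    mean_temp_c = temp$mean_temp_c,
    pixel_count_w = temp$w,
    midpoint = (eyes$c1 + eyes$c2) / 2,
    shifted_midpoint = sm,
    eyes = eyes,
    geometry = geom,
    geometry_fit = geom_fit,
    otsu = ot,
    has_glasses = has_glasses,
    shift_fraction = shift_fraction,
    dim = dim(raw),
    diagnostics = list(head_mask = head_mask, upper_mask = upper_mask,
                       n_boundary_points = nrow(boundary),
                       thresholded = thresholded)
  ), class = "forehead_segmentation")
}

#' @export
print.forehead_segmentation <- function(x, ...) {
  cat("Forehead segmentation\n")
  cat(sprintf("  frame: %d x %d px, glasses: %s\n", x$dim[1L], x$dim[2L],
              x$has_glasses))
  cat(sprintf("  ellipse: center (%.1f, %.1f), axes (%.1f, %.1f) px, beta %.1f deg\n",
              x$geometry$center[[1L]], x$geometry$center[[2L]],
              x$geometry$Rmax, x$geometry$Rmin,
              x$geometry$beta * 180 / pi))
  cat(sprintf("  eye centres: (%.1f, %.1f) and (%.1f, %.1f)\n",
              x$eyes$c1[[1L]], x$eyes$c1[[2L]],
              x$eyes$c2[[1L]], x$eyes$c2[[2L]]))
  cat(sprintf("  forehead: %d px, mean temperature %.2f degC\n",
              x$pixel_count_w, x$mean_temp_c))
  invisible(x)
}

#' @export
summary.forehead_segmentation <- function(object, ...) {
  print(object)
  cat(sprintf("  Otsu threshold M = %d; boundary points: %d; k-means iterations: %d\n",
              object$otsu$threshold_M, object$diagnostics$n_boundary_points,
              object$eyes$n_iterations))
  invisible(object)
}

#' @export
coef.forehead_segmentation <- function(object, ...) {
  g <- object$geometry
  c(x0 = g$center[[1L]], y0 = g$center[[2L]], Rmax = g$Rmax, Rmin = g$Rmin,
    L = g$L, beta_deg = g$beta * 180 / pi,
    mean_temp_c = object$mean_temp_c, w = object$pixel_count_w)
}

#' @export
plot.forehead_segmentation <- function(x, raw = NULL, ...) {
  base <- if (is.null(raw)) x$diagnostics$head_mask else unclass(raw)
  img <- t(base)[, nrow(base):1, drop = FALSE]   # raster -> graphics::image
  graphics::image(seq_len(ncol(base)), seq_len(nrow(base)), img,
                  col = grDevices::gray.colors(128), xlab = "x",
                  ylab = "y (flipped)", useRaster = TRUE, ...)
  w <- which(x$mask != 0L)
  nr <- nrow(x$mask)
  graphics::points((w - 1L) %/% nr + 1L, nr - (w - 1L) %% nr,
                   pch = ".", col = "red")
  ep <- ellipse_points(x$geometry, 200L)
  graphics::lines(ep$x, nr + 1 - ep$y, col = "orange")
  graphics::points(c(x$eyes$c1[[1L]], x$eyes$c2[[1L]]),
                   nr + 1 - c(x$eyes$c1[[2L]], x$eyes$c2[[2L]]),
                   col = "cyan", pch = 3)
  invisible(x)
}
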
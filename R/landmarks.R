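#' Initial K-means centres from the ellipse geometry
#'
#' Places the two seeds at half the minor semi-axis to each side of the
#' centre and half the major semi-axis along the major direction, rotated
#' with the ellipse.  If the literal placement (major-axis offset toward
#' increasing y) falls in the discarded lower half-plane, the major-axis
#' offset is reflected across the centre so both seeds lie in the retained
#' upper half-ellipse, near the expected eye positions.
#'
#' @param geom `ellipse_geometry`.
#' @return list of class `cluster_pair` with `c1`, `c2` (named `(x, y)`,
#'   `c1` the left one), `n_iterations = 0`, `member_counts = c(0, 0)`.
#' @export
init_clusters <- function(geom) {
  line <- minor_axis_line(geom)
  down <- -geom$major_dir                # literal offset points down the image
  seeds <- lapply(c(-1, 1), function(s) {
    p <- geom$center + s * (geom$Rmin / 2) * geom$minor_dir +
      (geom$Rmax / 2) * down
    if (line$a * p[[1L]] + line$b * p[[2L]] + line$c <= 0)
      p <- geom$center + s * (geom$Rmin / 2) * geom$minor_dir -
        (geom$Rmax / 2) * down
    c(x = p[[1L]], y = p[[2L]])
  })
  order_pair(seeds[[1L]], seeds[[2L]], 0L, c(0L, 0L))
}

order_pair <- function(p1, p2, iter, counts) {
  if (p2[[1L]] < p1[[1L]] ||
      (p2[[1L]] == p1[[1L]] && p2[[2L]] < p1[[2L]])) {
    tmp <- p1; p1 <- p2; p2 <- tmp
    counts <- rev(counts)
  }
  structure(list(c1 = p1, c2 = p2, n_iterations = iter,
                 member_counts = counts),
            class = "cluster_pair")
}

#' @export
print.cluster_pair <- function(x, ...) {
  cat(sprintf("Cluster pair: c1 (%.2f, %.2f) [n=%d], c2 (%.2f, %.2f) [n=%d], %d iterations\n",
              x$c1[[1L]], x$c1[[2L]], x$member_counts[1L],
              x$c2[[1L]], x$c2[[2L]], x$member_counts[2L], x$n_iterations))
  invisible(x)
}

#' Select extreme-temperature candidate pixels in the upper half-ellipse
#'
#' Without glasses the eyes are the warmest points of the face, so candidates
#' are the pixels whose stretched intensity falls in the top `quantile` of the
#' nonzero upper-half intensities.  With glasses the lenses are the coldest
#' region, and raw temperatures are used instead (the contrast stretch can
#' clamp lens pixels to zero and destroy their ordering).  Whole intensity
#' classes are taken from the extreme end while the running count stays within
#' `floor(quantile * n)` pixels; if no class fits (no distinct extreme), an
#' insufficient-candidates error is raised.
#'
#' @param thresholded integer gray matrix (output of [stretch_threshold()]).
#' @param raw thermal frame matrix.
#' @param face_mask upper-half-ellipse mask (entries in \{0, 255\}).
#' @param has_glasses logical mode switch.
#' @param quantile fraction of region pixels to select, in (0, 0.5).
#' @return data.frame with columns `x`, `y` of candidate pixels.
#' @export
select_candidates <- function(thresholded, raw, face_mask, has_glasses,
                              quantile = 0.10) {
  assert_mask(face_mask)
  if (quantile <= 0 || quantile >= 0.5)
    stop("quantile must be in (0, 0.5)", call. = FALSE)
  region <- which(face_mask != 0L)
  if (!length(region)) stop("empty face region", call. = FALSE)
  if (has_glasses) {
    vals <- -unclass(raw)[region]        # negate: coldest first from the top
  } else {
    vals <- as.numeric(thresholded[region])
    keepnz <- vals > 0
    region <- region[keepnz]
    vals <- vals[keepnz]
  }
  n <- length(vals)
  cap <- floor(quantile * n)
  o <- order(vals, decreasing = TRUE)
  sv <- vals[o]
  # greedy whole-value classes from the extreme end, total <= cap
  run_end <- cumsum(rle(sv)$lengths)
  take <- run_end[run_end <= cap]
  if (!length(take) || max(take) < 2L)
    stop("insufficient-candidates: no distinct temperature extreme in region",
         call. = FALSE)
  sel <- region[o[seq_len(max(take))]]
  nr <- nrow(face_mask)
  data.frame(x = (sel - 1L) %/% nr + 1L, y = (sel - 1L) %% nr + 1L)
}

#' Two-cluster K-means over pixel coordinates
#'
#' Lloyd iterations with Euclidean distance from the given initial pair;
#' converged when both centroid shifts drop below 0.5 px, capped at 100
#' iterations.  If a cluster empties, its centre is re-seeded at the candidate
#' farthest from the other centre.  Output centres are ordered `c1$x <= c2$x`.
#'
#' @param candidates data.frame with columns `x`, `y` (>= 2 points).
#' @param init `cluster_pair` of distinct starting centres.
#' @param tol convergence threshold on the centroid shift, pixels.
#' @param max_iter iteration cap.
#' @return `cluster_pair` with final centres, iteration count, member counts.
#' @export
kmeans2 <- function(candidates, init, tol = 0.5, max_iter = 100L) {
  pts <- as.matrix(as.data.frame(candidates)[, c("x", "y")])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 2L)
    stop("insufficient-candidates: need at least 2 points", call. = FALSE)
  ctr <- rbind(unname(init$c1), unname(init$c2))
  if (all(ctr[1L, ] == ctr[2L, ]))
    stop("initial centres must be distinct", call. = FALSE)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d1 <- (pts[, 1L] - ctr[1L, 1L])^2 + (pts[, 2L] - ctr[1L, 2L])^2
    d2 <- (pts[, 1L] - ctr[2L, 1L])^2 + (pts[, 2L] - ctr[2L, 2L])^2
    assign1 <- d1 <= d2
    new <- ctr
    for (k in 1:2) {
      memb <- if (k == 1L) assign1 else !assign1
      if (!any(memb)) {
        other <- ctr[3L - k, ]
        far <- which.max((pts[, 1L] - other[1L])^2 + (pts[, 2L] - other[2L])^2)
        new[k, ] <- pts[far, ]
        message("kmeans2: empty cluster re-seeded at farthest candidate")
      } else {
        new[k, ] <- colMeans(pts[memb, , drop = FALSE])
      }
    }
    shift <- sqrt(rowSums((new - ctr)^2))
    ctr <- new
    if (all(shift < tol) || iter >= max_iter) break
  }
  d1 <- (pts[, 1L] - ctr[1L, 1L])^2 + (pts[, 2L] - ctr[1L, 2L])^2
  d2 <- (pts[, 1L] - ctr[2L, 1L])^2 + (pts[, 2L] - ctr[2L, 2L])^2
  n1 <- sum(d1 <= d2)
  order_pair(c(x = ctr[1L, 1L], y = ctr[1L, 2L]),
             c(x = ctr[2L, 1L], y = ctr[2L, 2L]),
             iter, c(n1, nrow(pts) - n1))
}

#' Detect the eye (or glasses-lens) centres
#'
#' Composition of [select_candidates()] and [kmeans2()] seeded by
#' [init_clusters()]: clusters the coordinates of the extreme-temperature
#' pixels of the upper half-ellipse into two spatial centres.
#'
#' @inheritParams select_candidates
#' @param upper_mask upper-half-ellipse mask.
#' @param geom fitted `ellipse_geometry`.
#' @param quantile candidate fraction, see [select_candidates()].
#' @return `cluster_pair` of final centres.
#' @export
detect_eye_regions <- function(thresholded, raw, upper_mask, geom,
                               has_glasses, quantile = 0.10) {
  cand <- select_candidates(thresholded, raw, upper_mask, has_glasses,
                            quantile)
  kmeans2(cand, init_clusters(geom))
}
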
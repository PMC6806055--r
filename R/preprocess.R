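#' Otsu threshold of a gray frame
#'
#' Splits the 8-bit histogram into background `S0 = [0, M]` and foreground
#' `S1 = [M + 1, 255]` at the threshold `M` minimising the weighted
#' within-class variance
#' `sigma_w^2(M) = w0 * var(S0) + w1 * var(S1)` (class weights are histogram
#' probabilities, variances are population variances; an empty class
#' contributes zero).  Ties are broken toward the smaller `M`.
#'
#' @param gray integer matrix in \[0, 255\].
#' @return list with `threshold_M` and `within_class_variance`, class `otsu_result`.
#' @export
otsu_threshold <- function(gray) {
  assert_gray(gray)
  h <- tabulate(as.vector(gray) + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L)
    stop("degenerate-histogram: image has fewer than 2 distinct intensities",
         call. = FALSE)
  p <- h / sum(h)
  i <- 0:255
  w0 <- cumsum(p)                      # weight of S0 = [0, M]
  s0 <- cumsum(i * p)                  # first moment of S0
  q0 <- cumsum(i * i * p)              # second moment of S0
  w1 <- 1 - w0
  s1 <- s0[256L] - s0
  q1 <- q0[256L] - q0
  v0 <- ifelse(w0 > 0, q0 / w0 - (s0 / w0)^2, 0)
  v1 <- ifelse(w1 > 0, q1 / w1 - (s1 / w1)^2, 0)
  within <- w0 * pmax(v0, 0) + w1 * pmax(v1, 0)
  M <- which.min(within) - 1L          # which.min takes the first (smallest M)
  structure(list(threshold_M = M, within_class_variance = within[M + 1L]),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("Otsu threshold M = %d (within-class variance %.4f)\n",
              x$threshold_M, x$within_class_variance))
  invisible(x)
}

#' Background removal by contrast stretch above a threshold
#'
#' Pixels at or below `M` become 0 (background); the remaining range is
#' stretched linearly to \[0, 255\]:
#' `P'' = floor(255 * (P' - M) / (255 - M))` for `P' > M`.
#'
#' @param gray integer matrix in \[0, 255\].
#' @param M integer threshold, `0 <= M < 255`.
#' @return integer matrix in \[0, 255\].
#' @export
stretch_threshold <- function(gray, M) {
  assert_gray(gray)
  M <- as.integer(M)
  if (M < 0L || M >= 255L)
    stop("invalid-threshold: M must be in [0, 254]", call. = FALSE)
  out <- ifelse(gray <= M, 0, floor(255 * (gray - M) / (255 - M)))
  storage.mode(out) <- "integer"
  out
}

#' Binarize a thresholded frame
#'
#' Zero stays zero; every positive value becomes 255.  The nonzero pixels
#' represent the head.
#'
#' @param thresholded integer matrix (output of [stretch_threshold()]).
#' @return matrix with entries in \{0, 255\}.
#' @export
binarize <- function(thresholded) {
  out <- ifelse(thresholded > 0L, 255L, 0L)
  storage.mode(out) <- "integer"
  out
}

#' Keep the largest 8-connected foreground component
#'
#' Suppresses secondary blobs (hands, reflections) so exactly one head region
#' reaches the ellipse fit.  Ties in size are broken by the component whose
#' bounding-box top-left corner comes first in row-major order.
#'
#' @param mask matrix with entries in \{0, 255\}.
#' @return mask restricted to its largest component.
#' @export
largest_component <- function(mask) {
  assert_mask(mask)
  fg <- mask != 0L
  if (!any(fg)) stop("no-foreground: mask is empty", call. = FALSE)
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  comp <- label_components(fg, connectivity = 8L)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # tie-break: smallest (min row, min col) of the bounding box, row-major
    keyrow <- vapply(best, function(k)
      min((idx[comp$membership == k] - 1L) %% nr + 1L), integer(1))
    keycol <- vapply(best, function(k)
      min((idx[comp$membership == k] - 1L) %/% nr + 1L), integer(1))
    best <- best[order(keyrow, keycol)][1L]
  }
  out <- matrix(0L, nr, nc)
  out[idx[comp$membership == best]] <- 255L
  out
}

# Connected-component labeling of a logical matrix via igraph; returns the
# igraph components() list for the TRUE pixels of `fg` (in which() order).
label_components <- function(fg, connectivity = 8L) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)                       # column-major linear indices
  rank <- integer(nr * nc); rank[idx] <- seq_along(idx)
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- NULL
  for (d in shifts) {
    dr <- d[1L]; dc <- d[2L]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    both <- fg[r1, c1, drop = FALSE] & fg[r1 + dr, c1 + dc, drop = FALSE]
    if (any(both)) {
      w <- which(both)
      rr <- ((w - 1L) %% length(r1)) + r1[1L]
      cc <- ((w - 1L) %/% length(r1)) + c1[1L]
      a <- (cc - 1L) * nr + rr
      b <- (cc + dc - 1L) * nr + rr + dr
      edges <- rbind(edges, cbind(rank[a], rank[b]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)
}

#' Fill interior holes of a mask
#'
#' Background pixels not 4-connected to the frame border are interior holes
#' (e.g. glasses lenses removed by the background threshold) and are set to
#' foreground, so boundary extraction yields only the outer head contour.
#'
#' @param mask matrix with entries in \{0, 255\}.
#' @return mask with holes filled.
#' @export
fill_holes <- function(mask) {
  assert_mask(mask)
  bg <- mask == 0L
  if (!any(bg)) return(mask)
  nr <- nrow(bg); nc <- ncol(bg)
  comp <- label_components(bg, connectivity = 4L)
  idx <- which(bg)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  border <- rows == 1L | rows == nr | cols == 1L | cols == nc
  outer <- unique(comp$membership[border])
  hole <- !(comp$membership %in% outer)
  out <- mask
  out[idx[hole]] <- 255L
  out
}

# 3x3 square erosion with zero padding: pixels outside the image count as
# background, so a blob touching the frame edge still erodes there.
erode3 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- fg
  out <- matrix(TRUE, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out & pad[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  out
}

#' Extract the one-pixel inner boundary of a mask
#'
#' Erodes the mask with a 3x3 square structuring element and XORs the result
#' with the original mask; the surviving pixels form the inner contour that
#' feeds the ellipse fit.  Points are returned in raster scan order as
#' `(x = column, y = row)` pairs.
#'
#' @param mask matrix with entries in \{0, 255\}.
#' @return data.frame with integer columns `x`, `y`.
#' @export
extract_boundary <- function(mask) {
  assert_mask(mask)
  fg <- mask != 0L
  if (sum(fg) < 9L)
    stop("empty boundary: mask too small to survive erosion", call. = FALSE)
  er <- erode3(fg)
  if (!any(er))
    stop("empty boundary: mask too small to survive erosion", call. = FALSE)
  b <- fg & !er                          # xor, since erosion is a subset
  w <- which(b)
  pts <- data.frame(x = (w - 1L) %/% nrow(b) + 1L,
                    y = (w - 1L) %% nrow(b) + 1L)
  pts[order(pts$y, pts$x), , drop = FALSE]
}
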
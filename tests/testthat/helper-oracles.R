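# Independent oracles and small fixture builders used across the suite.

# Population variance (divides by n, as in the thresholding objective).
popvar <- function(x) mean((x - mean(x))^2)

# Exhaustive Otsu oracle: literal scan of all 256 splits of the pixel values,
# weighted within-class variance computed from the class members themselves.
otsu_oracle <- function(gray) {
  v <- as.vector(gray)
  n <- length(v)
  best_m <- NA_integer_
  best <- Inf
  for (M in 0:255) {
    lo <- v[v <= M]
    hi <- v[v > M]
    within <- 0
    if (length(lo)) within <- within + length(lo) / n * popvar(lo)
    if (length(hi)) within <- within + length(hi) / n * popvar(hi)
    if (within < best) { best <- within; best_m <- M }
  }
  list(threshold_M = best_m, within_class_variance = best)
}

# Random test images with a variety of histogram shapes.
random_gray <- function(seed, nr = 32L, nc = 32L) {
  set.seed(seed)
  kind <- seed %% 4L
  v <- switch(as.character(kind),
    "0" = sample.int(256L, nr * nc, replace = TRUE) - 1L,
    "1" = pmin(pmax(round(stats::rnorm(nr * nc, 120, 40)), 0L), 255L),
    "2" = ifelse(stats::runif(nr * nc) < 0.4,
                 pmin(pmax(round(stats::rnorm(nr * nc, 60, 15)), 0L), 255L),
                 pmin(pmax(round(stats::rnorm(nr * nc, 190, 20)), 0L), 255L)),
    "3" = sample(c(0L, 31L, 128L, 255L), nr * nc, replace = TRUE,
                 prob = c(0.45, 0.2, 0.15, 0.2)))
  matrix(as.integer(v), nr, nc)
}

# Brute-force double-loop 3x3 erosion with zero padding (oracle for the
# morphological boundary).
erode_oracle <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    keep <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- cl + dc
      val <- rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && fg[rr, cc]
      if (!val) keep <- FALSE
    }
    out[r, cl] <- keep
  }
  out
}

# Mask helper: 0/255 integer matrix from a logical matrix.
as_mask <- function(logical_m) {
  out <- matrix(0L, nrow(logical_m), ncol(logical_m))
  out[logical_m] <- 255L
  out
}

# A noise-only frame (no head), background 25 degC.
noise_frame <- function(seed, nr = 120L, nc = 140L, sd = 0.2) {
  set.seed(seed)
  matrix(25 + stats::rnorm(nr * nc, 0, sd), nr, nc)
}
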
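test_that("cluster seeds sit at half-semi-axis offsets in the upper half", {
  g <- make_ellipse_geometry(c(70, 60), 30, 20, 0)
  init <- init_clusters(g)
  # literal placement (60, 75) / (80, 75) is in the discarded lower half;
  # the major-axis offset is reflected across the centre
  expect_equal(unname(init$c1), c(60, 45), tolerance = 1e-9)
  expect_equal(unname(init$c2), c(80, 45), tolerance = 1e-9)

  # beta = 0: seeds mirror across the vertical through the centre
  g2 <- make_ellipse_geometry(c(50.5, 44), 28, 19, 0)
  init2 <- init_clusters(g2)
  expect_equal(init2$c1[["x"]] + init2$c2[["x"]], 2 * 50.5, tolerance = 1e-9)
  expect_equal(init2$c1[["y"]], init2$c2[["y"]], tolerance = 1e-9)

  # beta = 90 deg: seeds mirror across the horizontal through the centre
  g90 <- make_ellipse_geometry(c(70, 60), 30, 20, pi / 2)
  init90 <- init_clusters(g90)
  expect_equal(init90$c1[["x"]], init90$c2[["x"]], tolerance = 1e-9)
  expect_equal(init90$c1[["y"]] + init90$c2[["y"]], 120, tolerance = 1e-9)
  expect_equal(init90$c1[["x"]], 70 - 15, tolerance = 1e-9)  # toward the apex
})

test_that("candidate selection takes whole extreme-intensity classes", {
  # 200-px region at intensity 150 with two 5-px spots at 255; decile cap is
  # 20 px, only the 10 pixels of the distinct top value qualify
  mask <- matrix(0L, 30, 30)
  mask[6:25, 6:15] <- 255L
  thr <- matrix(0L, 30, 30)
  thr[mask != 0L] <- 150L
  hot <- rbind(cbind(8:12, 8L), cbind(18:22, 12L))   # (row, col) pairs
  thr[hot] <- 255L
  raw <- matrix(25, 30, 30)
  cand <- select_candidates(thr, raw, mask, has_glasses = FALSE)
  expect_identical(nrow(cand), 10L)
  expect_setequal((cand$x - 1L) * 30L + cand$y, (hot[, 2] - 1L) * 30L + hot[, 1])
})

test_that("glasses mode selects the coldest raw pixels inside the region", {
  mask <- matrix(0L, 30, 30)
  mask[4:23, 4:23] <- 255L                 # 400-px region
  raw <- matrix(34, 30, 30)
  raw[8:12, 8:10] <- 28; raw[15:19, 16:18] <- 28    # 30 lens px
  thr <- matrix(0L, 30, 30); thr[mask != 0L] <- 100L
  cand <- select_candidates(thr, raw, mask, has_glasses = TRUE)
  expect_true(nrow(cand) >= 2)
  expect_true(all(raw[cbind(cand$y, cand$x)] == 28))

  # uniform region: no distinct extreme
  rawu <- matrix(34, 30, 30)
  expect_error(select_candidates(thr, rawu, mask, has_glasses = TRUE),
               "insufficient-candidates")
  thru <- thr
  expect_error(select_candidates(thru, rawu, mask, has_glasses = FALSE),
               "insufficient-candidates")
})

test_that("k-means converges to blob centroids and matches Lloyd reference", {
  set.seed(4)
  blob <- function(cx, cy) data.frame(x = cx + rep(-1:1, each = 3),
                                      y = cy + rep(-1:1, times = 3))
  cand <- rbind(blob(55, 45), blob(85, 45), c(55, 44))
  init <- thermoface:::order_pair(c(x = 50, y = 40), c(x = 90, y = 50),
                                  0L, c(0L, 0L))
  km <- kmeans2(cand, init)
  expect_lt(abs(km$c1[["x"]] - mean(cand$x[cand$x < 70])), 0.5)
  expect_lt(abs(km$c2[["x"]] - 85), 0.5)
  expect_true(all(km$member_counts >= 1))

  ref <- stats::kmeans(as.matrix(cand), centers = rbind(c(50, 40), c(90, 50)),
                       algorithm = "Lloyd")
  ctr <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(unname(c(km$c1[["x"]], km$c1[["y"]])), unname(ctr[1, ]),
               tolerance = 0.5)
  expect_equal(unname(c(km$c2[["x"]], km$c2[["y"]])), unname(ctr[2, ]),
               tolerance = 0.5)
})

test_that("k-means handles degeneracy, ordering and symmetry", {
  # all candidates identical: the empty cluster re-seeds and centres stay finite
  cand <- data.frame(x = rep(30, 5), y = rep(40, 5))
  init <- thermoface:::order_pair(c(x = 30, y = 40), c(x = 60, y = 80),
                                  0L, c(0L, 0L))
  expect_message(km <- kmeans2(cand, init), "re-seeded")
  expect_true(all(is.finite(c(km$c1, km$c2))))

  # invariant to candidate ordering
  set.seed(9)
  cand <- data.frame(x = c(rnorm(20, 50), rnorm(20, 90)),
                     y = rnorm(40, 45))
  init <- thermoface:::order_pair(c(x = 45, y = 45), c(x = 95, y = 45),
                                  0L, c(0L, 0L))
  k1 <- kmeans2(cand, init)
  k2 <- kmeans2(cand[sample(nrow(cand)), ], init)
  expect_equal(k1$c1, k2$c1, tolerance = 1e-12)
  expect_equal(k1$c2, k2$c2, tolerance = 1e-12)

  # symmetric candidates + symmetric init give mirrored centres
  candm <- data.frame(x = c(cand$x, 140 - cand$x), y = rep(cand$y, 2))
  km <- kmeans2(candm, thermoface:::order_pair(c(x = 40, y = 45),
                                               c(x = 100, y = 45),
                                               0L, c(0L, 0L)))
  expect_equal(km$c1[["x"]], 140 - km$c2[["x"]], tolerance = 1e-9)
  expect_equal(km$c1[["y"]], km$c2[["y"]], tolerance = 1e-9)
})

test_that("eye and lens centres are recovered on phantoms with few iterations", {
  ph <- generate_phantom(phantom_spec(seed = 21, beta_deg = 8))
  fit <- forehead_segment(ph$frame)
  truth <- ph$truth$eye_centers
  d1 <- sqrt(sum((c(fit$eyes$c1) - truth[1, ])^2))
  d2 <- sqrt(sum((c(fit$eyes$c2) - truth[2, ])^2))
  expect_lt(d1, 3); expect_lt(d2, 3)
  expect_lte(fit$eyes$n_iterations, 10L)

  phg <- generate_phantom(phantom_spec(seed = 22, beta_deg = -12,
                                       has_glasses = TRUE))
  fitg <- forehead_segment(phg$frame, has_glasses = TRUE)
  truthg <- phg$truth$eye_centers
  expect_lt(sqrt(sum((c(fitg$eyes$c1) - truthg[1, ])^2)), 3)
  expect_lt(sqrt(sum((c(fitg$eyes$c2) - truthg[2, ])^2)), 3)
  expect_lte(fitg$eyes$n_iterations, 10L)
})

test_that("mirroring the frame mirrors the detected centres", {
  ph <- generate_phantom(phantom_spec(seed = 30, beta_deg = 10))
  fit <- forehead_segment(ph$frame)
  mir <- ph$frame[, ncol(ph$frame):1]
  fitm <- forehead_segment(mir)
  nc1 <- ncol(ph$frame) + 1
  expect_equal(fitm$eyes$c1[["x"]], nc1 - fit$eyes$c2[["x"]], tolerance = 0.5)
  expect_equal(fitm$eyes$c2[["x"]], nc1 - fit$eyes$c1[["x"]], tolerance = 0.5)
  expect_equal(fitm$eyes$c1[["y"]], fit$eyes$c2[["y"]], tolerance = 0.5)
})
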
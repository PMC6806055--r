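test_that("circle points fit to a symmetric conic centred at the origin", {
  t <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- data.frame(x = 5 * cos(t), y = 5 * sin(t))
  conic <- fit_ellipse(pts)
  expect_equal(conic[["A"]], conic[["C"]], tolerance = 1e-9)
  expect_equal(conic[["B"]], 0, tolerance = 1e-9)
  g <- conic_to_geometry(conic)
  expect_equal(unname(g$center), c(0, 0), tolerance = 1e-9)
  expect_equal(g$Rmax, 5, tolerance = 1e-9)
  expect_equal(g$Rmin, 5, tolerance = 1e-9)
  expect_equal(g$L, 0, tolerance = 1e-6)
  expect_identical(g$beta, 0)            # circle: rotation tie rule
})

test_that("axis-aligned conics yield the closed-form geometry", {
  # upright ellipse x^2/9 + y^2/25 = 1: vertical major axis, beta = 0
  g <- conic_to_geometry(c(1 / 9, 0, 1 / 25, 0, 0, -1))
  expect_equal(g$Rmax, 5, tolerance = 1e-12)
  expect_equal(g$Rmin, 3, tolerance = 1e-12)
  expect_equal(g$L, 4, tolerance = 1e-12)
  expect_identical(g$beta, 0)
  expect_equal(unname(g$top_point), c(0, -5), tolerance = 1e-9)
  expect_equal(unname(g$left_minor_point), c(-3, 0), tolerance = 1e-9)

  # x^2/25 + y^2/9 = 1 has a horizontal major axis: |beta| = 90 deg
  gh <- conic_to_geometry(c(1 / 25, 0, 1 / 9, 0, 0, -1))
  expect_equal(gh$Rmax, 5, tolerance = 1e-12)
  expect_equal(gh$Rmin, 3, tolerance = 1e-12)
  expect_equal(gh$L, 4, tolerance = 1e-12)
  expect_equal(abs(gh$beta), pi / 2, tolerance = 1e-12)
})

test_that("generate-and-refit recovers all five parameters exactly", {
  cases <- list(
    list(center = c(70, 60), Rmax = 30, Rmin = 20, beta = 25 * pi / 180),
    list(center = c(70, 60), Rmax = 30, Rmin = 20, beta = -40 * pi / 180),
    list(center = c(12.5, 80.25), Rmax = 45, Rmin = 12, beta = 0),
    list(center = c(0, 0), Rmax = 10, Rmin = 9.5, beta = 1.2))
  for (cs in cases) {
    g0 <- make_ellipse_geometry(cs$center, cs$Rmax, cs$Rmin, cs$beta)
    pts <- ellipse_points(g0, 40L)
    g <- conic_to_geometry(fit_ellipse(pts))
    expect_equal(unname(g$center), unname(cs$center), tolerance = 1e-6)
    expect_equal(g$Rmax, cs$Rmax, tolerance = 1e-6)
    expect_equal(g$Rmin, cs$Rmin, tolerance = 1e-6)
    expect_equal(g$beta, cs$beta, tolerance = 1e-6)
    # residual of the fitted conic on the generating points
    expect_lt(max(abs(conic_residual(g$conic, pts$x, pts$y))), 1e-9)
    # axis endpoints lie on the conic
    expect_lt(abs(conic_residual(g$conic, g$top_point[[1]],
                                 g$top_point[[2]])), 1e-6)
    expect_lt(abs(conic_residual(g$conic, g$left_minor_point[[1]],
                                 g$left_minor_point[[2]])), 1e-6)
    # focal identity
    expect_equal(g$L^2, g$Rmax^2 - g$Rmin^2, tolerance = 1e-9)
  }
})

test_that("fit guards reject degenerate point sets", {
  expect_error(fit_ellipse(data.frame(x = 1:5, y = c(2, 4, 1, 7, 3))),
               "at least 6")
  expect_error(fit_ellipse(data.frame(x = 1:10, y = 2 * (1:10) + 1)),
               "collinear")
})

test_that("mirroring the point set across x = x0 negates beta exactly", {
  g0 <- make_ellipse_geometry(c(70, 60), 35, 22, 0.4)
  pts <- ellipse_points(g0, 50L)
  g <- conic_to_geometry(fit_ellipse(pts))
  mirrored <- data.frame(x = 2 * g$center[[1]] - pts$x, y = pts$y)
  gm <- conic_to_geometry(fit_ellipse(mirrored))
  expect_equal(gm$beta, -g$beta, tolerance = 1e-9)
  expect_equal(gm$Rmax, g$Rmax, tolerance = 1e-9)
})

test_that("refit stays within half a pixel and one degree under point noise", {
  for (seed in 1:10) {
    set.seed(seed)
    beta <- runif(1, -1.0, 1.0)
    Rmax <- runif(1, 30, 40)
    g0 <- make_ellipse_geometry(c(70, 60), Rmax,
                                Rmax / runif(1, 1.35, 1.55), beta)
    pts <- ellipse_points(g0, 200L)
    pts$x <- pts$x + rnorm(200, 0, 0.5)
    pts$y <- pts$y + rnorm(200, 0, 0.5)
    g <- conic_to_geometry(fit_ellipse(pts))
    expect_lt(max(abs(unname(g$center) - unname(g0$center))), 0.5)
    expect_lt(abs(g$Rmax - g0$Rmax), 0.5)
    expect_lt(abs(g$Rmin - g0$Rmin), 0.5)
    expect_lt(abs(g$beta - g0$beta), pi / 180)
  }
})

test_that("minor-axis line keeps the upper half in raster coordinates", {
  g <- make_ellipse_geometry(c(70, 60), 30, 20, 0)
  line <- minor_axis_line(g)
  expect_equal(line$m, 0, tolerance = 1e-12)            # horizontal y = 60
  expect_equal(line$b_intercept, 60, tolerance = 1e-9)
  keep <- function(x, y) line$a * x + line$b * y + line$c > 0
  expect_true(keep(10, 50))              # above (smaller y): kept
  expect_false(keep(10, 70))             # below: discarded
  expect_false(keep(10, 60))             # on the line: discarded (strict)

  g90 <- make_ellipse_geometry(c(70, 60), 30, 20, pi / 2)
  l90 <- minor_axis_line(g90)
  expect_true(is.na(l90$m))              # vertical line, implicit form only
  expect_equal(abs(l90$a), 1, tolerance = 1e-9)
  s <- l90$a * g90$top_point[[1]] + l90$b * g90$top_point[[2]] + l90$c
  expect_gt(s, 0)

  g30 <- make_ellipse_geometry(c(70, 60), 30, 20, pi / 6)
  l30 <- minor_axis_line(g30)
  dm <- g30$left_minor_point - g30$center
  expect_equal(l30$m, dm[[2]] / dm[[1]], tolerance = 1e-9)
  s <- l30$a * g30$top_point[[1]] + l30$b * g30$top_point[[2]] + l30$c
  expect_gt(s, 0)
})

test_that("half-plane cut is strict and leaves untouched masks alone", {
  m <- matrix(0L, 100, 100)
  m[40:80, 5:15] <- 255L
  g <- make_ellipse_geometry(c(10, 60), 30, 20, 0)
  cut <- cut_halfplane(m, minor_axis_line(g))
  w <- which(cut != 0L)
  ys <- (w - 1L) %% 100L + 1L
  expect_true(all(ys < 60))
  expect_true(any(m[60, ] != 0L) && all(cut[60, ] == 0L))

  # line entirely below the mask: identity
  far <- make_ellipse_geometry(c(10, 95), 30, 20, 0)
  expect_identical(cut_halfplane(m, minor_axis_line(far)), m)

  # line entirely above the mask: nothing kept
  high <- make_ellipse_geometry(c(10, 20), 15, 10, 0)
  expect_error(cut_halfplane(m, minor_axis_line(high)), "empty-region")
})

test_that("the minor-axis cut retains about half of the ellipse", {
  for (beta_deg in c(-60, -30, -10, 0, 15, 45, 60, 90)) {
    g <- make_ellipse_geometry(c(70, 60), 35, 24, beta_deg * pi / 180)
    full <- rasterize_ellipse(g, c(120, 140))
    upper <- cut_halfplane(full, minor_axis_line(g))
    frac <- sum(upper != 0L) / sum(full != 0L)
    expect_gt(frac, 0.4)
    expect_lt(frac, 0.6)
  }
})
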
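test_that("traced layers validate their contours", {
  expect_error(traced_layer(cbind(1:3, 1:3), cbind(1:4, 2:5), c(0, 0)),
               "4 points")
  crossing_a <- cbind(c(0, 10, 20, 30), c(0, 0, 10, 10))
  crossing_b <- cbind(c(0, 10, 20, 30), c(10, 10, 0, 0))
  expect_error(traced_layer(crossing_a, crossing_b, c(0, 0)), "cross")
})

test_that("midline of parallel lines and annular layers", {
  a <- cbind(seq(0, 100, by = 5), rep(0, 21))
  b <- cbind(seq(0, 100, by = 5), rep(12, 21))
  lay <- traced_layer(a, b, lumen_point = c(50, -50))
  mid <- midline(lay, n = 50)
  expect_equal(mid[, 2], rep(6, 50))
  expect_equal(mid[1, 1], 0)
  expect_equal(mid[50, 1], 100)

  an <- make_phantom("annulus", R = 100, h = 20)
  midr <- sqrt(rowSums(midline(an$layer)^2))
  expect_equal(mean(midr), 100, tolerance = 1e-3)
  expect_lt(diff(range(midr)), 0.5)
})

test_that("arc-length resampling is regular and starts at the apex tip", {
  straight <- cbind(seq(0, 45, by = 1), rep(0, 46))
  rp <- resample_curve(straight, 15)
  expect_equal(rp[, 1], c(0, 15, 30, 45))
  expect_equal(attr(rp, "s"), c(0, 15, 30, 45))

  # circle of circumference (just over) 150 um: 10 intervals of 15 um
  R <- 150 / (2 * pi) * 1.0001
  rp2 <- resample_curve(closed_circle(R, spacing = 0.2), 15)
  expect_equal(nrow(rp2), 11)

  sp <- make_phantom("spiral", a = 50, b = 15, phi_max = 3 * pi, n = 4000)
  rp3 <- resample_curve(sp$points, 15)
  gaps <- sqrt(rowSums(diff(rp3)^2))
  # chord lengths of a 15-um arc step vary by < 1%
  expect_lt(diff(range(gaps)) / mean(gaps), 0.01)

  expect_error(resample_curve(cbind(c(0, 5), c(0, 0)), 15), "shorter")
})

test_that("cubic spline fitting: interpolation, degeneracies, coefficients", {
  set.seed(6)
  pts <- cbind(cumsum(runif(8, 5, 15)), rnorm(8, sd = 3))
  sp <- fit_spline(pts)
  expect_equal(cbind(sp$fx(sp$knots), sp$fy(sp$knots)), pts)

  # collinear points: cubic and quadratic coefficients vanish
  lin <- fit_spline(cbind(seq(0, 70, by = 10), seq(0, 35, by = 5)))
  co <- spline_coefficients(lin, "y")
  expect_equal(co$a, rep(0, 7), tolerance = 1e-10)
  expect_equal(co$b, rep(0, 7), tolerance = 1e-10)

  expect_error(fit_spline(cbind(c(0, 1, 1, 2), c(0, 1, 1, 2))), "duplicate")
  expect_error(fit_spline(cbind(1:3, 1:3)), "4 points")
  expect_error(fit_spline(cbind(c(1, 3, 2, 4), 1:4), mode = "graph"),
               "increasing")

  # graph-mode fit of a cubic: a middle interval reproduces the polynomial
  xk <- seq(-3, 3, length.out = 12)
  spg <- fit_spline(cbind(xk, xk^3), mode = "graph")
  cog <- spline_coefficients(spg)
  i <- 6
  x0 <- cog$u[i]
  expect_equal(cog$a[i], 1, tolerance = 0.05)
  expect_equal(cog$b[i], 3 * x0, tolerance = 0.05)
  expect_equal(cog$c[i], 3 * x0^2, tolerance = 0.05)
  expect_equal(cog$d[i], x0^3, tolerance = 1e-9)
})

test_that("signed curvature: circle oracle, straight lines, graph formula", {
  for (R in c(25, 50, 100, 200)) {
    pr <- curvature_profile(fit_spline(closed_circle(R)),
                            lumen_point = c(0, 0))
    expect_lt(abs(mean(abs(pr$kappa)) * R - 1), 0.01)
    expect_true(all(pr$kappa > 0)) # bending around the lumen is positive
  }

  straight <- fit_spline(cbind(seq(0, 90, by = 10), seq(0, 45, by = 5)))
  expect_lt(max(abs(curvature_profile(straight)$kappa)), 1e-10)

  # graph mode evaluates the printed coefficient formula: at a knot,
  # kappa = 2 b / (1 + c^2)^(3/2)
  set.seed(8)
  xk <- seq(0, 120, by = 12)
  yk <- 10 * sin(xk / 40)
  spg <- fit_spline(cbind(xk, yk), mode = "graph")
  co <- spline_coefficients(spg)
  prg <- curvature_profile(spg, n = length(xk) * 10 - 9)
  at_knots <- prg[match(round(co$u, 6), round(prg$x, 6)), ]
  expect_equal(at_knots$kappa, 2 * co$b / (1 + co$c^2)^1.5, tolerance = 1e-6)
})

test_that("curvature is rigid-motion invariant and scale covariant", {
  sp0 <- make_phantom("spiral", a = 40, b = 12, phi_max = 2.5 * pi, n = 1500)
  pts <- resample_curve(sp0$points, 10)
  k0 <- curvature_profile(fit_spline(pts))$kappa

  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(pts %*% Rm, 2, c(31, -17), "+")
  k1 <- curvature_profile(fit_spline(moved))$kappa
  expect_equal(k1, k0, tolerance = 1e-8)

  k2 <- curvature_profile(fit_spline(pts * 2))$kappa
  expect_equal(k2, k0 / 2, tolerance = 1e-8)
})

test_that("layer thickness from midline normals", {
  a <- cbind(seq(0, 100, by = 2), rep(0, 51))
  b <- cbind(seq(0, 100, by = 2), rep(12, 51))
  lay <- traced_layer(a, b, lumen_point = c(50, -50))
  mid <- midline(lay, n = 30)
  th <- thickness_profile(mid[5:26, ], lay)
  expect_equal(th$thickness, rep(12, 22), tolerance = 1e-9)
  expect_false(any(th$fallback[2:21]))

  an <- make_phantom("annulus", R = 100, h = 20)
  midp <- midline(an$layer)[seq(10, 190, by = 10), ]
  tha <- thickness_profile(midp, an$layer)
  expect_lt(max(abs(tha$thickness - 20)) / 20, 0.02)
  expect_true(all(tha$thickness > 0))
})

test_that("total curvature over normalized arc length", {
  prof <- data.frame(s = seq(0, 1, length.out = 101),
                     kappa = rep(0.02, 101))
  expect_equal(total_curvature(prof), 0.02)

  anti <- data.frame(s = seq(0, 1, length.out = 101),
                     kappa = sin(2 * pi * seq(0, 1, length.out = 101)))
  expect_equal(total_curvature(anti), 0, tolerance = 1e-12)

  # open semicircle of radius R: integral of kappa over normalized s is 1/R
  R <- 80
  th <- seq(0, pi, length.out = 300)
  semi <- cbind(R * cos(th), R * sin(th))
  pr <- curvature_profile(fit_spline(resample_curve(semi, 5)),
                          lumen_point = c(0, 0))
  expect_equal(total_curvature(pr), 1 / R, tolerance = 0.03)

  expect_error(total_curvature(data.frame(s = 1, kappa = 1)), "degenerate")
})

test_that("local edge curvature at 19-um sampling", {
  straightish <- cbind(seq(0, 200, by = 2), rep(3, 101))
  expect_equal(local_edge_curvature(straightish, c(100, 3)), 0,
               tolerance = 1e-12)

  circ <- closed_circle(50, spacing = 0.5)
  ref <- circ[round(nrow(circ) / 2), ]
  k <- local_edge_curvature(circ, ref)
  expect_lt(abs(abs(k) * 50 - 1), 0.02)

  # reversing the tracing direction flips the sign
  k_rev <- local_edge_curvature(circ[nrow(circ):1, ], ref)
  expect_equal(k_rev, -k, tolerance = 1e-9)

  # too little edge around the reference: undefined, flagged
  short_edge <- cbind(seq(0, 40, by = 2), rep(0, 21))
  expect_warning(ks <- local_edge_curvature(short_edge, c(20, 0)), "short")
  expect_true(is.na(ks))
})
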
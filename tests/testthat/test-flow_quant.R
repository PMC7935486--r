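test_that("FRET/CFP ratio: uniform, identity, gain invariance, masking", {
  fr <- channel_stack(array(200, c(20, 20, 2)), 0.625, 12)
  cf <- channel_stack(array(100, c(20, 20, 2)), 0.625, 12)
  rs <- fret_ratio(fr, cf, background = c(0, 0))
  expect_equal(as.vector(rs$ratio), rep(2, 20 * 20 * 2))

  rs1 <- fret_ratio(cf, cf, background = c(0, 0))
  expect_equal(as.vector(rs1$ratio), rep(1, 20 * 20 * 2))

  # common gain cancels (with auto background, which scales along)
  set.seed(1)
  base <- array(50 + 150 * runif(20 * 20 * 2), c(20, 20, 2))
  f1 <- fret_ratio(channel_stack(base * 1.7, 1, 1),
                   channel_stack(base, 1, 1), background = "auto")
  f3 <- fret_ratio(channel_stack(base * 3 * 1.7, 1, 1),
                   channel_stack(base * 3, 1, 1), background = "auto")
  expect_equal(f1$ratio, f3$ratio, tolerance = 1e-6)

  # CFP at or below zero after subtraction is masked undefined
  cc <- array(100, c(10, 10, 1))
  cc[3:5, 3:5, 1] <- 0
  rs2 <- fret_ratio(channel_stack(array(200, c(10, 10, 1)), 1, 1),
                    channel_stack(cc, 1, 1), background = c(0, 0))
  expect_true(all(is.na(rs2$ratio[4, 4, 1])))
  expect_equal(rs2$ratio[8, 8, 1], 2)

  expect_error(fret_ratio(fr, channel_stack(array(1, c(10, 10, 2)), 0.625, 12)),
               "shape")
})

test_that("a single salt pixel is removed by the 3x3 median filter", {
  cf <- array(100, c(15, 15, 1))
  cf[8, 8, 1] <- 5000
  fr <- array(200, c(15, 15, 1))
  rs <- fret_ratio(channel_stack(fr, 1, 1), channel_stack(cf, 1, 1),
                   background = c(0, 0))
  expect_equal(rs$ratio[8, 8, 1], 2, tolerance = 1e-2)
})

test_that("PIV recovers integer and sub-pixel translations", {
  tex <- make_texture(200)
  A <- tex[41:160, 41:160]

  B <- shift_sample(tex, 3, 0)[41:160, 41:160]
  pf <- piv_pair(A, B)
  expect_true(all(pf$valid))
  expect_lt(max(abs(pf$v_row - 3)), 0.1)
  expect_lt(max(abs(pf$v_col)), 0.1)

  B2 <- shift_sample(tex, 0, 2.5)[41:160, 41:160]
  pf2 <- piv_pair(A, B2)
  expect_lt(max(abs(pf2$v_col - 2.5)), 0.2)

  pf3 <- piv_pair(A, A)
  expect_equal(max(abs(c(pf3$v_row, pf3$v_col))), 0, tolerance = 1e-10)

  # physical units: px/frame * pixel_size / frame_interval
  pf4 <- piv_pair(A, B, pixel_size = 0.625, frame_interval = 12)
  expect_equal(mean(pf4$speed_um_min), 3 * 0.625 / 12, tolerance = 0.01)
})

test_that("PIV is equivariant under a common translation of both frames", {
  tex <- make_texture(220, seed = 8)
  A1 <- tex[41:160, 41:160]
  B1 <- shift_sample(tex, 2, 1)[41:160, 41:160]
  A2 <- tex[51:170, 46:165] # both frames cropped 10 rows / 5 cols away
  B2 <- shift_sample(tex, 2, 1)[51:170, 46:165]
  pf1 <- piv_pair(A1, B1)
  pf2 <- piv_pair(A2, B2)
  expect_equal(mean(pf1$v_row), mean(pf2$v_row), tolerance = 0.05)
  expect_equal(mean(pf1$v_col), mean(pf2$v_col), tolerance = 0.05)
})

test_that("textureless interrogation windows are flagged invalid", {
  flat <- matrix(7, 80, 80)
  pf <- piv_pair(flat, flat)
  expect_false(any(pf$valid))
  expect_error(piv_pair(matrix(1, 10, 10), matrix(1, 10, 10)), "window")
  expect_error(piv_pair(matrix(1, 80, 80), matrix(1, 80, 81)), "shape")
})

test_that("vector median filtering rejects outliers and respects gradients", {
  gd <- c(3, 4)
  uni <- manual_piv_field(rep(1:3, 4), rep(1:4, each = 3),
                          rep(0.5, 12), rep(-0.2, 12), gd)
  f1 <- median_filter_field(uni)
  expect_equal(f1$v_row, rep(0.5, 12))
  expect_equal(f1$v_col, rep(-0.2, 12))

  out <- uni
  out$v_row[6] <- 50
  f2 <- median_filter_field(out)
  expect_equal(f2$v_row, rep(0.5, 12))

  # invalid vector replaced by its neighborhood median
  nav <- uni
  nav$v_row[6] <- NA
  nav$valid[6] <- FALSE
  f3 <- median_filter_field(nav)
  expect_equal(f3$v_row[6], 0.5)
  expect_true(f3$valid[6])

  # smooth gradient: filtered values stay within the local range
  grad <- manual_piv_field(rep(1:3, 4), rep(1:4, each = 3),
                           as.vector(outer(1:3, 1:4, "+")), rep(0, 12), gd)
  f4 <- median_filter_field(grad)
  expect_true(all(f4$v_row >= min(grad$v_row) & f4$v_row <= max(grad$v_row)))
})

test_that("velocity projection onto the apex-base line", {
  line <- apex_base_line(cbind(rep(10, 2), c(1, 100)), pixel_size = 1)
  mk <- function(v_row, v_col) {
    manual_piv_field(rep(10, 3), c(20, 50, 80), rep(v_row, 3), rep(v_col, 3),
                     c(1, 3))
  }
  # toward the apex (negative column direction) at 0.24
  pr <- project_onto_line(mk(0, -0.24), line)
  expect_equal(pr$speed, rep(0.24, 3))
  # perpendicular flow projects to zero
  pr2 <- project_onto_line(mk(0.4, 0), line)
  expect_equal(pr2$speed, rep(0, 3))
  # 60 degrees off the tangent: |v| = 1 projects to 0.5
  pr3 <- project_onto_line(mk(sin(pi / 3), -cos(pi / 3)), line)
  expect_equal(pr3$speed, rep(0.5, 3), tolerance = 1e-12)
  # Cauchy-Schwarz bound
  set.seed(2)
  vr <- rnorm(3)
  vc <- rnorm(3)
  pr4 <- project_onto_line(manual_piv_field(rep(10, 3), c(20, 50, 80),
                                            vr, vc, c(1, 3)), line)
  expect_true(all(abs(pr4$speed) <= sqrt(vr^2 + vc^2) + 1e-12))
  # a line far away from every window errors
  far <- apex_base_line(cbind(rep(500, 2), c(1, 100)), pixel_size = 1)
  expect_error(project_onto_line(mk(0, 1), far), "line")
})

test_that("extension-shrinkage rate: gradients, telescoping, smoothing", {
  s <- seq(0, 100, by = 12.5)
  expect_equal(extension_shrinkage_rate(s, rep(0.3, length(s)))$rate,
               rep(0, length(s) - 1))
  lin <- extension_shrinkage_rate(s, s / 100) # 0 -> 1 um/min over 100 um
  expect_equal(lin$rate_raw, rep(0.01, length(s) - 1))
  expect_equal(lin$rate, rep(0.01, length(s) - 1)) # MA of a constant

  set.seed(3)
  sp <- cumsum(runif(9, 5, 20))
  v <- rnorm(9)
  er <- extension_shrinkage_rate(sp, v)
  expect_equal(sum(er$rate_raw * diff(sp)), v[9] - v[1], tolerance = 1e-12)

  # sinusoidal profile: smoothed rate tracks the analytic derivative
  s2 <- seq(0, 300, by = 6)
  sp2 <- 0.3 * sin(2 * pi * s2 / 150)
  er2 <- extension_shrinkage_rate(s2, sp2, smooth_n = 5)
  truth <- 0.3 * (2 * pi / 150) * cos(2 * pi * er2$s / 150)
  expect_lt(max(abs(er2$rate - truth)), 0.15 * max(abs(truth)))

  expect_error(extension_shrinkage_rate(1, 1), "two windows")
  expect_error(extension_shrinkage_rate(c(1, 1), c(0, 1)), "increasing")
})

test_that("windowed ERK activity via Otsu masking and its time derivative", {
  h <- 60
  nt <- 6
  blob <- matrix(FALSE, h, h)
  blob[15:45, 15:45] <- TRUE
  cfp <- array(10, c(h, h, nt))
  fret <- array(20, c(h, h, nt))
  for (k in seq_len(nt)) {
    cfp[, , k][blob] <- 200
    fret[, , k][blob] <- 400
  }
  cs <- channel_stack(cfp, 1, 12)
  fs <- channel_stack(fret, 1, 12)
  rs <- fret_ratio(fs, cs, background = c(0, 0))
  ser <- window_erk_series(rs, cs, centers = cbind(30, 30), window_size = 40)
  expect_equal(ser$activity[, 1], rep(2, nt))
  expect_equal(ser$rate[, 1], rep(0, nt))

  # imposed activity 1 + 0.1 sin(2 pi t / 120): recovered rate matches the
  # analytic derivative within central-difference truncation
  nt2 <- 30
  tt <- (seq_len(nt2) - 1) * 12
  a_t <- 1 + 0.1 * sin(2 * pi * tt / 120)
  cfp2 <- array(10, c(h, h, nt2))
  fret2 <- array(10, c(h, h, nt2))
  for (k in seq_len(nt2)) {
    cfp2[, , k][blob] <- 200
    fret2[, , k][blob] <- 200 * a_t[k]
  }
  rs2 <- fret_ratio(channel_stack(fret2, 1, 12), channel_stack(cfp2, 1, 12),
                    background = c(0, 0))
  ser2 <- window_erk_series(rs2, channel_stack(cfp2, 1, 12),
                            centers = cbind(30, 30), window_size = 40)
  om <- 2 * pi / 120
  interior <- 2:(nt2 - 1)
  truth <- 0.1 * om * cos(om * tt[interior])
  # central differences attenuate by sin(om dt)/(om dt) ~ 0.935 at 12 min
  expect_lt(max(abs(ser2$rate[interior, 1] - truth)),
            0.1 * max(abs(truth)))
  expect_error(window_erk_series(rs2, channel_stack(cfp2, 1, 12),
                                 centers = cbind(5, 5), window_size = 40),
               "outside")
})

test_that("stacks round-trip through float TIFF plus JSON sidecar", {
  set.seed(4)
  s <- channel_stack(array(runif(12 * 10 * 3, 0, 300), c(12, 10, 3)), 0.625, 12)
  path <- file.path(tempdir(), "stack_roundtrip.tif")
  write_stack(s, path)
  s2 <- read_stack(path)
  expect_equal(s2$frames, s$frames, tolerance = 1e-5)
  expect_equal(s2$pixel_size, 0.625)
  expect_equal(s2$frame_interval, 12)
  file.remove(path, paste0(path, ".json"))
})
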
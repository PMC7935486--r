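# run code with a local, seeded RNG; the caller's RNG state is untouched
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic two-channel wave movie
#'
#' Describes a textured epithelium drifting toward the apex with a
#' superimposed retrograde ERK intensity wave, emulating the observables of
#' a cochlear-duct FRET time lapse: the apex sits at column 1, the flow
#' runs toward it, and the ERK wave travels the opposite way at the set
#' speed and wavelength. The local strain-rate oscillation leads the ERK
#' rate by `lag_min`, so the cross-correlation structure of the real data
#' is reproduced with known ground truth.
#'
#' @param width,height image size, px.
#' @param pixel_size um/px (default 0.625, i.e. a 40-px window is 25 um).
#' @param frame_interval min.
#' @param n_frames number of frames.
#' @param flow_speed mean tissue speed toward the apex, um/min.
#' @param wave_speed ERK wave speed toward the base, um/min.
#' @param wavelength ERK wavelength, um.
#' @param wave_amp relative FRET modulation amplitude of the wave.
#' @param strain_amp amplitude of the oscillatory flow component, um/min.
#' @param lag_min minutes by which the strain rate leads the ERK rate.
#' @param grain texture grain (Gaussian blur sigma), px.
#' @param noise_sd additive Gaussian noise s.d. (intensity units).
#' @param seed RNG seed.
#' @return A `wave_movie_spec` list.
#' @export
wave_movie_spec <- function(width = 512L, height = 64L, pixel_size = 0.625,
                            frame_interval = 12, n_frames = 30L,
                            flow_speed = 0.24, wave_speed = 0.42,
                            wavelength = 168, wave_amp = 0.3,
                            strain_amp = 0.05, lag_min = 24,
                            grain = 3, noise_sd = 1, seed = 1L) {
  if (wavelength <= 2 * pixel_size)
    stopf("wavelength is not resolved by the pixel grid")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), flow_speed = flow_speed,
                 wave_speed = wave_speed, wavelength = wavelength,
                 wave_amp = wave_amp, strain_amp = strain_amp,
                 lag_min = lag_min, grain = grain, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "wave_movie_spec")
}

#' Generate a synthetic FRET/CFP wave movie with ground truth
#'
#' CFP is a band-limited random texture advected by the specified flow
#' field (uniform drift toward the apex plus a small traveling oscillation
#' whose strain rate leads the ERK wave rate by the specified lag); FRET is
#' the same texture modulated by the retrograde ERK wave; both carry
#' additive Gaussian noise. Identical spec and seed give bit-identical
#' stacks.
#'
#' @param spec a `wave_movie_spec`.
#' @return List with `fret` and `cfp` (`channel_stack`s), `line` (the
#'   apex-base line along the middle row), and `truth` (flow speed toward
#'   apex, wave speed toward base, wavelength, lag).
#' @export
make_wave_movie <- function(spec) {
  stopifnot(inherits(spec, "wave_movie_spec"))
  ps <- spec$pixel_size
  nt <- spec$n_frames
  h <- spec$height
  wdt <- spec$width
  Tmax <- (nt - 1) * spec$frame_interval
  pad <- ceiling((spec$flow_speed + spec$strain_amp) * Tmax / ps) + 4L
  texw <- wdt + 2L * pad
  tex <- with_seed(spec$seed, {
    raw <- matrix(rnorm(h * texw), h, texw)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(raw), sigma = spec$grain))
    sm <- (sm - min(sm)) / (max(sm) - min(sm))
    20 + 200 * sm^2
  })
  noise <- with_seed(spec$seed + 1L, array(rnorm(h * wdt * nt * 2,
                                                 sd = spec$noise_sd),
                                           dim = c(h, wdt, nt, 2)))
  lam <- spec$wavelength
  b <- 2 * pi * spec$wave_speed / lam # temporal angular frequency
  xs <- (seq_len(wdt) - 1) * ps      # um, apex at x = 0
  theta <- function(x, t) 2 * pi * x / lam - b * t
  cfp <- array(0, c(h, wdt, nt))
  fret <- array(0, c(h, wdt, nt))
  for (k in seq_len(nt)) {
    t <- (k - 1) * spec$frame_interval
    # displacement field (um): integral of u(x,t') from 0 to t at fixed x;
    # u(x,t) = -flow + strain_amp * d/dx-phase term whose rate leads the wave
    tau <- spec$lag_min
    # oscillatory phase chosen so that the pipeline's extension-shrinkage
    # rate (d speed-toward-apex / d arc-from-apex) leads the ERK rate by tau
    disp <- -spec$flow_speed * t +
      (spec$strain_amp / b) * (cos(theta(xs, t + tau)) - cos(theta(xs, tau)))
    src_px <- (xs - disp) / ps + pad + 1 # texture column (1-based, fractional)
    i0 <- floor(src_px)
    f <- src_px - i0
    frame <- tex[, i0, drop = FALSE] * rep(1 - f, each = h) +
      tex[, i0 + 1, drop = FALSE] * rep(f, each = h)
    wv <- 1 + spec$wave_amp * sin(theta(xs, t))
    cfp[, , k] <- frame + noise[, , k, 1]
    fret[, , k] <- frame * rep(wv, each = h) + noise[, , k, 2]
  }
  mid <- h / 2
  line <- apex_base_line(cbind(rep(mid, 2), c(1, wdt)), pixel_size = ps)
  list(
    fret = channel_stack(fret, ps, spec$frame_interval),
    cfp = channel_stack(cfp, ps, spec$frame_interval),
    line = line,
    truth = list(flow_toward_apex = spec$flow_speed,
                 wave_speed_toward_base = spec$wave_speed,
                 wavelength = spec$wavelength, lag_min = spec$lag_min,
                 spec = unclass(spec))
  )
}

#' Geometric phantoms with closed-form ground truth
#'
#' Deterministic generators for the validation geometries used throughout
#' the package: traced circles (known curvature 1/R), annular layers
#' (known midline radius and thickness), Archimedean spirals (closed-form
#' curvature along arc length), rectangular and annular-sector duct masks
#' with landmarks, gradient volumes for projection/region tests, and
#' seeded homogeneous Poisson point fields.
#'
#' @param kind one of `"circle"`, `"annulus"`, `"spiral"`, `"rect_duct"`,
#'   `"sector_duct"`, `"gradient_volume"`, `"poisson_points"`.
#' @param ... kind-specific parameters, all in um unless noted:
#'   \describe{
#'     \item{circle}{`R` (radius), `n` points, `ccw` orientation.}
#'     \item{annulus}{`R` (midline radius), `h` (thickness), `n`,
#'       `arc` (subtended angle, rad; default 1.5*pi).}
#'     \item{spiral}{`a`, `b` (r = a + b phi), `phi_max`, `n`.}
#'     \item{rect_duct}{`width`, `height`, px.}
#'     \item{sector_duct}{`R_in`, `R_out`, `arc` (rad), px per um `scale`.}
#'     \item{gradient_volume}{`width`, `height`, `nz`, intensity gradient
#'       along columns from `lo` to `hi` (8-bit).}
#'     \item{poisson_points}{`rho` (um^-2), `width`, `height`, `seed`.}
#'   }
#' @return List with the phantom geometry and a `truth` element holding the
#'   analytic ground truth.
#' @export
make_phantom <- function(kind = c("circle", "annulus", "spiral", "rect_duct",
                                  "sector_duct", "gradient_volume",
                                  "poisson_points"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  switch(kind,
    circle = phantom_circle(args),
    annulus = phantom_annulus(args),
    spiral = phantom_spiral(args),
    rect_duct = phantom_rect_duct(args),
    sector_duct = phantom_sector_duct(args),
    gradient_volume = phantom_gradient_volume(args),
    poisson_points = phantom_poisson(args)
  )
}

arg_or <- function(args, name, default) {
  if (is.null(args[[name]])) default else args[[name]]
}

phantom_circle <- function(args) {
  R <- arg_or(args, "R", 100)
  n <- arg_or(args, "n", 200)
  ccw <- arg_or(args, "ccw", TRUE)
  arc <- arg_or(args, "arc", 2 * pi)
  th <- seq(0, arc, length.out = n)
  if (!ccw) th <- rev(th)
  pts <- cbind(R * cos(th), R * sin(th))
  list(points = pts, truth = list(kappa = 1 / R, R = R, center = c(0, 0)))
}

phantom_annulus <- function(args) {
  R <- arg_or(args, "R", 100)
  h <- arg_or(args, "h", 20)
  n <- arg_or(args, "n", 200)
  arc <- arg_or(args, "arc", 1.5 * pi)
  th <- seq(0, arc, length.out = n)
  inner <- cbind((R - h / 2) * cos(th), (R - h / 2) * sin(th))
  outer <- cbind((R + h / 2) * cos(th), (R + h / 2) * sin(th))
  list(apical = inner, basal = outer,
       layer = traced_layer(inner, outer, lumen_point = c(0, 0)),
       truth = list(R = R, thickness = h, kappa = 1 / R, center = c(0, 0)))
}

phantom_spiral <- function(args) {
  a <- arg_or(args, "a", 50)
  b <- arg_or(args, "b", 15)
  phi_max <- arg_or(args, "phi_max", 4 * pi)
  n <- arg_or(args, "n", 800)
  phi <- seq(0, phi_max, length.out = n)
  r <- a + b * phi
  pts <- cbind(r * cos(phi), r * sin(phi))
  kappa_of_phi <- function(p) {
    rr <- a + b * p
    (rr^2 + 2 * b^2) / (rr^2 + b^2)^1.5
  }
  list(points = pts, phi = phi, kappa_of_phi = kappa_of_phi,
       truth = list(a = a, b = b, kappa = kappa_of_phi(phi)))
}

phantom_rect_duct <- function(args) {
  w <- arg_or(args, "width", 200L)
  h <- arg_or(args, "height", 60L)
  pad <- 6L
  mask <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  mask[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- TRUE
  # medial curve = top edge, lateral = bottom edge, apex at the left end
  medial <- cbind(rep(pad + 0.5, 2), c(pad + 0.5, pad + w + 0.5))
  lateral <- cbind(rep(pad + h + 0.5, 2), c(pad + 0.5, pad + w + 0.5))
  landmarks <- list(apex = c(pad + h / 2, pad + 1),
                    medial_end = c(pad + 1, pad + w),
                    lateral_end = c(pad + h, pad + w))
  list(mask = mask, medial = medial, lateral = lateral,
       landmarks = landmarks,
       truth = list(width = w, height = h, area = w * h))
}

phantom_sector_duct <- function(args) {
  R_in <- arg_or(args, "R_in", 40)
  R_out <- arg_or(args, "R_out", 90)
  arc <- arg_or(args, "arc", pi)
  npx <- ceiling(2 * R_out) + 10L
  cx <- npx / 2
  rows <- matrix(seq_len(npx), npx, npx)
  cols <- matrix(seq_len(npx), npx, npx, byrow = TRUE)
  rr <- sqrt((rows - cx)^2 + (cols - cx)^2)
  th <- atan2(cols - cx, rows - cx) # 0 along +row axis
  mask <- rr >= R_in & rr <= R_out & th >= 0 & th <= arc
  nth <- 80
  tt <- seq(0.002, arc - 0.002, length.out = nth)
  medial <- cbind(cx + R_in * cos(tt), cx + R_in * sin(tt))
  lateral <- cbind(cx + R_out * cos(tt), cx + R_out * sin(tt))
  list(mask = mask, medial = medial, lateral = lateral,
       center = c(cx, cx),
       truth = list(R_in = R_in, R_out = R_out, arc = arc))
}

phantom_gradient_volume <- function(args) {
  w <- arg_or(args, "width", 120L)
  h <- arg_or(args, "height", 40L)
  nz <- arg_or(args, "nz", 6L)
  lo <- arg_or(args, "lo", 40)
  hi <- arg_or(args, "hi", 240)
  # gradient along rows: the mediolateral axis of a rect_duct phantom
  grad <- matrix(rep(seq(lo, hi, length.out = h), times = w), h, w)
  edu <- array(rep(grad, nz), c(h, w, nz))
  marker <- array(200, c(h, w, nz))
  list(edu = edu, marker = marker,
       truth = list(row_values = seq(lo, hi, length.out = h) / 255))
}

phantom_poisson <- function(args) {
  rho <- arg_or(args, "rho", 0.01)
  w <- arg_or(args, "width", 400)
  h <- arg_or(args, "height", 200)
  seed <- arg_or(args, "seed", 1L)
  pts <- with_seed(seed, {
    n <- rpois(1, rho * w * h)
    cbind(runif(n, 0, w), runif(n, 0, h))
  })
  list(points = pts, bounds = list(x = c(0, w), y = c(0, h)),
       truth = list(rho = rho, area = w * h))
}

#' Paired periodic series with a known lag
#'
#' `a` is a sinusoid of the given period; `b` repeats it delayed by `lag`;
#' independent Gaussian noise is added to both. Used to validate the
#' cross-correlation lag estimator end to end.
#'
#' @param lag delay of `b` behind `a`, min (`a` leads; expected peak lag is
#'   `-lag`).
#' @param period oscillation period, min.
#' @param n number of samples.
#' @param sampling sampling interval, min.
#' @param noise_sd Gaussian noise s.d. (the sinusoid has amplitude 1).
#' @param seed RNG seed.
#' @return List with `t`, `a`, `b`, `truth` (expected peak lag).
#' @export
make_lagged_series <- function(lag, period, n = 200L, sampling = 1,
                               noise_sd = 0, seed = 1L) {
  if (lag != 0 && sampling > lag)
    stopf("sampling interval must not exceed the lag")
  if (n * sampling < 3 * period)
    stopf("series span must cover at least 3 periods")
  tt <- (seq_len(n) - 1) * sampling
  noise <- with_seed(seed, matrix(rnorm(2 * n, sd = noise_sd), n, 2))
  list(t = tt,
       a = sin(2 * pi * tt / period) + noise[, 1],
       b = sin(2 * pi * (tt - lag) / period) + noise[, 2],
       truth = list(peak_lag = -lag, period = period))
}
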
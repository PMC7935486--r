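# Independent oracles and fixture builders shared across the test files.
# Everything here is written directly from the governing equations and
# elementary geometry, independent of the package internals it checks.

# one forward-Euler step of the cell chain, written per equation:
# all derivatives evaluated on the incoming state, then applied at once
r_euler_step <- function(state, params) {
  p <- params
  N <- p$N
  x <- state$x
  E <- state$E
  F <- state$F
  eps <- diff(x) / p$L - 1
  if (p$mode == "uncoupled") {
    centers <- (x[1:N] + x[2:(N + 1)]) / 2
    E <- 0.5 * (sin(pi * (centers + p$v * state$t) / p$w) + 1)
  }
  xdot <- numeric(N + 1)
  for (i in 2:N) {
    el <- if (p$elastic == "printed") {
      p$k * (eps[i] - if (i + 1 <= N) eps[i + 1] else 0)
    } else {
      p$k * (eps[i] - eps[i - 1])
    }
    xdot[i] <- (el + F[i]) / p$eta_c
  }
  xdot[N + 1] <- if (p$tip == "force") {
    (-p$k * eps[N] + p$F_tip) / p$eta_c
  } else {
    p$F_tip / p$eta_c
  }
  Edot <- if (p$mode == "coupled") (tanh(p$alpha * eps) - E) / p$eta_E else 0
  Fdot <- (p$lam * E - F) / p$eta_F
  x2 <- x + p$dt * xdot
  E2 <- if (p$mode == "coupled") E + p$dt * Edot else {
    centers2 <- (x2[1:N] + x2[2:(N + 1)]) / 2
    0.5 * (sin(pi * (centers2 + p$v * (state$t + p$dt)) / p$w) + 1)
  }
  list(t = state$t + p$dt, x = x2, eps = diff(x2) / p$L - 1,
       E = E2, F = F + p$dt * Fdot)
}

# sinusoidal traveling-wave kymograph with additive Gaussian noise
make_kymo_phantom <- function(speed, n_pos = 80, n_t = 80, pos_step = 5,
                              dt = 12, amp = 0.3, noise = 0.05,
                              lambda = 168, seed = 1) {
  s <- (seq_len(n_pos) - 1) * pos_step
  tt <- (seq_len(n_t) - 1) * dt
  m <- outer(s, tt, function(s, t) 1 + amp * sin(2 * pi * (s - speed * t) / lambda))
  set.seed(seed)
  m <- m + matrix(rnorm(length(m), sd = noise), nrow(m))
  structure(m, class = "kymograph", s = s, t = tt,
            pos_step = pos_step, time_step = dt)
}

# sub-pixel resampling of an image shifted by (drow, dcol): the content
# moves by +d, sampled with bilinear interpolation
shift_sample <- function(img, drow, dcol) {
  nr <- nrow(img)
  nc <- ncol(img)
  r <- matrix(seq_len(nr), nr, nc) - drow
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dcol
  r0 <- floor(r)
  c0 <- floor(c)
  fr <- r - r0
  fc <- c - c0
  r0 <- pmin(pmax(r0, 1), nr - 1)
  c0 <- pmin(pmax(c0, 1), nc - 1)
  v <- img[cbind(c(r0), c(c0))] * (1 - c(fr)) * (1 - c(fc)) +
    img[cbind(c(r0 + 1), c(c0))] * c(fr) * (1 - c(fc)) +
    img[cbind(c(r0), c(c0 + 1))] * (1 - c(fr)) * c(fc) +
    img[cbind(c(r0 + 1), c(c0 + 1))] * c(fr) * c(fc)
  matrix(v, nr, nc)
}

# band-limited random texture for PIV tests
make_texture <- function(n = 200, sigma = 2, seed = 7) {
  set.seed(seed)
  raw <- matrix(rnorm(n * n), n, n)
  as.matrix(EBImage::gblur(EBImage::Image(raw), sigma = sigma))
}

# a manually assembled PIV field with the attributes the projection and
# filtering operations rely on
manual_piv_field <- function(row, col, v_row, v_col, grid_dim, step = 20,
                             pixel_size = 1, frame_interval = 1) {
  out <- data.frame(row = row, col = col, v_row = v_row, v_col = v_col,
                    corr = 1, valid = !is.na(v_row))
  out$speed_um_min <- sqrt(out$v_row^2 + out$v_col^2) * pixel_size / frame_interval
  structure(out, class = c("piv_field", "data.frame"),
            window_size = 40L, overlap = 0.5, step = step,
            pixel_size = pixel_size, frame_interval = frame_interval,
            grid_dim = grid_dim)
}

# polygon area (shoelace)
poly_area <- function(p) {
  abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) - p[, 2] * c(p[-1, 1], p[1, 1]))) / 2
}

# closed circle trace with exactly even arc-length spacing
closed_circle <- function(R, spacing = 2, center = c(0, 0)) {
  n <- max(16, round(2 * pi * R / spacing))
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(center[1] + R * cos(th), center[2] + R * sin(th))
}
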
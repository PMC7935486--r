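test_that("default parameters carry the reference set and validate inputs", {
  p <- default_params("coupled")
  expect_equal(p[c("eta_c", "k", "F_tip", "alpha", "eta_E", "eta_F", "lam")],
               list(eta_c = 40, k = 20, F_tip = 6, alpha = 3, eta_E = 30,
                    eta_F = 10, lam = 9))
  expect_equal(p$N, 1000L)
  expect_equal(p$dt, 0.01)
  expect_equal(p$L, 5)
  expect_identical(p$mode, "coupled")

  pu <- default_params("uncoupled")
  expect_equal(pu$w, 84)
  expect_equal(pu$v, 0.42)

  expect_error(default_params("x"))
  expect_error(chain_params(40, 20, 5, 6, 3, 30, 10, 9, dt = 50),
               "explicit-Euler")
  expect_error(chain_params(40, 20, 5, 6, 3, 30, 10, 9, N = 1), "N")
  expect_error(chain_params(-1, 20, 5, 6, 3, 30, 10, 9), "eta_c")
})

test_that("the chain initializes at rest spacing", {
  p <- chain_params(40, 20, 5, 6, 3, 30, 10, 9, N = 3)
  st <- init_chain(p)
  expect_equal(st$x, c(0, 5, 10, 15))
  expect_equal(st$eps, rep(0, 3))
  expect_equal(st$E, rep(0, 3))
  expect_equal(st$t, 0)
  big <- init_chain(default_params("coupled"))
  expect_equal(big$x[1001], 5000)
})

test_that("one Euler step matches an independent per-equation evaluation", {
  mk_state <- function(N, L) {
    x <- (0:N) * L + c(0, cumsum(rep(c(0.4, -0.2), length.out = N)))
    structure(list(t = 3, x = x, eps = diff(x) / L - 1,
                   E = seq(-0.5, 0.5, length.out = N),
                   F = seq(0, 4, length.out = N)),
              class = "chain_state")
  }
  for (mode in c("coupled", "uncoupled")) {
    for (elastic in c("conventional", "printed")) {
      for (tip in c("kinematic", "force")) {
        p <- chain_params(40, 20, 5, 6, 3, 30, 10, 9, N = 4, dt = 0.01,
                          mode = mode,
                          w = if (mode == "uncoupled") 84 else NULL,
                          v = if (mode == "uncoupled") 0.42 else NULL,
                          elastic = elastic, tip = tip)
        st <- mk_state(4, 5)
        got <- euler_step(st, p)
        want <- r_euler_step(st, p)
        expect_equal(got$x, want$x, tolerance = 1e-14)
        expect_equal(got$E, want$E, tolerance = 1e-14)
        expect_equal(got$F, want$F, tolerance = 1e-14)
        expect_equal(got$eps, want$eps, tolerance = 1e-14)
        expect_equal(got$t, want$t)
      }
    }
  }
})

test_that("direct evaluation of the junction velocity and fixed points", {
  # interior junction: net elastic strain difference 0.1 and force 6 nN
  # moves at (20 * 0.1 + 6) / 40 = 0.2 um/min
  p <- chain_params(40, 20, 5, 6, 3, 30, 10, 9, N = 3, dt = 0.01)
  x <- c(0, 5, 10.5, 15.5) # eps = (0, 0.1, 0); junction 2: eps_2 - eps_1 = 0.1
  st <- structure(list(t = 0, x = x, eps = diff(x) / 5 - 1,
                       E = c(0, 0, 0), F = c(0, 6, 0)),
                  class = "chain_state")
  st2 <- euler_step(st, p)
  expect_equal((st2$x[2] - st$x[2]) / p$dt, 0.2)

  # eps = 0, E = 0 is a fixed point of the ERK relaxation
  rest <- init_chain(p)
  expect_equal(euler_step(rest, p)$E, rep(0, 3))

  # E = 1, F = lam = 9 is a fixed point of the force relaxation
  st3 <- structure(list(t = 0, x = c(0, 5, 10, 15), eps = rep(0, 3),
                        E = rep(1, 3), F = rep(9, 3)),
                   class = "chain_state")
  expect_equal(euler_step(st3, p)$F, rep(9, 3))
})

test_that("without tip force and contractility the rest state is exact", {
  p <- chain_params(40, 20, 5, F_tip = 0, alpha = 3, eta_E = 30, eta_F = 10,
                    lam = 0, N = 50, dt = 0.01)
  traj <- run_chain(p, duration = 300, record_interval = 5, discard = 0)
  expect_true(all(traj$eps == 0))
  expect_true(all(traj$E == 0))
  expect_true(all(traj$F == 0))
})

test_that("coupled ERK activity stays within [-1, 1] and forces stay bounded", {
  p <- chain_params(40, 20, 5, 6, 3, 30, 10, 9, N = 120, dt = 0.01)
  traj <- run_chain(p, duration = 1500, record_interval = 5, discard = 0,
                    record_x = TRUE)
  expect_true(all(abs(traj$E) <= 1))
  expect_true(all(abs(traj$F) <= 9 + 1e-9))
})

test_that("retrograde waves: ERK stripes drift opposite to the cell flow", {
  p <- chain_params(40, 20, 5, 6, 3, 30, 10, 9, N = 120, dt = 0.01)
  traj <- run_chain(p, duration = 1500, record_interval = 5, discard = 600,
                    record_x = TRUE)
  # mean junction motion is forward (toward the tip)
  drift <- mean(traj$x[nrow(traj$x), ]) - mean(traj$x[1, ])
  expect_gt(drift, 0)
  # ERK stripe displacement over 20 min, in cell index, is backward
  cells <- 60:110
  i0 <- 100
  prof0 <- traj$E[i0, cells]
  shifts <- -10:10
  cc <- vapply(shifts, function(sh) {
    cor(prof0, traj$E[i0 + 4, cells + sh])
  }, numeric(1))
  expect_lt(shifts[which.max(cc)], 0)
})

test_that("the printed elastic orientation is numerically unstable", {
  p <- chain_params(40, 20, 5, 6, 3, 30, 10, 9, N = 100, dt = 0.01,
                    elastic = "printed")
  expect_error(run_chain(p, duration = 300, record_interval = 5, discard = 0),
               "unstable")
})

test_that("imposed ERK wave: range, 168-um period, retrograde crest", {
  p <- default_params("uncoupled")
  X <- seq(0, 1000, by = 0.25)
  E <- imposed_erk(X, t = 37, p)
  expect_true(all(E >= 0 & E <= 1))
  expect_equal(imposed_erk(X + 168, 37, p), E, tolerance = 1e-12)
  expect_gt(max(abs(imposed_erk(X + 84, 37, p) - E)), 0.5)
  # crest displaces by -v per minute (toward the fixed base)
  Xf <- seq(300, 500, by = 0.001)
  crest0 <- Xf[which.max(imposed_erk(Xf, 100, p))]
  crest1 <- Xf[which.max(imposed_erk(Xf, 110, p))]
  expect_equal(crest1 - crest0, -10 * p$v, tolerance = 1e-2)
  expect_error(imposed_erk(X, 0, default_params("coupled")), "uncoupled")
})

test_that("rate series are central-difference derivatives of the records", {
  tt <- seq(0, 600, by = 2)
  om <- 2 * pi / 150
  fake <- structure(list(t = tt,
                         eps = matrix(sin(om * tt), ncol = 1),
                         E = matrix(cos(om * tt), ncol = 1),
                         record_interval = 2,
                         params = default_params("coupled")),
                    class = "chain_trajectory")
  r <- model_rate_series(fake)
  interior <- 2:(length(tt) - 1)
  expect_lt(max(abs(r$d_eps[interior, 1] - om * cos(om * tt[interior]))),
            om^2 * 2^2) # second-order truncation bound
  expect_lt(max(abs(r$d_E[interior, 1] + om * sin(om * tt[interior]))),
            om^2 * 2^2)
  const <- fake
  const$eps <- matrix(1, length(tt), 1)
  expect_true(all(model_rate_series(const)$d_eps == 0))
  fake$t <- fake$t[1:2]
  fake$eps <- fake$eps[1:2, , drop = FALSE]
  fake$E <- fake$E[1:2, , drop = FALSE]
  expect_error(model_rate_series(fake), "3")
})

test_that("cross-correlation lag: identity, shifts, ties, errors", {
  tt <- 0:399
  a <- sin(2 * pi * tt / 50)
  same <- xcorr_lag(a, a, max_lag = 30)
  expect_equal(same$peak_lag, 0)
  expect_equal(same$peak_corr, 1, tolerance = 1e-12)

  b <- sin(2 * pi * (tt - 7) / 50) # delayed: a leads by 7
  expect_equal(xcorr_lag(a, b, max_lag = 30)$peak_lag, -7)
  # dt scaling
  expect_equal(xcorr_lag(a, b, max_lag = 360, dt = 12)$peak_lag, -84)

  expect_error(xcorr_lag(rep(1, 50), rnorm(50), max_lag = 10), "variance")
  expect_error(xcorr_lag(a, b[-1], max_lag = 10), "length")
  expect_error(xcorr_lag(a[1:20], b[1:20], max_lag = 25), "span")
  expect_true(all(abs(same$corr) <= 1 + 1e-12))
})

test_that("cross-correlation curve agrees with stats::ccf", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 120
    a <- as.numeric(arima.sim(list(ar = 0.7), n))
    b <- as.numeric(arima.sim(list(ar = 0.5), n))
    mine <- xcorr_lag(a, b, max_lag = 20)
    ref <- ccf(a, b, lag.max = 20, plot = FALSE, demean = TRUE)
    expect_equal(mine$corr, as.numeric(ref$acf), tolerance = 1e-10)
    expect_equal(mine$lags, as.numeric(ref$lag))
  }
})

test_that("white-noise pairs give only small spurious peak correlations", {
  peaks <- vapply(1:4, function(seed) {
    set.seed(seed)
    abs(xcorr_lag(rnorm(100), rnorm(100), max_lag = 25)$peak_corr)
  }, numeric(1))
  expect_lt(median(peaks), 0.3)
  set.seed(11)
  expect_lt(abs(xcorr_lag(rnorm(400), rnorm(400), max_lag = 25)$peak_corr),
            0.25)
})

test_that("halving the Euler step leaves the lag estimates unchanged", {
  lag_at_dt <- function(dt, mode) {
    p <- chain_params(40, 20, 5, 6, 3, 30, 10, 9, N = 300, dt = dt,
                      mode = mode,
                      w = if (mode == "uncoupled") 84 else NULL,
                      v = if (mode == "uncoupled") 0.42 else NULL)
    model_lag(run_chain(p, duration = 3000, discard = 1000,
                        record_x = FALSE))$lag
  }
  expect_lt(abs(lag_at_dt(0.01, "coupled") - lag_at_dt(0.005, "coupled")), 1)
  expect_lt(abs(lag_at_dt(0.01, "uncoupled") - lag_at_dt(0.005, "uncoupled")), 1)
})

test_that("wave speeds convert to cell diameters per hour", {
  expect_equal(cells_per_hour(0.42, 4), 6)
  expect_equal(cells_per_hour(1.4, 10), 8)
  expect_equal(cells_per_hour(0.42, 4, round = FALSE), 6.3)
})
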
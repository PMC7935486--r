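#' Default parameter set of the mechanochemical cell-chain model
#'
#' Returns the reference parameter set of the 1D spring-chain model of the
#' elongating cochlear-duct epithelium: cells are linear springs (constant
#' `k`, rest length `L`) joined at junctions that move against a viscous
#' substrate friction `eta_c`; stretch activates ERK through a saturating
#' response with sensitivity `alpha` and timescale `eta_E`; ERK activity
#' drives contractile force with amplitude `lam` and timescale `eta_F`; the
#' basal junction is fixed and the apical tip junction advances under the
#' self-propelling force `F_tip`.
#'
#' In the `"uncoupled"` regime the strain-to-ERK feedback is severed and ERK
#' activity is prescribed as a retrograde traveling wave of half-wavelength
#' `w` (84 um, i.e. a 168-um wavelength) and speed `v` (0.42 um/min), the
#' values measured on explanted cochlear ducts.
#'
#' @param mode `"coupled"` (closed mechanochemical feedback) or
#'   `"uncoupled"` (imposed ERK wave).
#' @return A `chain_params` object (list of model constants).
#' @examples
#' default_params("coupled")
#' @export
default_params <- function(mode = c("coupled", "uncoupled")) {
  mode <- match.arg(mode)
  p <- list(
    eta_c = 40, k = 20, L = 5, F_tip = 6, alpha = 3,
    eta_E = 30, eta_F = 10, lam = 9,
    N = 1000L, dt = 0.01, mode = mode,
    elastic = "conventional", tip = "kinematic"
  )
  if (mode == "uncoupled") {
    p$w <- 84
    p$v <- 0.42
  }
  do.call(chain_params, p)
}

#' Construct and validate chain-model parameters
#'
#' @param eta_c viscous friction at junctions, nN min/um.
#' @param k spring constant, nN.
#' @param L rest cell length, um.
#' @param F_tip tip self-propelling force, nN.
#' @param alpha strain sensitivity of ERK activation (dimensionless).
#' @param eta_E ERK relaxation timescale, min.
#' @param eta_F force relaxation timescale, min.
#' @param lam force amplitude per unit ERK activity, nN.
#' @param N number of cells.
#' @param dt forward-Euler time step, min; must be smaller than both
#'   relaxation timescales.
#' @param mode `"coupled"` or `"uncoupled"`.
#' @param w half-wavelength of the imposed ERK wave, um (uncoupled only).
#' @param v speed of the imposed ERK wave, um/min (uncoupled only).
#' @param elastic orientation of the elastic term at junction i:
#'   `"conventional"` uses k(eps_i - eps_(i-1)) (tension difference of the
#'   adjacent springs); `"printed"` uses k(eps_i - eps_(i+1)).
#' @param tip moving-boundary form at the apical junction: `"kinematic"`
#'   advances it at its free-motion speed F_tip/eta_c; `"force"` balances
#'   the last spring against F_tip.
#' @return A validated `chain_params` object.
#' @export
chain_params <- function(eta_c, k, L, F_tip, alpha, eta_E, eta_F, lam,
                         N = 1000L, dt = 0.01,
                         mode = c("coupled", "uncoupled"),
                         w = NULL, v = NULL,
                         elastic = c("conventional", "printed"),
                         tip = c("kinematic", "force")) {
  mode <- match.arg(mode)
  elastic <- match.arg(elastic)
  tip <- match.arg(tip)
  for (nm in c("eta_c", "k", "L", "eta_E", "eta_F", "dt"))
    check_number(get(nm), nm)
  for (nm in c("F_tip", "alpha", "lam")) { # zero allowed (e.g. rest tests)
    check_number(get(nm), nm, positive = FALSE)
    if (get(nm) < 0) stopf("'%s' must be >= 0", nm)
  }
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stopf("'N' must be an integer >= 2")
  if (dt >= min(eta_E, eta_F))
    stopf("'dt' (%g) must be < min(eta_E, eta_F) = %g for explicit-Euler stability",
          dt, min(eta_E, eta_F))
  if (mode == "uncoupled") {
    check_number(w, "w")
    check_number(v, "v")
  }
  p <- list(eta_c = eta_c, k = k, L = L, F_tip = F_tip, alpha = alpha,
            eta_E = eta_E, eta_F = eta_F, lam = lam, N = as.integer(N),
            dt = dt, mode = mode, w = w, v = v, elastic = elastic, tip = tip)
  structure(p, class = "chain_params")
}

#' @export
print.chain_params <- function(x, ...) {
  cat(sprintf("chain_params: %s regime, N = %d cells, dt = %g min\n",
              x$mode, x$N, x$dt))
  cat(sprintf("  eta_c=%g k=%g L=%g F_tip=%g alpha=%g eta_E=%g eta_F=%g lam=%g\n",
              x$eta_c, x$k, x$L, x$F_tip, x$alpha, x$eta_E, x$eta_F, x$lam))
  if (x$mode == "uncoupled")
    cat(sprintf("  imposed wave: half-wavelength w=%g um, speed v=%g um/min\n",
                x$w, x$v))
  cat(sprintf("  elastic term: %s; tip boundary: %s\n", x$elastic, x$tip))
  invisible(x)
}

#' Initial rest state of the cell chain
#'
#' Junctions at rest spacing `L`, zero strain, zero ERK activity and zero
#' contractile force at `t = 0`. Waves are subsequently seeded
#' deterministically by the tip forcing, so no stochastic initial condition
#' is needed.
#'
#' @param params a `chain_params` object.
#' @return A `chain_state` object with fields `t`, `x` (junction positions,
#'   length N+1), `eps`, `E`, `F` (per cell, length N).
#' @export
init_chain <- function(params) {
  stopifnot(inherits(params, "chain_params"))
  N <- params$N
  structure(list(t = 0, x = (0:N) * params$L,
                 eps = numeric(N), E = numeric(N), F = numeric(N)),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  N <- length(x$E)
  cat(sprintf("chain_state at t = %g min: %d cells, span %.2f um\n",
              x$t, N, x$x[N + 1] - x$x[1]))
  cat(sprintf("  strain in [%.3f, %.3f], ERK in [%.3f, %.3f]\n",
              min(x$eps), max(x$eps), min(x$E), max(x$E)))
  invisible(x)
}

check_state <- function(state, params) {
  stopifnot(inherits(state, "chain_state"), inherits(params, "chain_params"))
  N <- params$N
  if (length(state$x) != N + 1 || length(state$E) != N || length(state$F) != N)
    stopf("state dimensions do not match params (N = %d)", N)
  if (any(diff(state$x) <= 0))
    stopf("junction positions must be strictly increasing")
  invisible(TRUE)
}

run_cpp <- function(state, params, n_steps, record_every, discard_steps,
                    record_x = TRUE) {
  p <- params
  .chain_run_cpp(state$x, state$E, state$F, state$t,
                 p$eta_c, p$k, p$L, p$F_tip, p$alpha, p$eta_E, p$eta_F,
                 p$lam, p$dt, as.numeric(n_steps), as.numeric(record_every),
                 as.numeric(discard_steps),
                 as.integer(p$mode == "uncoupled"),
                 if (is.null(p$w)) 1 else p$w, if (is.null(p$v)) 0 else p$v,
                 as.integer(p$elastic == "printed"),
                 as.integer(p$tip == "force"), as.integer(record_x))
}

#' Advance the chain by one forward-Euler step
#'
#' All derivatives are evaluated on the current state and applied
#' simultaneously; strains are recomputed from the updated junction
#' positions. An error is raised if the update breaks the junction ordering
#' (numerical instability).
#'
#' @param state a `chain_state`.
#' @param params a `chain_params`.
#' @return The updated `chain_state` at `t + dt`.
#' @export
euler_step <- function(state, params) {
  check_state(state, params)
  r <- run_cpp(state, params, n_steps = 1, record_every = 1,
               discard_steps = 2, record_x = FALSE)
  structure(list(t = r$t_final, x = r$x_final,
                 eps = diff(r$x_final) / params$L - 1,
                 E = r$E_final, F = r$F_final),
            class = "chain_state")
}

#' Imposed retrograde ERK wave of the uncoupled regime
#'
#' `E(X, t) = 0.5 * (sin(pi * (X + v t) / w) + 1)`: a sinusoidal wave of
#' spatial period `2w` traveling toward the fixed (basal) end at speed `v`,
#' bounded in `[0, 1]`.
#'
#' @param X position, um (vectorised).
#' @param t time, min.
#' @param params an uncoupled `chain_params` (fields `w`, `v`).
#' @return ERK activity values in `[0, 1]`.
#' @export
imposed_erk <- function(X, t, params) {
  stopifnot(inherits(params, "chain_params"))
  if (params$mode != "uncoupled")
    stopf("imposed_erk() applies to the uncoupled regime only")
  0.5 * (sin(pi * (X + params$v * t) / params$w) + 1)
}

#' Integrate the cell-chain model and record a trajectory
#'
#' Iterates the forward-Euler step, discards the initial transient, and
#' records per-cell strain, ERK activity and force (and junction positions)
#' on a regular grid. With the default parameters the coupled regime
#' develops a sustained train of retrograde ERK activity waves emitted near
#' the advancing tip.
#'
#' @param params a `chain_params`.
#' @param duration total simulated time, min.
#' @param record_interval recording interval, min (>= `dt`).
#' @param discard initial transient to drop, min.
#' @param init optional initial `chain_state` (default [init_chain()]).
#' @param record_x record junction positions as well (needed for CSV export
#'   and Eulerian analyses; adds memory).
#' @return A `chain_trajectory`: list with `t` (record times), matrices
#'   `eps`, `E`, `F` of size (records x N), optionally `x`
#'   (records x (N+1)), plus `record_interval` and `params`.
#' @export
run_chain <- function(params, duration = 6000, record_interval = 1,
                      discard = 2000, init = NULL, record_x = TRUE) {
  stopifnot(inherits(params, "chain_params"))
  check_number(duration, "duration")
  check_number(record_interval, "record_interval")
  check_number(discard, "discard", positive = FALSE)
  if (discard < 0 || duration <= discard)
    stopf("need duration > discard >= 0")
  if (record_interval < params$dt)
    stopf("record_interval must be >= dt")
  state <- if (is.null(init)) init_chain(params) else init
  check_state(state, params)
  n_steps <- round(duration / params$dt)
  rec <- round(record_interval / params$dt)
  disc <- round(discard / params$dt)
  r <- run_cpp(state, params, n_steps, rec, disc, record_x = record_x)
  structure(list(t = r$t, eps = r$eps, E = r$E, F = r$F,
                 x = r$x, record_interval = record_interval, params = params),
            class = "chain_trajectory")
}

#' @export
print.chain_trajectory <- function(x, ...) {
  cat(sprintf("chain_trajectory: %s regime, %d cells, %d records (t = %g..%g min, every %g min)\n",
              x$params$mode, ncol(x$E), length(x$t), min(x$t), max(x$t),
              x$record_interval))
  invisible(x)
}

#' @describeIn run_chain Space-time image of ERK activity (cells x time) of
#'   a recorded trajectory; oblique stripes are the traveling waves.
#' @param col color palette.
#' @param ... passed to [graphics::image()].
#' @param x a `chain_trajectory`.
#' @export
plot.chain_trajectory <- function(x, col = hcl.colors(64, "viridis"), ...) {
  image(x = x$t, y = seq_len(ncol(x$E)) * x$params$L, z = x$E,
        xlab = "time (min)", ylab = "position (um)", col = col,
        main = sprintf("ERK activity, %s regime", x$params$mode), ...)
  invisible(x)
}

#' @export
as.data.frame.chain_trajectory <- function(x, ...) {
  N <- ncol(x$E)
  nt <- length(x$t)
  data.frame(
    time = rep(x$t, times = N),
    cell = rep(seq_len(N), each = nt),
    x = if (!is.null(x$x)) as.vector((x$x[, 1:N] + x$x[, 2:(N + 1)]) / 2) else NA_real_,
    eps = as.vector(x$eps),
    E = as.vector(x$E),
    F = as.vector(x$F)
  )
}

#' Per-cell rate time series of a trajectory
#'
#' Central-difference time derivatives of per-cell strain (the
#' extension-shrinkage rate of the model) and of ERK activity, on the
#' recording grid; one-sided differences at the ends.
#'
#' @param traj a `chain_trajectory` with at least 3 records.
#' @return List with `t`, matrices `d_eps` and `d_E` (records x N), both in
#'   min^-1.
#' @export
model_rate_series <- function(traj) {
  stopifnot(inherits(traj, "chain_trajectory"))
  if (length(traj$t) < 3) stopf("need at least 3 recorded snapshots")
  dt <- traj$record_interval
  list(t = traj$t, d_eps = time_derivative(traj$eps, dt),
       d_E = time_derivative(traj$E, dt))
}

# central differences down columns of a (time x series) matrix,
# one-sided at the first/last sample
time_derivative <- function(m, dt) {
  m <- as.matrix(m)
  n <- nrow(m)
  d <- m
  d[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (m[2, ] - m[1, ]) / dt
  d[n, ] <- (m[n, ] - m[n - 1, ]) / dt
  d
}

#' Normalized cross-correlation and peak lag of two series
#'
#' Both series are z-scored and correlated over lags in
#' `[-max_lag, +max_lag]`; the correlation at lag `l` aligns `a(t)` with
#' `b(t - l)`, so a negative peak lag means the first series leads
#' (precedes) the second. Ties at the peak are broken toward the smaller
#' absolute lag.
#'
#' @param a,b equal-length, uniformly sampled numeric series.
#' @param max_lag largest lag examined, in time units.
#' @param dt sampling interval (time units per sample), default 1.
#' @return An `xcorr_result`: list with `lags`, `corr`, `peak_lag`,
#'   `peak_corr`.
#' @examples
#' t <- 0:199
#' a <- sin(2 * pi * t / 50)
#' b <- sin(2 * pi * (t - 7) / 50) # b delayed: a leads by 7
#' xcorr_lag(a, b, max_lag = 20)$peak_lag
#' @export
xcorr_lag <- function(a, b, max_lag, dt = 1) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stopf("series must have equal length")
  n <- length(a)
  L <- floor(max_lag / dt)
  if (L >= n) stopf("max_lag must be smaller than the series span")
  if (sd(a) == 0 || sd(b) == 0) stopf("zero-variance series")
  za <- (a - mean(a)) / sd(a)
  zb <- (b - mean(b)) / sd(b)
  lags <- (-L):L
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(za[(1 + l):n] * zb[1:(n - l)]) / (n - 1)
    else sum(za[1:(n + l)] * zb[(1 - l):n]) / (n - 1)
  }, numeric(1))
  i <- which(cc == max(cc))
  i <- i[which.min(abs(lags[i]))]
  structure(list(lags = lags * dt, corr = cc,
                 peak_lag = lags[i] * dt, peak_corr = cc[i]),
            class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("xcorr_result: peak lag %g (corr %.3f) over lags [%g, %g]\n",
              x$peak_lag, x$peak_corr, min(x$lags), max(x$lags)))
  invisible(x)
}

#' Cross-correlation lag between strain rate and ERK rate of the model
#'
#' For each analysis cell, cross-correlates the extension-shrinkage rate
#' (d eps/dt) against the ERK activity rate (d E/dt) and takes the peak lag;
#' the summary is the median over cells. By default the analysis cells sit
#' at 84--90% of the chain, inside the established wave train adjacent to
#' the tip generation zone (cells whose oscillation is near-sinusoidal);
#' cells without detectable oscillation are dropped.
#'
#' A negative lag means the strain rate leads the ERK rate.
#'
#' @param traj a `chain_trajectory` recorded at (sub-)minute resolution.
#' @param cells indices of analysis cells; default
#'   `round(seq(0.84, 0.90, by = 0.01) * N)`.
#' @param max_lag largest lag examined, min.
#' @return List with `lag` (median peak lag, min), `per_cell` (named vector
#'   of per-cell peak lags), and `cells`.
#' @export
model_lag <- function(traj, cells = NULL, max_lag = 120) {
  stopifnot(inherits(traj, "chain_trajectory"))
  N <- ncol(traj$E)
  if (is.null(cells)) cells <- unique(round(seq(0.84, 0.90, by = 0.01) * N))
  rates <- model_rate_series(traj)
  per <- vapply(cells, function(j) {
    a <- rates$d_eps[, j]
    b <- rates$d_E[, j]
    if (sd(a) < 1e-9 || sd(b) < 1e-9) return(NA_real_)
    xcorr_lag(a, b, max_lag = max_lag, dt = traj$record_interval)$peak_lag
  }, numeric(1))
  names(per) <- cells
  if (all(is.na(per))) stopf("no analysis cell shows detectable oscillation")
  list(lag = median(per, na.rm = TRUE), per_cell = per, cells = cells)
}

#' Wave speed expressed in cell diameters per hour
#'
#' Converts a wave speed in um/min into cell diameters per hour given a
#' typical cell length, rounding to the nearest integer as customarily
#' quoted when comparing epithelia with different cell sizes.
#'
#' @param speed_um_min wave speed, um/min.
#' @param cell_length_um typical cell diameter, um.
#' @param round round to the nearest integer (default TRUE).
#' @return Speed in cells per hour.
#' @examples
#' cells_per_hour(0.42, 4) # 6
#' cells_per_hour(1.4, 10) # 8
#' @export
cells_per_hour <- function(speed_um_min, cell_length_um, round = TRUE) {
  check_number(speed_um_min, "speed_um_min")
  check_number(cell_length_um, "cell_length_um")
  v <- speed_um_min * 60 / cell_length_um
  if (round) round(v) else v
}
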
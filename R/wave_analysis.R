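#' Kymograph of ERK activity along the apex-base line
#'
#' Samples the ratio stack along the line at regular arc-length steps; at
#' each sample the activity is averaged over a band of `band_width` px
#' perpendicular to the line (1-px spacing, bilinear interpolation).
#' Columns are frames, rows run from the apex tip toward the base.
#'
#' @param ratio a `ratio_stack` (or `channel_stack`; its `frames` are used).
#' @param line an `apex_base_line` within the image.
#' @param band_width band width perpendicular to the line, px.
#' @param step arc-length sampling step, um; default half the default PIV
#'   grid spacing (10 px).
#' @return A `kymograph`: matrix `[position x time]` with attributes `s`
#'   (um from apex), `t` (min), `pos_step`, `time_step`.
#' @export
kymograph <- function(ratio, line, band_width = 20L, step = NULL) {
  frames <- if (inherits(ratio, "ratio_stack")) ratio$ratio else ratio$frames
  fi <- ratio$frame_interval
  ps <- ratio$pixel_size
  stopifnot(inherits(line, "apex_base_line"))
  if (band_width < 1) stopf("band_width must be >= 1")
  if (is.null(step)) step <- 10 * ps
  total <- max(line$s)
  if (total <= step) stopf("line too short for the sampling step")
  svals <- seq(0, total, by = step)
  pts <- t(vapply(svals, function(sv) line_point(line, sv), numeric(4)))
  # pts: row, col, tangent (row, col); normal = rotate tangent by 90 deg
  nrm <- cbind(-pts[, 4], pts[, 3])
  offs <- seq(-(band_width - 1) / 2, (band_width - 1) / 2, by = 1)
  nt <- dim(frames)[3]
  km <- matrix(NA_real_, length(svals), nt)
  for (k in seq_len(nt)) {
    fr <- frames[, , k]
    for (i in seq_along(svals)) {
      rr <- pts[i, 1] + offs * nrm[i, 1]
      cc <- pts[i, 2] + offs * nrm[i, 2]
      km[i, k] <- mean(bilinear(fr, rr, cc), na.rm = TRUE)
    }
  }
  structure(km, class = "kymograph", s = svals,
            t = (seq_len(nt) - 1) * fi, pos_step = step, time_step = fi)
}

# point and unit tangent at arc length sv (um) on the polyline
line_point <- function(line, sv) {
  s <- line$s
  i <- findInterval(sv, s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(s) - 1L)
  f <- (sv - s[i]) / (s[i + 1] - s[i])
  p <- line$points[i, ] + f * (line$points[i + 1, ] - line$points[i, ])
  d <- line$points[i + 1, ] - line$points[i, ]
  c(p, d / sqrt(sum(d^2)))
}

# bilinear interpolation of a matrix at (row, col) positions; NA outside
bilinear <- function(m, r, c) {
  nr <- nrow(m)
  nc <- ncol(m)
  r0 <- floor(r)
  c0 <- floor(c)
  fr <- r - r0
  fc <- c - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  out <- rep(NA_real_, length(r))
  if (any(ok)) {
    i <- which(ok)
    v00 <- m[cbind(r0[i], c0[i])]
    v10 <- m[cbind(r0[i] + 1, c0[i])]
    v01 <- m[cbind(r0[i], c0[i] + 1)]
    v11 <- m[cbind(r0[i] + 1, c0[i] + 1)]
    out[i] <- v00 * (1 - fr[i]) * (1 - fc[i]) + v10 * fr[i] * (1 - fc[i]) +
      v01 * (1 - fr[i]) * fc[i] + v11 * fr[i] * fc[i]
  }
  out
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d positions (step %g um) x %d frames (step %g min)\n",
              nrow(x), attr(x, "pos_step"), ncol(x), attr(x, "time_step")))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, col = hcl.colors(64, "viridis"), ...) {
  image(x = attr(x, "t"), y = attr(x, "s"), z = t(unclass(x)),
        xlab = "time (min)", ylab = "arc length from apex (um)",
        col = col, ...)
  invisible(x)
}

#' Traveling-wave speed from a kymograph
#'
#' Detects per-time-column activity maxima, links them across columns into
#' ridges (nearest continuation within `max_jump` position steps), fits a
#' line position ~ time to each ridge, and reports the mean and dispersion
#' of the per-ridge speeds. Positive ridge slope (position growing from the
#' apex) means apex-to-base propagation.
#'
#' @param kymo a `kymograph`.
#' @param min_len minimum ridge length, frames.
#' @param max_jump largest ridge step between consecutive frames, position
#'   samples.
#' @param min_prominence drop maxima whose activity is below this quantile
#'   of the kymograph (0 disables).
#' @param smooth_pos moving-average span (position samples) applied to each
#'   time column before maxima detection; `NULL` (default) picks about a
#'   sixth of the dominant spatial wavelength estimated from the kymograph.
#' @return A `wave_speed_estimate`: list with `speed` (mean um/min), `sd`,
#'   `n_ridges`, `per_ridge` (signed slopes, um/min), `direction`.
#' @export
wave_speed <- function(kymo, min_len = 5L, max_jump = 3L,
                       min_prominence = 0.5, smooth_pos = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  s <- attr(kymo, "s")
  tt <- attr(kymo, "t")
  km <- unclass(kymo)
  wl <- dominant_wavelength(km) # samples; NA if spectrum is featureless
  if (is.null(smooth_pos))
    smooth_pos <- if (is.na(wl)) 3L else max(3L, round(wl / 6))
  min_sep <- if (is.na(wl)) 0 else wl / 2
  if (smooth_pos > 1) km <- apply(km, 2, smooth_ma, n = smooth_pos)
  thr <- quantile(km, min_prominence, na.rm = TRUE, names = FALSE)
  ridges <- list() # each: list(rows, cols)
  active <- list()
  for (k in seq_along(tt)) {
    prof <- km[, k]
    mx <- local_maxima(prof)
    mx <- mx[prof[mx] >= thr]
    mx <- thin_maxima(mx, prof[mx], min_sep)
    sub <- parabolic_offsets(prof, mx)
    used <- rep(FALSE, length(mx))
    if (length(active)) {
      keep <- logical(length(active))
      for (ai in seq_along(active)) {
        rr <- active[[ai]]$rows
        # predict the next crest row from the ridge's recent drift
        last_row <- tail(rr, 1)
        if (length(rr) >= 2) {
          recent <- tail(diff(rr), 4)
          last_row <- last_row + median(recent)
        }
        if (length(mx)) {
          dd <- abs(mx - last_row)
          j <- which.min(dd)
          if (dd[j] <= max_jump && !used[j]) {
            active[[ai]]$rows <- c(active[[ai]]$rows, mx[j])
            active[[ai]]$cols <- c(active[[ai]]$cols, k)
            active[[ai]]$sub <- c(active[[ai]]$sub, sub[j])
            used[j] <- TRUE
            keep[ai] <- TRUE
            next
          }
        }
        ridges[[length(ridges) + 1]] <- active[[ai]]
      }
      active <- active[keep]
    }
    for (j in which(!used))
      active[[length(active) + 1]] <- list(rows = mx[j], cols = k, sub = sub[j])
  }
  ridges <- c(ridges, active)
  # maxima pinned near the domain edges (partially visible crests) flatten
  # the fitted slope; exclude an edge margin before fitting
  margin <- if (is.na(wl)) smooth_pos else max(smooth_pos, round(wl / 4))
  nr <- nrow(km)
  ridges <- lapply(ridges, function(r) {
    keep <- r$rows > margin & r$rows <= nr - margin
    list(rows = r$rows[keep], cols = r$cols[keep], sub = r$sub[keep])
  })
  ridges <- Filter(function(r) length(r$cols) >= min_len, ridges)
  if (!length(ridges)) stopf("no ridges detected in the kymograph")
  # keep only well-tracked ridges: at least half as long as the longest
  longest <- max(vapply(ridges, function(r) length(r$cols), numeric(1)))
  ridges <- Filter(function(r) length(r$cols) >= longest / 2, ridges)
  pos_step <- attr(kymo, "pos_step")
  slopes <- vapply(ridges, function(r) {
    unname(coef(lm(I(s[r$rows] + r$sub * pos_step) ~ tt[r$cols]))[2])
  }, numeric(1))
  len <- vapply(ridges, function(r) length(r$cols), numeric(1))
  structure(list(speed = sum(abs(slopes) * len) / sum(len),
                 sd = if (length(slopes) > 1) sd(abs(slopes)) else NA_real_,
                 n_ridges = length(slopes), per_ridge = slopes,
                 ridge_len = len,
                 direction = if (sum(slopes * len) >= 0) "apex-to-base" else "base-to-apex"),
            class = "wave_speed_estimate")
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# parabolic sub-sample refinement of maxima positions (offset in samples)
parabolic_offsets <- function(prof, mx) {
  vapply(mx, function(r) {
    if (r <= 1 || r >= length(prof)) return(0)
    ym <- prof[r - 1]
    y0 <- prof[r]
    yp <- prof[r + 1]
    den <- ym - 2 * y0 + yp
    if (!is.finite(den) || den >= 0) return(0)
    off <- 0.5 * (ym - yp) / den
    if (abs(off) > 1) 0 else off
  }, numeric(1))
}

# greedy non-maximum suppression: keep the highest maxima at least
# min_sep samples apart
thin_maxima <- function(mx, heights, min_sep) {
  if (min_sep <= 0 || length(mx) < 2) return(mx)
  ord <- order(heights, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || all(abs(mx[i] - kept) >= min_sep))
      kept <- c(kept, mx[i])
  sort(kept)
}

# dominant spatial period (in samples) of the mean detrended column
# spectrum; NA when no clear periodic component exists
dominant_wavelength <- function(km) {
  n <- nrow(km)
  if (n < 8) return(NA_real_)
  pw <- rep(0, n)
  for (k in seq_len(ncol(km))) {
    col <- km[, k]
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col <- col - mean(col)
    pw <- pw + Mod(fft(col))^2
  }
  half <- 2:floor(n / 2) # skip the DC component
  if (!length(half) || all(pw[half] == 0)) return(NA_real_)
  fi <- half[which.max(pw[half])]
  if (pw[fi] < 4 * mean(pw[half])) return(NA_real_) # featureless spectrum
  n / (fi - 1)
}

#' @export
print.wave_speed_estimate <- function(x, ...) {
  cat(sprintf("wave speed: %.3f +/- %.3f um/min (%d ridges, %s)\n",
              x$speed, ifelse(is.na(x$sd), 0, x$sd), x$n_ridges, x$direction))
  invisible(x)
}

#' Cross-correlation lag between paired window series
#'
#' Applies [xcorr_lag()] to each column pair of two series matrices on a
#' shared time grid (e.g. extension-shrinkage rate vs ERK activity rate per
#' interrogation window) and summarises the per-window peak lags.
#'
#' @param a,b numeric matrices (time x window) or vectors on the same grid.
#' @param max_lag largest lag examined, time units.
#' @param dt sampling interval.
#' @return List with `mean_lag`, `sd_lag`, `per_window` (peak lags) and
#'   `results` (the per-window `xcorr_result`s).
#' @export
pair_lag <- function(a, b, max_lag, dt = 1) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stopf("series matrices differ in shape")
  res <- lapply(seq_len(ncol(a)), function(j) {
    ok <- !is.na(a[, j]) & !is.na(b[, j])
    xcorr_lag(a[ok, j], b[ok, j], max_lag = max_lag, dt = dt)
  })
  per <- vapply(res, `[[`, numeric(1), "peak_lag")
  list(mean_lag = mean(per), sd_lag = if (length(per) > 1) sd(per) else 0,
       per_window = per, results = res)
}
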
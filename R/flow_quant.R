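#' Timed single-channel image stack
#'
#' Container for one fluorescence channel of a time lapse: a numeric array
#' `[rows, cols, frames]` with the physical calibration needed downstream.
#'
#' @param frames numeric array `[rows, cols, frames]` (a matrix is taken as
#'   a single frame).
#' @param pixel_size um per pixel.
#' @param frame_interval min between frames (the PIV pairing interval).
#' @return A `channel_stack` object.
#' @export
channel_stack <- function(frames, pixel_size, frame_interval = 12) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stopf("'frames' must be a [rows, cols, frames] array")
  check_number(pixel_size, "pixel_size")
  check_number(frame_interval, "frame_interval")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("channel_stack: %d x %d px, %d frames, %g um/px, %g min/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

# 3x3 median filter per frame (EBImage constant-time median filter;
# frames are rescaled into [0,1] for filtering and scaled back)
median3 <- function(frame) {
  rng <- range(frame)
  if (rng[1] == rng[2]) return(frame)
  f <- (frame - rng[1]) / (rng[2] - rng[1])
  g <- EBImage::medianFilter(f, size = 1)
  as.matrix(g) * (rng[2] - rng[1]) + rng[1]
}

estimate_background <- function(frame, frac = 0.01) {
  q <- quantile(frame, frac, names = FALSE)
  mean(frame[frame <= q])
}

#' FRET/CFP ratiometric ERK activity stack
#'
#' Per frame and channel: 3x3 median filtering to remove shot noise, then
#' background subtraction, then the pixelwise FRET/CFP ratio. Pixels whose
#' background-subtracted CFP signal is not positive carry no ratio and are
#' set to `NA`.
#'
#' @param fret,cfp matching `channel_stack`s.
#' @param background per-channel background: `"auto"` (mean of the darkest
#'   1% of pixels, per frame and channel), a numeric length-2 vector
#'   `c(fret, cfp)`, or a logical mask matrix marking a background region
#'   whose per-frame mean is used.
#' @return A `ratio_stack`: list with `ratio` (array, `NA` where undefined),
#'   `intensity` (filtered background-subtracted FRET brightness), and the
#'   calibration of the inputs.
#' @export
fret_ratio <- function(fret, cfp, background = "auto") {
  stopifnot(inherits(fret, "channel_stack"), inherits(cfp, "channel_stack"))
  if (!identical(dim(fret$frames), dim(cfp$frames)))
    stopf("FRET and CFP stacks differ in shape")
  if (fret$pixel_size != cfp$pixel_size ||
      fret$frame_interval != cfp$frame_interval)
    stopf("FRET and CFP stacks differ in calibration")
  d <- dim(fret$frames)
  ratio <- array(NA_real_, d)
  intensity <- array(0, d)
  for (k in seq_len(d[3])) {
    f <- median3(fret$frames[, , k])
    c0 <- median3(cfp$frames[, , k])
    bg <- background_pair(background, f, c0)
    f <- f - bg[1]
    c0 <- c0 - bg[2]
    r <- f / c0
    r[c0 <= 0] <- NA_real_
    ratio[, , k] <- r
    intensity[, , k] <- f
  }
  structure(list(ratio = ratio, intensity = intensity,
                 pixel_size = fret$pixel_size,
                 frame_interval = fret$frame_interval),
            class = "ratio_stack")
}

background_pair <- function(background, f, c0) {
  if (identical(background, "auto"))
    return(c(estimate_background(f), estimate_background(c0)))
  if (is.logical(background)) {
    if (!identical(dim(background), dim(f)))
      stopf("background mask shape does not match the frames")
    return(c(mean(f[background]), mean(c0[background])))
  }
  if (is.numeric(background) && length(background) == 2L) return(background)
  if (is.numeric(background) && length(background) == 1L)
    return(rep(background, 2))
  stopf("'background' must be \"auto\", one or two numbers, or a logical mask")
}

#' @export
print.ratio_stack <- function(x, ...) {
  d <- dim(x$ratio)
  cat(sprintf("ratio_stack: %d x %d px, %d frames; ratio in [%.3g, %.3g] (%.1f%% undefined)\n",
              d[1], d[2], d[3], min(x$ratio, na.rm = TRUE),
              max(x$ratio, na.rm = TRUE), 100 * mean(is.na(x$ratio))))
  invisible(x)
}

# interrogation-window grid: centers of fully interior windows
piv_grid <- function(nrow, ncol, window_size, overlap) {
  step <- round(window_size * (1 - overlap))
  if (step < 1) stopf("overlap too large for the window size")
  r0 <- seq(1L, nrow - window_size + 1L, by = step)
  c0 <- seq(1L, ncol - window_size + 1L, by = step)
  list(row0 = r0, col0 = c0, step = step,
       crow = r0 + window_size / 2 - 0.5, ccol = c0 + window_size / 2 - 0.5)
}

# normalized (zero-padded) cross-correlation displacement of one window
# pair, with 3-point Gaussian sub-pixel refinement;
# returns c(drow, dcol, peak_corr) or NA for textureless windows
window_displacement <- function(A, B, max_disp) {
  A <- A - mean(A)
  B <- B - mean(B)
  if (sum(A^2) == 0 || sum(B^2) == 0) return(c(NA_real_, NA_real_, NA_real_))
  n <- nrow(A)
  P <- 2L * n
  pad <- function(m) {
    out <- matrix(0, P, P)
    out[1:n, 1:n] <- m
    out
  }
  FA <- fft(pad(A))
  FB <- fft(pad(B))
  FI <- fft(pad(matrix(1, n, n)))
  FA2 <- fft(pad(A^2))
  FB2 <- fft(pad(B^2))
  xc <- function(Ff, Gf) Re(fft(Conj(Ff) * Gf, inverse = TRUE)) / P^2
  cross <- xc(FA, FB)        # sum A(x) B(x+s)
  na2 <- xc(FA2, FI)         # sum A(x)^2 over the overlap
  nb2 <- xc(FI, FB2)         # sum B(x+s)^2 over the overlap
  den <- sqrt(pmax(na2, 0) * pmax(nb2, 0))
  cc <- ifelse(den > 1e-12, cross / den, -Inf)
  sh <- c(0:(P %/% 2 - 1), -(P %/% 2):(-1)) # shift per (wrapped) index
  keep <- abs(sh) <= max_disp
  m <- cc
  m[!keep, ] <- -Inf
  m[, !keep] <- -Inf
  idx <- arrayInd(which.max(m), dim(m))
  pk <- c(sh[idx[1]], sh[idx[2]])
  wrap <- function(i) ((i - 1) %% P) + 1
  ref <- function(cm, c0, cp) {
    if (cm > 0 && c0 > 0 && cp > 0 && (2 * log(c0) - log(cm) - log(cp)) > 0)
      (log(cm) - log(cp)) / (2 * (log(cm) + log(cp) - 2 * log(c0)))
    else if ((2 * c0 - cm - cp) > 0) (cm - cp) / (2 * (cm + cp - 2 * c0))
    else 0
  }
  dr <- ref(cc[wrap(idx[1] - 1), idx[2]], cc[idx[1], idx[2]],
            cc[wrap(idx[1] + 1), idx[2]])
  dc <- ref(cc[idx[1], wrap(idx[2] - 1)], cc[idx[1], idx[2]],
            cc[idx[1], wrap(idx[2] + 1)])
  c(pk[1] + dr, pk[2] + dc, cc[idx[1], idx[2]])
}

#' Particle image velocimetry on one frame pair
#'
#' Splits the frames into interrogation windows (default 40 px with 50%
#' overlap), estimates per-window displacement as the peak of the
#' normalized cross-correlation with 3-point Gaussian sub-pixel refinement,
#' and flags windows without texture as invalid.
#'
#' @param frameA,frameB matrices of identical shape (time `T` and `T + dt`).
#' @param window_size interrogation window side, px (even).
#' @param overlap window overlap fraction.
#' @param pixel_size um/px (for velocity conversion).
#' @param frame_interval min between the frames.
#' @param max_disp largest accepted displacement, px (default a quarter
#'   window).
#' @return A `piv_field`: data frame with window centers (`row`, `col`, px),
#'   displacements `v_row`, `v_col` (px per frame pair), `speed_um_min`,
#'   `corr`, `valid`; grid metadata in attributes.
#' @export
piv_pair <- function(frameA, frameB, window_size = 40L, overlap = 0.5,
                     pixel_size = 1, frame_interval = 1,
                     max_disp = window_size / 4) {
  frameA <- as.matrix(frameA)
  frameB <- as.matrix(frameB)
  if (!identical(dim(frameA), dim(frameB))) stopf("frames differ in shape")
  if (window_size %% 2 != 0) stopf("window_size must be even")
  if (any(dim(frameA) < window_size)) stopf("frames smaller than one window")
  g <- piv_grid(nrow(frameA), ncol(frameA), window_size, overlap)
  res <- expand.grid(r0 = g$row0, c0 = g$col0)
  disp <- t(apply(res, 1, function(rc) {
    rows <- rc[1]:(rc[1] + window_size - 1L)
    cols <- rc[2]:(rc[2] + window_size - 1L)
    window_displacement(frameA[rows, cols], frameB[rows, cols], max_disp)
  }))
  out <- data.frame(
    row = rep(g$crow, times = length(g$col0)),
    col = rep(g$ccol, each = length(g$row0)),
    v_row = disp[, 1], v_col = disp[, 2], corr = disp[, 3],
    valid = !is.na(disp[, 1])
  )
  out$speed_um_min <- sqrt(out$v_row^2 + out$v_col^2) * pixel_size / frame_interval
  structure(out, class = c("piv_field", "data.frame"),
            window_size = window_size, overlap = overlap,
            step = g$step, pixel_size = pixel_size,
            frame_interval = frame_interval,
            grid_dim = c(length(g$crow), length(g$ccol)))
}

#' Median filtering of a PIV vector field
#'
#' Componentwise median over the `(2 radius + 1)^2` neighborhood on the
#' window grid; invalid vectors are excluded from the medians and replaced
#' by their neighborhood median.
#'
#' @param field a `piv_field`.
#' @param radius neighborhood radius in grid units.
#' @return The smoothed `piv_field`.
#' @export
median_filter_field <- function(field, radius = 1L) {
  stopifnot(inherits(field, "piv_field"))
  gd <- attr(field, "grid_dim")
  u <- matrix(field$v_row, gd[1], gd[2])
  v <- matrix(field$v_col, gd[1], gd[2])
  medn <- function(m) {
    out <- m
    for (i in seq_len(gd[1])) for (j in seq_len(gd[2])) {
      ri <- max(1, i - radius):min(gd[1], i + radius)
      cj <- max(1, j - radius):min(gd[2], j + radius)
      nb <- m[ri, cj]
      out[i, j] <- median(nb, na.rm = TRUE)
    }
    out
  }
  u2 <- medn(u)
  v2 <- medn(v)
  field$v_row <- as.vector(u2)
  field$v_col <- as.vector(v2)
  field$valid <- !is.na(field$v_row)
  ps <- attr(field, "pixel_size")
  fi <- attr(field, "frame_interval")
  field$speed_um_min <- sqrt(field$v_row^2 + field$v_col^2) * ps / fi
  field
}

#' Apex-base measurement line
#'
#' An ordered polyline in pixel coordinates, starting at the apex tip and
#' running toward the base, with cumulative arc length in um.
#'
#' @param points two-column matrix `(row, col)` in px, ordered from the
#'   apex tip.
#' @param pixel_size um/px.
#' @return An `apex_base_line` with fields `points` (px) and `s` (um from
#'   the apex tip).
#' @export
apex_base_line <- function(points, pixel_size = 1) {
  points <- check_matrix2(points, "points")
  if (nrow(points) < 2) stopf("line needs at least 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) stopf("line has duplicate consecutive points")
  structure(list(points = points, s = c(0, cumsum(seg)) * pixel_size,
                 pixel_size = pixel_size),
            class = "apex_base_line")
}

# nearest point on a polyline: returns index of segment, closest point,
# distance, tangent (unit, in direction of increasing arc length), s (um)
nearest_on_line <- function(line, p) {
  pts <- line$points
  nseg <- nrow(pts) - 1
  best <- NULL
  for (i in seq_len(nseg)) {
    a <- pts[i, ]
    d <- pts[i + 1, ] - a
    len2 <- sum(d^2)
    tt <- max(0, min(1, sum((p - a) * d) / len2))
    q <- a + tt * d
    dist <- sqrt(sum((p - q)^2))
    if (is.null(best) || dist < best$dist) {
      s_here <- line$s[i] + tt * (line$s[i + 1] - line$s[i])
      best <- list(dist = dist, q = q, tangent = d / sqrt(len2), s = s_here)
    }
  }
  best
}

#' Project PIV velocities onto the apex-base line
#'
#' Window centers lying within one grid spacing of the line are assigned to
#' it; each velocity is converted to um/min and projected on the local unit
#' tangent. The elongation speed is reported positive toward the apex (the
#' line is ordered apex to base, so this is minus the tangential component).
#'
#' @param field a `piv_field` (positions in px).
#' @param line an `apex_base_line` on the same image.
#' @param max_dist assignment distance, px (default one grid spacing).
#' @return Data frame ordered by arc length: `s` (um from apex), `speed`
#'   (um/min toward the apex), plus the window center and index.
#' @export
project_onto_line <- function(field, line, max_dist = NULL) {
  stopifnot(inherits(field, "piv_field"), inherits(line, "apex_base_line"))
  if (is.null(max_dist)) max_dist <- attr(field, "step")
  ps <- attr(field, "pixel_size")
  fi <- attr(field, "frame_interval")
  rows <- lapply(seq_len(nrow(field)), function(i) {
    np <- nearest_on_line(line, c(field$row[i], field$col[i]))
    if (np$dist > max_dist || !field$valid[i]) return(NULL)
    vel <- c(field$v_row[i], field$v_col[i]) * ps / fi
    data.frame(s = np$s, speed = -sum(vel * np$tangent), window = i,
               row = field$row[i], col = field$col[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stopf("no PIV window lies on the line")
  out <- out[order(out$s), ]
  # windows from parallel grid rows can land on the same arc position;
  # collapse entries closer than half a grid spacing along the line
  grp <- cumsum(c(TRUE, diff(out$s) > attr(field, "step") * ps / 2))
  out <- data.frame(
    s = as.numeric(tapply(out$s, grp, mean)),
    speed = as.numeric(tapply(out$speed, grp, mean)),
    window = as.integer(tapply(out$window, grp, function(x) x[1])),
    row = as.numeric(tapply(out$row, grp, mean)),
    col = as.numeric(tapply(out$col, grp, mean))
  )
  rownames(out) <- NULL
  out
}

# MATLAB-style moving average: window shrinks symmetrically at the ends
smooth_ma <- function(x, n = 5L) {
  n <- as.integer(n)
  if (n <= 1) return(x)
  half <- n %/% 2
  vapply(seq_along(x), function(i) {
    h <- min(half, i - 1, length(x) - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Extension-shrinkage rate along the apex-base line
#'
#' The diagonal strain-rate component: finite difference of the elongation
#' speed between adjacent interrogation windows along the line, divided by
#' their separation in arc length, then smoothed with a moving average
#' (default 5 samples).
#'
#' @param s arc-length positions of the windows, um (ordered).
#' @param speed elongation speeds at those windows, um/min.
#' @param smooth_n moving-average span in samples (1 = no smoothing).
#' @return Data frame with `s` (midpoint arc length), `rate` (smoothed,
#'   min^-1) and `rate_raw` (unsmoothed).
#' @export
extension_shrinkage_rate <- function(s, speed, smooth_n = 5L) {
  if (length(s) != length(speed)) stopf("'s' and 'speed' differ in length")
  if (length(s) < 2) stopf("need at least two windows along the line")
  if (any(diff(s) <= 0)) stopf("'s' must be strictly increasing")
  raw <- diff(speed) / diff(s)
  data.frame(s = (s[-1] + s[-length(s)]) / 2,
             rate = smooth_ma(raw, smooth_n), rate_raw = raw)
}

#' Per-window ERK activity and its rate over time
#'
#' Within each interrogation window and frame, Otsu's threshold on the CFP
#' channel extracts the cytoplasmic region and the ERK activity is the mean
#' FRET/CFP ratio over that mask. Frames with an empty mask are `NA` and
#' isolated `NA`s are linearly interpolated. The ERK activity rate is the
#' central-difference time derivative.
#'
#' @param ratio a `ratio_stack`.
#' @param cfp the matching CFP `channel_stack`.
#' @param centers two-column matrix of window centers `(row, col)`, px.
#' @param window_size window side, px.
#' @return List with `t` (min), matrices `activity` and `rate`
#'   (frames x windows).
#' @export
window_erk_series <- function(ratio, cfp, centers, window_size = 40L) {
  stopifnot(inherits(ratio, "ratio_stack"), inherits(cfp, "channel_stack"))
  centers <- check_matrix2(centers, "centers")
  d <- dim(ratio$ratio)
  half <- window_size / 2
  nt <- d[3]
  act <- matrix(NA_real_, nt, nrow(centers))
  for (wi in seq_len(nrow(centers))) {
    r0 <- round(centers[wi, 1] - half + 1)
    c0 <- round(centers[wi, 2] - half + 1)
    if (r0 < 1 || c0 < 1 || r0 + window_size - 1 > d[1] ||
        c0 + window_size - 1 > d[2])
      stopf("window %d extends outside the image", wi)
    rows <- r0:(r0 + window_size - 1)
    cols <- c0:(c0 + window_size - 1)
    for (k in seq_len(nt)) {
      cw <- cfp$frames[rows, cols, k]
      rng <- range(cw)
      if (rng[1] == rng[2]) next
      thr <- EBImage::otsu((cw - rng[1]) / (rng[2] - rng[1]), levels = 256)
      mask <- (cw - rng[1]) / (rng[2] - rng[1]) > thr
      vals <- ratio$ratio[rows, cols, k][mask]
      vals <- vals[!is.na(vals)]
      if (length(vals)) act[k, wi] <- mean(vals)
    }
    act[, wi] <- fill_isolated_na(act[, wi])
  }
  rate <- time_derivative(act, ratio$frame_interval)
  list(t = (seq_len(nt) - 1) * ratio$frame_interval,
       activity = act, rate = rate)
}

# linear interpolation of isolated interior NAs only
fill_isolated_na <- function(x) {
  nas <- which(is.na(x))
  for (i in nas) {
    if (i > 1 && i < length(x) && !is.na(x[i - 1]) && !is.na(x[i + 1]))
      x[i] <- (x[i - 1] + x[i + 1]) / 2
  }
  x
}
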
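#' Traced epithelial layer
#'
#' The manually traced apical and basal contours of an epithelial layer,
#' in um, both ordered from the apex tip, plus a reference point on the
#' lumen side used to orient the curvature sign.
#'
#' @param apical,basal two-column coordinate matrices (um), >= 4 points
#'   each, ordered from the apex tip.
#' @param lumen_point a point on the lumen side of the layer (um).
#' @return A `traced_layer`.
#' @export
traced_layer <- function(apical, basal, lumen_point) {
  apical <- check_matrix2(apical, "apical")
  basal <- check_matrix2(basal, "basal")
  if (nrow(apical) < 4 || nrow(basal) < 4)
    stopf("each contour needs at least 4 points")
  lumen_point <- as.numeric(lumen_point)
  if (length(lumen_point) != 2) stopf("'lumen_point' must be one 2D point")
  if (polylines_intersect(apical, basal))
    stopf("apical and basal contours cross")
  structure(list(apical = apical, basal = basal, lumen_point = lumen_point),
            class = "traced_layer")
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1
  d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(FALSE)
  t1 <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  t2 <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  t1 >= 0 && t1 <= 1 && t2 >= 0 && t2 <= 1
}

polylines_intersect <- function(a, b) {
  for (i in seq_len(nrow(a) - 1))
    for (j in seq_len(nrow(b) - 1))
      if (segments_intersect(a[i, ], a[i + 1, ], b[j, ], b[j + 1, ]))
        return(TRUE)
  FALSE
}

arc_lengths <- function(pts) c(0, cumsum(sqrt(rowSums(diff(pts)^2))))

# resample a polyline at given arc-length positions (linear interpolation)
polyline_at <- function(pts, s_target) {
  s <- arc_lengths(pts)
  cbind(approx(s, pts[, 1], xout = s_target)$y,
        approx(s, pts[, 2], xout = s_target)$y)
}

#' Midline of a traced layer
#'
#' The medial curve of the layer: both contours are resampled at matched
#' normalized arc length and the midpoints are taken. For layer-like
#' (roughly parallel) contours this coincides with the skeleton of the
#' enclosed band.
#'
#' @param layer a `traced_layer`.
#' @param n number of midline samples.
#' @return Two-column matrix of midline points (um), ordered from the apex
#'   tip.
#' @export
midline <- function(layer, n = 200L) {
  stopifnot(inherits(layer, "traced_layer"))
  ta <- seq(0, 1, length.out = n)
  a <- polyline_at(layer$apical, ta * max(arc_lengths(layer$apical)))
  b <- polyline_at(layer$basal, ta * max(arc_lengths(layer$basal)))
  (a + b) / 2
}

#' Resample a curve at regular arc-length intervals
#'
#' Returns points equally spaced in arc length (default every 15 um),
#' starting at the first point (the apex tip).
#'
#' @param curve two-column matrix of ordered points (um).
#' @param interval spacing, um.
#' @return Two-column matrix of resampled points; attribute `s` carries the
#'   arc-length positions.
#' @export
resample_curve <- function(curve, interval = 15) {
  curve <- check_matrix2(curve, "curve")
  check_number(interval, "interval")
  total <- max(arc_lengths(curve))
  if (total < interval) stopf("curve (%.3g um) shorter than the sampling interval", total)
  sv <- seq(0, total, by = interval)
  structure(polyline_at(curve, sv), s = sv)
}

#' Interpolating natural cubic spline through sampled curve points
#'
#' Default is a parametric fit (chord-length parameter, one natural cubic
#' per coordinate), which represents curled curves that are not graphs of a
#' function; `mode = "graph"` fits y = S(x) directly for formula-level work
#' on monotone-x samples. Per-interval coefficients (a, b, c, d) of
#' `S_i(u) = a (u - u_i)^3 + b (u - u_i)^2 + c (u - u_i) + d` are exposed
#' via [spline_coefficients()].
#'
#' @param points two-column matrix of >= 4 sample points (um); for graph
#'   mode, strictly increasing x.
#' @param mode `"parametric"` or `"graph"`.
#' @return A `spline_curve`: knots (parameter values), coordinate
#'   interpolants, and the sample points.
#' @export
fit_spline <- function(points, mode = c("parametric", "graph")) {
  mode <- match.arg(mode)
  points <- check_matrix2(points, "points")
  if (nrow(points) < 4) stopf("need at least 4 points for a cubic spline")
  if (any(rowSums(diff(points)^2) == 0))
    stopf("duplicate consecutive points")
  if (mode == "graph") {
    if (any(diff(points[, 1]) <= 0))
      stopf("graph mode needs strictly increasing x")
    u <- points[, 1]
    fy <- splinefun(u, points[, 2], method = "natural")
    fx <- NULL
  } else {
    # closed curves get periodic end conditions (no end-flattening bias);
    # open curves keep natural ends
    closed <- nrow(points) >= 5 &&
      sqrt(sum((points[1, ] - points[nrow(points), ])^2)) < 1e-9
    meth <- if (closed) "periodic" else "natural"
    if (closed) points[nrow(points), ] <- points[1, ]
    u <- arc_lengths(points)
    fx <- splinefun(u, points[, 1], method = meth)
    fy <- splinefun(u, points[, 2], method = meth)
  }
  structure(list(knots = u, fx = fx, fy = fy, mode = mode, points = points),
            class = "spline_curve")
}

#' @export
print.spline_curve <- function(x, ...) {
  cat(sprintf("spline_curve (%s): %d knots over [%g, %g]\n",
              x$mode, length(x$knots), min(x$knots), max(x$knots)))
  invisible(x)
}

#' Per-interval cubic coefficients of a fitted spline
#'
#' @param spline a `spline_curve`.
#' @param coord `"y"` (default; the only choice in graph mode) or `"x"`.
#' @return Data frame with one row per interval: knot `u_i` and
#'   coefficients `a`, `b`, `c`, `d`.
#' @export
spline_coefficients <- function(spline, coord = c("y", "x")) {
  stopifnot(inherits(spline, "spline_curve"))
  coord <- match.arg(coord)
  f <- if (coord == "y") spline$fy else spline$fx
  if (is.null(f)) stopf("no x-coordinate spline in graph mode")
  u <- spline$knots
  n <- length(u)
  i <- seq_len(n - 1)
  d <- f(u[i])
  c_ <- f(u[i], deriv = 1)
  b <- f(u[i], deriv = 2) / 2
  b_next <- f(u[i + 1], deriv = 2) / 2
  a <- (b_next - b) / (3 * diff(u))
  data.frame(u = u[i], a = a, b = b, c = c_, d = d)
}

# signed curvature of the parametric spline at parameter values
parametric_curvature <- function(spline, at) {
  x1 <- spline$fx(at, deriv = 1)
  x2 <- spline$fx(at, deriv = 2)
  y1 <- spline$fy(at, deriv = 1)
  y2 <- spline$fy(at, deriv = 2)
  (x1 * y2 - y1 * x2) / (x1^2 + y1^2)^1.5
}

#' Signed curvature profile along a fitted epithelial curve
#'
#' In parametric mode the standard parametric curvature is evaluated; in
#' graph mode the spline-coefficient formula
#' `kappa_i(x) = (6a(x - x_i) + 2b) / (1 + (3a(x - x_i)^2 + 2b(x - x_i) + c)^2)^(3/2)`
#' is used. The sign is oriented by the lumen: curvature is positive where
#' the curve bends toward (is convex around) the lumen side, independent of
#' the tracing direction.
#'
#' @param spline a `spline_curve`.
#' @param lumen_point point on the lumen side (um); `NULL` keeps the
#'   orientation-dependent standard sign.
#' @param n number of evaluation points along the curve.
#' @return A `curvature_profile` data frame: `arc` (um from the first
#'   point), `s` (normalized arc length in `[0, 1]`), `kappa` (um^-1), and
#'   the evaluation coordinates.
#' @export
curvature_profile <- function(spline, lumen_point = NULL, n = 200L) {
  stopifnot(inherits(spline, "spline_curve"))
  u <- seq(min(spline$knots), max(spline$knots), length.out = n)
  if (spline$mode == "graph") {
    x <- u
    y <- spline$fy(u)
    y1 <- spline$fy(u, deriv = 1)
    y2 <- spline$fy(u, deriv = 2)
    kap <- y2 / (1 + y1^2)^1.5
    tx <- 1 / sqrt(1 + y1^2)
    ty <- y1 / sqrt(1 + y1^2)
  } else {
    x <- spline$fx(u)
    y <- spline$fy(u)
    kap <- parametric_curvature(spline, u)
    x1 <- spline$fx(u, deriv = 1)
    y1 <- spline$fy(u, deriv = 1)
    nt <- sqrt(x1^2 + y1^2)
    tx <- x1 / nt
    ty <- y1 / nt
  }
  if (!is.null(lumen_point)) {
    # left normal of the travel direction; lumen side decides the sign
    nx <- -ty
    ny <- tx
    side <- sign((lumen_point[1] - x) * nx + (lumen_point[2] - y) * ny)
    kap <- abs(kap) * sign(kap * side)
  }
  arc <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  out <- data.frame(arc = arc, s = arc / max(arc), kappa = kap, x = x, y = y)
  class(out) <- c("curvature_profile", "data.frame")
  out
}

#' Layer thickness along the midline
#'
#' At each midline sample the thickness is the length of the segment
#' through the point, normal to the midline, clipped by the apical and
#' basal contours. Where a normal misses a contour the nearest-vertex
#' distance is used instead and the sample is flagged.
#'
#' @param mid two-column matrix of midline points (um), ordered.
#' @param layer the `traced_layer`.
#' @return Data frame with `arc` (um along the midline), `thickness` (um)
#'   and `fallback` (logical).
#' @export
thickness_profile <- function(mid, layer) {
  stopifnot(inherits(layer, "traced_layer"))
  mid <- check_matrix2(mid, "mid")
  n <- nrow(mid)
  tang <- rbind(mid[2, ] - mid[1, ],
                (mid[3:n, , drop = FALSE] - mid[1:(n - 2), , drop = FALSE]) / 2,
                mid[n, ] - mid[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(-tang[, 2], tang[, 1])
  th <- numeric(n)
  fb <- logical(n)
  for (i in seq_len(n)) {
    da <- ray_polyline_hit(mid[i, ], nrm[i, ], layer$apical)
    db <- ray_polyline_hit(mid[i, ], nrm[i, ], layer$basal)
    near <- nearest_dist(mid[i, ], layer$apical) +
      nearest_dist(mid[i, ], layer$basal)
    # near the open ends of a traced layer the normal can miss the adjacent
    # contour and catch the far side; fall back to nearest distances there
    if (is.na(da) || is.na(db) || da + db > 3 * near) {
      th[i] <- near
      fb[i] <- TRUE
    } else {
      th[i] <- da + db
    }
  }
  data.frame(arc = arc_lengths(mid), thickness = th, fallback = fb)
}

# distance from p along +/-dir to the nearest polyline crossing (NA if none)
ray_polyline_hit <- function(p, dir, poly) {
  best <- NA_real_
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]
    d2 <- poly[i + 1, ] - a
    den <- dir[1] * d2[2] - dir[2] * d2[1]
    if (abs(den) < 1e-12) next
    tt <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / den
    uu <- ((a[1] - p[1]) * dir[2] - (a[2] - p[2]) * dir[1]) / den
    if (uu >= -1e-9 && uu <= 1 + 1e-9) {
      dist <- abs(tt)
      if (is.na(best) || dist < best) best <- dist
    }
  }
  best
}

nearest_dist <- function(p, poly) {
  min(sqrt(colSums((t(poly) - p)^2)))
}

#' Total curvature over normalized arc length
#'
#' The integral of signed curvature against the normalized arc-length
#' coordinate `s` in `[0, 1]` (trapezoid rule), summarizing the overall
#' bending of the layer in um^-1.
#'
#' @param profile a `curvature_profile` (or data frame with `s`, `kappa`).
#' @return A single number, um^-1.
#' @export
total_curvature <- function(profile) {
  if (!is.data.frame(profile) || !all(c("s", "kappa") %in% names(profile)))
    stopf("'profile' must have columns 's' and 'kappa'")
  if (nrow(profile) < 2) stopf("profile is empty or degenerate")
  pracma::trapz(profile$s, profile$kappa)
}

#' Local curvature of a traced edge at a reference point
#'
#' Samples four points along the edge at regular 19-um arc intervals,
#' bracketing the reference point symmetrically (two on each side), fits
#' the cubic interpolant through them (one cubic per coordinate,
#' chord-length parameter), and evaluates the signed curvature at the two
#' knots adjacent to the reference, averaging them: for a cubic the
#' curvature estimate is markedly more accurate at the knots than inside
#' the central interval, and their mean is a second-order estimate at the
#' reference. The sign follows the tracing direction (reversing the edge
#' flips it); pass the result through a lumen-side convention where needed.
#'
#' @param edge two-column matrix of ordered edge points (um).
#' @param ref_point reference point (um); its nearest position on the edge
#'   anchors the sampling.
#' @param spacing sampling interval, um.
#' @return Signed curvature (um^-1), or `NA` with a warning if the edge is
#'   too short around the reference.
#' @export
local_edge_curvature <- function(edge, ref_point, spacing = 19) {
  edge <- check_matrix2(edge, "edge")
  ref_point <- as.numeric(ref_point)
  s <- arc_lengths(edge)
  d <- sqrt(colSums((t(edge) - ref_point)^2))
  s0 <- s[which.min(d)]
  offs <- c(-1.5, -0.5, 0.5, 1.5) * spacing
  if (s0 + offs[1] < 0 || s0 + offs[4] > max(s)) {
    warning("edge too short around the reference point; curvature undefined")
    return(NA_real_)
  }
  pts <- polyline_at(edge, s0 + offs)
  u <- arc_lengths(pts)
  fx <- splinefun(u, pts[, 1], method = "fmm")
  fy <- splinefun(u, pts[, 2], method = "fmm")
  kap_at <- function(um) {
    (fx(um, 1) * fy(um, 2) - fy(um, 1) * fx(um, 2)) /
      (fx(um, 1)^2 + fy(um, 1)^2)^1.5
  }
  mean(c(kap_at(u[2]), kap_at(u[3])))
}
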
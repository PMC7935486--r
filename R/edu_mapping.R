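#' Split a z-stack into roof and floor substacks
#'
#' Splits at the middle z index; with an odd slice count the middle slice
#' goes to the floor substack (a fixed, deterministic rule).
#'
#' @param stack numeric array `[rows, cols, z]` (one channel).
#' @return List with `roof` (first half) and `floor` (second half).
#' @export
split_roof_floor <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stopf("'stack' must be a [rows, cols, z] array")
  nz <- dim(stack)[3]
  if (nz < 2) stopf("need at least 2 z slices to split")
  half <- nz %/% 2
  list(roof = stack[, , seq_len(half), drop = FALSE],
       floor = stack[, , (half + 1):nz, drop = FALSE])
}

#' Project a z-stack onto the xy plane
#'
#' Maximum, summed, or duct-restricted mean projection. The mean is taken
#' only over z samples inside the duct mask, so its denominator varies with
#' the local epithelial thickness; pixels with no in-duct sample are `NA`.
#'
#' @param stack numeric array `[rows, cols, z]`.
#' @param method `"max"`, `"sum"` or `"mean_within_duct"`.
#' @param mask logical array of the same shape (required for
#'   `"mean_within_duct"`).
#' @return A matrix `[rows, cols]`.
#' @export
project_stack <- function(stack, method = c("max", "sum", "mean_within_duct"),
                          mask = NULL) {
  method <- match.arg(method)
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stopf("'stack' must be a [rows, cols, z] array")
  if (method == "max") return(apply(stack, c(1, 2), max))
  if (method == "sum") return(apply(stack, c(1, 2), sum))
  if (is.null(mask)) stopf("mean_within_duct needs a duct mask")
  if (!identical(dim(mask), dim(stack))) stopf("mask shape does not match")
  num <- apply(stack * mask, c(1, 2), sum)
  den <- apply(mask, c(1, 2), sum)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Binarize the duct from an epithelial-marker image
#'
#' Otsu threshold, morphological closing (3-px disc), hole filling, and
#' retention of the largest connected component; the perimeter is the
#' traced boundary of that component.
#'
#' @param img numeric matrix (e.g. an E-cadherin projection).
#' @return List with `mask` (logical matrix) and `perimeter` (two-column
#'   matrix of ordered boundary coordinates `(row, col)`, px).
#' @export
binarize_duct <- function(img) {
  img <- as.matrix(img)
  rng <- range(img)
  if (rng[1] == rng[2]) stopf("constant image cannot be thresholded")
  f <- (img - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(f, levels = 256)
  m <- EBImage::Image(f > thr)
  m <- EBImage::closing(m, EBImage::makeBrush(3, shape = "disc"))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  tab <- table(lab[lab > 0])
  biggest <- as.integer(names(tab)[which.max(tab)])
  mask <- matrix(as.array(lab) == biggest, nrow(img), ncol(img))
  per <- EBImage::ocontour(EBImage::Image(mask))[[1]]
  # EBImage contours are 0-based (x = row index of the matrix layout)
  perimeter <- cbind(per[, 1] + 1, per[, 2] + 1)
  list(mask = mask, perimeter = perimeter)
}

# walk the closed perimeter from the vertex nearest `from` to the vertex
# nearest `to`, choosing the direction that avoids vertex `avoid`
perimeter_path <- function(per, from, to, avoid) {
  n <- nrow(per)
  idx <- function(p) which.min(colSums((t(per) - p)^2))
  i0 <- idx(from)
  i1 <- idx(to)
  ia <- idx(avoid)
  fwd <- if (i1 >= i0) i0:i1 else c(i0:n, 1:i1)
  bwd <- if (i1 <= i0) i0:i1 else c(i0:1, n:i1)
  if (ia %in% fwd && !(ia %in% bwd)) bwd_path(per, bwd) else per[fwd, , drop = FALSE]
}

bwd_path <- function(per, ii) per[ii, , drop = FALSE]

#' Partition the duct into an along-duct x mediolateral grid of regions
#'
#' The duct perimeter is split at the apex tip into a medial and a lateral
#' curve (tip to the medial end, tip to the lateral end). Marks are placed
#' at 20 equal arc-length bins along each curve, corresponding marks are
#' joined by chords, and each chord is divided into 10, yielding 200
#' quadrilateral regions indexed along the duct (1..20 from the apex) and
#' mediolaterally (1..10 from the medial side). The outermost region edges
#' follow the duct curves.
#'
#' Instead of a mask + landmarks, explicit `medial` and `lateral` curves
#' (both ordered from the apex end) may be supplied directly.
#'
#' @param mask logical duct mask (from [binarize_duct()]).
#' @param landmarks list with `apex`, `medial_end`, `lateral_end` points
#'   `(row, col)` on or near the perimeter.
#' @param medial,lateral optional explicit boundary curves (two-column
#'   matrices), overriding the perimeter construction.
#' @param n_along,n_across grid size (default 20 x 10).
#' @param tol largest accepted landmark-to-perimeter distance, px.
#' @return A `duct_partition`: list of region polygons (`regions[[k]][[j]]`),
#'   the curves, and the grid size.
#' @export
build_partition <- function(mask = NULL, landmarks = NULL, medial = NULL,
                            lateral = NULL, n_along = 20L, n_across = 10L,
                            tol = 10) {
  if (is.null(medial) || is.null(lateral)) {
    if (is.null(mask) || is.null(landmarks))
      stopf("supply either mask + landmarks or explicit medial/lateral curves")
    b <- if (is.list(mask) && !is.null(mask$perimeter)) mask
         else list(perimeter = mask_perimeter(mask))
    per <- b$perimeter
    for (nm in c("apex", "medial_end", "lateral_end")) {
      p <- landmarks[[nm]]
      if (is.null(p)) stopf("landmark '%s' missing", nm)
      if (min(sqrt(colSums((t(per) - as.numeric(p))^2))) > tol)
        stopf("landmark '%s' lies farther than %g px from the perimeter", nm, tol)
    }
    medial <- perimeter_path(per, landmarks$apex, landmarks$medial_end,
                             landmarks$lateral_end)
    lateral <- perimeter_path(per, landmarks$apex, landmarks$lateral_end,
                              landmarks$medial_end)
  }
  medial <- check_matrix2(medial, "medial")
  lateral <- check_matrix2(lateral, "lateral")
  sm <- seq(0, max(arc_lengths(medial)), length.out = n_along + 1)
  sl <- seq(0, max(arc_lengths(lateral)), length.out = n_along + 1)
  mm <- polyline_at(medial, sm)
  ll <- polyline_at(lateral, sl)
  # chord k: n_across+1 division points from the medial mark to the lateral
  chords <- lapply(seq_len(n_along + 1), function(k) {
    f <- seq(0, 1, length.out = n_across + 1)
    cbind(mm[k, 1] + f * (ll[k, 1] - mm[k, 1]),
          mm[k, 2] + f * (ll[k, 2] - mm[k, 2]))
  })
  curve_seg <- function(curve, s_from, s_to, n = 8) {
    polyline_at(curve, seq(s_from, s_to, length.out = n))
  }
  regions <- lapply(seq_len(n_along), function(k) {
    lapply(seq_len(n_across), function(j) {
      top <- chords[[k]][c(j, j + 1), , drop = FALSE]
      bot <- chords[[k + 1]][c(j + 1, j), , drop = FALSE]
      right <- if (j == n_across) curve_seg(lateral, sl[k], sl[k + 1])
               else rbind(chords[[k]][j + 1, ], chords[[k + 1]][j + 1, ])
      left <- if (j == 1) curve_seg(medial, sm[k + 1], sm[k])
              else rbind(chords[[k + 1]][j, ], chords[[k]][j, ])
      poly <- rbind(top[1, ], right, bot[2, ], left, deparse.level = 0)
      poly[!duplicated(round(poly, 9)), , drop = FALSE]
    })
  })
  structure(list(regions = regions, medial = medial, lateral = lateral,
                 n_along = n_along, n_across = n_across),
            class = "duct_partition")
}

mask_perimeter <- function(mask) {
  per <- EBImage::ocontour(EBImage::Image(mask))[[1]]
  cbind(per[, 1] + 1, per[, 2] + 1)
}

#' @export
print.duct_partition <- function(x, ...) {
  cat(sprintf("duct_partition: %d x %d regions\n", x$n_along, x$n_across))
  invisible(x)
}

# even-odd point-in-polygon, vectorised over points
points_in_polygon <- function(px, py, poly) {
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# assign points to regions; first hit in region order wins (exact tiling)
assign_regions <- function(partition, px, py) {
  idx <- rep(NA_integer_, length(px))
  kk <- 0L
  for (k in seq_len(partition$n_along)) {
    for (j in seq_len(partition$n_across)) {
      kk <- kk + 1L
      open <- is.na(idx)
      if (!any(open)) return(idx)
      hit <- points_in_polygon(px[open], py[open], partition$regions[[k]][[j]])
      idx[which(open)[hit]] <- kk
    }
  }
  idx
}

#' Regional mean EdU intensity map
#'
#' Mean EdU intensity per partition region, normalized by 255 (8-bit
#' scale). Pixel centers are assigned to regions with a half-open rule, so
#' every pixel is counted exactly once.
#'
#' @param edu numeric matrix (EdU projection, 8-bit scale).
#' @param partition a `duct_partition`.
#' @param mask optional logical mask restricting the counted pixels.
#' @return A `region_map`: list with `mean` (n_along x n_across matrix in
#'   `[0, 1]`), `count` (pixels per region), `empty` (logical matrix).
#' @export
region_means <- function(edu, partition, mask = NULL) {
  stopifnot(inherits(partition, "duct_partition"))
  edu <- as.matrix(edu)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(edu), ncol(edu))
  pts <- which(mask, arr.ind = TRUE)
  idx <- assign_regions(partition, pts[, 1], pts[, 2])
  nreg <- partition$n_along * partition$n_across
  vals <- edu[mask]
  mean_v <- rep(NA_real_, nreg)
  count_v <- rep(0L, nreg)
  ok <- !is.na(idx)
  if (any(ok)) {
    agg_n <- tapply(vals[ok], idx[ok], length)
    agg_m <- tapply(vals[ok], idx[ok], mean)
    ii <- as.integer(names(agg_n))
    count_v[ii] <- as.integer(agg_n)
    mean_v[ii] <- agg_m / 255
  }
  shape <- function(v) matrix(v, partition$n_along, partition$n_across, byrow = TRUE)
  structure(list(mean = shape(mean_v), count = shape(count_v),
                 empty = shape(count_v == 0L)),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map: %d x %d regions, %d empty; mean intensity %.3f\n",
              nrow(x$mean), ncol(x$mean), sum(x$empty),
              mean(x$mean, na.rm = TRUE)))
  invisible(x)
}

#' Cell density along the mediolateral axis
#'
#' Divides a rectangular counting domain into equal sections along one
#' axis and reports cells per unit area and the section centroid position.
#'
#' @param points two-column matrix of cell (nucleus) positions, um.
#' @param bounds list with `x = c(min, max)`, `y = c(min, max)` of the
#'   counting domain, um.
#' @param axis `"x"` or `"y"`: the mediolateral axis along which sections
#'   are laid out.
#' @param n_sections number of sections (default 5).
#' @return Data frame with `section`, `position` (centroid along the axis),
#'   `n_cells`, `area` (um^2), `density` (cells/um^2).
#' @export
cell_density <- function(points, bounds, axis = c("y", "x"), n_sections = 5L) {
  axis <- match.arg(axis)
  points <- check_matrix2(points, "points")
  v <- if (axis == "x") points[, 1] else points[, 2]
  rng <- if (axis == "x") bounds$x else bounds$y
  other <- if (axis == "x") bounds$y else bounds$x
  br <- seq(rng[1], rng[2], length.out = n_sections + 1)
  sec <- cut(v, br, include.lowest = TRUE, labels = FALSE)
  area <- diff(br)[1] * (other[2] - other[1])
  data.frame(
    section = seq_len(n_sections),
    position = (br[-1] + br[-length(br)]) / 2,
    n_cells = vapply(seq_len(n_sections), function(i) sum(sec == i, na.rm = TRUE), integer(1)),
    area = area,
    density = vapply(seq_len(n_sections), function(i) sum(sec == i, na.rm = TRUE), integer(1)) / area
  )
}
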
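# Geometry of a segmented seed region and the 15 shape descriptors.
#
# Conventions: pixel coordinates are (row, col) centers on the unit lattice.
# Quantities measured on boundary pixel centers are corrected by a
# quarter-pixel lattice offset per boundary crossing (+0.5 px on Feret
# diameters, +0.25 px on the enclosing-circle radius, +pi/2 on the
# perimeter) so that rasterized primitives agree with their continuous
# counterparts.

# Perimeter of an ordered closed boundary-pixel contour.
#
# The raw chain-code polygon (diagonal steps sqrt(2)) overestimates smooth
# boundaries by ~5%, so the default estimator anchors on the convex hull of
# the contour points (whose polygon length is staircase-free), adds the
# extra path length of concave sections -- measured on a moving-average
# smoothed copy of the contour as the excess of the smoothed arc over the
# hull chord between consecutive hull vertices -- and finally a
# quarter-pixel outward offset (+pi/2) because boundary pixel centers sit
# inside the generating contour by between zero and one pixel diagonal
# depending on the local edge orientation.
#' Perimeter of a closed boundary-pixel contour
#'
#' @param contour n x 2 matrix of ordered (row, col) boundary pixel
#'   coordinates (closed: last point adjacent to first).
#' @param smooth_window circular moving-average window used when measuring
#'   concave detours.
#' @param method `"hull_anchored"` (default) or `"chain"` (raw chain-code
#'   polygon length, diagonal steps sqrt(2)).
#' @return perimeter estimate in pixels.
#' @export
contour_perimeter <- function(contour, smooth_window = 5L,
                              method = c("hull_anchored", "chain")) {
  method <- match.arg(method)
  n <- nrow(contour)
  if (n < 2L) return(4)  # single pixel: its own boundary
  r <- contour[, 1]; c <- contour[, 2]
  chain <- function(r, c) {
    dr <- diff(c(r, r[1])); dc <- diff(c(c, c[1]))
    sum(sqrt(dr^2 + dc^2))
  }
  if (method == "chain" || n <= smooth_window) return(chain(r, c))
  hidx <- sort(grDevices::chull(cbind(c, r)))  # cyclic contour order
  if (length(hidx) < 3L) return(chain(r, c))
  hull_len <- chain(r[hidx], c[hidx])
  sm <- .smooth_contour(contour, smooth_window)
  rs <- sm[, 1]; cs <- sm[, 2]
  seg <- sqrt(diff(c(rs, rs[1]))^2 + diff(c(cs, cs[1]))^2)
  cum <- c(0, cumsum(seg))                     # arc length up to each vertex
  detour <- 0
  m <- length(hidx)
  for (t in seq_len(m)) {
    i <- hidx[t]; j <- hidx[(t %% m) + 1L]
    arc <- if (j > i) cum[j] - cum[i] else cum[n + 1L] - cum[i] + cum[j]
    chord <- sqrt((r[i] - r[j])^2 + (c[i] - c[j])^2)
    detour <- detour + max(0, arc - chord)
  }
  hull_len + detour + pi / 2
}

# circular moving-average smoothing of a closed contour (n x 2)
.smooth_contour <- function(contour, window = 5L) {
  n <- nrow(contour)
  if (n <= window) return(contour)
  k <- window %/% 2L
  idx <- function(i) ((i - 1L) %% n) + 1L
  rs <- cs <- numeric(n)
  for (o in (-k):k) {
    rs <- rs + contour[idx(seq_len(n) + o), 1]
    cs <- cs + contour[idx(seq_len(n) + o), 2]
  }
  cbind(rs, cs) / window
}

# circle through 0/1/2/3 points, list(center = c(x, y), r)
.circle_of <- function(pts) {
  n <- nrow(pts)
  if (n == 0L) return(list(center = c(0, 0), r = -1))
  if (n == 1L) return(list(center = pts[1, ], r = 0))
  if (n == 2L) {
    cen <- (pts[1, ] + pts[2, ]) / 2
    return(list(center = cen, r = sqrt(sum((pts[1, ] - cen)^2))))
  }
  ax <- pts[1, 1]; ay <- pts[1, 2]; bx <- pts[2, 1]; by <- pts[2, 2]
  cx <- pts[3, 1]; cy <- pts[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) {  # collinear: fall back to the widest pair
    dd <- as.matrix(stats::dist(pts))
    ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
    return(.circle_of(pts[ij, , drop = FALSE]))
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), r = sqrt((ax - ux)^2 + (ay - uy)^2))
}

.in_circle <- function(p, circ, eps = 1e-7) {
  circ$r >= 0 && sqrt(sum((p - circ$center)^2)) <= circ$r + eps
}

# Welzl's minimum enclosing circle (deterministic pseudo-shuffled order)
min_enclosing_circle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  ord <- order((seq_len(n) * 2654435761) %% (n + 7))  # fixed pseudo-shuffle
  pts <- pts[ord, , drop = FALSE]
  welzl <- function(i, R) {
    if (i == 0L || nrow(R) == 3L) return(.circle_of(R))
    D <- welzl(i - 1L, R)
    p <- pts[i, ]
    if (.in_circle(p, D)) D else welzl(i - 1L, rbind(R, p))
  }
  circ <- welzl(n, matrix(numeric(0), 0, 2))
  list(center = unname(circ$center), r = unname(circ$r))
}

# interior angles (degrees) of a convex polygon given in hull vertex order
.hull_angles <- function(hull) {
  n <- nrow(hull)
  if (n < 3L) return(numeric(0))
  ang <- numeric(n)
  for (i in seq_len(n)) {
    p <- hull[((i - 2L) %% n) + 1L, ]
    q <- hull[i, ]
    r <- hull[(i %% n) + 1L, ]
    v1 <- p - q; v2 <- r - q
    co <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang[i] <- acos(pmin(1, pmax(-1, co))) * 180 / pi
  }
  ang
}

# max perpendicular distance from contour points to the hull boundary
# (depth of the deepest convexity defect)
.max_hull_distance <- function(contour, hull) {
  n <- nrow(hull)
  if (n < 3L) return(0)
  dmax <- 0
  for (i in seq_len(nrow(contour))) {
    p <- contour[i, ]
    best <- Inf
    for (j in seq_len(n)) {
      a <- hull[j, ]; b <- hull[(j %% n) + 1L, ]
      ab <- b - a
      t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
      t <- pmin(1, pmax(0, t))
      proj <- a + t * ab
      d <- sqrt(sum((p - proj)^2))
      if (d < best) best <- d
    }
    if (best > dmax) dmax <- best
  }
  dmax
}

#' Summarize the geometry of a seed region
#'
#' Computes the geometric quantities the shape descriptors are built from:
#' pixel area A, boundary perimeter P, largest and smallest diameters
#' (convex-hull Feret extents over 1-degree rotations), the minimum
#' enclosing circle area, the moment-equivalent ellipse semiaxes (a >= b)
#' and principal-axis angle, the four quadrant areas cut by the principal
#' axes through the centroid, the centroid-to-contour radius range, the
#' convex-hull interior angles, and the deepest convexity-defect depth.
#'
#' @param region a `seed_region` (see [extract_regions()]).
#' @param perimeter_method `"hull_anchored"` (default; staircase-corrected,
#'   see [contour_perimeter()]) or `"chain"` (raw chain-code polygon length
#'   with sqrt(2) diagonals).
#' @return an object of class `"seed_geometry"`: a list with elements
#'   `A`, `P`, `D_max`, `D_min`, `A_circum`, `a`, `b`, `theta`,
#'   `quadrant_areas` (length 4), `radii_range` (r_min, r_mean, r_max),
#'   `hull_angles`, `max_hull_dist`, `centroid`.
#' @export
summarize_geometry <- function(region, perimeter_method = "hull_anchored") {
  stopifnot(inherits(region, "seed_region"))
  if (region$area_px < 5L) stop("region too small (area < 5 px)")
  mask <- region$mask
  ij <- which(mask, arr.ind = TRUE)
  A <- nrow(ij)
  # image coordinates: x = col, y = row
  x <- ij[, 2]; y <- ij[, 1]
  xc <- mean(x); yc <- mean(y)
  dx <- x - xc; dy <- y - yc
  # central second moments with the 1/12 pixel-extent term
  mu20 <- mean(dx^2) + 1 / 12
  mu02 <- mean(dy^2) + 1 / 12
  mu11 <- mean(dx * dy)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  # the 1/12 pixel term shifts both eigenvalues; a collinear pixel set has
  # zero spatial variance across the minor axis
  if (l2 - 1 / 12 <= 1e-9) stop("degenerate (collinear) region")
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (theta < 0) theta <- theta + pi

  # contour-based quantities (contour is stored in frame coordinates;
  # shift to the crop frame of the mask so radii share the centroid origin)
  contour <- cbind(region$contour[, 1] - region$bbox[1] + 1L,
                   region$contour[, 2] - region$bbox[2] + 1L)
  P <- contour_perimeter(contour, method = perimeter_method)
  cp <- cbind(contour[, 2], contour[, 1])     # (x, y)
  hidx <- grDevices::chull(cp)
  hull <- cp[hidx, , drop = FALSE]
  # Feret extents over 1-degree rotations, half-pixel corrected
  ang <- (0:179) * pi / 180
  proj_w <- vapply(ang, function(t) {
    p <- hull[, 1] * cos(t) + hull[, 2] * sin(t)
    max(p) - min(p)
  }, 0)
  D_min <- min(proj_w) + 0.5
  dd <- as.matrix(stats::dist(hull))
  D_max <- max(dd) + 0.5
  # quarter-pixel correction: boundary centers underestimate the generating
  # contour's circumradius by ~0 at smooth extrema and ~0.7 at corners
  mec <- min_enclosing_circle(hull)
  A_circum <- pi * (mec$r + 0.25)^2

  # quadrant areas in the principal frame (canonical axis direction by
  # third-moment sign; trig snapped so 90-degree lattice rotations are exact)
  ct <- cos(theta); st <- sin(theta)
  if (abs(ct) < 1e-12) ct <- 0
  if (abs(st) < 1e-12) st <- 0
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  if (sum(u^3) < 0) u <- -u
  if (sum(v^3) < 0) v <- -v
  # pixels on a principal axis are shared half-half between the adjacent
  # quadrants, so mirror-symmetric shapes balance exactly
  wu <- ifelse(abs(u) < 1e-9, 0.5, as.numeric(u > 0))
  wv <- ifelse(abs(v) < 1e-9, 0.5, as.numeric(v > 0))
  q1 <- sum(wu * wv); q2 <- sum((1 - wu) * wv)
  q3 <- sum((1 - wu) * (1 - wv)); q4 <- sum(wu * (1 - wv))

  # radius range measured on the smoothed contour: extreme raw radii carry
  # half-pixel staircase noise that the roundness ratio would amplify
  sm <- .smooth_contour(contour)
  radii <- sqrt((sm[, 2] - xc)^2 + (sm[, 1] - yc)^2)
  structure(list(
    A = A, P = P, D_max = D_max, D_min = D_min, A_circum = A_circum,
    a = a, b = b, theta = theta,
    quadrant_areas = c(q1, q2, q3, q4),
    radii_range = c(min(radii), mean(radii), max(radii)),
    hull_angles = .hull_angles(hull),
    max_hull_dist = .max_hull_distance(cp, hull),
    centroid = c(yc, xc)
  ), class = "seed_geometry")
}

#' Fifteen shape descriptors of a seed region
#'
#' Computes, from a [summarize_geometry()] summary, the descriptor set used
#' by the shape classifier (field numbering 1-15):
#' \describe{
#'   \item{1 circularity1}{4 pi A / P^2}
#'   \item{2 compactness1}{2 sqrt(pi A) / P (perimeter of the equal-area
#'     circle over the shape perimeter)}
#'   \item{3 defect_ratio}{(A_circum - A) / A_circum, the unfilled fraction
#'     of the minimum enclosing circle}
#'   \item{4 circularity2}{4 A / (pi D_max^2)}
#'   \item{5 compactness2}{sqrt(4 A / pi) / D_max (equal-area-circle
#'     diameter over the largest diameter)}
#'   \item{6 ellipticity_index}{pi a^2 / A}
#'   \item{7 elongation}{D_min / D_max}
#'   \item{8 eccentricity}{sqrt(a^2 - b^2) / a of the moment ellipse}
#'   \item{9 out_of_roundness}{(r_max - r_min) / r_mean over
#'     centroid-to-contour radii}
#'   \item{10/11 hull_max_angle, hull_min_angle}{largest/smallest interior
#'     angle of the convex hull polygon, degrees}
#'   \item{12 max_convex_distance}{depth of the deepest convexity defect
#'     (max contour-to-hull distance), pixels}
#'   \item{13-15 sar1..sar3}{symmetry area ratios |1 - (Ai+Aj)/(Ak+Al)| over
#'     the three pairings of the principal-axis quadrant areas}
#' }
#'
#' @param geom a `seed_geometry` object, or a `seed_region` (summarized
#'   on the fly).
#' @return named numeric vector `shape_01` ... `shape_15`.
#' @export
shape_features <- function(geom) {
  if (inherits(geom, "seed_region")) geom <- summarize_geometry(geom)
  stopifnot(inherits(geom, "seed_geometry"))
  A <- geom$A; P <- geom$P
  if (P <= 0) stop("zero denominator: perimeter P (circularity1)")
  if (geom$D_max <= 0) stop("zero denominator: D_max (circularity2)")
  if (geom$A_circum <= 0) stop("zero denominator: A_circum (defect_ratio)")
  if (geom$a <= 0) stop("zero denominator: semimajor axis a (eccentricity)")
  q <- geom$quadrant_areas
  sar <- function(num, den) {
    if (den == 0) stop("zero denominator: quadrant areas (symmetry area ratio)")
    abs(1 - num / den)
  }
  ha <- geom$hull_angles
  out <- c(
    shape_01 = 4 * pi * A / P^2,
    shape_02 = 2 * sqrt(pi * A) / P,
    shape_03 = (geom$A_circum - A) / geom$A_circum,
    shape_04 = 4 * A / (pi * geom$D_max^2),
    shape_05 = sqrt(4 * A / pi) / geom$D_max,
    shape_06 = pi * geom$a^2 / A,
    shape_07 = geom$D_min / geom$D_max,
    shape_08 = sqrt(max(geom$a^2 - geom$b^2, 0)) / geom$a,
    shape_09 = (geom$radii_range[3] - geom$radii_range[1]) / geom$radii_range[2],
    shape_10 = if (length(ha)) max(ha) else NA_real_,
    shape_11 = if (length(ha)) min(ha) else NA_real_,
    shape_12 = geom$max_hull_dist,
    shape_13 = sar(q[1] + q[2], q[3] + q[4]),
    shape_14 = sar(q[1] + q[3], q[2] + q[4]),
    shape_15 = sar(q[1] + q[4], q[2] + q[3])
  )
  if (any(!is.finite(out)))
    stop("non-finite shape feature: ", paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}
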
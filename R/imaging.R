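#' @useDynLib seedvision, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct and validate an RGB frame
#'
#' A frame is a plain numeric array of dimension H x W x 3 holding channel
#' intensities in \[0, 255\] (R, G, B in that channel order), with pixel
#' coordinates given as (row, col), 1-based. Bounding boxes are inclusive
#' (row0, col0, row1, col1).
#'
#' @param pixels numeric array H x W x 3, intensities in \[0, 255\].
#' @param id optional frame identifier string.
#' @return the validated array with class `"seed_frame"` and attribute `id`.
#' @export
seed_frame <- function(pixels, id = "frame") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("frame must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("empty frame")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("frame intensities must lie in [0, 255]")
  structure(pixels, class = "seed_frame", id = id)
}

#' Read an RGB frame from a PNG file
#'
#' @param path path to a PNG image (grayscale images are replicated to RGB;
#'   an alpha channel, if present, is dropped).
#' @return a `seed_frame` array with intensities in \[0, 255\].
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) img <- array(rep(img[, , 1], 3L), c(dim(img)[1:2], 3L))
  seed_frame(round(img[, , 1:3, drop = FALSE] * 255),
             id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write an RGB frame to a PNG file
#'
#' @param frame H x W x 3 array in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  png::writePNG(unclass(frame) / 255, path)
  invisible(path)
}

#' Frame to grayscale
#'
#' Gray level is the channel mean (R + G + B) / 3, the intensity axis of the
#' HSI model used throughout the package.
#'
#' @param frame H x W x 3 array in \[0, 255\].
#' @return numeric matrix of gray levels.
#' @export
frame_gray <- function(frame) {
  (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
}

#' Threshold a frame into a foreground mask
#'
#' Computes the gray image (R+G+B)/3 and thresholds it. By default seeds are
#' assumed brighter than the background (dark field); set `invert = TRUE` for
#' dark objects on a light background.
#'
#' @param frame a `seed_frame` (H x W x 3 array, \[0, 255\]).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_t threshold intensity in \[0, 255\]; required when
#'   `method = "fixed"`.
#' @param invert logical; if TRUE, keep pixels *below* the threshold.
#' @return logical matrix, TRUE on foreground.
#' @export
binarize <- function(frame, method = c("otsu", "fixed"), fixed_t = NULL,
                     invert = FALSE) {
  method <- match.arg(method)
  if (!is.array(frame) || length(dim(frame)) != 3L || any(dim(frame)[1:2] < 1L))
    stop("empty or malformed frame")
  gray <- frame_gray(frame)
  if (method == "fixed") {
    if (is.null(fixed_t)) stop("fixed_t is required when method = \"fixed\"")
    t <- fixed_t
  } else {
    if (diff(range(gray)) == 0) {
      warning("constant frame: Otsu threshold undefined, returning empty mask")
      return(matrix(FALSE, nrow(gray), ncol(gray)))
    }
    t <- EBImage::otsu(gray / 255, range = c(0, 1), levels = 256L) * 255
  }
  if (invert) gray < t else gray > t
}

#' Morphological opening with a disc
#'
#' One erosion followed by one dilation with a disc structuring element,
#' removing specks smaller than the element.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels (>= 1); element size is 2*radius + 1.
#' @return logical matrix.
#' @export
morph_clean <- function(mask, radius = 2L) {
  stopifnot(radius >= 1)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  m <- EBImage::dilate(EBImage::erode(mask * 1L, brush), brush)
  m > 0.5
}

#' Fill interior holes of a binary mask
#'
#' Background regions not connected (4-connectivity) to the image border are
#' set to foreground; border-connected background is preserved.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  EBImage::fillHull(mask * 1L) > 0.5
}

#' Apply a binary mask to a frame (AND of original and binary images)
#'
#' @param frame H x W x 3 array.
#' @param mask logical H x W matrix.
#' @return array with all channels zeroed where the mask is FALSE.
#' @export
apply_mask <- function(frame, mask) {
  if (!all(dim(frame)[1:2] == dim(mask))) stop("frame/mask shape mismatch")
  out <- unclass(frame)
  out[, , 1] <- out[, , 1] * mask
  out[, , 2] <- out[, , 2] * mask
  out[, , 3] <- out[, , 3] * mask
  out
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels that
# touch diagonally with a union-find pass over the label ids.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  h <- nrow(lab); w <- ncol(lab)
  # diagonal neighbor pairs: (i,j)-(i+1,j+1) and (i+1,j)-(i,j+1)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -w]; b2 <- lab[-h, -1]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE])
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) union2(pairs[k, 1], pairs[k, 2])
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Moore boundary following on a logical matrix; returns an n x 2 matrix of
# (row, col) boundary pixel coordinates, ordered, closed (last is 8-adjacent
# to first). Jacob's stopping criterion.
trace_contour <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  idx <- which(t(pad))  # row-major scan
  if (!length(idx)) stop("empty mask: no contour")
  first <- idx[1]
  r0 <- (first - 1L) %/% (w + 2L) + 1L
  c0 <- (first - 1L) %% (w + 2L) + 1L
  # clockwise Moore neighborhood starting at W
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  if (sum(pad) == 1L) return(cbind(r0 - 1L, c0 - 1L))
  pts_r <- integer(0); pts_c <- integer(0)
  cr <- r0; cc <- c0
  b <- 1L               # backtrack direction index (W): scan starts after it
  start_b <- NA_integer_
  maxit <- 8L * sum(pad) + 8L
  for (it in seq_len(maxit)) {
    found <- FALSE
    for (k in 0:7) {
      d <- ((b - 1L + k) %% 8L) + 1L
      nr <- cr + dr[d]; nc <- cc + dc[d]
      if (pad[nr, nc]) {
        if (cr == r0 && cc == c0) {
          if (is.na(start_b)) start_b <- d
          else if (d == start_b && length(pts_r) > 1L) {
            return(cbind(pts_r - 1L, pts_c - 1L))
          }
        }
        pts_r <- c(pts_r, cr); pts_c <- c(pts_c, cc)
        # new backtrack: direction from the new pixel back toward the last
        # background neighbor scanned before it
        prev <- ((d - 2L) %% 8L) + 1L
        pr <- cr + dr[prev]; pc <- cc + dc[prev]
        cr <- nr; cc <- nc
        b <- which(dr == (pr - cr) & dc == (pc - cc))
        found <- TRUE
        break
      }
    }
    if (!found) { pts_r <- cr; pts_c <- cc; break }  # isolated pixel
    if (cr == r0 && cc == c0 && length(pts_r) >= sum(pad) * 4L) break
  }
  cbind(pts_r - 1L, pts_c - 1L)
}

#' Extract per-seed regions from a segmented frame
#'
#' Labels the mask with 8-connected components, drops components below
#' `min_area`, and returns one `seed_region` per component, ordered by
#' centroid (row, then column). Each region carries a tight-crop mask, the
#' masked color sub-image (background zeroed), the ordered Moore boundary
#' contour, centroid, inclusive bounding box and pixel area.
#'
#' @param frame H x W x 3 array.
#' @param mask logical H x W foreground mask.
#' @param min_area minimum component area in pixels (>= 1).
#' @return list of `seed_region` objects (possibly empty).
#' @export
extract_regions <- function(frame, mask, min_area = 50L) {
  stopifnot(min_area >= 1)
  if (!all(dim(frame)[1:2] == dim(mask))) stop("frame/mask shape mismatch")
  lab <- label_components8(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  regions <- list()
  for (k in seq_len(n)) {
    sel <- lab == k
    area <- sum(sel)
    if (area < min_area) next
    rows <- which(rowSums(sel) > 0); cols <- which(colSums(sel) > 0)
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    m <- sel[r0:r1, c0:c1, drop = FALSE]
    sub <- unclass(frame)[r0:r1, c0:c1, , drop = FALSE]
    sub[, , 1] <- sub[, , 1] * m
    sub[, , 2] <- sub[, , 2] * m
    sub[, , 3] <- sub[, , 3] * m
    ij <- which(sel, arr.ind = TRUE)
    cen <- c(mean(ij[, 1]), mean(ij[, 2]))
    contour <- trace_contour(m)
    contour[, 1] <- contour[, 1] + r0 - 1L
    contour[, 2] <- contour[, 2] + c0 - 1L
    regions[[length(regions) + 1L]] <- structure(list(
      mask = m, subimage = sub, contour = contour,
      centroid = cen, bbox = c(r0, c0, r1, c1), area_px = area
    ), class = "seed_region")
  }
  if (!length(regions)) return(list())
  ord <- order(vapply(regions, function(r) r$centroid[1], 0),
               vapply(regions, function(r) r$centroid[2], 0))
  regions[ord]
}

#' @export
print.seed_region <- function(x, ...) {
  cat(sprintf("seed_region: area %d px, centroid (%.1f, %.1f), bbox [%d:%d, %d:%d]\n",
              x$area_px, x$centroid[1], x$centroid[2],
              x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

#' Segment a frame into seed regions
#'
#' Convenience wrapper: threshold, open with a disc, fill holes, mask the
#' original frame, and extract per-seed regions.
#'
#' @param frame H x W x 3 array.
#' @param method threshold method, `"otsu"` or `"fixed"`.
#' @param fixed_t fixed threshold intensity (used when `method = "fixed"`).
#' @param radius opening disc radius (pixels).
#' @param min_area minimum region area (pixels).
#' @param invert TRUE for dark objects on a light background.
#' @return list of `seed_region` objects.
#' @export
segment_frame <- function(frame, method = "otsu", fixed_t = NULL,
                          radius = 2L, min_area = 50L, invert = FALSE) {
  mask <- binarize(frame, method = method, fixed_t = fixed_t, invert = invert)
  # fill before opening too: dark surface defects threshold as holes, and
  # eroding a hole-riddled mask can split one seed into fragments
  mask <- fill_holes(morph_clean(fill_holes(mask), radius = radius))
  extract_regions(frame, mask, min_area = min_area)
}
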
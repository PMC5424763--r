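# Texture descriptors: gray-level co-occurrence matrix (GLCM) statistics
# over four orientations, plus two local operators -- a rotation-invariant
# local-similarity average and Tamura coarseness.

# orientation -> displacement (drow, dcol); angles measured so that 0 deg
# is "to the right" and 45 deg is "up-right" (image rows increase downward)
.glcm_offset <- function(theta, d) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of quantized gray levels at displacement
#' (`d`, `theta`), restricted to pairs where both pixels are mask-true, and
#' normalizes the counts to sum to 1. Gray values are quantized to `levels`
#' equal-width bins over \[0, 255\].
#'
#' @param gray numeric matrix of gray levels in \[0, 255\].
#' @param mask logical matrix, same shape (defaults to all-true).
#' @param d displacement in pixels (>= 1).
#' @param theta orientation in degrees: 0, 45, 90 or 135.
#' @param levels number of gray bins (>= 2), default 16.
#' @return an object of class `"glcm"`: the levels x levels matrix `p`
#'   summing to 1, with attributes `d`, `theta`, `levels`.
#' @export
compute_glcm <- function(gray, mask = NULL, d = 1L, theta = 0,
                         levels = 16L) {
  stopifnot(d >= 1, levels >= 2)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  stopifnot(all(dim(gray) == dim(mask)))
  q <- pmin(floor(gray * levels / 256), levels - 1L)  # 0-based bins
  off <- .glcm_offset(theta, as.integer(d))
  h <- nrow(gray); w <- ncol(gray)
  r1 <- max(1L, 1L - off[1]):min(h, h - off[1])
  c1 <- max(1L, 1L - off[2]):min(w, w - off[2])
  if (!length(r1) || !length(c1)) stop("no valid pixel pair at this displacement")
  i <- q[r1, c1, drop = FALSE]
  j <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + off[1], c1 + off[2], drop = FALSE]
  if (!any(ok)) stop("no valid pixel pair at this displacement")
  counts <- tabulate(i[ok] * levels + j[ok] + 1L, nbins = levels * levels)
  p <- matrix(counts / sum(counts), levels, levels, byrow = TRUE)
  structure(list(p = p, d = as.integer(d), theta = theta,
                 levels = as.integer(levels)), class = "glcm")
}

#' GLCM statistics: ASM, entropy, contrast, homogeneity
#'
#' Angular second moment sum(p^2); entropy -sum(p log p) (natural log,
#' zero-probability cells contribute nothing); contrast sum((i-j)^2 p);
#' homogeneity sum(p / (1 + (i-j)^2)).
#'
#' @param glcm a `"glcm"` object (normalized).
#' @return named numeric vector `asm`, `entropy`, `contrast`, `homogeneity`.
#' @export
glcm_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  p <- glcm$p
  n <- nrow(p)
  ij <- outer(seq_len(n), seq_len(n), "-")
  pn <- p[p > 0]
  c(asm = sum(p^2),
    entropy = -sum(pn * log(pn)),
    contrast = sum(ij^2 * p),
    homogeneity = sum(p / (1 + ij^2)))
}

#' Average a feature over the four GLCM orientations
#'
#' The arithmetic mean over 0, 45, 90 and 135 degrees; the orientation set
#' is closed under 90-degree rotation, making the aggregate invariant to
#' such rotations.
#'
#' @param values numeric vector of exactly four per-orientation values.
#' @return their mean.
#' @export
aggregate_orientations <- function(values) {
  if (length(values) != 4L) stop("exactly four orientation values expected")
  mean(values)
}

#' Local similarity map
#'
#' For every mask-true pixel whose 8 neighbors are all mask-true, the
#' fraction of neighbors whose absolute gray difference from the center is
#' at most `similarity_t`. The count over the full 8-neighborhood is
#' invariant to rotation of the neighborhood, so the map (and its mean) is
#' rotation invariant by construction. Smooth surfaces score near 1;
#' spots and rough patches score low.
#'
#' @param gray numeric matrix of gray levels.
#' @param mask logical matrix, same shape (defaults to all-true).
#' @param similarity_t similarity threshold in gray levels (>= 0).
#' @return numeric matrix of fractions in \[0, 1\], NA where ineligible.
#' @export
lsp_map <- function(gray, mask = NULL, similarity_t = 10) {
  stopifnot(similarity_t >= 0)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  h <- nrow(gray); w <- ncol(gray)
  if (h < 3L || w < 3L) stop("no eligible pixel: image smaller than 3 x 3")
  cnt <- matrix(0L, h - 2L, w - 2L)
  elig <- matrix(TRUE, h - 2L, w - 2L)
  ctr <- gray[2:(h - 1L), 2:(w - 1L)]
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- gray[(2:(h - 1L)) + dr, (2:(w - 1L)) + dc]
    cnt <- cnt + (abs(nb - ctr) <= similarity_t)
    elig <- elig & mask[(2:(h - 1L)) + dr, (2:(w - 1L)) + dc]
  }
  elig <- elig & mask[2:(h - 1L), 2:(w - 1L)]
  if (!any(elig)) stop("no eligible pixel for the local similarity map")
  out <- matrix(NA_real_, h, w)
  inner <- cnt / 8
  inner[!elig] <- NA_real_
  out[2:(h - 1L), 2:(w - 1L)] <- inner
  out
}

# Tamura coarseness: per-pixel best dyadic window size 2^k maximizing the
# directional difference of window averages, averaged over the mask.
tamura_coarseness <- function(gray, mask = NULL, kmax = 4L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  h <- nrow(gray); w <- ncol(gray)
  if (min(h, w) < 2L) stop("region smaller than the smallest window")
  kmax <- min(kmax, floor(log2(min(h, w))))
  if (kmax < 1L) stop("region smaller than the smallest window")
  # integral image with zero padding row/col 1
  S <- matrix(0, h + 1L, w + 1L)
  S[-1, -1] <- apply(apply(gray, 2, cumsum), 1, cumsum) |> t()
  win_avg <- function(k) {
    # average over the 2^k x 2^k window centered (lower-right biased) at
    # each pixel; undefined cells NA
    s <- 2L^k; half <- s %/% 2L
    out <- matrix(NA_real_, h, w)
    if (h - half + 1L < 1L + half || w - half + 1L < 1L + half) return(out)
    r0 <- (1L + half):(h - half + 1L)
    c0 <- (1L + half):(w - half + 1L)
    blk <- S[r0 + half, c0 + half] - S[r0 - half, c0 + half] -
      S[r0 + half, c0 - half] + S[r0 - half, c0 - half]
    out[r0, c0] <- blk / s^2
    out
  }
  Ebest <- matrix(-Inf, h, w)
  Sbest <- matrix(1, h, w)
  for (k in 1:kmax) {
    A <- win_avg(k)
    half <- 2L^(k - 1L)
    Eh <- Ev <- matrix(NA_real_, h, w)
    if (w - half >= 1L + half) {
      cs <- (1L + half):(w - half)
      Eh[, cs] <- abs(A[, cs + half] - A[, cs - half])
    }
    if (h - half >= 1L + half) {
      rs <- (1L + half):(h - half)
      Ev[rs, ] <- abs(A[rs + half, ] - A[rs - half, ])
    }
    E <- pmax(Eh, Ev, na.rm = TRUE)
    E[is.na(Eh) & is.na(Ev)] <- NA_real_
    upd <- !is.na(E) & E > Ebest + 1e-12
    Ebest[upd] <- E[upd]
    Sbest[upd] <- 2^k
  }
  valid <- mask & is.finite(Ebest)
  if (!any(valid)) stop("region smaller than the smallest window")
  mean(Sbest[valid])
}

#' Local-similarity texture features: gray average and coarseness
#'
#' `lsp_gray_average` is the mean of the [lsp_map()] over eligible pixels;
#' `lsp_coarseness` is the Tamura coarseness (the mask-averaged best dyadic
#' window size maximizing the directional window-average difference).
#'
#' @param gray numeric matrix of gray levels.
#' @param mask logical matrix (defaults to all-true).
#' @param similarity_t similarity threshold in gray levels.
#' @param coarseness_kmax largest dyadic window exponent (window 2^kmax).
#' @return named numeric vector `lsp_gray_average`, `lsp_coarseness`.
#' @export
lsp_features <- function(gray, mask = NULL, similarity_t = 10,
                         coarseness_kmax = 4L) {
  m <- lsp_map(gray, mask, similarity_t)
  c(lsp_gray_average = mean(m, na.rm = TRUE),
    lsp_coarseness = tamura_coarseness(gray, mask, coarseness_kmax))
}

#' Six texture descriptors of a seed region
#'
#' GLCM statistics (entropy, angular second moment, contrast, homogeneity)
#' computed at distance `d` for orientations 0/45/90/135 degrees and
#' averaged, plus the local-similarity gray average and Tamura coarseness.
#' Field numbering 7-12 of the color-texture set: lsp_gray_average (7),
#' entropy (8), asm (9), contrast (10), homogeneity (11),
#' lsp_coarseness (12). GLCM pairs are restricted to mask-true pixels.
#'
#' @param region a `seed_region`.
#' @param d GLCM displacement (pixels).
#' @param levels GLCM gray levels.
#' @param similarity_t local-similarity threshold (gray levels).
#' @param coarseness_kmax largest dyadic window exponent.
#' @return named numeric vector `tex_07` ... `tex_12`.
#' @export
texture_features <- function(region, d = 1L, levels = 16L,
                             similarity_t = 10, coarseness_kmax = 4L) {
  stopifnot(inherits(region, "seed_region"))
  gray <- frame_gray(region$subimage)
  mask <- region$mask
  per <- vapply(c(0, 45, 90, 135), function(th) {
    glcm_features(compute_glcm(gray, mask, d = d, theta = th, levels = levels))
  }, numeric(4))
  agg <- apply(per, 1, aggregate_orientations)
  lsp <- lsp_features(gray, mask, similarity_t, coarseness_kmax)
  c(tex_07 = unname(lsp["lsp_gray_average"]),
    tex_08 = unname(agg["entropy"]),
    tex_09 = unname(agg["asm"]),
    tex_10 = unname(agg["contrast"]),
    tex_11 = unname(agg["homogeneity"]),
    tex_12 = unname(lsp["lsp_coarseness"]))
}

#' All 27 descriptors of a seed region
#'
#' The 15 shape, 6 color and 6 texture descriptors as one named row, using
#' the per-classifier field numbering (`shape_01..shape_15` for the shape
#' net pool; `color_01..color_06` and `tex_07..tex_12` for the
#' color-texture net pool, numbered 1-12 jointly).
#'
#' @param region a `seed_region`.
#' @param ... passed to [texture_features()].
#' @return named numeric vector of length 27.
#' @export
extract_features <- function(region, ...) {
  c(shape_features(summarize_geometry(region)),
    color_features(region),
    texture_features(region, ...))
}
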
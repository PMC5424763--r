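# Synthetic seed-frame generator: renders grids of seed-like blobs with
# controllable shape class, surface color class and defect density, plus
# exact ground-truth masks and labels, so every pipeline stage is testable
# without physical seed images.

# run code under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.shape_classes <- c("circular", "oval", "triangular", "elongated", "irregular")
.color_classes <- c("reddish_brown", "black", "gray", "white")

# base surface colors (R, G, B). Good grades (reddish-brown, black) are
# dark with high/low saturation; reject grades (gray, white) are pale.
.base_colors <- list(
  reddish_brown = c(165, 95, 60),
  black = c(118, 106, 96),
  gray = c(172, 170, 168),
  white = c(200, 196, 188)
)

#' Specification of one synthetic seed
#'
#' The generator's ground-truth grading rule mirrors the target phenotypes:
#' a seed is `good` iff its shape class is circular or oval AND its surface
#' color class is reddish-brown or black AND its dark-spot density is
#' below 0.02; any other combination is the reject class `ng`.
#'
#' @param shape_class one of circular, oval, triangular, elongated,
#'   irregular.
#' @param color_class one of reddish_brown, black, gray, white.
#' @param spot_density fraction of the seed area covered by dark spots,
#'   in \[0, 0.2\].
#' @param roughness additive surface-noise standard deviation (gray
#'   levels).
#' @param size_px equivalent radius in pixels.
#' @param center (row, col) center in the frame, or NULL for grid
#'   placement.
#' @return list of class `"seed_spec"` including the derived `label`.
#' @export
seed_spec <- function(shape_class, color_class, spot_density = 0,
                      roughness = 2, size_px = 18, center = NULL) {
  shape_class <- match.arg(shape_class, .shape_classes)
  color_class <- match.arg(color_class, .color_classes)
  stopifnot(spot_density >= 0, spot_density <= 0.2, roughness >= 0,
            size_px >= 5)
  label <- if (shape_class %in% c("circular", "oval") &&
               color_class %in% c("reddish_brown", "black") &&
               spot_density < 0.02) "good" else "ng"
  structure(list(shape_class = shape_class, color_class = color_class,
                 spot_density = spot_density, roughness = roughness,
                 size_px = size_px, center = center, label = label),
            class = "seed_spec")
}

# boundary radius function r(phi) of a seed outline; star-convex shapes
.radius_fun <- function(spec) {
  r0 <- spec$size_px
  switch(spec$shape_class,
    circular = {
      w <- stats::runif(1, 0, 0.02)
      ph <- stats::runif(1, 0, 2 * pi)
      function(phi) r0 * (1 + w * cos(2 * phi + ph))
    },
    oval = {
      q <- stats::runif(1, 1.35, 1.6)
      a <- r0 * sqrt(q); b <- r0 / sqrt(q)
      rot <- stats::runif(1, 0, pi)
      function(phi) a * b / sqrt((b * cos(phi - rot))^2 + (a * sin(phi - rot))^2)
    },
    elongated = {
      q <- stats::runif(1, 2.2, 3.0)
      a <- r0 * sqrt(q); b <- r0 / sqrt(q)
      rot <- stats::runif(1, 0, pi)
      function(phi) a * b / sqrt((b * cos(phi - rot))^2 + (a * sin(phi - rot))^2)
    },
    triangular = {
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 0.18, 0.26)
      function(phi) r0 * (1 + amp * cos(3 * (phi - ph)))
    },
    irregular = {
      m <- 2:5
      amp <- stats::runif(4, 0.05, 0.13)
      ph <- stats::runif(4, 0, 2 * pi)
      function(phi) {
        pert <- rowSums(vapply(1:4, function(k) amp[k] * cos(m[k] * phi + ph[k]),
                               numeric(length(phi))))
        r0 * (1 + pert)
      }
    })
}

# render one seed into the frame; returns modified frame + the seed's mask
.render_seed <- function(frame, spec) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  rf <- .radius_fun(spec)
  rmax <- spec$size_px * 2.2
  cen <- spec$center
  r0 <- max(1L, floor(cen[1] - rmax)); r1 <- min(h, ceiling(cen[1] + rmax))
  c0 <- max(1L, floor(cen[2] - rmax)); c1 <- min(w, ceiling(cen[2] + rmax))
  rr <- r0:r1; cc <- c0:c1
  # 2 x 2 supersampled coverage of { rho <= r(phi) }
  cov <- matrix(0, length(rr), length(cc))
  for (or in c(-0.25, 0.25)) for (oc in c(-0.25, 0.25)) {
    dy <- outer(rr + or - cen[1], rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc + oc - cen[2])
    rho <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    cov <- cov + (rho <= rf(as.vector(phi)))
  }
  cov <- cov / 4
  mask_local <- cov >= 0.5
  if (!any(mask_local)) return(list(frame = frame, mask_rc = NULL))

  # surface: base color with per-seed jitter, radial shading, roughness
  base <- .base_colors[[spec$color_class]] * stats::runif(1, 0.93, 1.07)
  dy <- outer(rr - cen[1], rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - cen[2])
  rho_n <- sqrt(dx^2 + dy^2) / max(rf(seq(0, 2 * pi, length.out = 64)))
  shade <- 1 - 0.25 * pmin(rho_n, 1)^2
  noise <- matrix(stats::rnorm(length(rr) * length(cc), 0, spec$roughness),
                  length(rr), length(cc))
  # dark spots: Poisson-placed discs covering ~spot_density of the area
  spot_f <- matrix(1, length(rr), length(cc))
  if (spec$spot_density > 0) {
    area <- sum(mask_local)
    sr <- stats::runif(1, 1.3, 2.2)
    nspots <- stats::rpois(1, spec$spot_density * area / (pi * sr^2))
    if (nspots > 0) {
      inside <- which(mask_local, arr.ind = TRUE)
      pick <- inside[sample.int(nrow(inside), nspots, replace = TRUE), ,
                     drop = FALSE]
      for (s in seq_len(nspots)) {
        d2 <- (row(spot_f) - pick[s, 1])^2 + (col(spot_f) - pick[s, 2])^2
        spot_f[d2 <= sr^2] <- 0.35
      }
    }
  }
  for (ch in 1:3) {
    val <- (base[ch] * shade * spot_f + noise) * cov
    cur <- frame[rr, cc, ch]
    frame[rr, cc, ch] <- pmin(255, pmax(0, cur * (1 - cov) + val))
  }
  mask_rc <- which(mask_local, arr.ind = TRUE)
  mask_rc[, 1] <- mask_rc[, 1] + r0 - 1L
  mask_rc[, 2] <- mask_rc[, 2] + c0 - 1L
  list(frame = frame, mask_rc = mask_rc)
}

#' Plan a synthetic multi-seed frame
#'
#' Default geometry mirrors the capture layout: a 3 x 7 grid of 21 seeds
#' on a dark field, rendered at desk scale (400 x 400 px).
#'
#' @param specs list of [seed_spec()]s (length nrow * ncol); NULL draws a
#'   random good/NG mix.
#' @param nrow,ncol grid dimensions.
#' @param frame_h,frame_w frame size in pixels.
#' @param background background gray level.
#' @param rng_seed integer seed; the plan and its rendering are
#'   deterministic given this seed.
#' @return list of class `"frame_plan"`.
#' @export
frame_plan <- function(specs = NULL, nrow = 3L, ncol = 7L,
                       frame_h = 400L, frame_w = 400L, background = 5,
                       rng_seed = 1L) {
  n <- nrow * ncol
  if (is.null(specs)) {
    specs <- with_local_seed(rng_seed, {
      lapply(seq_len(n), function(i) random_seed_spec())
    })
  }
  stopifnot(length(specs) == n)
  structure(list(specs = specs, nrow = nrow, ncol = ncol,
                 frame_h = frame_h, frame_w = frame_w,
                 background = background, rng_seed = rng_seed),
            class = "frame_plan")
}

#' Draw a random seed specification
#'
#' `good` draws from the good phenotype (circular/oval, reddish-brown or
#' black, spot density below 0.015); `ng` draws a defect pattern (bad
#' shape, bad color, heavy spotting, or several at once); NULL picks
#' good/ng with equal probability. Uses the current RNG state.
#'
#' @param label "good", "ng" or NULL.
#' @param size_px equivalent radius (a single value or range to sample).
#' @return a [seed_spec()].
#' @export
random_seed_spec <- function(label = NULL, size_px = c(15, 21)) {
  if (is.null(label)) label <- sample(c("good", "ng"), 1L)
  sz <- if (length(size_px) == 2L) stats::runif(1, size_px[1], size_px[2]) else size_px
  # slimmer equivalent radius for stretched classes so every class fits
  # the same grid cell
  scale_for <- c(circular = 1, oval = 0.95, triangular = 0.88,
                 elongated = 0.68, irregular = 0.8)
  rough <- stats::runif(1, 1, 4)
  if (label == "good") {
    shape <- sample(c("circular", "oval"), 1L)
    seed_spec(shape, sample(c("reddish_brown", "black"), 1L),
              spot_density = stats::runif(1, 0, 0.015),
              roughness = rough, size_px = sz * scale_for[[shape]])
  } else {
    mode <- sample(c("shape", "color", "spots", "mixed"), 1L,
                   prob = c(0.3, 0.3, 0.2, 0.2))
    shape <- switch(mode,
      shape = , mixed = sample(c("triangular", "elongated", "irregular"), 1L),
      sample(c("circular", "oval"), 1L))
    color <- switch(mode,
      color = , mixed = sample(c("gray", "white"), 1L),
      sample(c("reddish_brown", "black"), 1L))
    spots <- switch(mode,
      spots = stats::runif(1, 0.05, 0.2),
      mixed = stats::runif(1, 0, 0.2),
      stats::runif(1, 0, 0.015))
    seed_spec(shape, color, spot_density = spots, roughness = rough,
              size_px = sz * scale_for[[shape]])
  }
}

#' Render a planned frame with ground truth
#'
#' Renders anti-aliased seed blobs with class-dependent base color,
#' radial shading, additive Gaussian surface noise and Poisson-placed dark
#' spots on a dark field. Seeds are placed on the plan's grid with a small
#' jitter; an error is raised if two seeds would overlap. Deterministic in
#' `plan$rng_seed`.
#'
#' @param plan a [frame_plan()].
#' @return list: `frame` (H x W x 3 array), `masks` (list of per-seed
#'   ground-truth index matrices, row-major order), `labels` (character),
#'   `specs`, `centers` (n x 2 matrix of (row, col)).
#' @export
make_frame <- function(plan) {
  stopifnot(inherits(plan, "frame_plan"))
  with_local_seed(plan$rng_seed + 1L, {
    h <- plan$frame_h; w <- plan$frame_w
    frame <- array(plan$background, c(h, w, 3))
    ch <- h / plan$nrow; cw <- w / plan$ncol
    masks <- list(); labels <- character(0)
    centers <- matrix(0, 0, 2)
    k <- 0L
    for (i in seq_len(plan$nrow)) for (j in seq_len(plan$ncol)) {
      k <- k + 1L
      spec <- plan$specs[[k]]
      if (is.null(spec$center)) {
        jit <- stats::runif(2, -2, 2)
        spec$center <- c((i - 0.5) * ch + jit[1], (j - 0.5) * cw + jit[2])
      }
      stretch <- c(circular = 1.03, oval = 1.27, triangular = 1.27,
                   elongated = 1.74, irregular = 1.55)[[spec$shape_class]]
      if (2 * (stretch * spec$size_px + 2) > min(ch, cw))
        stop("seed too large for its grid cell: seeds would overlap")
      res <- .render_seed(frame, spec)
      frame <- res$frame
      masks[[k]] <- res$mask_rc
      labels[k] <- spec$label
      centers <- rbind(centers, spec$center)
    }
    # overlap guard on the exact masks
    all_px <- do.call(rbind, masks)
    if (nrow(unique(all_px)) < nrow(all_px)) stop("seeds overlap")
    list(frame = frame, masks = masks, labels = labels,
         specs = plan$specs, centers = centers)
  })
}

#' Labeled feature table from rendered seeds
#'
#' Renders `n_good + n_ng` seeds (one per small frame), segments each with
#' the real imaging stack, extracts the 27 descriptors and returns the
#' labeled table. Features come from actual rendered images, not from
#' sampled distributions. Deterministic in `rng_seed`.
#'
#' @param n_good,n_ng number of good / reject seeds (>= 1).
#' @param rng_seed integer seed.
#' @param config segmentation and feature parameters
#'   ([default_config()]).
#' @return data frame: `label`, `shape_class`, `color_class`,
#'   `spot_density`, then the 27 feature columns.
#' @export
make_feature_dataset <- function(n_good, n_ng, rng_seed = 1L,
                                 config = default_config()) {
  stopifnot(n_good >= 1, n_ng >= 1)
  labels <- c(rep("good", n_good), rep("ng", n_ng))
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    rows[[i]] <- with_local_seed(rng_seed * 10000L + i, {
      spec <- random_seed_spec(labels[i])
      spec$center <- c(48, 48) + stats::runif(2, -2, 2)
      fr <- array(5, c(96, 96, 3))
      fr <- .render_seed(fr, spec)$frame
      regions <- segment_frame(fr, method = config$threshold_mode,
                               fixed_t = config$fixed_t,
                               radius = config$morph_radius,
                               min_area = config$min_area)
      if (!length(regions))
        stop(sprintf("seed %d: segmentation found no region", i))
      # pathological surfaces can fragment; grade the dominant component
      best <- regions[[which.max(vapply(regions, function(r) r$area_px, 0))]]
      feats <- extract_features(best,
                                d = config$glcm_distance,
                                levels = config$glcm_levels,
                                similarity_t = config$lsp_similarity_t,
                                coarseness_kmax = config$coarseness_kmax)
      cbind(data.frame(label = spec$label, shape_class = spec$shape_class,
                       color_class = spec$color_class,
                       spot_density = spec$spot_density,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(feats)))
    })
  }
  do.call(rbind, rows)
}
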
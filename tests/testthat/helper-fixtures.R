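# Fixture builders shared across the test files. Everything is generated
# in code; no stored image data.

# rasterize an indicator f(dy, dx) on an n x n lattice centered mid-grid
rasterize <- function(f, n) {
  cen <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) f(i - cen, j - cen))
}

rasterize_disk <- function(r, pad = 5) {
  rasterize(function(y, x) x^2 + y^2 <= r^2, 2 * (r + pad) + 1)
}

# solid rectangle mask of rows x cols inside a padded field
rasterize_rect <- function(rows, cols, pad = 5) {
  m <- matrix(FALSE, rows + 2 * pad, cols + 2 * pad)
  m[pad + seq_len(rows), pad + seq_len(cols)] <- TRUE
  m
}

# a gray frame (all channels equal) from a mask
mask_frame <- function(mask, fg = 200, bg = 0) {
  fr <- array(bg, c(dim(mask), 3))
  for (ch in 1:3) fr[, , ch] <- ifelse(mask, fg, bg)
  fr
}

# the single seed_region of a mask
region_of <- function(mask, fg = 200) {
  regs <- extract_regions(mask_frame(mask, fg), mask, min_area = 5)
  stopifnot(length(regs) == 1L)
  regs[[1]]
}

# brute-force GLCM by explicit pair enumeration (independent oracle)
glcm_bruteforce <- function(gray, mask, d, theta, levels) {
  q <- pmin(floor(gray * levels / 256), levels - 1L)
  off <- switch(as.character(theta),
                "0" = c(0L, d), "45" = c(-d, d),
                "90" = c(-d, 0L), "135" = c(-d, -d))
  h <- nrow(gray); w <- ncol(gray)
  p <- matrix(0, levels, levels)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 < 1 || i2 > h || j2 < 1 || j2 > w) next
    if (!mask[i, j] || !mask[i2, j2]) next
    p[q[i, j] + 1L, q[i2, j2] + 1L] <- p[q[i, j] + 1L, q[i2, j2] + 1L] + 1
  }
  p / sum(p)
}

# brute-force binary erosion by neighborhood test (independent oracle)
erode_bruteforce <- function(mask, se) {
  rh <- (nrow(se) - 1L) %/% 2L; rw <- (ncol(se) - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ok <- TRUE
    for (a in -rh:rh) for (b in -rw:rw) {
      if (se[a + rh + 1L, b + rw + 1L] == 0) next
      ii <- i + a; jj <- j + b
      if (ii < 1 || ii > h || jj < 1 || jj > w || !mask[ii, jj]) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

dilate_bruteforce <- function(mask, se) {
  rh <- (nrow(se) - 1L) %/% 2L; rw <- (ncol(se) - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    hit <- FALSE
    for (a in -rh:rh) for (b in -rw:rw) {
      if (se[rh - a + 1L, rw - b + 1L] == 0) next  # reflected element
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj]) {
        hit <- TRUE; break
      }
    }
    out[i, j] <- hit
  }
  out
}

# map each generated center to its segmented region (nearest centroid)
match_regions_to_centers <- function(regions, centers) {
  cen <- t(vapply(regions, function(r) r$centroid, numeric(2)))
  vapply(seq_len(nrow(centers)), function(i) {
    d2 <- (cen[, 1] - centers[i, 1])^2 + (cen[, 2] - centers[i, 2])^2
    which.min(d2)
  }, integer(1))
}
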
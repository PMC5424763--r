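# Color descriptors: RGB and HSI channel means over the masked seed pixels.

#' Convert RGB intensities to the HSI color model
#'
#' Geometric HSI conversion: intensity I = (R+G+B)/3; saturation
#' S = 1 - 3 min(R,G,B)/(R+G+B) (0 for a black pixel); hue from the arccos
#' form, reflected to 360 - theta when B > G, and set to 0 for achromatic
#' pixels (S = 0).
#'
#' @param r,g,b intensities in \[0, 255\] (vectorized).
#' @return list with components `h` (degrees in \[0, 360)), `s` in \[0, 1\],
#'   `i` in \[0, 255\].
#' @export
rgb_to_hsi <- function(r, g, b) {
  stopifnot(all(r >= 0 & r <= 255), all(g >= 0 & g <= 255),
            all(b >= 0 & b <= 255))
  i <- (r + g + b) / 3
  s <- ifelse(r + g + b == 0, 0, 1 - 3 * pmin(r, g, b) / (r + g + b))
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  co <- ifelse(den == 0, 1, pmin(1, pmax(-1, num / den)))
  theta <- acos(co) * 180 / pi
  h <- ifelse(b > g, 360 - theta, theta)
  h <- ifelse(s == 0, 0, h)
  list(h = h, s = s, i = i)
}

#' Six color descriptors of a seed region
#'
#' Channel means over mask-true pixels only (field numbering 1-6 of the
#' color-texture set): mean blue, green and red; mean hue (degrees / 360,
#' so on \[0, 1\]); mean saturation; and mean gray level (R+G+B)/3, which
#' equals the HSI intensity mean.
#'
#' Hue is averaged arithmetically by default; a hue near the 0/360 wrap
#' can therefore average misleadingly (e.g. pixels at 1 and 359 degrees
#' average to 180). Set `circular_hue = TRUE` for the circular mean.
#'
#' @param region a `seed_region`.
#' @param circular_hue use the circular mean of hue instead of the
#'   arithmetic mean.
#' @return named numeric vector `color_01` ... `color_06`
#'   (b_mean, g_mean, r_mean, h_mean, s_mean, gray_mean).
#' @export
color_features <- function(region, circular_hue = FALSE) {
  stopifnot(inherits(region, "seed_region"))
  sel <- region$mask
  if (!any(sel)) stop("empty mask: no pixels to average")
  r <- region$subimage[, , 1][sel]
  g <- region$subimage[, , 2][sel]
  b <- region$subimage[, , 3][sel]
  hsi <- rgb_to_hsi(r, g, b)
  h_mean <- if (circular_hue) {
    a <- hsi$h * pi / 180
    (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360 / 360
  } else mean(hsi$h) / 360
  c(color_01 = mean(b), color_02 = mean(g), color_03 = mean(r),
    color_04 = h_mean, color_05 = mean(hsi$s), color_06 = mean(hsi$i))
}
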
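# Frozen analytic values for the rasterized primitives:
#   disk r = 40:        circularity1 -> 1, eccentricity -> 0, elongation -> 1,
#                       defect_ratio -> 0, sar1..3 -> 0
#   rectangle 100 x 50: P = 300, A = 5000, circularity1 = 4*pi*5000/300^2
#                       = 0.69813, D_max = sqrt(12500) = 111.803, D_min = 50,
#                       elongation = 0.44721,
#                       eccentricity = sqrt(1 - 50^2/100^2) = 0.86603,
#                       defect_ratio = (pi*55.902^2 - 5000)/(pi*55.902^2)
#                       = 0.49070
#   ellipse a=50 b=30:  eccentricity = sqrt(2500-900)/50 = 0.8,
#                       elongation = 0.6

test_that("disk geometry matches closed forms", {
  r <- region_of(rasterize_disk(40))
  g <- summarize_geometry(r)
  expect_lt(abs(g$A - pi * 40^2) / (pi * 40^2), 0.01)
  expect_lt(abs(g$P - 2 * pi * 40) / (2 * pi * 40), 0.01)
  expect_lt(abs(g$D_max - 80) / 80, 0.01)
  expect_lt(abs(g$D_min - 80) / 80, 0.015)
  expect_equal(sum(g$quadrant_areas), g$A)
  f <- shape_features(g)
  expect_gt(f[["shape_01"]], 0.98)   # circularity1 -> 1
  expect_lt(f[["shape_08"]], 0.05)   # eccentricity -> 0
  expect_gt(f[["shape_07"]], 0.98)   # elongation -> 1
  expect_lt(f[["shape_03"]], 0.02)   # defect_ratio -> 0
  expect_lt(max(f[["shape_13"]], f[["shape_14"]], f[["shape_15"]]), 0.01)
  expect_lt(abs(f[["shape_06"]] - 1), 0.02)  # ellipticity index -> 1
})

test_that("rectangle geometry matches closed forms", {
  r <- region_of(rasterize_rect(50, 100))
  g <- summarize_geometry(r)
  expect_equal(g$A, 5000)
  expect_lt(abs(g$D_max - sqrt(12500)), 1)
  expect_lt(abs(g$D_min - 50), 1)
  f <- shape_features(g)
  expect_lt(abs(f[["shape_01"]] - 0.69813) / 0.69813, 0.02)
  expect_lt(abs(f[["shape_07"]] - 0.44721) / 0.44721, 0.02)
  expect_lt(abs(f[["shape_08"]] - 0.86603) / 0.86603, 0.02)
  expect_lt(abs(f[["shape_03"]] - 0.49070) / 0.49070, 0.02)
  expect_lt(max(f[["shape_13"]], f[["shape_14"]], f[["shape_15"]]), 0.01)
})

test_that("ellipse eccentricity and elongation match closed forms", {
  m <- rasterize(function(y, x) (x / 50)^2 + (y / 30)^2 <= 1, 111)
  f <- shape_features(summarize_geometry(region_of(m)))
  expect_lt(abs(f[["shape_08"]] - 0.8) / 0.8, 0.02)
  expect_lt(abs(f[["shape_07"]] - 0.6) / 0.6, 0.02)
  expect_lt(max(f[["shape_13"]], f[["shape_14"]], f[["shape_15"]]), 0.01)
})

test_that("all 15 features are invariant under 90-degree rotation and mirror", {
  shapes <- list(
    rasterize(function(y, x) (x / 45)^2 + (y / 28)^2 <= 1, 101),
    rasterize_rect(40, 70),
    rasterize(function(y, x) {
      phi <- atan2(y, x)
      sqrt(x^2 + y^2) <= 30 * (1 + 0.2 * cos(3 * phi))
    }, 91)
  )
  for (m in shapes) {
    f0 <- shape_features(summarize_geometry(region_of(m)))
    variants <- list(
      t(m),                       # transpose
      m[nrow(m):1, ],             # vertical mirror
      m[, ncol(m):1],             # horizontal mirror
      t(m)[ncol(m):1, ]           # 90-degree rotation
    )
    for (v in variants) {
      fv <- shape_features(summarize_geometry(region_of(v)))
      expect_equal(fv, f0, tolerance = 1e-12)
    }
  }
})

test_that("features are stable under small rotations and 2x upsampling", {
  # rasterized ellipse rotated by 17 degrees: dimensionless features move < 2%
  mk <- function(ang, s = 1) {
    rasterize(function(y, x) {
      xr <- x * cos(ang) + y * sin(ang)
      yr <- -x * sin(ang) + y * cos(ang)
      (xr / (40 * s))^2 + (yr / (26 * s))^2 <= 1
    }, round(101 * s))
  }
  f0 <- shape_features(summarize_geometry(region_of(mk(0))))
  frot <- shape_features(summarize_geometry(region_of(mk(17 * pi / 180))))
  f2x <- shape_features(summarize_geometry(region_of(mk(0, s = 2))))
  for (k in c(1:9, 13:15)) {  # dimensionless features (hull angles and
    nm <- sprintf("shape_%02d", k)  # defect depth excluded: degrees / px)
    expect_lt(abs(frot[[nm]] - f0[[nm]]), max(0.02 * abs(f0[[nm]]), 0.02))
    expect_lt(abs(f2x[[nm]] - f0[[nm]]), max(0.02 * abs(f0[[nm]]), 0.02))
  }
})

test_that("circularity orders disk above other shapes; defect ratio detects gaps", {
  f_disk <- shape_features(summarize_geometry(region_of(rasterize_disk(35))))
  f_rect <- shape_features(summarize_geometry(region_of(rasterize_rect(40, 80))))
  f_tri <- shape_features(summarize_geometry(region_of(
    rasterize(function(y, x) {
      phi <- atan2(y, x)
      sqrt(x^2 + y^2) <= 28 * (1 + 0.22 * cos(3 * phi))
    }, 85))))
  expect_gt(f_disk[["shape_01"]], f_rect[["shape_01"]])
  expect_gt(f_disk[["shape_01"]], f_tri[["shape_01"]])
  expect_lt(f_disk[["shape_03"]], f_rect[["shape_03"]])
  expect_lt(f_disk[["shape_03"]], f_tri[["shape_03"]])
  # convexity-defect depth: near zero for convex shapes, positive for the
  # three-lobed blob
  expect_lt(f_disk[["shape_12"]], 1)
  expect_gt(f_tri[["shape_12"]], 2)
})

test_that("degenerate and invalid regions are rejected", {
  thin <- matrix(FALSE, 12, 12); thin[6, 2:11] <- TRUE
  expect_error(summarize_geometry(region_of(thin)), "degenerate|collinear")
  tiny <- matrix(FALSE, 6, 6); tiny[3, 3:4] <- TRUE
  fr <- mask_frame(tiny)
  regs <- extract_regions(fr, tiny, min_area = 1)
  expect_error(summarize_geometry(regs[[1]]), "too small")
})

test_that("minimum enclosing circle is exact on known point sets", {
  # square corners: circle through the diagonal
  pts <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10), c(5, 5))
  mec <- seedvision:::min_enclosing_circle(pts)
  expect_equal(mec$r, sqrt(50), tolerance = 1e-9)
  expect_equal(mec$center, c(5, 5), tolerance = 1e-9)
  # two points: diameter circle
  mec2 <- seedvision:::min_enclosing_circle(rbind(c(0, 0), c(6, 8)))
  expect_equal(mec2$r, 5, tolerance = 1e-9)
  # collinear points fall back to the widest pair
  mec3 <- seedvision:::min_enclosing_circle(rbind(c(0, 0), c(2, 0), c(7, 0)))
  expect_equal(mec3$r, 3.5, tolerance = 1e-9)
})
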
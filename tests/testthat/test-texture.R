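test_that("compute_glcm matches hand-enumerated pair counts", {
  # 2 x 2 image, columns 0 and 255, 2 levels, theta 0: both horizontal
  # pairs are (0, 1)
  g <- matrix(c(0, 0, 255, 255), 2, 2)
  p <- compute_glcm(g, levels = 2, theta = 0)$p
  expect_equal(p, matrix(c(0, 0, 1, 0), 2, 2))
  # 4 x 4 checkerboard, theta 0: half (0,1), half (1,0)
  cb <- 255 * outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  p2 <- compute_glcm(cb, levels = 2, theta = 0)$p
  expect_equal(p2, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  # constant image: single diagonal entry 1 at the bin of the gray value
  p3 <- compute_glcm(matrix(100, 5, 5), levels = 16, theta = 45)$p
  bin <- floor(100 * 16 / 256) + 1
  expect_equal(p3[bin, bin], 1)
  expect_equal(sum(p3), 1)
})

test_that("glcm_features implement the four statistics", {
  # single off-diagonal mass P(0,1) = 1
  g <- matrix(c(0, 0, 255, 255), 2, 2)
  f <- glcm_features(compute_glcm(g, levels = 2, theta = 0))
  expect_equal(unname(f), c(1, 0, 1, 0.5))
  # checkerboard: asm 0.5, entropy ln 2, contrast 1, homogeneity 0.5
  cb <- 255 * outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  f2 <- glcm_features(compute_glcm(cb, levels = 2, theta = 0))
  expect_equal(unname(f2), c(0.5, log(2), 1, 0.5))
  # constant image: asm 1, entropy 0, contrast 0, homogeneity 1
  f3 <- glcm_features(compute_glcm(matrix(7, 4, 4), levels = 4, theta = 90))
  expect_equal(unname(f3), c(1, 0, 0, 1))
})

test_that("compute_glcm equals the brute-force enumeration oracle", {
  set.seed(20240101)
  for (trial in 1:250) {
    lv <- sample(2:16, 1)
    th <- sample(c(0, 45, 90, 135), 1)
    g <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    mask <- matrix(sample(c(TRUE, TRUE, TRUE, FALSE), 64, replace = TRUE), 8, 8)
    got <- try(compute_glcm(g, mask, d = 1, theta = th, levels = lv),
               silent = TRUE)
    oracle <- glcm_bruteforce(g, mask, 1, th, lv)
    if (inherits(got, "try-error")) {
      expect_true(all(is.na(oracle)) || sum(oracle, na.rm = TRUE) == 0)
    } else {
      expect_equal(got$p, oracle)
    }
  }
})

test_that("orientation aggregation is the mean and closed under 90-degree rotation", {
  expect_equal(aggregate_orientations(c(1, 1, 1, 1)), 1)
  expect_equal(aggregate_orientations(c(0, 1, 0, 1)), 0.5)
  expect_error(aggregate_orientations(1:3), "four")
  # aggregated contrast identical for an image and its 90-degree rotation
  set.seed(5)
  g <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  agg_con <- function(im) {
    aggregate_orientations(vapply(c(0, 45, 90, 135), function(th)
      glcm_features(compute_glcm(im, levels = 8, theta = th))[["contrast"]], 0))
  }
  rot90 <- t(g)[ncol(g):1, ]
  expect_equal(agg_con(g), agg_con(rot90), tolerance = 1e-12)
})

test_that("lsp_map counts similar neighbors with rotation invariance", {
  expect_true(all(lsp_map(matrix(100, 5, 5)) == 1, na.rm = TRUE))
  # center 100 with 4 similar and 4 dissimilar neighbors -> 0.5
  g <- matrix(100, 3, 3)
  g[1, ] <- 200; g[2, 3] <- 200  # four neighbors at 200
  expect_equal(lsp_map(g, similarity_t = 10)[2, 2], 0.5)
  # isolated bright speck scores 0
  sp <- matrix(100, 5, 5); sp[3, 3] <- 250
  expect_equal(lsp_map(sp, similarity_t = 10)[3, 3], 0)
  # rotation invariance of the map's value set
  set.seed(9)
  r <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  m1 <- lsp_map(r, similarity_t = 20)
  m2 <- lsp_map(t(r)[ncol(r):1, ], similarity_t = 20)
  expect_equal(sort(as.vector(m1[!is.na(m1)])), sort(as.vector(m2[!is.na(m2)])))
  expect_error(lsp_map(matrix(1, 2, 2)), "eligible|smaller")
})

test_that("lsp features separate smooth, spotted and blocky surfaces", {
  smooth <- matrix(120, 24, 24)
  expect_equal(lsp_features(smooth)[["lsp_gray_average"]], 1)
  # spotted surface scores lower than smooth
  set.seed(3)
  spotted <- smooth
  idx <- cbind(sample(3:22, 12), sample(3:22, 12))
  spotted[idx] <- 30
  expect_lt(lsp_features(spotted)[["lsp_gray_average"]], 1)
  # Tamura coarseness: blocks coarser than a fine checkerboard
  fine <- 255 * outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  blocks <- 255 * outer(1:32, 1:32, function(i, j) ((i - 1) %/% 8 + (j - 1) %/% 8) %% 2)
  expect_gt(lsp_features(blocks)[["lsp_coarseness"]],
            lsp_features(fine)[["lsp_coarseness"]])
  expect_error(lsp_features(matrix(1, 2, 2)), "smaller|eligible")
})

test_that("asm and entropy are anti-monotone across increasing randomness", {
  set.seed(11)
  constant <- matrix(100, 16, 16)
  blocks <- 200 * outer(1:16, 1:16, function(i, j) ((i - 1) %/% 4 + (j - 1) %/% 4) %% 2)
  noise <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  fam <- list(constant, blocks, noise)
  asm <- vapply(fam, function(im)
    glcm_features(compute_glcm(im, levels = 8, theta = 0))[["asm"]], 0)
  ent <- vapply(fam, function(im)
    glcm_features(compute_glcm(im, levels = 8, theta = 0))[["entropy"]], 0)
  expect_true(all(diff(asm) < 0))
  expect_true(all(diff(ent) > 0))
})

test_that("texture_features returns the six numbered descriptors", {
  r <- region_of(rasterize_disk(16))
  f <- texture_features(r)
  expect_named(f, sprintf("tex_%02d", 7:12))
  expect_true(f[["tex_09"]] > 0 && f[["tex_09"]] <= 1)   # asm
  expect_true(f[["tex_11"]] > 0 && f[["tex_11"]] <= 1)   # homogeneity
  expect_gte(f[["tex_10"]], 0)                           # contrast
  expect_gte(f[["tex_08"]], 0)                           # entropy
  expect_true(f[["tex_07"]] >= 0 && f[["tex_07"]] <= 1)  # lsp average
})
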
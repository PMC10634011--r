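px_block <- function(rows, cols, dims) {
  g <- expand.grid(r = rows, c = cols)
  as.integer(g$r + (g$c - 1) * dims[1])
}

test_that("morphology of a 10x10 square matches hand geometry", {
  dims <- c(30, 30)
  px <- px_block(5:14, 8:17, dims)
  m <- morphology_features(px, dims, mpp = 1)
  expect_equal(m[["area_um2"]], 100)
  expect_equal(m[["length_um"]], 40)                     # pixel boundary
  expect_equal(m[["circularity"]], 4 * pi * 100 / 1600)  # ~0.7854
  expect_equal(m[["solidity"]], 1)
  expect_equal(m[["max_diameter_um"]], 10 * sqrt(2))     # corner-to-corner
  expect_equal(m[["min_diameter_um"]], 10)               # calliper width
})

test_that("single-pixel objects use the pixel boundary without NaNs", {
  m <- morphology_features(5L, c(10, 10), mpp = 0.5)
  expect_equal(m[["length_um"]], 4 * 0.5)
  expect_equal(m[["area_um2"]], 0.25)
  expect_true(all(is.finite(m)))
})

test_that("rectangles (convex masks) have solidity 1 and a rasterised disc is compact", {
  dims <- c(60, 60)
  for (w in c(3, 7, 12)) {
    px <- px_block(10:(10 + w), 20:(20 + 2 * w), dims)
    expect_equal(morphology_features(px, dims, 1)[["solidity"]], 1,
                 tolerance = 1e-9)
  }
  # rasterised disc r = 20: calliper diameters ~ 2r, near-convex, and the
  # boundary length equals the brute-force exposed-edge count
  dims <- c(120, 120)
  g <- expand.grid(r = 1:120, c = 1:120)
  keep <- (g$r - 60)^2 + (g$c - 60)^2 <= 20^2
  px <- as.integer(g$r[keep] + (g$c[keep] - 1) * 120)
  m <- morphology_features(px, dims, 1)
  expect_equal(m[["max_diameter_um"]], 2 * 20, tolerance = 0.06)
  expect_equal(m[["min_diameter_um"]], 2 * 20, tolerance = 0.06)
  # the pixel union of a digitised disc is not convex: its corner-point
  # hull circumscribes the staircase, so solidity sits a little below 1
  expect_gt(m[["solidity"]], 0.94)
  expect_equal(m[["length_um"]], oracle_perimeter_edges(px, dims))
  expect_equal(m[["circularity"]],
               4 * pi * length(px) / oracle_perimeter_edges(px, dims)^2)
})

test_that("intensity statistics match brute-force pixel enumeration", {
  set.seed(5)
  rgb <- array(runif(20 * 20 * 3), dim = c(20, 20, 3))
  st <- channel_stack(rgb, mpp = 0.5)
  # constant channel under the mask
  st$dab <- matrix(0.4, 20, 20)
  px <- px_block(3:6, 3:6, c(20, 20))
  f <- intensity_features(st, px)
  expect_equal(unname(f[c("dab_min", "dab_max", "dab_mean", "dab_median")]),
               rep(0.4, 4))
  expect_equal(f[["dab_sd"]], 0)
  # two-pixel {0, 1}: population SD = 0.5
  st$dab[3, 3] <- 0; st$dab[4, 3] <- 1
  f2 <- intensity_features(st, px_block(3:4, 3, c(20, 20)))
  expect_equal(f2[["dab_mean"]], 0.5)
  expect_equal(f2[["dab_median"]], 0.5)
  expect_equal(f2[["dab_sd"]], 0.5)
  # random mask vs direct recomputation, all 7 channels
  st2 <- channel_stack(rgb, mpp = 0.5)
  px <- sample(400, 37)
  f3 <- intensity_features(st2, px)
  for (ch in channel_names()) {
    v <- st2[[ch]][px]
    expect_equal(f3[[paste0(ch, "_min")]], min(v))
    expect_equal(f3[[paste0(ch, "_mean")]], mean(v))
    expect_equal(f3[[paste0(ch, "_sd")]],
                 sqrt(mean((v - mean(v))^2)))
  }
})

test_that("Haralick limits for constant objects are the documented ones", {
  img <- matrix(0.7, 10, 10)
  f <- haralick_features(img, px_block(2:5, 2:5, c(10, 10)))
  expect_equal(f[["asm"]], 1)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["idm"]], 1)
  expect_equal(f[["correlation"]], 0)
  expect_error(haralick_features(img, 5L), "2 pixels")
})

test_that("a 1x4 alternating strip matches the hand-built GLCM", {
  img <- matrix(0, 4, 8)
  img[2, 2:5] <- c(0.1, 0.9, 0.1, 0.9)   # quantises to 0,1,0,1 at 2 levels
  px <- px_block(2, 2:5, c(4, 8))
  f <- haralick_features(img, px, glcm_params(levels = 2, directions = 1))
  # 3 horizontal pairs, symmetric: all 6 entries off-diagonal
  # P = [[0, .5], [.5, 0]] -> contrast 1, ASM .5, entropy 1
  expect_equal(f[["contrast"]], 1)
  expect_equal(f[["asm"]], 0.5)
  expect_equal(f[["entropy"]], 1)
})

test_that("all 13 Haralick features match the brute-force oracle", {
  set.seed(99)
  for (rep in 1:10) {
    img <- matrix(sample(c(0.2, 0.8), 64, replace = TRUE), 8, 8)
    px <- sort(sample(64, 40))
    got <- haralick_features(img, px, glcm_params(levels = 32))
    want <- oracle_haralick(img, px, levels = 32)
    expect_lt(max(abs(unname(got) - want)), 1e-10)
  }
})

test_that("the GLCM is symmetric with rows summing to 1", {
  set.seed(12)
  img <- matrix(runif(100), 10, 10)
  px <- sample(100, 60)
  q <- taupath:::quantize_levels(img[px], 8)
  qimg <- matrix(0L, 10, 10); qimg[px] <- q
  inm <- matrix(FALSE, 10, 10); inm[px] <- TRUE
  p <- taupath:::glcm_one_offset(qimg, inm, 0L, 1L, 8L, symmetric = TRUE)
  expect_equal(sum(p), 1)
  expect_equal(p, t(p))
})

test_that("feature vectors are translation invariant and 90-degree stable", {
  set.seed(8)
  patch <- matrix(runif(49), 7, 7)
  base <- array(1, dim = c(40, 40, 3))
  make_stack <- function(at_r, at_c, m) {
    rgb <- base
    for (ch in 1:3) rgb[at_r:(at_r + nrow(m) - 1), at_c:(at_c + ncol(m) - 1), ch] <-
      m[, ] * 0.5
    channel_stack(rgb, mpp = 0.5)
  }
  px1 <- px_block(5:11, 5:11, c(40, 40))
  px2 <- px_block(20:26, 25:31, c(40, 40))
  st1 <- make_stack(5, 5, patch)
  st2 <- make_stack(20, 25, patch)
  obj <- function(px) {
    o <- tibble::tibble(object_id = 1L, tile_id = "t", region_group = "cortex",
                        n_pixels = length(px), area_um2 = length(px) * 0.25,
                        centroid_x = 0, centroid_y = 0, min_row = 1L,
                        max_row = 1L, min_col = 1L, max_col = 1L, mpp = 0.5,
                        img_h = 40L, img_w = 40L, pixels = list(px),
                        polygon = list(list()))
    class(o) <- c("tau_objects", class(o))
    o
  }
  f1 <- extract_features(obj(px1), st1)
  f2 <- extract_features(obj(px2), st2)
  expect_equal(f1[, feature_names()], f2[, feature_names()], tolerance = 1e-12)
  # 90-degree rotation: area/solidity and (4-direction) Haralick unchanged
  rot <- t(patch[nrow(patch):1, ])
  st3 <- make_stack(5, 5, rot)
  f3 <- extract_features(obj(px1), st3)
  har <- grep("^haralick_", feature_names(), value = TRUE)
  expect_equal(as.numeric(f1[, har]), as.numeric(f3[, har]), tolerance = 1e-10)
  expect_equal(f1$area_um2, f3$area_um2)
  expect_equal(f1$solidity, f3$solidity)
})

test_that("assembled vectors have 54 ordered values and round-trip CSV", {
  spec <- slide_spec(width = 128, height = 128, mpp = 0.5,
                     counts = c(CB = 2, NFT = 1, TA = 0, TF = 3, non_tau = 1),
                     nuclei = 3, seed = 77)
  tile <- generate_tile(spec)
  st <- channel_stack(tile$rgb, 0.5)
  objs <- detect_objects(st$dab, mpp = 0.5)
  feats <- extract_features(objs, st)
  expect_identical(setdiff(names(feats), c("object_id", "tile_id",
                                           "region_group")),
                   feature_names())
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(feats[, feature_names()], path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(as.matrix(back), as.matrix(feats[, feature_names()]),
               tolerance = 1e-12)
})
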
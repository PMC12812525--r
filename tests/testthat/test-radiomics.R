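# The 366-descriptor radiomics pool: shape, first-order and texture
# features, the auditable manifest, and the assembly contract.

test_that("manifest counts: 366 = 14 shape + 4 x (18 + 70)", {
  man <- radiomic_manifest()
  expect_identical(nrow(man), 366L)
  expect_identical(sum(man$family == "shape"), 14L)
  expect_identical(sum(man$family == "first_order"), 72L)
  expect_identical(sum(man$family == "second_order"), 280L)
  expect_true(all(man$source_sequence[man$family == "shape"] == "T1CE"))
  for (s in c("T1", "T1CE", "T2", "FLAIR")) {
    expect_identical(sum(man$family == "first_order" &
                           man$source_sequence == s), 18L)
    expect_identical(sum(man$family == "second_order" &
                           man$source_sequence == s), 70L)
  }
  expect_false(any(duplicated(man$feature)))
})

test_that("shape features: cube volume, sphericity ordering, 14 names", {
  g <- array(0L, c(14, 14, 14)); g[3:12, 3:12, 3:12] <- 1L  # 10^3 cube
  sh <- extract_shape(gtv_mask(g, c(1, 1, 1)))
  expect_length(sh, 14)
  expect_lt(abs(sh[["volume"]] - 1000) / 1000, 0.02)
  expect_equal(sh[["maximum_3d_diameter"]], sqrt(3 * 81), tolerance = 1e-8)

  # rasterized ball vs an equal-volume elongated box
  gb <- array(0L, c(24, 24, 24))
  cc <- 12.5
  for (x in 1:24) for (y in 1:24) for (z in 1:24)
    if ((x - cc)^2 + (y - cc)^2 + (z - cc)^2 <= 81) gb[x, y, z] <- 1L
  ball <- extract_shape(gtv_mask(gb, c(1, 1, 1)))
  vol_ball <- sum(gb)
  side <- round(sqrt(vol_ball / 30))
  gx <- array(0L, c(40, 20, 20))  # generous padding around the box
  gx[6:35, 6:(5 + side), 6:(5 + side)] <- 1L
  box <- extract_shape(gtv_mask(gx, c(1, 1, 1)))
  expect_gt(ball[["sphericity"]], box[["sphericity"]])
  expect_gt(box[["elongation"]], ball[["elongation"]] - 1)  # defined
  expect_error(extract_shape(gtv_mask(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "empty ROI")
})

test_that("first-order features match straight formulas (oracle)", {
  # degenerate constant ROI
  g <- array(0L, c(4, 4, 4)); g[1:2, 1:2, 1:2] <- 1L
  img <- intensity_volume(array(7, c(4, 4, 4)), c(1, 1, 1), "T1")
  fo <- extract_first_order(img, gtv_mask(g, c(1, 1, 1)))
  expect_length(fo, 18)
  expect_equal(fo[["mean"]], 7)
  expect_equal(fo[["variance"]], 0)
  expect_equal(fo[["entropy"]], 0)
  expect_equal(fo[["uniformity"]], 1)

  # hand-listed 8-voxel ROI {1,1,2,2,3,3,4,4}
  arr <- array(0, c(4, 4, 4))
  arr[1:2, 1:2, 1:2] <- c(1, 1, 2, 2, 3, 3, 4, 4)
  img2 <- intensity_volume(arr, c(1, 1, 1), "T1")
  fo2 <- extract_first_order(img2, gtv_mask(g, c(1, 1, 1)))
  expect_equal(fo2[["mean"]], 2.5)
  expect_equal(fo2[["range"]], 3)

  # random ROI against independent straight-formula computations
  t <- toy_image_roi()
  fo3 <- extract_first_order(t$image, t$gtv,
                             discretization_config(value = 16))
  v <- t$image$grid[t$gtv$grid > 0]
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  expect_equal(fo3[["energy"]], sum(v^2), tolerance = 1e-12)
  expect_equal(fo3[["mean"]], mu, tolerance = 1e-12)
  expect_equal(fo3[["variance"]], m2, tolerance = 1e-12)
  expect_equal(fo3[["skewness"]], (sum((v - mu)^3) / n) / m2^1.5,
               tolerance = 1e-12)
  expect_equal(fo3[["kurtosis"]], (sum((v - mu)^4) / n) / m2^2,
               tolerance = 1e-12)
  expect_equal(fo3[["root_mean_squared"]], sqrt(sum(v^2) / n),
               tolerance = 1e-12)
  expect_equal(fo3[["mean_absolute_deviation"]], sum(abs(v - mu)) / n,
               tolerance = 1e-12)
  # histogram entropy/uniformity oracle on 16 bins
  lev <- pmin(floor(16 * (v - min(v)) / (max(v) - min(v))) + 1, 16)
  p <- as.vector(table(lev)) / n
  expect_equal(fo3[["entropy"]], -sum(p * log2(p)), tolerance = 1e-12)
  expect_equal(fo3[["uniformity"]], sum(p^2), tolerance = 1e-12)
})

test_that("co-occurrence counts match a hand-counted toy matrix", {
  # 3x3x1 toy, distance 1, direction (1,0,0)
  arr <- array(c(1, 2, 3,
                 1, 1, 2,
                 2, 3, 3), c(3, 3, 1))
  img <- array(as.integer(arr), c(3, 3, 1))
  mask <- array(1L, c(3, 3, 1))
  counts <- gliomap:::cpp_glcm(img, mask, c(3L, 3L, 1L), 3L)
  counts <- array(counts, c(3, 3, 13))
  M <- counts[, , 1]  # direction (1,0,0): pairs along x within each column
  oracle <- matrix(0, 3, 3)
  for (y in 1:3) for (x in 1:2) {
    a <- arr[x, y, 1]; b <- arr[x + 1, y, 1]
    oracle[a, b] <- oracle[a, b] + 1
  }
  expect_identical(M, oracle)
})

test_that("checkerboard maximizes contrast and minimizes homogeneity", {
  sh <- c(8, 8, 8)
  idx <- .coords <- expand.grid(x = 1:8, y = 1:8, z = 1:8)
  checker <- array(as.numeric((idx$x + idx$y + idx$z) %% 2), sh)
  smooth <- array(rep(seq(0, 1, length.out = 8), each = 1), sh)
  set.seed(2)
  noisy <- array(runif(prod(sh)), sh)
  gtv <- gtv_mask(array(1L, sh), c(1, 1, 1))
  disc <- discretization_config(value = 2)
  f_check <- extract_second_order(intensity_volume(checker, c(1, 1, 1), "T1"),
                                  gtv, disc)
  f_smooth <- extract_second_order(intensity_volume(smooth, c(1, 1, 1), "T1"),
                                   gtv, disc)
  f_noisy <- extract_second_order(intensity_volume(noisy, c(1, 1, 1), "T1"),
                                  gtv, disc)
  expect_gt(f_check[["glcm_contrast"]], f_smooth[["glcm_contrast"]])
  expect_gt(f_check[["glcm_contrast"]], f_noisy[["glcm_contrast"]])
  expect_lt(f_check[["glcm_idm"]], f_smooth[["glcm_idm"]])
  expect_lt(f_check[["glcm_idm"]], f_noisy[["glcm_idm"]])
})

test_that("second-order vector has exactly the 70 manifest names", {
  t <- toy_image_roi()
  so <- extract_second_order(t$image, t$gtv)
  expect_length(so, 70)
  man <- radiomic_manifest()
  expected <- sub("^T1_", "", man$feature[man$family == "second_order" &
                                            man$source_sequence == "T1"])
  expect_identical(names(so), expected)
})

test_that("assembled row is length 366 and deterministic in the image", {
  t <- toy_image_roi()
  seqs <- list(T1 = t$image,
               T1CE = intensity_volume(t$image$grid, c(1, 1, 1), "T1CE"),
               T2 = intensity_volume(t$image$grid * 2 + 5, c(1, 1, 1), "T2"),
               FLAIR = intensity_volume(sqrt(abs(t$image$grid)), c(1, 1, 1),
                                        "FLAIR"))
  row <- assemble_feature_table(seqs, t$gtv)
  expect_length(row, 366)
  expect_identical(names(row), radiomic_manifest()$feature)
  # identical images under different sequence names give identical blocks
  b1 <- row[grep("^T1_", names(row))]
  b2 <- row[grep("^T1CE_", names(row))]
  expect_equal(unname(b1), unname(b2), tolerance = 1e-12)
  expect_error(assemble_feature_table(seqs[c("T1", "T2")], t$gtv),
               "missing sequence")
})

test_that("intensity shift moves the mean only; texture is shift-invariant", {
  t <- toy_image_roi()
  shifted <- intensity_volume(t$image$grid + 37.5, c(1, 1, 1), "T1")
  fo1 <- extract_first_order(t$image, t$gtv)
  fo2 <- extract_first_order(shifted, t$gtv)
  expect_equal(fo2[["mean"]], fo1[["mean"]] + 37.5, tolerance = 1e-10)
  expect_equal(fo2[["variance"]], fo1[["variance"]], tolerance = 1e-10)
  so1 <- extract_second_order(t$image, t$gtv)
  so2 <- extract_second_order(shifted, t$gtv)
  expect_equal(unname(so1), unname(so2), tolerance = 1e-9)
})

test_that("direction-averaged texture is invariant to 90-degree rotation", {
  t <- toy_image_roi()
  rot_grid <- aperm(t$image$grid, c(2, 1, 3))[dim(t$image$grid)[2]:1, , ]
  rot_gtv <- aperm(t$gtv$grid, c(2, 1, 3))[dim(t$gtv$grid)[2]:1, , ]
  so1 <- extract_second_order(t$image, t$gtv)
  so2 <- extract_second_order(intensity_volume(rot_grid, c(1, 1, 1), "T1"),
                              gtv_mask(rot_gtv, c(1, 1, 1)))
  expect_equal(unname(so1), unname(so2), tolerance = 1e-6)
})

test_that("first-order features are invariant to voxel order in the ROI", {
  t <- toy_image_roi()
  g <- t$image$grid
  roi <- which(t$gtv$grid > 0)
  set.seed(8)
  g[roi] <- g[roi][sample(length(roi))]
  fo1 <- extract_first_order(t$image, t$gtv)
  fo2 <- extract_first_order(intensity_volume(g, c(1, 1, 1), "T1"), t$gtv)
  expect_equal(fo1, fo2, tolerance = 1e-12)
})
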
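# Generators: parcellated atlas, deformations, tumors, intensities,
# segmenter corruption and ML cohorts.

test_that("atlas has 32 labels, mirror symmetry and is deterministic", {
  atlas <- fix_atlas()
  present <- setdiff(unique(as.vector(atlas$grid)), 0L)
  expect_length(present, 32)
  expect_setequal(present, 1:32)

  # reflecting across the mid-sagittal plane maps left labels to right
  g <- atlas$grid
  refl <- g[dim(g)[1]:1, , ]
  pairs <- mirror_pairs()
  map <- integer(33)
  map[pairs[, "left"] + 1L] <- pairs[, "right"]
  map[pairs[, "right"] + 1L] <- pairs[, "left"]
  map[c(15:18) + 1L] <- 15:18  # midline structures map to themselves
  paired <- g %in% c(pairs) | g %in% 15:18
  agree <- map[g[paired] + 1L] == refl[paired]
  expect_gt(mean(agree), 0.95)

  again <- make_atlas_labels(c(48, 48, 48), c(3, 3, 3), seed = 4)
  expect_identical(atlas$grid, again$grid)
  expect_error(make_atlas_labels(c(16, 48, 48)), "32 structures")
})

test_that("brain foreground is a single connected component", {
  atlas <- fix_atlas()
  shape <- dim(atlas$grid)
  n <- gliomap:::cpp_n_components(array(as.integer(atlas$grid > 0), shape),
                                  shape)
  expect_identical(n, 1L)
})

test_that("zero-amplitude deformation is the identity with identity inverse", {
  f <- sample_deformation(c(32, 32, 32), c(3, 3, 3), amplitude = 0,
                          smoothness = 10, seed = 1)
  expect_equal(max(abs(f$disp)), 0)
  expect_equal(max(abs(f$inverse)), 0)
})

test_that("pure translation has the exact analytic inverse", {
  f <- sample_deformation(c(32, 32, 32), c(3, 3, 3), amplitude = 0,
                          smoothness = 10, translation = c(2, 0, 0))
  expect_equal(unique(as.vector(f$disp[, , , 1])), 2)
  expect_equal(unique(round(as.vector(f$inverse[, , , 1]), 8)), -2)
  expect_equal(max(abs(f$inverse[, , , 2:3])), 0)
})

test_that("forward-then-inverse residual is sub-voxel for 3 mm fields", {
  sh <- c(48, 48, 48); sp <- c(3, 3, 3)
  f <- sample_deformation(sh, sp, amplitude = 3, smoothness = 10, seed = 9)
  comp <- gliomap:::cpp_compose_disp(f$disp, f$inverse, sh, sp)
  mag <- sqrt(comp[, , , 1]^2 + comp[, , , 2]^2 + comp[, , , 3]^2) / min(sp)
  expect_lt(as.numeric(quantile(mag, 0.99)), 0.5)
  # positive Jacobian everywhere by construction
  jd <- gliomap:::cpp_jacobian_det(f$disp, sh, sp)
  expect_gt(min(jd), 0)
})

test_that("over-aggressive deformation amplitudes are rejected", {
  expect_error(sample_deformation(c(32, 32, 32), c(3, 3, 3), amplitude = 20,
                                  smoothness = 10, seed = 1),
               "diffeomorphism|Jacobian")
})

test_that("tumor implantation: degenerate, containment, analytic volume", {
  atlas <- fix_atlas()
  cen <- round(dim(atlas$grid) / 2)
  expect_equal(sum(implant_tumor(atlas, cen, c(0, 0, 0))$grid), 0)

  gtv <- implant_tumor(atlas, cen, c(12, 14, 10), edema_margin = 6, seed = 3)
  # necrotic voxels are 26-surrounded only by necrotic or enhancing voxels
  g <- gtv$grid
  nec <- which(g == 2L, arr.ind = TRUE)
  ok <- TRUE
  for (r in seq_len(nrow(nec))) {
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      v <- nec[r, ] + c(dx, dy, dz)
      if (any(v < 1) || any(v > dim(g))) next
      if (!(g[v[1], v[2], v[3]] %in% c(1L, 2L))) ok <- FALSE
    }
  }
  expect_true(ok)

  # unperturbed interior core matches the analytic ellipsoid volume +/- 20%
  gtv0 <- implant_tumor(atlas, cen, c(12, 14, 10), edema_margin = 0,
                        perturb = 0)
  analytic <- 4 / 3 * pi * 12 * 14 * 10 / prod(atlas$spacing)
  expect_lt(abs(sum(gtv0$grid > 0) - analytic) / analytic, 0.2)

  expect_error(implant_tumor(atlas, c(1, 1, 1), c(5, 5, 5)),
               "inside the brain")
})

test_that("gtv union is spatially connected", {
  s <- fix_subject()
  shape <- dim(s$gtv$grid)
  n <- gliomap:::cpp_n_components(array(as.integer(s$gtv$grid > 0), shape),
                                  shape)
  expect_identical(n, 1L)
})

test_that("noise-free intensity limit is piecewise constant at class means", {
  atlas <- fix_atlas()
  gtv <- implant_tumor(atlas, round(dim(atlas$grid) / 2), c(10, 10, 10),
                       seed = 2)
  p <- generative_params(sd_range = c(0, 0), bias_amplitude = 0,
                         gamma_range = c(1, 1), blur_sigma_mm = c(0, 0),
                         downsample_range = c(1, 1), seed = 5)
  img <- synthesize_intensities(atlas, gtv, p, "T1")
  cls <- atlas$grid
  cls[gtv$grid > 0L] <- 32L + gtv$grid[gtv$grid > 0L]
  for (id in sample(setdiff(unique(as.vector(cls)), 0L), 5)) {
    vals <- unique(round(img$grid[cls == id], 10))
    expect_length(vals, 1)
  }
  expect_equal(unique(as.vector(img$grid[cls == 0L])), 0)
})

test_that("class sample means obey the CLT bound and draws are reproducible", {
  atlas <- fix_atlas()
  gtv <- implant_tumor(atlas, round(dim(atlas$grid) / 2), c(10, 10, 10),
                       seed = 2)
  p <- generative_params(sd_range = c(8, 8), bias_amplitude = 0,
                         gamma_range = c(1, 1), blur_sigma_mm = c(0, 0),
                         downsample_range = c(1, 1), seed = 6)
  img <- synthesize_intensities(atlas, gtv, p, "T2")
  p0 <- generative_params(sd_range = c(0, 0), bias_amplitude = 0,
                          gamma_range = c(1, 1), blur_sigma_mm = c(0, 0),
                          downsample_range = c(1, 1), seed = 6)
  means <- synthesize_intensities(atlas, gtv, p0, "T2")
  cls <- atlas$grid
  cls[gtv$grid > 0L] <- 32L + gtv$grid[gtv$grid > 0L]
  counts <- table(cls[cls > 0])
  big <- as.integer(names(counts)[counts >= 1000])
  for (id in head(big, 5)) {
    n <- sum(cls == id)
    drawn_mean <- unique(round(means$grid[cls == id], 8))[1]
    expect_lt(abs(mean(img$grid[cls == id]) - drawn_mean), 4 * 8 / sqrt(n))
  }
  img2 <- synthesize_intensities(atlas, gtv, p, "T2")
  expect_identical(img$grid, img2$grid)
})

test_that("corruption is confined to the GTV halo and strong inside the GTV", {
  s <- fix_subject()
  truth <- s$truth_labels
  gtv <- s$gtv
  shape <- dim(truth$grid)

  empty <- gtv_mask(array(0L, shape), truth$spacing)
  expect_identical(corrupt_parcellation(truth, empty, seed = 1)$grid,
                   truth$grid)

  cor <- corrupt_parcellation(truth, gtv, halo = 6, seed = 1)
  halo_region <- array(gliomap:::cpp_dilate(
    array(as.integer(gtv$grid > 0), shape), shape, 6 / truth$spacing),
    shape) > 0
  expect_identical(cor$grid[!halo_region], truth$grid[!halo_region])

  ing <- gtv$grid > 0
  expect_gte(mean(cor$grid[ing] != truth$grid[ing]), 0.5)
})

test_that("ml cohort: null AUROC, planted features rank top, exact balance", {
  null_tab <- make_ml_cohort(500, 16, 16, 5, effect_size = 0, seed = 21)
  X <- as.matrix(null_tab[, setdiff(names(null_tab),
                                    c("subject_id", "label"))])
  aucs <- apply(X, 2, function(col)
    gliomap:::.auroc(col, null_tab$label))
  expect_true(all(abs(aucs - 0.5) < 0.1))

  tab <- make_ml_cohort(500, 16, 16, 5, effect_size = 3, seed = 22)
  X <- as.matrix(tab[, setdiff(names(tab), c("subject_id", "label"))])
  aucs <- apply(X, 2, function(col) gliomap:::.auroc(col, tab$label))
  top10 <- names(sort(aucs, decreasing = TRUE))[1:10]
  expect_true(all(attr(tab, "informative") %in% top10))

  bal <- make_ml_cohort(100, 8, 0, 2, 1, class_balance = 0.5, seed = 23)
  expect_identical(sum(bal$label), 50L)
  expect_error(make_ml_cohort(10, 4, 0, 1, 1, class_balance = 0.001),
               "infeasible")
})

test_that("generators are bit-identical across repeated calls", {
  a1 <- make_atlas_labels(c(32, 32, 32), c(3, 3, 3), seed = 7)
  a2 <- make_atlas_labels(c(32, 32, 32), c(3, 3, 3), seed = 7)
  expect_identical(a1$grid, a2$grid)
  f1 <- sample_deformation(c(32, 32, 32), c(3, 3, 3), 3, 10, seed = 7)
  f2 <- sample_deformation(c(32, 32, 32), c(3, 3, 3), 3, 10, seed = 7)
  expect_identical(f1$disp, f2$disp)
  t1 <- make_ml_cohort(50, 8, 8, 3, 2, seed = 7)
  t2 <- make_ml_cohort(50, 8, 8, 3, 2, seed = 7)
  expect_identical(t1, t2)
})
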
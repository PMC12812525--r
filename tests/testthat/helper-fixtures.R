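# Shared fixtures, built once per test run and memoized. Small grids (48^3)
# keep unit tests fast; the acceptance suite builds its own 64^3 cohort.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

fix_atlas <- function() memo("atlas", make_atlas_labels(c(48, 48, 48),
                                                        c(3, 3, 3), seed = 4))

fix_subject <- function() memo("subject",
                               make_phantom_subject(fix_atlas(), seed = 11,
                                                    radii_range = c(10, 16)))

fix_case <- function() memo("case", {
  s <- fix_subject()
  fill_tumor_labels(s$corrupted_labels, fix_atlas(), s$gtv)
})

# tiny handmade label volume on a unit grid
toy_labels <- function(shape = c(6, 6, 6), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  dict <- canonical_labels()
  label_volume(array(sample(0:32, prod(shape), replace = TRUE), shape),
               spacing, dict)
}

toy_gtv <- function(shape = c(6, 6, 6), spacing = c(1, 1, 1), seed = 2) {
  set.seed(seed)
  gtv_mask(array(sample(0:3, prod(shape), replace = TRUE, prob = c(.6, .2, .1, .1)),
                 shape), spacing)
}

# small intensity volume with a compact ROI for radiomics tests
toy_image_roi <- function(shape = c(10, 10, 10), seed = 3) {
  set.seed(seed)
  img <- intensity_volume(array(rnorm(prod(shape), 100, 20), shape),
                          c(1, 1, 1), "T1")
  g <- array(0L, shape)
  g[3:8, 3:8, 3:8] <- 1L
  list(image = img, gtv = gtv_mask(g, c(1, 1, 1)))
}

# Macro-averaged per-structure Dice restricted to the GTV. Structures enter
# the mean only with at least `min_support` ground-truth voxels inside the
# GTV: one- or few-voxel slivers cannot be meaningfully scored by Dice and
# are excluded, as is standard in segmentation evaluation.
mean_dice_in_gtv <- function(pred, truth, gtv, min_support = 10) {
  ing <- gtv$grid > 0
  tt <- table(truth$grid[ing][truth$grid[ing] > 0])
  ids <- as.integer(names(tt)[tt >= min_support])
  mean(vapply(ids, function(l) {
    a <- pred$grid[ing] == l
    b <- truth$grid[ing] == l
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1)))
}
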
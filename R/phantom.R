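# Synthetic inputs: parcellated brains, implanted tumors, smooth invertible
# deformations, label-conditioned GMM intensities, simulated segmenter
# failures, and planted-signal ML cohorts. Every generator is deterministic
# given its seed and draws from its own named stream.

.coord_grids <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  list(
    x = array(rep(seq_len(nx) - 1L, times = ny * nz), dim = shape),
    y = array(rep(rep(seq_len(ny) - 1L, each = nx), times = nz), dim = shape),
    z = array(rep(seq_len(nz) - 1L, each = nx * ny), dim = shape)
  )
}

#' Generate a synthetic parcellated brain atlas
#'
#' Builds an ellipsoidal brain partitioned into the canonical 32 structures:
#' a CSF shell, three midline structures (3rd ventricle, 4th ventricle,
#' brain-stem) straddling the mid-sagittal plane, and 14 structure pairs
#' mirrored left/right via a seeded Voronoi partition of one hemisphere.
#' Geometry is schematic; only the topology (32 named, paired, contiguous
#' structures) matters for exercising the parcellation-repair method.
#'
#' @param shape Voxel counts per axis (each >= 32).
#' @param spacing Voxel size in mm (default 3 mm isotropic, spanning an
#'   adult-head-sized field of view at 64^3).
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return A [label_volume()] with all 32 canonical labels present.
#' @export
make_atlas_labels <- function(shape = c(64, 64, 64), spacing = c(3, 3, 3),
                              seed = 1) {
  shape <- as.integer(shape)
  if (any(shape < 32))
    stop("shape too small to host 32 structures: each axis must be >= 32")
  g <- .coord_grids(shape)
  c0 <- (shape - 1) / 2
  semi <- c(0.42, 0.46, 0.40) * shape  # voxel semi-axes
  ex <- (g$x - c0[1]) / semi[1]
  ey <- (g$y - c0[2]) / semi[2]
  ez <- (g$z - c0[3]) / semi[3]
  r <- sqrt(ex^2 + ey^2 + ez^2)
  brain <- r <= 1

  lab <- array(0L, dim = shape)
  csf <- brain & r > 0.90
  lab[csf] <- 15L

  ell <- function(cen_frac, rad_frac) {
    cen <- c0 + cen_frac * shape
    rad <- pmax(rad_frac * shape, 1.6)
    ((g$x - cen[1]) / rad[1])^2 + ((g$y - cen[2]) / rad[2])^2 +
      ((g$z - cen[3]) / rad[3])^2 <= 1
  }
  v3 <- ell(c(0, -0.02, 0.02), c(0.030, 0.060, 0.060))   # 3rd ventricle
  v4 <- ell(c(0, 0.10, -0.12), c(0.030, 0.050, 0.050))   # 4th ventricle
  bs <- ell(c(0, 0.14, -0.26), c(0.050, 0.060, 0.110))   # brain-stem
  lab[brain & !csf & v3] <- 16L
  lab[brain & !csf & v4 & lab == 0L] <- 17L
  lab[brain & !csf & bs & lab == 0L] <- 18L

  interior <- brain & lab == 0L
  seeds <- with_stream(seed, "atlas_seeds", {
    # 14 seed points in the right hemisphere interior, physical coords
    pts <- matrix(NA_real_, 14, 3)
    k <- 0; tries <- 0
    while (k < 14 && tries < 10000) {
      tries <- tries + 1
      p <- c(runif(1, c0[1] + 0.06 * shape[1], c0[1] + 0.85 * semi[1]),
             runif(1, c0[2] - 0.85 * semi[2], c0[2] + 0.85 * semi[2]),
             runif(1, c0[3] - 0.85 * semi[3], c0[3] + 0.85 * semi[3]))
      v <- round(p) + 1
      if (all(v >= 1) && all(v <= shape) && interior[v[1], v[2], v[3]]) {
        k <- k + 1
        pts[k, ] <- p
      }
    }
    if (k < 14) stop("could not place 14 hemisphere seeds; enlarge shape")
    pts
  })

  idx <- which(interior)
  xs <- g$x[idx]; ys <- g$y[idx]; zs <- g$z[idx]
  right <- xs > c0[1]
  xm <- ifelse(right, xs, 2 * c0[1] - xs)  # mirror left voxels to the right
  d2 <- matrix(0, length(idx), 14)
  for (k in 1:14)
    d2[, k] <- ((xm - seeds[k, 1]) * spacing[1])^2 +
      ((ys - seeds[k, 2]) * spacing[2])^2 +
      ((zs - seeds[k, 3]) * spacing[3])^2
  nearest <- max.col(-d2, ties.method = "first")
  lab[idx] <- ifelse(right, nearest + 18L, nearest)

  vol <- label_volume(lab, spacing)
  present <- setdiff(unique(as.vector(lab)), 0L)
  if (length(present) != 32)
    stop("atlas generation yielded ", length(present), " labels, expected 32")
  vol
}

#' Sample a smooth invertible deformation field
#'
#' Gaussian-smoothed white noise scaled to the requested peak amplitude,
#' plus an optional small affine (rotation + translation) part. The field is
#' rejected if its Jacobian determinant is not strictly positive everywhere;
#' the fixed-point inverse is computed and stored.
#'
#' @param shape Voxel counts per axis.
#' @param spacing Voxel size (mm).
#' @param amplitude Peak non-linear displacement magnitude (mm).
#' @param smoothness Gaussian smoothing length of the noise (mm); must be
#'   comfortably larger than `amplitude` to preserve diffeomorphism.
#' @param seed Integer seed.
#' @param translation Optional fixed translation (mm 3-vector); when given
#'   with `rotation_deg = 0` and `amplitude = 0` the field is a pure
#'   translation with an exact analytic inverse.
#' @param rotation_deg Optional fixed rotation angle about the z axis
#'   (degrees) applied about the grid centre. `NULL` draws a small random
#'   rotation scaled with `amplitude`.
#' @return A [deformation_field()] with its inverse stored.
#' @export
sample_deformation <- function(shape, spacing, amplitude, smoothness, seed = 1,
                               translation = NULL, rotation_deg = NULL) {
  shape <- as.integer(shape)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude > 0 && amplitude > 0.6 * smoothness)
    stop("amplitude ", amplitude, " mm too large for smoothness ", smoothness,
         " mm; diffeomorphism not guaranteed")
  n <- prod(shape)
  dim4 <- c(shape, 3L)
  u <- array(0, dim = dim4)
  if (amplitude > 0) {
    noise <- with_stream(seed, "deformation_noise",
                         array(rnorm(3 * n), dim = dim4))
    sm <- cpp_gaussian_smooth(noise, shape, smoothness / spacing)
    sm <- array(sm, dim = dim4)
    mag <- sqrt(sm[, , , 1]^2 + sm[, , , 2]^2 + sm[, , , 3]^2)
    if (max(mag) > 0) sm <- sm * (amplitude / max(mag))
    u <- sm
  }
  if (is.null(rotation_deg))
    rotation_deg <- if (amplitude > 0)
      with_stream(seed, "deformation_affine", runif(1, -1, 1)) *
        amplitude / 10 else 0
  if (is.null(translation)) translation <- c(0, 0, 0)
  if (rotation_deg != 0 || any(translation != 0)) {
    th <- rotation_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    g <- .coord_grids(shape)
    cen <- (shape - 1) / 2 * spacing
    px <- g$x * spacing[1] - cen[1]
    py <- g$y * spacing[2] - cen[2]
    pz <- g$z * spacing[3] - cen[3]
    u[, , , 1] <- u[, , , 1] + (R[1, 1] * px + R[1, 2] * py + R[1, 3] * pz) -
      px + translation[1]
    u[, , , 2] <- u[, , , 2] + (R[2, 1] * px + R[2, 2] * py + R[2, 3] * pz) -
      py + translation[2]
    u[, , , 3] <- u[, , , 3] + (R[3, 1] * px + R[3, 2] * py + R[3, 3] * pz) -
      pz + translation[3]
  }
  jd <- cpp_jacobian_det(u, shape, spacing)
  if (min(jd) <= 0)
    stop("deformation amplitude too large: Jacobian determinant reaches ",
         signif(min(jd), 3))
  inv <- cpp_invert_disp(u, shape, spacing, 50L, 0.02 * min(spacing))
  deformation_field(u, spacing, inverse = array(inv$inverse, dim = dim4))
}

#' Implant a multi-compartment tumor into a parcellated brain
#'
#' Nested perturbed ellipsoids: a necrotic/cystic core strictly inside an
#' enhancing rim, surrounded by an edema shell of width `edema_margin`.
#' The tumor is clipped to the brain foreground.
#'
#' @param labels A [label_volume()]; the brain foreground is `grid > 0`.
#' @param center Voxel triple (1-based) of the tumor centre; must lie inside
#'   the brain foreground.
#' @param radii Ellipsoid semi-axes of the tumor core in mm.
#' @param edema_margin Edema shell width in mm.
#' @param seed Integer seed for the boundary perturbation.
#' @param necrotic_frac Relative radius of the necrotic core (default 0.55).
#' @param perturb Relative amplitude of the smooth boundary perturbation
#'   (0 gives exact ellipsoids).
#' @return A [gtv_mask()] aligned with `labels`.
#' @export
implant_tumor <- function(labels, center, radii, edema_margin = 6, seed = 1,
                          necrotic_frac = 0.55, perturb = 0.25) {
  shape <- dim(labels$grid)
  spacing <- labels$spacing
  center <- as.integer(round(center))
  if (any(center < 1) || any(center > shape) ||
      labels$grid[center[1], center[2], center[3]] == 0L)
    stop("tumor center must lie inside the brain foreground")
  out <- array(0L, dim = shape)
  if (all(radii <= 0))
    return(gtv_mask(out, spacing))
  g <- .coord_grids(shape)
  dx <- (g$x - (center[1] - 1)) * spacing[1]
  dy <- (g$y - (center[2] - 1)) * spacing[2]
  dz <- (g$z - (center[3] - 1)) * spacing[3]
  radii <- pmax(radii, 1e-6)
  rcore <- sqrt((dx / radii[1])^2 + (dy / radii[2])^2 + (dz / radii[3])^2)
  re <- radii + edema_margin
  redema <- sqrt((dx / re[1])^2 + (dy / re[2])^2 + (dz / re[3])^2)
  eff <- 1
  if (perturb > 0) {
    noise <- with_stream(seed, "tumor_perturb", array(rnorm(prod(shape)), shape))
    sm <- array(cpp_gaussian_smooth(noise, shape,
                                    pmax(max(radii) / 2 / spacing, 1)), shape)
    if (max(abs(sm)) > 0) sm <- sm / max(abs(sm))
    eff <- 1 + perturb * sm
  }
  core <- rcore <= eff
  necro <- rcore <= necrotic_frac * eff
  edema <- redema <= eff & !core
  out[edema] <- 3L
  out[core] <- 1L
  out[necro] <- 2L
  out[labels$grid == 0L] <- 0L
  gtv_mask(out, spacing)
}

#' Parameters of the label-conditioned intensity model
#'
#' The generative model samples, per (anatomy or tumor sub-label) class, a
#' Gaussian mean and standard deviation from uniform ranges, then corrupts
#' the image with a smooth multiplicative bias field, a random gamma
#' transform, Gaussian blurring (slice thickness) and down/up-sampling
#' (slice spacing).
#'
#' @param mean_range,sd_range Uniform ranges for class means / sds
#'   (arbitrary MR units).
#' @param bias_amplitude Log-amplitude of the multiplicative bias field.
#' @param bias_smoothness_mm Smoothing length of the bias field (mm).
#' @param gamma_range Range of the gamma exponent (> 0).
#' @param blur_sigma_mm Range of the blurring sigma (mm).
#' @param downsample_range Range of the isotropic downsampling factor (>= 1).
#' @param seed Integer seed.
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(mean_range = c(20, 230), sd_range = c(2, 12),
                              bias_amplitude = 0.3, bias_smoothness_mm = 40,
                              gamma_range = c(0.75, 1.33),
                              blur_sigma_mm = c(0, 1.5),
                              downsample_range = c(1, 1.8), seed = 1) {
  stopifnot(diff(range(mean_range)) >= 0, all(sd_range >= 0),
            bias_amplitude >= 0, bias_smoothness_mm > 0,
            all(gamma_range > 0), all(blur_sigma_mm >= 0),
            all(downsample_range >= 1))
  structure(list(mean_range = mean_range, sd_range = sd_range,
                 bias_amplitude = bias_amplitude,
                 bias_smoothness_mm = bias_smoothness_mm,
                 gamma_range = gamma_range, blur_sigma_mm = blur_sigma_mm,
                 downsample_range = downsample_range, seed = seed),
            class = "generative_params")
}

#' Synthesize an MRI sequence from labels and a tumor mask
#'
#' Voxel intensities are sampled i.i.d. from a Gaussian mixture conditioned
#' on the anatomical label, with tumor sub-labels acting as three extra
#' classes so that tumors are visible in the synthetic sequences. The image
#' is then corrupted by a smooth positive bias field, a gamma transform,
#' Gaussian blurring, and downsampling followed by linear resampling back to
#' the target grid. Deterministic given `params$seed` and `sequence_name`.
#'
#' @param labels A [label_volume()].
#' @param gtv A [gtv_mask()] aligned with `labels` (may be empty).
#' @param params A [generative_params()] object.
#' @param sequence_name One of "T1", "T1CE", "T2", "FLAIR"; each sequence
#'   draws its own class means/variances.
#' @return An [intensity_volume()].
#' @export
synthesize_intensities <- function(labels, gtv, params,
                                   sequence_name = c("T1", "T1CE", "T2",
                                                     "FLAIR")) {
  sequence_name <- match.arg(sequence_name)
  .same_geometry(labels, gtv)
  stopifnot(inherits(params, "generative_params"))
  shape <- dim(labels$grid)
  spacing <- labels$spacing
  cls <- labels$grid
  cls[gtv$grid > 0L] <- 32L + gtv$grid[gtv$grid > 0L]
  ids <- setdiff(sort(unique(as.vector(cls))), 0L)
  tag <- paste0("intensity_", sequence_name)
  img <- with_stream(params$seed, tag, {
    mu <- runif(length(ids), params$mean_range[1], params$mean_range[2])
    sg <- runif(length(ids), params$sd_range[1], params$sd_range[2])
    gamma <- exp(runif(1, log(params$gamma_range[1]),
                       log(params$gamma_range[2])))
    blur <- runif(1, params$blur_sigma_mm[1], params$blur_sigma_mm[2])
    f <- runif(1, params$downsample_range[1], params$downsample_range[2])
    look_mu <- numeric(max(ids) + 1)
    look_sg <- numeric(max(ids) + 1)
    look_mu[ids + 1] <- mu
    look_sg[ids + 1] <- sg
    im <- array(look_mu[cls + 1L] + look_sg[cls + 1L] * rnorm(prod(shape)),
                dim = shape)
    im[cls == 0L] <- 0
    if (params$bias_amplitude > 0) {
      bn <- array(rnorm(prod(shape)), shape)
      bs <- array(cpp_gaussian_smooth(bn, shape,
                                      params$bias_smoothness_mm / spacing),
                  shape)
      if (max(abs(bs)) > 0) bs <- bs / max(abs(bs))
      im <- im * exp(params$bias_amplitude * bs)
    }
    if (gamma != 1) {
      lo <- min(im); hi <- max(im)
      if (hi > lo) im <- lo + (hi - lo) * (((im - lo) / (hi - lo))^gamma)
    }
    if (blur > 0)
      im <- array(cpp_gaussian_smooth(im, shape, rep(blur, 3) / spacing),
                  shape)
    if (f > 1) {
      small <- pmax(as.integer(round(shape / f)), 2L)
      dn <- cpp_resample_lin(im, shape, small)
      im <- array(cpp_resample_lin(dn, small, shape), shape)
    }
    im
  })
  intensity_volume(img, spacing, sequence_name)
}

#' Simulate segmenter failure on and around the tumor
#'
#' Reproduces the characteristic failure of whole-brain segmenters on
#' glioma: inside the GTV plus a halo, labels are randomly reassigned among
#' CSF, the cortical/white-matter labels of the affected hemisphere, and
#' background. Voxels outside the halo are bitwise unchanged.
#'
#' @param truth A [label_volume()] ground-truth parcellation.
#' @param gtv A [gtv_mask()] aligned with `truth`.
#' @param halo Corruption halo width around the GTV (mm).
#' @param seed Integer seed.
#' @param strength Per-voxel probability of reassignment inside the halo.
#' @return A corrupted [label_volume()].
#' @export
corrupt_parcellation <- function(truth, gtv, halo = 6, seed = 1,
                                 strength = 0.9) {
  .same_geometry(truth, gtv)
  shape <- dim(truth$grid)
  out <- truth$grid
  inside <- gtv$grid > 0L
  if (!any(inside)) return(label_volume(out, truth$spacing, truth$label_dict))
  region <- if (halo > 0) {
    array(cpp_dilate(array(as.integer(inside), shape), shape,
                     halo / truth$spacing), shape) > 0
  } else inside
  cen <- colMeans(which(inside, arr.ind = TRUE))
  left_side <- cen[1] < (shape[1] + 1) / 2
  pool <- c(15L, if (left_side) c(1L, 2L) else c(19L, 20L), 0L)
  idx <- which(region)
  with_stream(seed, "corrupt", {
    hit <- runif(length(idx)) < strength
    out[idx[hit]] <- sample(pool, sum(hit), replace = TRUE)
  })
  label_volume(out, truth$spacing, truth$label_dict)
}

#' Generate a complete phantom subject
#'
#' Bundles a ground-truth subject parcellation (the atlas warped by a known
#' random deformation), an implanted tumor, the simulated segmenter output,
#' optionally four synthetic MRI sequences, and the true deformation field.
#'
#' @param atlas A [make_atlas_labels()] volume (shared across subjects).
#' @param seed Integer seed; drives deformation, tumor and corruption draws.
#' @param amplitude,smoothness Deformation parameters (mm).
#' @param radii_range Range the three tumor core semi-axes are drawn from (mm).
#' @param edema_margin Edema shell width (mm).
#' @param halo Corruption halo (mm).
#' @param with_intensities Also synthesize the four MRI sequences.
#' @param params [generative_params()] used when `with_intensities = TRUE`.
#' @return An object of class `phantom_subject` with elements `truth_labels`,
#'   `corrupted_labels`, `gtv`, `sequences`, `true_field`, `metadata`.
#' @export
make_phantom_subject <- function(atlas, seed = 1, amplitude = 3,
                                 smoothness = 10,
                                 radii_range = c(12, 20), edema_margin = 6,
                                 halo = 6, with_intensities = FALSE,
                                 params = generative_params(seed = seed)) {
  shape <- dim(atlas$grid)
  spacing <- atlas$spacing
  field <- sample_deformation(shape, spacing, amplitude, smoothness,
                              seed = seed)
  truth_grid <- cpp_warp_nn(atlas$grid, shape, spacing, diag(3), c(0, 0, 0),
                            field$disp)
  truth <- label_volume(array(truth_grid, shape), spacing, atlas$label_dict)
  # pick an interior tumor centre: brain voxels at least max radius from edge
  radii <- with_stream(seed, "tumor_radii", runif(3, radii_range[1],
                                                  radii_range[2]))
  # interior candidates: smoothed brain indicator close to 1 keeps the
  # centre at least roughly one tumor radius away from the brain surface
  margin_vox <- (max(radii) + edema_margin) / spacing
  brain <- array(as.numeric(truth$grid > 0L), shape)
  interior <- array(cpp_gaussian_smooth(brain, shape, margin_vox / 2), shape)
  candidates <- which(truth$grid > 0L & interior > 0.99)
  if (!length(candidates))
    candidates <- which(truth$grid > 0L)
  cen_idx <- with_stream(seed, "tumor_center",
                         candidates[sample.int(length(candidates), 1)])
  center <- which(array(seq_len(prod(shape)), shape) == cen_idx,
                  arr.ind = TRUE)[1, ]
  gtv <- implant_tumor(truth, center, radii, edema_margin, seed = seed)
  corrupted <- corrupt_parcellation(truth, gtv, halo = halo, seed = seed)
  sequences <- NULL
  if (with_intensities)
    sequences <- lapply(stats::setNames(nm = c("T1", "T1CE", "T2", "FLAIR")),
                        function(s) synthesize_intensities(truth, gtv, params, s))
  structure(list(truth_labels = truth, corrupted_labels = corrupted,
                 gtv = gtv, sequences = sequences, true_field = field,
                 metadata = list(seed = seed, center = center, radii = radii,
                                 amplitude = amplitude,
                                 smoothness = smoothness)),
            class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat("phantom_subject (seed", x$metadata$seed, "):",
      paste(dim(x$truth_labels$grid), collapse = "x"), "voxels;",
      sum(x$gtv$grid > 0), "GTV voxels;",
      if (is.null(x$sequences)) "no intensities" else "4 sequences", "\n")
  invisible(x)
}

#' Generate a synthetic ML cohort with planted informative features
#'
#' Feature matrix of standard-normal noise in which `n_informative` randomly
#' chosen columns receive a class-conditional mean shift of `effect_size`
#' standard deviations; binary labels at the requested balance.
#'
#' @param n_subjects Number of rows.
#' @param n_spatial,n_radiomic Number of spatial / radiomic-style columns.
#' @param n_informative Number of planted informative features
#'   (<= n_spatial + n_radiomic).
#' @param effect_size Class-conditional mean shift in sd units.
#' @param class_balance Fraction of positive labels.
#' @param seed Integer seed.
#' @param dataset Dataset tag stored as an attribute.
#' @return A data.frame: `subject_id`, feature columns, `label`; attributes
#'   `informative` (planted column names) and `dataset`.
#' @export
make_ml_cohort <- function(n_subjects, n_spatial = 32, n_radiomic = 366,
                           n_informative = 5, effect_size = 1,
                           class_balance = 0.5, seed = 1,
                           dataset = "phantom") {
  p <- n_spatial + n_radiomic
  if (n_informative > p)
    stop("n_informative must be <= n_spatial + n_radiomic")
  n_pos <- round(n_subjects * class_balance)
  if (n_pos < 1 || n_pos > n_subjects - 1)
    stop("class_balance ", class_balance, " infeasible for n = ", n_subjects)
  cols <- c(sprintf("spatial_%02d", seq_len(n_spatial)),
            sprintf("radiomic_%03d", seq_len(n_radiomic)))
  tab <- with_stream(seed, "ml_cohort", {
    y <- integer(n_subjects)
    y[sample.int(n_subjects, n_pos)] <- 1L
    X <- matrix(rnorm(n_subjects * p), n_subjects, p,
                dimnames = list(NULL, cols))
    informative <- sort(sample.int(p, n_informative))
    for (j in informative) X[y == 1L, j] <- X[y == 1L, j] + effect_size
    list(X = X, y = y, informative = cols[informative])
  })
  out <- data.frame(subject_id = sprintf("subj_%04d", seq_len(n_subjects)),
                    tab$X, label = tab$y, check.names = FALSE)
  attr(out, "informative") <- tab$informative
  attr(out, "dataset") <- dataset
  out
}
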
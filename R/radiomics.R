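# IBSI-style radiomics pool: 14 shape descriptors (T1CE only, shape is
# sequence-invariant), 18 first-order statistics and 70 second-order texture
# features (GLCM 24 + GLRLM 16 + GLSZM 16 + GLDM 14) per sequence;
# 14 + 4 x 88 = 366 descriptors per subject. Texture matrices are counted in
# compiled code over the 13 unique 3D directions and features averaged.

.SHAPE_NAMES <- c("volume", "surface_area", "surface_volume_ratio",
                  "sphericity", "asphericity", "maximum_3d_diameter",
                  "maximum_2d_diameter_slice", "maximum_2d_diameter_column",
                  "maximum_2d_diameter_row", "major_axis_length",
                  "minor_axis_length", "least_axis_length", "elongation",
                  "flatness")

.FIRSTORDER_NAMES <- c("energy", "total_energy", "entropy", "minimum",
                       "p10", "p90", "maximum", "mean", "median",
                       "interquartile_range", "range",
                       "mean_absolute_deviation",
                       "robust_mean_absolute_deviation", "root_mean_squared",
                       "skewness", "kurtosis", "variance", "uniformity")

.GLCM_NAMES <- c("autocorrelation", "joint_average", "cluster_prominence",
                 "cluster_shade", "cluster_tendency", "contrast",
                 "correlation", "difference_average", "difference_entropy",
                 "difference_variance", "joint_energy", "joint_entropy",
                 "imc1", "imc2", "idm", "idmn", "id", "idn",
                 "inverse_variance", "maximum_probability", "sum_average",
                 "sum_entropy", "sum_squares", "mcc")

.GLRLM_NAMES <- c("short_run_emphasis", "long_run_emphasis",
                  "gray_level_nonuniformity",
                  "gray_level_nonuniformity_normalized",
                  "run_length_nonuniformity",
                  "run_length_nonuniformity_normalized", "run_percentage",
                  "gray_level_variance", "run_variance", "run_entropy",
                  "low_gray_level_run_emphasis",
                  "high_gray_level_run_emphasis",
                  "short_run_low_gray_level_emphasis",
                  "short_run_high_gray_level_emphasis",
                  "long_run_low_gray_level_emphasis",
                  "long_run_high_gray_level_emphasis")

.GLSZM_NAMES <- c("small_area_emphasis", "large_area_emphasis",
                  "gray_level_nonuniformity",
                  "gray_level_nonuniformity_normalized",
                  "size_zone_nonuniformity",
                  "size_zone_nonuniformity_normalized", "zone_percentage",
                  "gray_level_variance", "zone_variance", "zone_entropy",
                  "low_gray_level_zone_emphasis",
                  "high_gray_level_zone_emphasis",
                  "small_area_low_gray_level_emphasis",
                  "small_area_high_gray_level_emphasis",
                  "large_area_low_gray_level_emphasis",
                  "large_area_high_gray_level_emphasis")

.GLDM_NAMES <- c("small_dependence_emphasis", "large_dependence_emphasis",
                 "gray_level_nonuniformity", "dependence_nonuniformity",
                 "dependence_nonuniformity_normalized",
                 "gray_level_variance", "dependence_variance",
                 "dependence_entropy", "low_gray_level_emphasis",
                 "high_gray_level_emphasis",
                 "small_dependence_low_gray_level_emphasis",
                 "small_dependence_high_gray_level_emphasis",
                 "large_dependence_low_gray_level_emphasis",
                 "large_dependence_high_gray_level_emphasis")

.SEQUENCES <- c("T1", "T1CE", "T2", "FLAIR")

#' Gray-level discretization settings
#'
#' @param mode "fixed_bin_count" (default) or "fixed_bin_width".
#' @param value Bin count (default 32) or bin width, respectively.
#' @param resegment Optional `c(lo, hi)` intensity range applied to the ROI
#'   before discretization.
#' @return An object of class `discretization_config`.
#' @export
discretization_config <- function(mode = c("fixed_bin_count",
                                           "fixed_bin_width"),
                                  value = 32, resegment = NULL) {
  mode <- match.arg(mode)
  if (value <= 0) stop("discretization value must be > 0")
  structure(list(mode = mode, value = value, resegment = resegment),
            class = "discretization_config")
}

# Discretize ROI values to integer levels 1..n; constant ROI -> level 1.
.discretize <- function(vals, disc) {
  if (!is.null(disc$resegment))
    vals <- pmin(pmax(vals, disc$resegment[1]), disc$resegment[2])
  if (disc$mode == "fixed_bin_count") {
    n <- as.integer(disc$value)
    rng <- range(vals)
    if (rng[2] <= rng[1]) return(list(lev = rep(1L, length(vals)), n = 1L))
    lev <- pmin(as.integer(floor(n * (vals - rng[1]) / (rng[2] - rng[1]))) + 1L,
                n)
    list(lev = lev, n = n)
  } else {
    w <- disc$value
    lo <- if (!is.null(disc$resegment)) disc$resegment[1] else min(vals)
    lev <- as.integer(floor((vals - lo) / w)) + 1L
    list(lev = lev, n = max(lev))
  }
}

.gtv_union <- function(gtv) gtv$grid > 0L

#' Shape descriptors of the tumor mask
#'
#' 14 morphological features on the whole GTV (union of sub-labels): voxel
#' volume, surface area (smoothed-gradient coarea estimate), their ratio,
#' sphericity, asphericity, maximum 3D diameter and the three in-plane
#' maximum 2D diameters over boundary voxels, and the PCA axis lengths with
#' elongation and flatness.
#'
#' @param gtv A [gtv_mask()] with a non-empty ROI.
#' @param spacing Optional spacing override (mm); defaults to `gtv$spacing`.
#' @return Named numeric vector of length 14.
#' @export
extract_shape <- function(gtv, spacing = NULL) {
  if (is.null(spacing)) spacing <- gtv$spacing
  mask <- .gtv_union(gtv)
  if (!any(mask)) stop("empty ROI: GTV has no voxels")
  shape <- dim(mask)
  voxvol <- prod(spacing)
  n <- sum(mask)
  volume <- n * voxvol

  chi <- array(as.numeric(mask), shape)
  sm <- array(cpp_gaussian_smooth(chi, shape, rep(1, 3)), shape)
  gx <- (sm[c(2:shape[1], shape[1]), , ] - sm[c(1, 1:(shape[1] - 1)), , ]) /
    (2 * spacing[1])
  gy <- (sm[, c(2:shape[2], shape[2]), ] - sm[, c(1, 1:(shape[2] - 1)), ]) /
    (2 * spacing[2])
  gz <- (sm[, , c(2:shape[3], shape[3])] - sm[, , c(1, 1:(shape[3] - 1))]) /
    (2 * spacing[3])
  surface <- sum(sqrt(gx^2 + gy^2 + gz^2)) * voxvol

  sphericity <- (pi^(1 / 3)) * (6 * volume)^(2 / 3) / surface
  asphericity <- (surface^3 / (36 * pi * volume^2))^(1 / 3) - 1

  bidx <- cpp_boundary_idx(array(as.integer(mask), shape), shape)
  bc <- arrayInd(bidx + 1L, shape)
  bp <- sweep(bc - 1, 2, spacing, `*`)
  maxpair <- function(pts) {
    if (nrow(pts) < 2) return(0)
    mx <- 0
    step <- 512L
    for (i in seq(1, nrow(pts), by = step)) {
      ii <- i:min(i + step - 1L, nrow(pts))
      d2 <- outer(rowSums(pts[ii, , drop = FALSE]^2),
                  rowSums(pts^2), `+`) -
        2 * pts[ii, , drop = FALSE] %*% t(pts)
      mx <- max(mx, max(d2))
    }
    sqrt(max(mx, 0))
  }
  max3d <- maxpair(bp)
  # in-plane maxima: largest pairwise distance within any single slice
  plane_max <- function(axis) {
    keep <- setdiff(1:3, axis)
    mx <- 0
    for (s in unique(bc[, axis])) {
      pts <- bp[bc[, axis] == s, keep, drop = FALSE]
      mx <- max(mx, maxpair(pts))
    }
    mx
  }
  max2d_slice <- plane_max(3)   # axial (x-y) planes
  max2d_column <- plane_max(2)  # coronal (x-z) planes
  max2d_row <- plane_max(1)     # sagittal (y-z) planes

  vc <- arrayInd(which(mask), shape)
  vp <- sweep(vc - 1, 2, spacing, `*`)
  ev <- if (nrow(vp) > 1) {
    eigen(stats::cov(vp) * (nrow(vp) - 1) / nrow(vp),
          symmetric = TRUE, only.values = TRUE)$values
  } else c(0, 0, 0)
  ev <- pmax(ev, 0)
  axes <- 4 * sqrt(ev)
  elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flatness <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  stats::setNames(
    c(volume, surface, surface / volume, sphericity, asphericity, max3d,
      max2d_slice, max2d_column, max2d_row, axes[1], axes[2], axes[3],
      elongation, flatness),
    .SHAPE_NAMES)
}

#' First-order intensity statistics over the tumor ROI
#'
#' The 18 IBSI first-order features; entropy and uniformity use the
#' discretized histogram. Degenerate (constant) ROIs give zero variance,
#' skewness, kurtosis and entropy.
#'
#' @param image An [intensity_volume()].
#' @param gtv A [gtv_mask()] aligned with `image`.
#' @param disc A [discretization_config()].
#' @return Named numeric vector of length 18.
#' @export
extract_first_order <- function(image, gtv, disc = discretization_config()) {
  .same_geometry(image, gtv)
  vals <- image$grid[.gtv_union(gtv)]
  if (!length(vals)) stop("empty ROI: GTV has no voxels")
  voxvol <- prod(image$spacing)
  n <- length(vals)
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)
  skew <- if (m2 > 0) mean((vals - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((vals - mu)^4) / m2^2 else 0
  p10 <- as.numeric(quantile(vals, 0.10, type = 7))
  p90 <- as.numeric(quantile(vals, 0.90, type = 7))
  mid <- vals[vals >= p10 & vals <= p90]
  rmad <- if (length(mid)) mean(abs(mid - mean(mid))) else 0
  d <- .discretize(vals, disc)
  p <- tabulate(d$lev, d$n) / n
  p <- p[p > 0]
  stats::setNames(
    c(sum(vals^2), voxvol * sum(vals^2), -sum(p * log2(p)), min(vals),
      p10, p90, max(vals), mu, median(vals),
      as.numeric(quantile(vals, 0.75) - quantile(vals, 0.25)),
      max(vals) - min(vals), mean(abs(vals - mu)), rmad,
      sqrt(mean(vals^2)), skew, kurt, m2, sum(p^2)),
    .FIRSTORDER_NAMES)
}

# ---- texture families ------------------------------------------------------

.glcm_features_one <- function(P) {
  # P: symmetric normalized co-occurrence matrix (nlev x nlev)
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(i * P)
  sigma2 <- sum((i - mu)^2 * P)
  pd <- vapply(0:(n - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  ps <- vapply(2:(2 * n), function(k) sum(P[(i + j) == k]), numeric(1))
  kd <- 0:(n - 1)
  ks <- 2:(2 * n)
  eps <- .Machine$double.eps
  da <- sum(kd * pd)
  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pxy <- outer(px, px)
  hxy1 <- -sum(P * log2(pxy + eps))
  hxy2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  corr <- if (sigma2 > 0) (sum(i * j * P) - mu^2) / sigma2 else 1
  mcc <- if (n > 1 && all(px > 0)) {
    # Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) px(k))
    Q <- sweep(P, 1, px, `/`) %*% t(sweep(P, 2, px, `/`))
    lam <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(lam) > 1 && lam[2] > 0) sqrt(min(lam[2], 1)) else 1
  } else 1
  c(autocorrelation = sum(i * j * P),
    joint_average = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    difference_variance = sum((kd - da)^2 * pd),
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    imc1 = imc1,
    imc2 = imc2,
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + ((i - j) / n)^2)),
    id = sum(P / (1 + abs(i - j))),
    idn = sum(P / (1 + abs(i - j) / n)),
    inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    maximum_probability = max(P),
    sum_average = sum(ks * ps),
    sum_entropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    sum_squares = sigma2,
    mcc = mcc)
}

.glcm_features <- function(disc_grid, mask, nlev) {
  shape <- dim(mask)
  counts <- cpp_glcm(array(disc_grid, shape), array(as.integer(mask), shape),
                     shape, nlev)
  counts <- array(counts, c(nlev, nlev, 13))
  feats <- matrix(NA_real_, 13, length(.GLCM_NAMES),
                  dimnames = list(NULL, .GLCM_NAMES))
  used <- logical(13)
  for (d in 1:13) {
    M <- counts[, , d]
    M <- M + t(M)  # symmetrize
    tot <- sum(M)
    if (tot == 0) next
    used[d] <- TRUE
    feats[d, ] <- .glcm_features_one(M / tot)
  }
  if (!any(used)) stop("ROI too small for co-occurrence statistics")
  colMeans(feats[used, , drop = FALSE])
}

.glrlm_features <- function(disc_grid, mask, nlev) {
  shape <- dim(mask)
  np <- sum(mask)
  maxrun <- max(shape)
  counts <- cpp_glrlm(array(disc_grid, shape), array(as.integer(mask), shape),
                      shape, nlev, maxrun)
  counts <- array(counts, c(nlev, maxrun, 13))
  gl <- matrix(seq_len(nlev), nlev, maxrun)
  rl <- matrix(seq_len(maxrun), nlev, maxrun, byrow = TRUE)
  feats <- matrix(NA_real_, 13, length(.GLRLM_NAMES),
                  dimnames = list(NULL, .GLRLM_NAMES))
  for (d in 1:13) {
    R <- counts[, , d]
    nr <- sum(R)
    if (nr == 0) next
    p <- R / nr
    mui <- sum(gl * p); muj <- sum(rl * p)
    pp <- p[p > 0]
    feats[d, ] <- c(
      short_run_emphasis = sum(R / rl^2) / nr,
      long_run_emphasis = sum(R * rl^2) / nr,
      gray_level_nonuniformity = sum(rowSums(R)^2) / nr,
      gray_level_nonuniformity_normalized = sum(rowSums(R)^2) / nr^2,
      run_length_nonuniformity = sum(colSums(R)^2) / nr,
      run_length_nonuniformity_normalized = sum(colSums(R)^2) / nr^2,
      run_percentage = nr / np,
      gray_level_variance = sum((gl - mui)^2 * p),
      run_variance = sum((rl - muj)^2 * p),
      run_entropy = -sum(pp * log2(pp)),
      low_gray_level_run_emphasis = sum(R / gl^2) / nr,
      high_gray_level_run_emphasis = sum(R * gl^2) / nr,
      short_run_low_gray_level_emphasis = sum(R / (gl^2 * rl^2)) / nr,
      short_run_high_gray_level_emphasis = sum(R * gl^2 / rl^2) / nr,
      long_run_low_gray_level_emphasis = sum(R * rl^2 / gl^2) / nr,
      long_run_high_gray_level_emphasis = sum(R * gl^2 * rl^2) / nr)
  }
  ok <- stats::complete.cases(feats)
  colMeans(feats[ok, , drop = FALSE])
}

.glszm_features <- function(disc_grid, mask, nlev) {
  shape <- dim(mask)
  np <- sum(mask)
  zones <- cpp_glszm(array(disc_grid, shape), array(as.integer(mask), shape),
                     shape)
  maxsize <- max(zones[, 2])
  S <- matrix(0, nlev, maxsize)
  for (k in seq_len(nrow(zones)))
    S[zones[k, 1], zones[k, 2]] <- S[zones[k, 1], zones[k, 2]] + 1
  nz <- sum(S)
  gl <- matrix(seq_len(nlev), nlev, maxsize)
  sz <- matrix(seq_len(maxsize), nlev, maxsize, byrow = TRUE)
  p <- S / nz
  mui <- sum(gl * p); muj <- sum(sz * p)
  pp <- p[p > 0]
  stats::setNames(c(
    sum(S / sz^2) / nz, sum(S * sz^2) / nz,
    sum(rowSums(S)^2) / nz, sum(rowSums(S)^2) / nz^2,
    sum(colSums(S)^2) / nz, sum(colSums(S)^2) / nz^2,
    nz / np,
    sum((gl - mui)^2 * p), sum((sz - muj)^2 * p), -sum(pp * log2(pp)),
    sum(S / gl^2) / nz, sum(S * gl^2) / nz,
    sum(S / (gl^2 * sz^2)) / nz, sum(S * gl^2 / sz^2) / nz,
    sum(S * sz^2 / gl^2) / nz, sum(S * gl^2 * sz^2) / nz),
    .GLSZM_NAMES)
}

.gldm_features <- function(disc_grid, mask, nlev, alpha = 0L) {
  shape <- dim(mask)
  D <- cpp_gldm(array(disc_grid, shape), array(as.integer(mask), shape),
                shape, nlev, as.integer(alpha))
  nd <- sum(D)
  ncol_d <- ncol(D)
  gl <- matrix(seq_len(nlev), nlev, ncol_d)
  dp <- matrix(seq_len(ncol_d), nlev, ncol_d, byrow = TRUE)  # dependence + 1
  p <- D / nd
  mui <- sum(gl * p); muj <- sum(dp * p)
  pp <- p[p > 0]
  stats::setNames(c(
    sum(D / dp^2) / nd, sum(D * dp^2) / nd,
    sum(rowSums(D)^2) / nd,
    sum(colSums(D)^2) / nd, sum(colSums(D)^2) / nd^2,
    sum((gl - mui)^2 * p), sum((dp - muj)^2 * p), -sum(pp * log2(pp)),
    sum(D / gl^2) / nd, sum(D * gl^2) / nd,
    sum(D / (gl^2 * dp^2)) / nd, sum(D * gl^2 / dp^2) / nd,
    sum(D * dp^2 / gl^2) / nd, sum(D * gl^2 * dp^2) / nd),
    .GLDM_NAMES)
}

#' Second-order (texture) features over the tumor ROI
#'
#' 70 features: 24 co-occurrence (GLCM, symmetric, averaged over the 13
#' unique 3D directions at distance 1), 16 run-length (GLRLM, averaged over
#' directions), 16 size-zone (GLSZM, 26-connected zones) and 14 dependence
#' (GLDM, alpha = 0) features on the discretized ROI.
#'
#' @inheritParams extract_first_order
#' @return Named numeric vector of length 70 with family-prefixed names.
#' @export
extract_second_order <- function(image, gtv, disc = discretization_config()) {
  .same_geometry(image, gtv)
  mask <- .gtv_union(gtv)
  if (!any(mask)) stop("empty ROI: GTV has no voxels")
  vals <- image$grid[mask]
  d <- .discretize(vals, disc)
  disc_grid <- array(0L, dim = dim(mask))
  disc_grid[mask] <- d$lev
  nlev <- max(d$n, 1L)
  out <- c(
    stats::setNames(.glcm_features(disc_grid, mask, nlev),
                    paste0("glcm_", .GLCM_NAMES)),
    stats::setNames(.glrlm_features(disc_grid, mask, nlev),
                    paste0("glrlm_", .GLRLM_NAMES)),
    stats::setNames(.glszm_features(disc_grid, mask, nlev),
                    paste0("glszm_", .GLSZM_NAMES)),
    stats::setNames(.gldm_features(disc_grid, mask, nlev),
                    paste0("gldm_", .GLDM_NAMES)))
  out
}

#' The canonical 366-descriptor radiomics manifest
#'
#' Fixed, auditable feature list: 14 shape descriptors sourced from T1CE,
#' then for each sequence (T1, T1CE, T2, FLAIR) 18 first-order and 70
#' second-order features. 14 + 4 x (18 + 70) = 366.
#'
#' @return A data.frame with columns `feature`, `family` (shape /
#'   first_order / second_order) and `source_sequence`, 366 rows in
#'   canonical order.
#' @export
radiomic_manifest <- function() {
  rows <- list(data.frame(feature = paste0("shape_", .SHAPE_NAMES),
                          family = "shape", source_sequence = "T1CE"))
  second <- c(paste0("glcm_", .GLCM_NAMES), paste0("glrlm_", .GLRLM_NAMES),
              paste0("glszm_", .GLSZM_NAMES), paste0("gldm_", .GLDM_NAMES))
  for (s in .SEQUENCES) {
    rows[[length(rows) + 1]] <-
      data.frame(feature = paste0(s, "_firstorder_", .FIRSTORDER_NAMES),
                 family = "first_order", source_sequence = s)
    rows[[length(rows) + 1]] <-
      data.frame(feature = paste0(s, "_", second),
                 family = "second_order", source_sequence = s)
  }
  do.call(rbind, rows)
}

#' Assemble the full 366-feature radiomics row for one subject
#'
#' Concatenates, in manifest order, the 14 shape features (GTV geometry,
#' tagged T1CE) and per sequence the 18 first-order plus 70 second-order
#' features. A missing or misaligned sequence is a hard error naming the
#' sequence; nothing is imputed.
#'
#' @param sequences Named list with elements "T1", "T1CE", "T2", "FLAIR",
#'   each an [intensity_volume()].
#' @param gtv A [gtv_mask()] aligned with all four sequences.
#' @param disc A [discretization_config()].
#' @return Named numeric vector of length 366, with the manifest attached as
#'   attribute `manifest`.
#' @export
assemble_feature_table <- function(sequences, gtv,
                                   disc = discretization_config()) {
  missing <- setdiff(.SEQUENCES, names(sequences))
  if (length(missing))
    stop("missing sequence(s): ", paste(missing, collapse = ", "))
  for (s in .SEQUENCES) {
    if (!inherits(sequences[[s]], "intensity_volume"))
      stop("sequence ", s, " is not an intensity volume")
    tryCatch(.same_geometry(sequences[[s]], gtv),
             error = function(e) stop("sequence ", s, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  man <- radiomic_manifest()
  out <- numeric(0)
  shp <- extract_shape(gtv)
  out <- c(out, stats::setNames(shp, paste0("shape_", names(shp))))
  for (s in .SEQUENCES) {
    fo <- extract_first_order(sequences[[s]], gtv, disc)
    so <- extract_second_order(sequences[[s]], gtv, disc)
    out <- c(out, stats::setNames(fo, paste0(s, "_firstorder_", names(fo))),
             stats::setNames(so, paste0(s, "_", names(so))))
  }
  stopifnot(identical(names(out), man$feature))
  attr(out, "manifest") <- man
  out
}
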
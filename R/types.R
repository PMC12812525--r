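#' @useDynLib gliomap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median quantile predict pnorm var
#' @importFrom utils head read.csv write.csv
NULL

# ---- canonical parcellation dictionary -------------------------------------

.PAIRED_STRUCTURES <- c(
  "cerebral white matter", "cerebral cortex", "lateral ventricle",
  "inferior lateral ventricle", "cerebellum white matter", "cerebellum cortex",
  "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
  "accumbens area", "ventral DC"
)
.MIDLINE_STRUCTURES <- c("CSF", "3rd ventricle", "4th ventricle", "brain-stem")

#' Canonical 32-structure label dictionary
#'
#' The parcellation vocabulary used throughout the package: 14 left/right
#' structure pairs plus four midline structures (CSF, 3rd ventricle,
#' 4th ventricle, brain-stem). Labels 1-14 are the left structures, 15-18
#' the midline structures, 19-32 the right structures; left label `i`
#' pairs with right label `i + 18`.
#'
#' @return Named character vector of length 32; names are the label ids
#'   ("1".."32"), values the structure names.
#' @export
canonical_labels <- function() {
  nm <- c(paste("left", .PAIRED_STRUCTURES), .MIDLINE_STRUCTURES,
          paste("right", .PAIRED_STRUCTURES))
  stats::setNames(nm, as.character(seq_along(nm)))
}

#' Left/right structure pairing of the canonical dictionary
#'
#' @return Two-column integer matrix (left id, right id), 14 rows.
#' @export
mirror_pairs <- function() {
  cbind(left = 1:14, right = 19:32)
}

# ---- containers ------------------------------------------------------------

.check_grid <- function(grid, spacing) {
  stopifnot(length(dim(grid)) == 3, length(spacing) == 3, all(spacing > 0))
}

#' Construct a parcellation label volume
#'
#' @param grid 3D integer array of labels (0 = background).
#' @param spacing Physical voxel size per axis in mm.
#' @param label_dict Named character vector mapping label id to structure name;
#'   defaults to [canonical_labels()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, spacing, label_dict = canonical_labels()) {
  .check_grid(grid, spacing)
  storage.mode(grid) <- "integer"
  present <- setdiff(sort(unique(as.vector(grid))), 0L)
  unknown <- setdiff(present, as.integer(names(label_dict)))
  if (length(unknown))
    stop("label ids in grid missing from label_dict: ",
         paste(unknown, collapse = ", "))
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 label_dict = label_dict),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$grid), collapse = "x"),
      "voxels @", paste(signif(x$spacing, 3), collapse = "x"), "mm\n")
  present <- setdiff(unique(as.vector(x$grid)), 0L)
  cat("  labels present:", length(present), "of", length(x$label_dict), "\n")
  invisible(x)
}

#' Construct a gross-tumor-volume mask
#'
#' Sub-labels: 0 = non-tumor, 1 = enhancing core, 2 = necrotic/cystic core,
#' 3 = peritumoral edema. The GTV proper is the union of all three.
#'
#' @param grid 3D integer array with values in 0..3.
#' @param spacing Voxel size (mm).
#' @return An object of class `gtv_mask`.
#' @export
gtv_mask <- function(grid, spacing) {
  .check_grid(grid, spacing)
  storage.mode(grid) <- "integer"
  if (!all(grid %in% 0:3)) stop("GTV sub-labels must be in 0..3")
  structure(list(grid = grid, spacing = as.numeric(spacing)),
            class = "gtv_mask")
}

#' @export
print.gtv_mask <- function(x, ...) {
  n <- tabulate(x$grid + 1L, 4L)
  cat("gtv_mask:", paste(dim(x$grid), collapse = "x"), "voxels;",
      "enhancing", n[2], "| necrotic", n[3], "| edema", n[4], "\n")
  invisible(x)
}

#' Construct an intensity volume
#'
#' @param grid 3D numeric array (finite values).
#' @param spacing Voxel size (mm).
#' @param sequence_name One of "T1", "T1CE", "T2", "FLAIR".
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(grid, spacing,
                             sequence_name = c("T1", "T1CE", "T2", "FLAIR")) {
  .check_grid(grid, spacing)
  sequence_name <- match.arg(sequence_name)
  if (!all(is.finite(grid))) stop("intensity grid contains non-finite values")
  storage.mode(grid) <- "double"
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 sequence_name = sequence_name),
            class = "intensity_volume")
}

#' Construct a dense displacement field
#'
#' Displacements are stored in mm on the voxel grid; the field maps an
#' output-grid physical point `x` to the source sample point `x + u(x)`.
#'
#' @param disp 4D numeric array `(nx, ny, nz, 3)` of mm displacements.
#' @param spacing Voxel size (mm).
#' @param inverse Optional 4D array, same layout, holding the inverse map.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(disp, spacing, inverse = NULL) {
  stopifnot(length(dim(disp)) == 4, dim(disp)[4] == 3,
            length(spacing) == 3, all(spacing > 0))
  structure(list(disp = disp, spacing = as.numeric(spacing),
                 inverse = inverse),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  m <- sqrt(x$disp[, , , 1]^2 + x$disp[, , , 2]^2 + x$disp[, , , 3]^2)
  cat("deformation_field:", paste(dim(x$disp)[1:3], collapse = "x"),
      sprintf("voxels; |u| max %.2f mm, mean %.2f mm;", max(m), mean(m)),
      if (is.null(x$inverse)) "inverse: absent" else "inverse: stored", "\n")
  invisible(x)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix (det +1).
#' @param translation mm 3-vector.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation determinant must be +1, got ", det(rotation))
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%s) mm\n",
              ang, paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

.same_geometry <- function(a, b, what = "volumes") {
  da <- dim(a$grid %||% a$disp)[1:3]
  db <- dim(b$grid %||% b$disp)[1:3]
  if (!identical(da, db))
    stop(sprintf("misaligned %s: shapes %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(sprintf("misaligned %s: spacings differ", what))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- seeded sub-streams ----------------------------------------------------

# Derive a reproducible 31-bit sub-seed from (seed, tag); each operation uses
# its own named stream so adding operations never shifts other draws.
stream_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

with_stream <- function(seed, tag, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, tag))
  force(code)
}
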
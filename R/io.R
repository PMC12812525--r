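# Formats and orchestration: NIfTI-1 volumes and displacement fields,
# label-dictionary TSV, feature-table CSV, YAML run configuration, phantom
# cohort emission and the end-to-end pipeline.

#' Write a volume to NIfTI-1
#'
#' Label and GTV grids are written as integer payloads, intensities as
#' float; spacing goes into the header pixdim. Displacement fields use the
#' 5D NIfTI vector convention `(nx, ny, nz, 1, 3)`.
#'
#' @param volume A [label_volume()], [gtv_mask()], [intensity_volume()] or
#'   [deformation_field()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "deformation_field")) {
    d <- dim(volume$disp)
    arr <- array(volume$disp, c(d[1:3], 1, 3))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(volume$spacing, 1, 1)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  grid <- volume$grid
  if (inherits(volume, c("label_volume", "gtv_mask")))
    storage.mode(grid) <- "integer"
  img <- RNifti::asNifti(grid)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' Integer payloads load as label volumes (or a GTV mask with `as = "gtv"`),
#' floating-point payloads as intensity volumes; 5D vector payloads load as
#' displacement fields. Spacing is taken from the header and survives a
#' write/read round trip.
#'
#' @param path NIfTI file path.
#' @param as Override: "auto", "labels", "gtv", "intensity" or "field".
#' @param sequence_name Sequence tag used when reading intensities.
#' @param label_dict Dictionary used when reading labels.
#' @return The corresponding volume object.
#' @export
read_volume <- function(path, as = c("auto", "labels", "gtv", "intensity",
                                     "field"),
                        sequence_name = "T1",
                        label_dict = canonical_labels()) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  arr <- array(as.vector(img), dim(img))  # drop header attributes
  nd <- length(dim(arr))
  if (nd == 5 || as == "field") {
    if (nd != 5 || dim(arr)[5] != 3)
      stop("displacement fields must be 5D NIfTI with 3 vector components")
    spacing <- pd[1:3]
    return(deformation_field(array(arr, c(dim(arr)[1:3], 3)), spacing))
  }
  if (nd != 3)
    stop("expected a 3D volume, got ", nd, "D payload in ", path)
  spacing <- pd[1:3]
  integral <- all(arr == round(arr))
  if (as == "auto") as <- if (integral) "labels" else "intensity"
  switch(as,
         labels = label_volume(array(as.integer(arr), dim(arr)), spacing,
                               label_dict),
         gtv = gtv_mask(array(as.integer(arr), dim(arr)), spacing),
         intensity = intensity_volume(arr, spacing, sequence_name))
}

#' Write / read a rigid transform as a plain-text 4x4 matrix
#'
#' Homogeneous row-major layout; an optional companion displacement-field
#' file path is stored as a comment line.
#'
#' @param rigid A [rigid_transform()].
#' @param path Output text file.
#' @param field_path Optional path of an associated field NIfTI.
#' @return `path` / the transform (with attribute `field_path` if present).
#' @export
write_transform <- function(rigid, path, field_path = NULL) {
  m <- rbind(cbind(rigid$rotation, rigid$translation), c(0, 0, 0, 1))
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  if (!is.null(field_path)) lines <- c(paste("# field:", field_path), lines)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  fp <- sub("^# field: ", "", grep("^# field: ", lines, value = TRUE))
  rows <- grep("^#", lines, invert = TRUE, value = TRUE)
  m <- do.call(rbind, lapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  out <- rigid_transform(m[1:3, 1:3], m[1:3, 4])
  if (length(fp)) attr(out, "field_path") <- fp
  out
}

#' Write / read a label dictionary as two-column TSV
#' @param label_dict Named character vector (id -> name).
#' @param path TSV path.
#' @return `path` / the dictionary.
#' @export
write_label_dict <- function(label_dict, path) {
  utils::write.table(data.frame(id = names(label_dict),
                                name = unname(label_dict)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_dict
#' @export
read_label_dict <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "character"))
  stats::setNames(tab$name, tab$id)
}

#' Write / read a feature table as CSV
#'
#' Layout: `subject_id` first column, `label` last, feature names in the
#' header; comma separator, '.' decimal, UTF-8.
#'
#' @param table Feature table data.frame.
#' @param path CSV path.
#' @return `path` / the table.
#' @export
write_feature_table <- function(table, path) {
  ord <- c("subject_id", setdiff(names(table), c("subject_id", "label")),
           "label")
  utils::write.csv(table[, intersect(ord, names(table)), drop = FALSE],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Emit a phantom cohort as NIfTI bundles plus a manifest
#'
#' Writes, per subject, the ground-truth and corrupted parcellations, GTV,
#' four synthetic sequences and the true deformation field, plus a shared
#' atlas, a label-dictionary TSV, a synthetic clinical table (survival
#' times, IDH and MGMT statuses) and a JSON manifest.
#'
#' @param dir Output directory (created).
#' @param n_subjects Number of subjects.
#' @param shape,spacing Grid geometry.
#' @param seed Master seed.
#' @param with_intensities Write the four MRI sequences (slower).
#' @param ... Passed to [make_phantom_subject()].
#' @return The manifest list, invisibly.
#' @export
write_phantom_cohort <- function(dir, n_subjects, shape = c(64, 64, 64),
                                 spacing = c(3, 3, 3), seed = 1,
                                 with_intensities = TRUE, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- make_atlas_labels(shape, spacing, seed = seed)
  write_volume(atlas, file.path(dir, "atlas_labels.nii.gz"))
  write_label_dict(atlas$label_dict, file.path(dir, "label_dict.tsv"))
  clin <- with_stream(seed, "clinical", data.frame(
    subject_id = sprintf("subj_%04d", seq_len(n_subjects)),
    os_days = round(stats::rlnorm(n_subjects, log(400), 0.6)),
    idh = sample(c("wildtype", "mutated", "NOS/NEC", "negative"),
                 n_subjects, replace = TRUE, prob = c(0.7, 0.2, 0.05, 0.05)),
    mgmt = sample(c("methylated", "unmethylated"), n_subjects,
                  replace = TRUE)))
  subjects <- list()
  for (i in seq_len(n_subjects)) {
    sid <- clin$subject_id[i]
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    subj <- make_phantom_subject(atlas, seed = stream_seed(seed, sid),
                                 with_intensities = with_intensities, ...)
    write_volume(subj$truth_labels, file.path(sdir, "truth_labels.nii.gz"))
    write_volume(subj$corrupted_labels, file.path(sdir, "mask_synth.nii.gz"))
    write_volume(subj$gtv, file.path(sdir, "gtv.nii.gz"))
    write_volume(subj$true_field, file.path(sdir, "true_field.nii.gz"))
    if (with_intensities)
      for (s in names(subj$sequences))
        write_volume(subj$sequences[[s]],
                     file.path(sdir, paste0(tolower(s), ".nii.gz")))
    subjects[[i]] <- list(subject_id = sid, seed = subj$metadata$seed,
                          gtv_voxels = sum(subj$gtv$grid > 0))
  }
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  manifest <- list(n_subjects = n_subjects, shape = shape, spacing = spacing,
                   seed = seed, with_intensities = with_intensities,
                   subjects = subjects)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Default run configuration
#'
#' @param cohort_dir Directory produced by [write_phantom_cohort()].
#' @param out_dir Run directory to create.
#' @param task "os", "idh" or "mgmt".
#' @param feature_set "spatial", "radiomics" or "combined".
#' @param seed Master seed.
#' @param n_repeats,k CV plan.
#' @param ffs_cap Forward-selection cap.
#' @param n_models Ensemble size (top configurations from the grid).
#' @param compose_mode Parcellation composition mode.
#' @return A `run_config` list, serializable to YAML.
#' @export
run_config <- function(cohort_dir, out_dir, task = c("os", "idh", "mgmt"),
                       feature_set = c("spatial", "radiomics", "combined"),
                       seed = 1, n_repeats = 2, k = 5, ffs_cap = 3,
                       n_models = 2, compose_mode = "composite") {
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir,
                 task = match.arg(task), feature_set = match.arg(feature_set),
                 seed = seed, n_repeats = n_repeats, k = k,
                 ffs_cap = ffs_cap, n_models = n_models,
                 compose_mode = compose_mode,
                 version = as.character(utils::packageVersion("gliomap"))),
            class = "run_config")
}

#' Run the full pipeline on a phantom cohort directory
#'
#' Parcellation repair per subject, spatial (and optionally radiomics)
#' feature extraction, label construction for the chosen task, and repeated
#' CV of the grid-search-ranked ensemble. Stage markers make a rerun with
#' identical config + seed idempotent: completed per-subject feature rows
#' are reused.
#'
#' @param config A [run_config()] (or YAML path read with
#'   [yaml::read_yaml()]).
#' @return The run directory path, invisibly; `metrics.json`,
#'   `features.csv` and `config.yaml` are written inside it.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config.yaml"))
  log_path <- file.path(cfg$out_dir, "run.log")
  log_line <- function(stage, ...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                       stage, ..., "\n",
                                       file = log_path, append = TRUE)
  log_line("start", "task", cfg$task, "feature_set", cfg$feature_set,
           "seed", cfg$seed)
  man <- jsonlite::read_json(file.path(cfg$cohort_dir, "manifest.json"),
                             simplifyVector = TRUE)
  atlas <- read_volume(file.path(cfg$cohort_dir, "atlas_labels.nii.gz"),
                       as = "labels")
  clin <- utils::read.csv(file.path(cfg$cohort_dir, "clinical.csv"))
  feat_path <- file.path(cfg$out_dir, "features.csv")
  rows <- list()
  for (sid in clin$subject_id) {
    marker <- file.path(cfg$out_dir, paste0(sid, ".done.csv"))
    if (file.exists(marker)) {
      rows[[sid]] <- utils::read.csv(marker, check.names = FALSE)
      next
    }
    sdir <- file.path(cfg$cohort_dir, sid)
    seg <- read_volume(file.path(sdir, "mask_synth.nii.gz"), as = "labels")
    gtv <- read_volume(file.path(sdir, "gtv.nii.gz"), as = "gtv")
    case <- fill_tumor_labels(seg, atlas, gtv,
                              config = list(compose_mode = cfg$compose_mode))
    row <- data.frame(subject_id = sid)
    if (cfg$feature_set %in% c("spatial", "combined")) {
      sp <- occupancy_ratios(case$mask_final, gtv, subject_id = sid)
      spv <- as.data.frame(t(unclass(sp)))
      names(spv) <- sprintf("spatial_%02d", seq_along(sp))
      row <- cbind(row, spv)
    }
    if (cfg$feature_set %in% c("radiomics", "combined")) {
      seqs <- lapply(stats::setNames(nm = c("T1", "T1CE", "T2", "FLAIR")),
                     function(s) {
                       p <- file.path(sdir, paste0(tolower(s), ".nii.gz"))
                       if (!file.exists(p))
                         stop("subject ", sid, ": missing sequence ", s)
                       read_volume(p, as = "intensity", sequence_name = s)
                     })
      rad <- assemble_feature_table(seqs, gtv)
      row <- cbind(row, as.data.frame(t(unclass(rad))))
    }
    utils::write.csv(row, marker, row.names = FALSE)
    log_line("features", sid, "gtv_voxels", sum(gtv$grid > 0))
    rows[[sid]] <- row
  }
  features <- do.call(rbind, rows)
  labels <- switch(cfg$task,
                   os = binarize_os(clin$os_days),
                   idh = binarize_idh(clin$idh),
                   mgmt = as.integer(clin$mgmt == "methylated"))
  tab <- cbind(features, label = labels[match(features$subject_id,
                                              clin$subject_id)])
  tab <- tab[!is.na(tab$label), ]
  write_feature_table(tab, feat_path)
  grid <- grid_search(default_model_grid(), tab, seed = cfg$seed)
  configs <- grid[seq_len(min(cfg$n_models, length(grid)))]
  plan <- cv_plan(n_repeats = cfg$n_repeats, k = cfg$k, seed = cfg$seed)
  report <- repeated_cv(tab, plan, configs, ffs_cap = cfg$ffs_cap)
  jsonlite::write_json(list(summary = report$summary, count = report$count,
                            observations = report$observations),
                       file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$observations,
                   file.path(cfg$out_dir, "observations.csv"),
                   row.names = FALSE)
  log_line("done", "observations", report$count)
  invisible(cfg$out_dir)
}
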
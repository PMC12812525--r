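# The 32-value spatial distribution pattern: per-structure volumes, tumor
# occupancy ratios against the repaired parcellation, and cohort summaries.

#' Per-structure volumes (and optional GTV overlap volumes)
#'
#' @param labels A [label_volume()] with the canonical 32-label dictionary.
#' @param gtv Optional [gtv_mask()]; adds per-structure overlap volumes.
#' @return A data.frame with columns `label`, `structure`, `volume_l` and,
#'   when `gtv` is given, `overlap_l` (all in liters). Structures absent
#'   from the grid get volume 0 with a warning.
#' @export
structure_volumes <- function(labels, gtv = NULL) {
  ids <- as.integer(names(labels$label_dict))
  present <- setdiff(unique(as.vector(labels$grid)), 0L)
  unknown <- setdiff(present, ids)
  if (length(unknown))
    stop("unknown label ids in grid: ", paste(unknown, collapse = ", "))
  voxel_l <- prod(labels$spacing) * 1e-6  # mm^3 -> liters
  counts <- tabulate(labels$grid[labels$grid > 0L], nbins = max(ids))[ids]
  counts[is.na(counts)] <- 0L
  missing <- ids[counts == 0L]
  if (length(missing))
    warning("structures absent from grid: ",
            paste(labels$label_dict[as.character(missing)], collapse = ", "))
  out <- data.frame(label = ids,
                    structure = unname(labels$label_dict[as.character(ids)]),
                    volume_l = counts * voxel_l)
  if (!is.null(gtv)) {
    .same_geometry(labels, gtv)
    sel <- labels$grid > 0L & gtv$grid > 0L
    ov <- tabulate(labels$grid[sel], nbins = max(ids))[ids]
    ov[is.na(ov)] <- 0L
    out$overlap_l <- ov * voxel_l
  }
  out
}

#' Tumor occupancy ratios: the 32-value spatial distribution pattern
#'
#' For each canonical structure `s`, the fraction of its volume in the
#' repaired parcellation that lies under the GTV:
#' `ratio(s) = |mask_final = s  &  gtv > 0| / |mask_final = s|`.
#' Structures with zero total volume get ratio 0 (never NaN) and are
#' recorded in the `zero_volume` attribute as a QC flag.
#'
#' @param mask_final A [label_volume()] (the repaired parcellation).
#' @param gtv A [gtv_mask()] aligned with `mask_final`.
#' @param subject_id Optional identifier stored on the result.
#' @return An object of class `spatial_features`: a named numeric vector of
#'   length 32 in canonical label order, all values in `[0, 1]`.
#' @export
occupancy_ratios <- function(mask_final, gtv, subject_id = NULL) {
  .same_geometry(mask_final, gtv)
  ids <- as.integer(names(mask_final$label_dict))
  if (length(ids) != 32)
    stop("occupancy ratios require the canonical 32-label dictionary")
  tot <- tabulate(mask_final$grid[mask_final$grid > 0L], nbins = max(ids))[ids]
  sel <- mask_final$grid > 0L & gtv$grid > 0L
  ov <- tabulate(mask_final$grid[sel], nbins = max(ids))[ids]
  tot[is.na(tot)] <- 0L; ov[is.na(ov)] <- 0L
  ratios <- ifelse(tot > 0L, ov / tot, 0)
  names(ratios) <- unname(mask_final$label_dict[as.character(ids)])
  structure(ratios, class = "spatial_features",
            subject_id = subject_id,
            zero_volume = names(ratios)[tot == 0L])
}

#' @export
print.spatial_features <- function(x, ...) {
  id <- attr(x, "subject_id")
  cat("spatial distribution pattern",
      if (!is.null(id)) paste0("(", id, ")"), "\n")
  top <- sort(unclass(x), decreasing = TRUE)
  top <- top[top > 0]
  if (!length(top)) cat("  no structure overlaps the GTV\n")
  else for (i in seq_len(min(5, length(top))))
    cat(sprintf("  %-32s %.3f\n", names(top)[i], top[i]))
  zv <- attr(x, "zero_volume")
  if (length(zv)) cat("  QC: zero-volume structures:",
                      paste(zv, collapse = ", "), "\n")
  invisible(x)
}

#' Cohort summary of spatial distribution patterns
#'
#' Per-structure arithmetic mean and population standard deviation over a
#' cohort, in the layout of a per-structure mean +/- sd table.
#'
#' @param vectors A list of [occupancy_ratios()] results (or a numeric
#'   matrix with 32 named columns, one row per subject).
#' @return A data.frame with columns `structure`, `mean`, `sd`, `n` and a
#'   formatted `mean_sd` column.
#' @export
cohort_summary <- function(vectors) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    if (!length(vectors)) stop("empty cohort: no spatial feature vectors")
    m <- do.call(rbind, lapply(vectors, unclass))
  } else {
    m <- as.matrix(vectors)
    if (!nrow(m)) stop("empty cohort: no spatial feature vectors")
  }
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  data.frame(structure = colnames(m), mean = mu, sd = sd_pop, n = nrow(m),
             mean_sd = sprintf("%.3f ± %.3f", mu, sd_pop),
             row.names = NULL)
}
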
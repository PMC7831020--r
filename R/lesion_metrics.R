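#' Label connected lesion components
#'
#' Separates a binary lesion mask into maximal connected components, the
#' step that turns a patient's segmentation into individual metastases.
#' Connectivity follows the usual 3-D neighborhood definitions: 6 (faces),
#' 18 (faces + edges) or 26 (faces + edges + corners, the MATLAB
#' `bwlabeln` default). Components are numbered 1..K consecutively.
#'
#' @param mask [lesion_mask()].
#' @param connectivity 6, 18 or 26. Default 26.
#' @return An object of class `labeled_lesions`: list with `labels` (3-D
#'   integer array), `n_components`, `grid`, `connectivity`, `patient_id`.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  labels <- .label_components_cpp(as.integer(mask$data),
                                  mask$grid$shape, as.integer(connectivity))
  k <- attr(labels, "n_components")
  attr(labels, "n_components") <- NULL
  structure(list(grid = mask$grid, labels = labels,
                 n_components = k, connectivity = as.integer(connectivity),
                 patient_id = mask$patient_id),
            class = "labeled_lesions")
}

#' @export
print.labeled_lesions <- function(x, ...) {
  cat(sprintf("labeled_lesions [%s]: %d components (connectivity %d)\n",
              x$patient_id, x$n_components, x$connectivity))
  invisible(x)
}

# 0-based voxel coordinates of voxels with the given label, as an n x 3 matrix
label_coords <- function(labels, value) {
  idx <- which(labels == value, arr.ind = TRUE)
  idx - 1
}

#' Centroid of one labeled lesion
#'
#' Unweighted mean of the member voxel coordinates, in 0-based voxel index
#' space.
#'
#' @param labeled `labeled_lesions`.
#' @param lesion_id component label in 1..K.
#' @return numeric length-3 coordinate.
#' @export
lesion_centroid <- function(labeled, lesion_id) {
  stopifnot(inherits(labeled, "labeled_lesions"))
  if (length(lesion_id) != 1L || lesion_id < 1L ||
      lesion_id > labeled$n_components)
    stop("unknown lesion_id: ", lesion_id)
  unname(colMeans(label_coords(labeled$labels, lesion_id)))
}

#' Assign a centroid to an atlas region
#'
#' The centroid is mapped to its nearest voxel (fractional .5 rounded toward
#' the lower index) and takes that voxel's region. If that voxel is
#' background, the nearest labeled voxel by Euclidean distance wins; ties are
#' broken deterministically toward the lowest region_id, then the lowest
#' linear index.
#'
#' @param centroid length-3 coordinate in 0-based voxel space.
#' @param atlas `region_atlas`.
#' @return list with `region_id`, `laterality`, `compartment`.
#' @export
assign_region <- function(centroid, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  shape <- atlas$grid$shape
  if (length(centroid) != 3L || any(centroid < -0.5) ||
      any(centroid > shape - 0.5))
    stop("centroid outside grid bounds")
  vox <- pmin(pmax(ceiling(centroid - 0.5), 0L), shape - 1L)
  lab <- atlas$labels[vox[1] + 1L, vox[2] + 1L, vox[3] + 1L]
  if (lab == 0L) {
    fg <- which(atlas$labels > 0L)
    coords <- arrayInd(fg, shape) - 1
    d2 <- (coords[, 1] - centroid[1])^2 + (coords[, 2] - centroid[2])^2 +
      (coords[, 3] - centroid[3])^2
    cand <- which(d2 <= min(d2) + 1e-9)
    cand_lab <- atlas$labels[fg[cand]]
    cand <- cand[order(cand_lab, fg[cand])]
    lab <- atlas$labels[fg[cand[1]]]
  }
  row <- atlas$regions[match(lab, atlas$regions$region_id), ]
  list(region_id = row$region_id, laterality = row$laterality,
       compartment = row$compartment)
}

#' Per-lesion records for one patient
#'
#' Combines labeling, centroid computation and region assignment into the
#' lesion table: one row per connected component with its voxel count,
#' normalized volume (voxel count x voxel volume), centroid and assigned
#' region.
#'
#' @param labeled `labeled_lesions`.
#' @param atlas `region_atlas` on the same grid.
#' @return data.frame with columns patient_id, lesion_id, voxel_count,
#'   volume_mm3, cx, cy, cz, region_id, laterality, compartment.
#' @export
lesion_table <- function(labeled, atlas) {
  stopifnot(inherits(labeled, "labeled_lesions"),
            inherits(atlas, "region_atlas"))
  if (!same_grid(labeled$grid, atlas$grid))
    stop_grid_mismatch(labeled$grid$shape, atlas$grid$shape)
  k <- labeled$n_components
  if (k == 0L)
    return(data.frame(patient_id = character(), lesion_id = integer(),
                      voxel_count = integer(), volume_mm3 = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      region_id = integer(), laterality = character(),
                      compartment = character()))
  fg <- which(labeled$labels > 0L)
  labs <- labeled$labels[fg]
  coords <- arrayInd(fg, labeled$grid$shape) - 1
  counts <- tabulate(labs, nbins = k)
  cx <- rowsum(coords[, 1], labs)[, 1] / counts
  cy <- rowsum(coords[, 2], labs)[, 1] / counts
  cz <- rowsum(coords[, 3], labs)[, 1] / counts
  assign <- lapply(seq_len(k), function(i)
    assign_region(c(cx[i], cy[i], cz[i]), atlas))
  data.frame(
    patient_id = labeled$patient_id,
    lesion_id = seq_len(k),
    voxel_count = counts,
    volume_mm3 = counts * labeled$grid$voxel_volume,
    cx = cx, cy = cy, cz = cz,
    region_id = vapply(assign, `[[`, integer(1), "region_id"),
    laterality = vapply(assign, `[[`, character(1), "laterality"),
    compartment = vapply(assign, `[[`, character(1), "compartment"),
    stringsAsFactors = FALSE)
}

number_group_of <- function(n) {
  factor(ifelse(n >= 3, "3+", as.character(n)), levels = c("1", "2", "3+"))
}

#' Summarize one patient's lesion records
#'
#' Aggregates a patient's lesion rows into lesion number, number group
#' (1 / 2 / 3+), total volume (TV), mean volume of a single lesion (VSL =
#' TV / number) and infratentorial involvement (true when at least one
#' lesion sits in an infratentorial region).
#'
#' @param records lesion-table rows of a single patient.
#' @return one-row data.frame: patient_id, n_lesions, number_group, tv_mm3,
#'   vsl_mm3, infratentorial_involvement.
#' @export
summarize_patient <- function(records) {
  if (nrow(records) == 0L) stop("no lesion records supplied")
  if (length(unique(records$patient_id)) != 1L)
    stop("records must all belong to one patient")
  n <- nrow(records)
  tv <- sum(records$volume_mm3)
  data.frame(
    patient_id = records$patient_id[1],
    n_lesions = n,
    number_group = number_group_of(n),
    tv_mm3 = tv,
    vsl_mm3 = tv / n,
    infratentorial_involvement = any(records$compartment == "infratentorial"),
    stringsAsFactors = FALSE)
}

#' Summarize every patient in a cohort lesion table
#'
#' @param lesion_df lesion table (rows from [lesion_table()] for all
#'   patients).
#' @return data.frame, one row per patient, as in [summarize_patient()].
#' @export
summarize_cohort <- function(lesion_df) {
  if (nrow(lesion_df) == 0L) stop("no lesion records supplied")
  out <- do.call(rbind, lapply(split(lesion_df, lesion_df$patient_id),
                               summarize_patient))
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

#' Region-wise lesion burden
#'
#' Number of lesions, number of affected patients, total volume and mean
#' single-lesion volume per atlas region.
#'
#' @param lesion_df cohort lesion table.
#' @param atlas `region_atlas`; regions without lesions appear with zeros.
#' @return data.frame per region.
#' @export
region_summary <- function(lesion_df, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  out <- atlas$regions[, c("region_id", "name", "laterality", "compartment",
                           "volume_mm3")]
  out$n_lesions <- 0L
  out$n_patients <- 0L
  out$tv_mm3 <- 0
  out$vsl_mm3 <- NA_real_
  if (nrow(lesion_df)) {
    by_region <- split(lesion_df, lesion_df$region_id)
    for (rid in names(by_region)) {
      i <- match(as.integer(rid), out$region_id)
      rows <- by_region[[rid]]
      out$n_lesions[i] <- nrow(rows)
      out$n_patients[i] <- length(unique(rows$patient_id))
      out$tv_mm3[i] <- sum(rows$volume_mm3)
      out$vsl_mm3[i] <- mean(rows$volume_mm3)
    }
  }
  out
}
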
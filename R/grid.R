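#' Template grid specification
#'
#' A `grid_spec` describes the shared voxel grid every cohort volume must
#' live on: the array shape, the physical volume of one voxel, and a 4x4
#' voxel-to-world affine. Voxel indices are 0-based throughout the package;
#' world coordinates are obtained through the affine when one is supplied.
#'
#' The default voxel volume is 0.08 mm^3, the constant used when converting
#' voxel counts of normalized lesions to volumes; it is configurable because
#' it depends entirely on the template resolution.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_volume physical volume of a single voxel in mm^3 (> 0).
#' @param affine 4x4 voxel-to-world transform; identity for toy grids.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(24, 24, 24))
#' g$voxel_volume
#' @export
grid_spec <- function(shape, voxel_volume = 0.08, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be three integers >= 1")
  if (!is.numeric(voxel_volume) || length(voxel_volume) != 1L ||
      is.na(voxel_volume) || voxel_volume <= 0)
    stop("voxel_volume must be a positive scalar")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  structure(list(shape = shape, voxel_volume = voxel_volume, affine = affine),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, %.4g mm^3/voxel\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_volume))
  invisible(x)
}

#' Test whether two grids are compatible
#'
#' Grids are compatible when shapes are identical and affines agree within a
#' small tolerance. Voxel volume is carried metadata, not a compatibility
#' criterion.
#'
#' @param a,b `grid_spec` objects.
#' @param tol absolute tolerance on affine entries.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) < tol)
}

stop_grid_mismatch <- function(found, expected) {
  stop(sprintf("grid mismatch: volume has shape (%s) but expected (%s)",
               paste(found, collapse = ","),
               paste(expected, collapse = ",")), call. = FALSE)
}

#' Per-patient binary lesion mask
#'
#' @param data 3-D array; any positive value marks lesion (binarized at > 0).
#' @param grid `grid_spec` the mask lives on; data dimensions must match.
#' @param patient_id identifier.
#' @return An object of class `lesion_mask` with integer 0/1 `data`.
#' @export
lesion_mask <- function(data, grid, patient_id = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"))
  d <- dim(data)
  if (is.null(d) || length(d) != 3L || !identical(as.integer(d), grid$shape))
    stop_grid_mismatch(if (is.null(d)) length(data) else d, grid$shape)
  bin <- array(as.integer(data > 0), dim = grid$shape)
  structure(list(grid = grid, data = bin,
                 patient_id = as.character(patient_id)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("lesion_mask [%s]: %d foreground voxels on %d x %d x %d grid\n",
              x$patient_id, sum(x$data),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Labeled region atlas
#'
#' An integer parcellation of the template grid (0 = background) together
#' with per-region metadata: name, laterality (left/right/midline) and
#' tentorial compartment (supratentorial/infratentorial). Region volumes in
#' mm^3 are computed from label voxel counts and the grid's voxel volume.
#'
#' @param labels 3-D integer array of region labels, 0 for background.
#' @param grid `grid_spec`.
#' @param regions data.frame with columns `region_id`, `name`, `laterality`,
#'   `compartment`; one row per region, `region_id` unique and positive.
#' @return An object of class `region_atlas`; `regions` gains a
#'   `volume_mm3` column.
#' @export
region_atlas <- function(labels, grid, regions) {
  stopifnot(inherits(grid, "grid_spec"), is.data.frame(regions))
  d <- dim(labels)
  if (is.null(d) || !identical(as.integer(d), grid$shape))
    stop_grid_mismatch(d, grid$shape)
  labels <- array(as.integer(labels), dim = grid$shape)
  need <- c("region_id", "name", "laterality", "compartment")
  if (!all(need %in% names(regions)))
    stop("regions must have columns: ", paste(need, collapse = ", "))
  if (nrow(regions) < 1L)
    stop("atlas must define at least one region")
  regions$region_id <- as.integer(regions$region_id)
  if (anyDuplicated(regions$region_id) || any(regions$region_id <= 0L))
    stop("region_id values must be unique positive integers")
  if (!all(regions$laterality %in% c("left", "right", "midline")))
    stop("laterality must be left, right or midline")
  if (!all(regions$compartment %in% c("supratentorial", "infratentorial")))
    stop("compartment must be supratentorial or infratentorial")
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) == 0L)
    stop("atlas must define at least one region (all labels are background)")
  missing <- setdiff(present, regions$region_id)
  if (length(missing))
    stop("labels present in volume but not in region table: ",
         paste(missing, collapse = ", "))
  counts <- tabulate(labels[labels > 0L], nbins = max(regions$region_id))
  regions$volume_mm3 <- counts[regions$region_id] * grid$voxel_volume
  rownames(regions) <- NULL
  structure(list(grid = grid, labels = labels, regions = regions),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf(
    "region_atlas: %d regions, %d labeled voxels on %d x %d x %d grid\n",
    nrow(x$regions), sum(x$labels > 0L),
    x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Region volumes of an atlas
#'
#' Volume of each region is its label voxel count times the grid voxel
#' volume; these are the V_x denominators of the relative metastatic risk.
#'
#' @param atlas `region_atlas`.
#' @return data.frame with `region_id` and `volume_mm3`.
#' @export
atlas_region_volumes <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  atlas$regions[, c("region_id", "volume_mm3")]
}
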
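#' Read a lesion mask from a NIfTI volume
#'
#' Reads a template-space volume and binarizes it at > 0. When
#' `expected_grid` is supplied the file's shape and affine must match it and
#' the returned mask adopts that grid (including its voxel volume), which is
#' how cohort-wide grid compatibility is enforced.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param expected_grid optional `grid_spec` the volume must match.
#' @param patient_id identifier attached to the mask; defaults to the file
#'   name without extension.
#' @param voxel_volume optional override of the voxel volume in mm^3; by
#'   default the product of the header pixel dimensions.
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path, expected_grid = NULL, patient_id = NULL,
                      voxel_volume = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(arr)), " dimensions")
  grid <- grid_from_nifti(img, dim(arr), voxel_volume)
  if (!is.null(expected_grid)) {
    stopifnot(inherits(expected_grid, "grid_spec"))
    if (!identical(grid$shape, expected_grid$shape))
      stop_grid_mismatch(grid$shape, expected_grid$shape)
    if (!all(abs(grid$affine - expected_grid$affine) < 1e-4))
      stop("grid mismatch: volume affine differs from the expected grid")
    grid <- expected_grid
  }
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_mask(arr, grid, patient_id)
}

grid_from_nifti <- function(img, shape, voxel_volume = NULL) {
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) diag(4))
  aff <- matrix(as.numeric(aff)[1:16], 4, 4)
  if (is.null(voxel_volume)) {
    pd <- RNifti::pixdim(img)[seq_len(3)]
    pd[!is.finite(pd) | pd == 0] <- 1
    voxel_volume <- prod(abs(pd))
  }
  grid_spec(shape, voxel_volume = voxel_volume, affine = aff)
}

#' Write a scalar map as a NIfTI volume
#'
#' Used to export frequency maps, p-value maps and direction maps. The
#' volume must have exactly the grid's shape; the grid affine is written as
#' the sform.
#'
#' @param volume 3-D numeric array.
#' @param grid `grid_spec`.
#' @param path output file (.nii or .nii.gz).
#' @param datatype NIfTI storage type, e.g. "double" or "uint8".
#' @return `path`, invisibly.
#' @export
write_map <- function(volume, grid, path, datatype = "double") {
  stopifnot(inherits(grid, "grid_spec"))
  d <- dim(volume)
  if (is.null(d) || !identical(as.integer(d), grid$shape))
    stop_grid_mismatch(d, grid$shape)
  if (!dir.exists(dirname(path)))
    stop("cannot write volume: directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(array(as.numeric(volume), dim = grid$shape))
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a scalar map written by [write_map()]
#'
#' @param path NIfTI file.
#' @param expected_grid optional `grid_spec` to validate against.
#' @return list with `data` (3-D array) and `grid`.
#' @export
read_map <- function(path, expected_grid = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  grid <- grid_from_nifti(img, dim(arr))
  if (!is.null(expected_grid)) {
    if (!identical(grid$shape, expected_grid$shape))
      stop_grid_mismatch(grid$shape, expected_grid$shape)
    grid <- expected_grid
  }
  list(data = arr, grid = grid)
}

#' Write an atlas as a label volume plus a region metadata table
#'
#' The label image goes to `nii_path`; region metadata (region_id, name,
#' laterality, compartment) to a tab-separated sidecar at `tsv_path`.
#'
#' @param atlas `region_atlas`.
#' @param nii_path NIfTI output path for the integer label volume.
#' @param tsv_path output path of the region table.
#' @return `nii_path`, invisibly.
#' @export
write_atlas <- function(atlas, nii_path, tsv_path) {
  stopifnot(inherits(atlas, "region_atlas"))
  write_map(atlas$labels, atlas$grid, nii_path, datatype = "int16")
  utils::write.table(
    atlas$regions[, c("region_id", "name", "laterality", "compartment")],
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nii_path)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param nii_path label volume.
#' @param tsv_path region metadata table.
#' @param voxel_volume optional voxel-volume override in mm^3.
#' @return A [region_atlas()].
#' @export
read_atlas <- function(nii_path, tsv_path, voxel_volume = NULL) {
  img <- RNifti::readNifti(nii_path)
  arr <- as.array(img)
  grid <- grid_from_nifti(img, dim(arr), voxel_volume)
  regions <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  region_atlas(arr, grid, regions)
}
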
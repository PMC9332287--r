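#' Write a binary organ mask to disk
#'
#' Masks are serialized as NIfTI rasters (0/1 voxels) with a JSON sidecar
#' carrying the organ label and the voxel geometry, so the roundtrip through
#' [read_mask()] is lossless for both the boolean volume and the label.
#'
#' @param mask A [binary_mask()].
#' @param path Output file name ending in `.nii` or `.nii.gz`; the sidecar is
#'   written next to it with extension `.json`.
#' @param spacing,slice_thickness Voxel geometry in mm, recorded in the NIfTI
#'   header and the sidecar.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1), slice_thickness = 3) {
  if (!inherits(mask, "binary_mask")) stop_atvseg("`mask` must be a binary_mask")
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop_atvseg("`path` must end in .nii or .nii.gz")
  }
  img <- array(as.integer(mask$voxels), dim(mask$voxels))
  RNifti::writeNifti(
    RNifti::asNifti(img, pixdim = c(spacing[2], spacing[1], slice_thickness)),
    path
  )
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(label = mask$label, shape = dim(mask$voxels),
         spacing = as.numeric(spacing),
         slice_thickness = as.numeric(slice_thickness)),
    sidecar, auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a binary organ mask from disk
#'
#' @param path A `.nii`/`.nii.gz` file written by [write_mask()] (any NIfTI
#'   raster with 0/1 values works; the label then falls back to the file
#'   name unless a sidecar is present).
#' @param geometry Optional reference geometry the mask must match: a
#'   [ct_volume()], a [binary_mask()], or an integer dim vector. A mismatch
#'   is an error reporting both shapes.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, geometry = NULL) {
  if (!file.exists(path)) stop_atvseg("no such file: ", path)
  img <- RNifti::readNifti(path)
  vox <- array(as.array(img) != 0, dim(img))
  if (length(dim(vox)) == 2L) vox <- array(vox, c(dim(vox), 1L))
  label <- sub("\\.nii(\\.gz)?$", "", basename(path))
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$label)) label <- meta$label
  }
  mask <- binary_mask(vox, label)
  if (!is.null(geometry)) {
    ref_dim <- if (inherits(geometry, "ct_volume")) dim(geometry$data)
               else if (inherits(geometry, "binary_mask")) dim(geometry$voxels)
               else as.integer(geometry)
    check_congruent(mask$voxels, array(NA, ref_dim), what = "mask")
  }
  mask
}
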
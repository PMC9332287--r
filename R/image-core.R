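#' CT image slice
#'
#' A single axial CT slice: a rectangular grid of Hounsfield-unit (HU) values
#' together with its in-plane pixel spacing. Pixels are stored as a numeric
#' matrix whose rows run along y (the row direction) and columns along x, so
#' the voxel at 0-based position (x, y) is `pixels[y + 1, x + 1]`. Values are
#' kept in floating point because the denoiser's gradient-descent update
#' produces non-integer HU.
#'
#' @param pixels Numeric matrix of HU values.
#' @param spacing Numeric length-2 vector `(dx, dy)`, pixel spacing in mm;
#'   both entries must be positive.
#' @param index Integer position of the slice in its stack (1-based).
#' @return An object of class `ct_slice` with fields `pixels`, `spacing`,
#'   `index`.
#' @examples
#' s <- ct_slice(matrix(0, 8, 8), spacing = c(0.97, 0.97))
#' dim(s$pixels)
#' @export
ct_slice <- function(pixels, spacing = c(1, 1), index = 1L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_atvseg("`pixels` must be a numeric matrix")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_atvseg("`spacing` must be two positive numbers (dx, dy) in mm")
  }
  structure(
    list(pixels = pixels, spacing = spacing, index = as.integer(index)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf(
    "<ct_slice> %d x %d px, spacing %.3f x %.3f mm, index %d, HU range [%.1f, %.1f]\n",
    nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2], x$index,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

# accept either a ct_slice or a bare matrix in the math routines
pixel_matrix <- function(x) {
  if (inherits(x, "ct_slice")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop_atvseg("expected a ct_slice or a numeric matrix")
}

#' CT image volume
#'
#' An ordered stack of axial slices sharing one in-plane geometry, stored as a
#' 3D numeric array `[y, x, z]` of HU values with pixel spacing and slice
#' thickness in mm. Free-form acquisition metadata (kVp, scanner, ...) ride
#' along in `metadata`.
#'
#' @param data 3D numeric array `[y, x, z]` of HU values, or a list of
#'   `ct_slice` objects with identical shape and spacing.
#' @param spacing In-plane spacing `(dx, dy)` mm (ignored when `data` is a
#'   list of slices, which carry their own).
#' @param slice_thickness Through-plane thickness in mm.
#' @param metadata Named list of free-form acquisition descriptors.
#' @return An object of class `ct_volume` with fields `data`, `spacing`,
#'   `slice_thickness`, `metadata`.
#' @examples
#' v <- ct_volume(array(0, c(16, 16, 3)), spacing = c(1, 1), slice_thickness = 3)
#' n_slices(v)
#' @export
ct_volume <- function(data, spacing = c(1, 1), slice_thickness = 3,
                      metadata = list()) {
  if (is.list(data) && !is.array(data)) {
    if (length(data) == 0L) stop_atvseg("volume needs at least one slice")
    if (!all(vapply(data, inherits, logical(1), "ct_slice"))) {
      stop_atvseg("list input must contain ct_slice objects")
    }
    shp <- vapply(data, function(s) dim(s$pixels), integer(2))
    if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
      stop_atvseg("all slices must share an identical shape")
    }
    sp <- vapply(data, function(s) s$spacing, numeric(2))
    if (any(abs(sp - sp[, 1]) > 1e-9)) {
      stop_atvseg("all slices must share identical spacing")
    }
    spacing <- data[[1]]$spacing
    data <- array(unlist(lapply(data, `[[`, "pixels")),
                  c(shp[1, 1], shp[2, 1], length(data)))
  }
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data)) {
    stop_atvseg("`data` must be a numeric 3D array [y, x, z]")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0)) {
    stop_atvseg("`spacing` must be two positive numbers (dx, dy) in mm")
  }
  if (!is_number(slice_thickness) || slice_thickness <= 0) {
    stop_atvseg("`slice_thickness` must be a positive number (mm)")
  }
  structure(
    list(data = data, spacing = spacing,
         slice_thickness = as.numeric(slice_thickness), metadata = metadata),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ct_volume> %d x %d px x %d slices, spacing %.3f x %.3f mm, thickness %.1f mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$slice_thickness
  ))
  invisible(x)
}

#' @rdname ct_volume
#' @param volume A `ct_volume`.
#' @export
n_slices <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  dim(volume$data)[3]
}

#' Extract one slice of a volume
#'
#' @param volume A `ct_volume`.
#' @param i Slice index (1-based).
#' @return A `ct_slice`.
#' @export
get_slice <- function(volume, i) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is_count(i, 1L) || i > n_slices(volume)) {
    stop_atvseg("slice index out of range")
  }
  ct_slice(volume$data[, , i], spacing = volume$spacing, index = as.integer(i))
}

#' Binary organ mask
#'
#' A boolean voxel volume congruent with a CT volume, labelled with the organ
#' it delineates. Masks are the operands of [dice()].
#'
#' @param voxels Logical 3D array `[y, x, z]`.
#' @param label Organ name (e.g. `"heart"`, `"liver"`, or arbitrary).
#' @return An object of class `binary_mask`.
#' @examples
#' m <- binary_mask(array(c(TRUE, FALSE), c(4, 4, 2)), "liver")
#' sum(m$voxels)
#' @export
binary_mask <- function(voxels, label = "organ") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels)) {
    stop_atvseg("`voxels` must be a logical 3D array [y, x, z]")
  }
  if (!is.character(label) || length(label) != 1L) {
    stop_atvseg("`label` must be a single string")
  }
  structure(list(voxels = voxels, label = label), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> '%s': %d of %d voxels set (%d x %d x %d)\n",
              x$label, sum(x$voxels), length(x$voxels), d[1], d[2], d[3]))
  invisible(x)
}

check_congruent <- function(a, b, what = "mask") {
  da <- dim(a)
  db <- dim(b)
  if (length(da) != length(db) || any(da != db)) {
    stop_atvseg(sprintf(
      "%s geometry mismatch: %s vs %s", what,
      paste(da, collapse = "x"), paste(db, collapse = "x")
    ))
  }
  invisible(TRUE)
}
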
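# 3D connected components (26-connectivity) by vectorised minimum-label
# propagation with pointer jumping; returns an integer array of component
# ids (0 = background)
label_components_26 <- function(mask) {
  d <- dim(mask)
  n <- length(mask)
  lab <- array(0L, d)
  lab[mask] <- which(mask)
  offsets <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offsets <- offsets[!(offsets$di == 0 & offsets$dj == 0 & offsets$dk == 0), ]
  repeat {
    prev <- lab
    for (r in seq_len(nrow(offsets))) {
      nb <- shift_array3(lab, offsets$di[r], offsets$dj[r], offsets$dk[r],
                         fill = 0L)
      upd <- mask & nb > 0L & nb < lab
      lab[upd] <- nb[upd]
    }
    # pointer jumping: follow labels to their current roots
    v <- as.vector(lab)
    nz <- which(v > 0L)
    repeat {
      w <- v
      w[nz] <- v[v[nz]]
      if (identical(w, v)) break
      v <- w
    }
    lab <- array(v, d)
    if (identical(lab, prev)) break
  }
  lab
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components_26(mask)
  ids <- lab[lab > 0L]
  counts <- tabulate(ids, nbins = max(ids))
  keep <- which.max(counts)
  lab == keep
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(di = -r:r, dj = -r:r, dk = -r:r)
  g[g$di^2 + g$dj^2 + g$dk^2 <= radius^2, , drop = FALSE]
}

morph_3d <- function(mask, offsets, op) {
  out <- if (op == "dilate") array(FALSE, dim(mask)) else array(TRUE, dim(mask))
  for (r in seq_len(nrow(offsets))) {
    nb <- shift_array3(mask, offsets$di[r], offsets$dj[r], offsets$dk[r],
                       fill = (op != "dilate"))
    out <- if (op == "dilate") out | nb else out & nb
  }
  out
}

closing_3d <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- ball_offsets(radius)
  morph_3d(morph_3d(mask, off, "dilate"), off, "erode")
}

#' Segmenter configuration
#'
#' Settings for the intensity-window reference segmenter: a per-organ HU
#' window, a morphological closing radius, and the connected-component
#' rule. This deliberately simple segmenter is held fixed across
#' comparisons so that the only varying factor is the input image (raw vs
#' denoised).
#'
#' @param windows Data frame with columns `organ`, `low`, `high` (HU window
#'   bounds, `low < high`; voxels with `low <= HU <= high` are candidates).
#' @param morphology_radius Closing radius in voxels applied after
#'   component selection (0 disables morphology).
#' @param component_rule Currently `"largest"`: keep the largest
#'   26-connected component of the thresholded set.
#' @return An object of class `segmenter_config`.
#' @seealso [default_segmenter_config()]
#' @export
segmenter_config <- function(windows, morphology_radius = 1,
                             component_rule = "largest") {
  windows <- tibble::as_tibble(windows)
  if (!all(c("organ", "low", "high") %in% names(windows))) {
    stop_atvseg("`windows` needs columns organ, low, high")
  }
  if (any(windows$low >= windows$high)) {
    bad <- windows$organ[windows$low >= windows$high][1]
    stop_atvseg("window for organ '", bad, "' must satisfy low < high")
  }
  if (!is_number(morphology_radius) || morphology_radius < 0) {
    stop_atvseg("`morphology_radius` must be >= 0")
  }
  component_rule <- match.arg(component_rule, "largest")
  structure(
    list(windows = windows, morphology_radius = morphology_radius,
         component_rule = component_rule),
    class = "segmenter_config"
  )
}

#' Default window set for the thorax-default phantom
#'
#' HU windows bracketing each preset organ's mean value without touching
#' its neighbors' means, so the noiseless phantom is recovered exactly.
#'
#' @param morphology_radius Closing radius in voxels (default 1).
#' @return A [segmenter_config()].
#' @export
default_segmenter_config <- function(morphology_radius = 1) {
  segmenter_config(
    tibble::tribble(
      ~organ,        ~low, ~high,
      "lung_right",  -710,  -650,
      "lung_left",   -770,  -715,
      "heart",         43,    49,
      "esophagus",     32,    37,
      "spinal_cord",   38,    42,
      "liver",         51,    61
    ),
    morphology_radius = morphology_radius
  )
}

#' Intensity-window reference segmentation
#'
#' Per organ: threshold the volume to its HU window, keep the largest
#' 26-connected component, then apply morphological closing with the
#' configured radius. Serves as a fixed, deterministic stand-in for a
#' learned segmenter when studying how input-image quality affects
#' segmentation. An organ whose thresholded set is empty yields an empty
#' mask with a warning (not an error).
#'
#' @param volume A [ct_volume()].
#' @param config A [segmenter_config()].
#' @param organs Organs to segment (default: every organ in the window
#'   table; an organ without a window is an error).
#' @return Named list of [binary_mask()] objects.
#' @export
reference_segment <- function(volume, config = default_segmenter_config(),
                              organs = NULL) {
  if (!inherits(volume, "ct_volume")) stop_atvseg("`volume` must be a ct_volume")
  if (!inherits(config, "segmenter_config")) {
    stop_atvseg("`config` must be a segmenter_config")
  }
  if (is.null(organs)) organs <- config$windows$organ
  missing <- setdiff(organs, config$windows$organ)
  if (length(missing) > 0L) {
    stop_atvseg("no HU window configured for organ(s): ",
                paste(missing, collapse = ", "))
  }
  out <- list()
  for (org in organs) {
    w <- config$windows[config$windows$organ == org, ]
    cand <- volume$data >= w$low & volume$data <= w$high
    if (!any(cand)) {
      warning("empty segmentation for organ '", org, "'", call. = FALSE)
      out[[org]] <- binary_mask(cand, org)
      next
    }
    seg <- largest_component(cand)
    seg <- closing_3d(seg, config$morphology_radius)
    out[[org]] <- binary_mask(seg, org)
  }
  out
}
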
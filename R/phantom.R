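#' Parametric CT phantom specification
#'
#' Describes a synthetic non-contrast thorax-like CT volume: ellipsoidal
#' "organs" painted in priority order over a soft-tissue background, plus an
#' additive noise model (white Gaussian, or Gaussian-correlated for a more
#' CT-like texture). Later organs carve earlier ones where they overlap;
#' each organ's ground-truth mask is exactly its painted voxel set.
#'
#' @param shape Integer `(nx, ny, nz)` voxel counts.
#' @param spacing In-plane pixel spacing `(dx, dy)` in mm.
#' @param slice_thickness Through-plane thickness in mm.
#' @param organs Data frame with one row per structure, columns `label`,
#'   `cx, cy, cz` (ellipsoid center, voxels), `ax, ay, az` (semi-axes,
#'   voxels), `hu` (mean HU) and optional `mask` (logical; `FALSE` paints
#'   the structure without exporting a mask, e.g. for bone).
#' @param background_hu Background tissue HU.
#' @param noise List: `model` (`"white"` or `"correlated"`), `sigma` (HU;
#'   0 disables noise), and for `"correlated"` a `kernel_fwhm` in mm.
#' @param seed Integer seed; identical spec (including seed) reproduces a
#'   bit-identical phantom.
#' @return An object of class `phantom_spec`.
#' @seealso [default_thorax_spec()], [build_phantom()]
#' @export
phantom_spec <- function(shape, spacing = c(1, 1), slice_thickness = 3,
                         organs, background_hu = 30,
                         noise = list(model = "white", sigma = 20),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop_atvseg("`shape` must be (nx, ny, nz)")
  }
  organs <- tibble::as_tibble(organs)
  need <- c("label", "cx", "cy", "cz", "ax", "ay", "az", "hu")
  if (!all(need %in% names(organs))) {
    stop_atvseg("`organs` needs columns ", paste(need, collapse = ", "))
  }
  if (!"mask" %in% names(organs)) organs$mask <- TRUE
  noise$model <- match.arg(noise$model, c("white", "correlated"))
  if (is.null(noise$sigma) || noise$sigma < 0) {
    stop_atvseg("`noise$sigma` must be >= 0")
  }
  if (noise$model == "correlated" &&
      (is.null(noise$kernel_fwhm) || noise$kernel_fwhm <= 0)) {
    stop_atvseg("correlated noise needs a positive `kernel_fwhm` (mm)")
  }
  structure(
    list(shape = shape, spacing = as.numeric(spacing),
         slice_thickness = as.numeric(slice_thickness), organs = organs,
         background_hu = background_hu, noise = noise,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

ellipsoid_mask <- function(shape, cx, cy, cz, ax, ay, az) {
  x <- seq_len(shape[1])
  y <- seq_len(shape[2])
  z <- seq_len(shape[3])
  dx2 <- ((x - cx) / ax)^2
  dy2 <- ((y - cy) / ay)^2
  dz2 <- ((z - cz) / az)^2
  # [y, x, z] layout to match ct_volume
  inside <- outer(outer(dy2, dx2, `+`), dz2, `+`) <= 1
  inside
}

correlated_noise_slice <- function(nr, nc, sigma, fwhm_px) {
  white <- matrix(stats::rnorm(nr * nc), nr, nc)
  sd_px <- fwhm_px / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sd_px))
  k1 <- stats::dnorm(-half:half, sd = sd_px)
  kern <- outer(k1, k1)
  kern <- kern / sqrt(sum(kern^2))  # unit L2 norm => output variance sigma^2
  kpad <- matrix(0, nr, nc)
  ki <- ((-half:half) %% nr) + 1L
  kj <- ((-half:half) %% nc) + 1L
  kpad[ki, kj] <- kern
  smooth <- Re(stats::fft(stats::fft(white) * stats::fft(kpad), inverse = TRUE)) /
    (nr * nc)
  sigma * smooth
}

noise_volume <- function(shape, spacing, noise) {
  d <- c(shape[2], shape[1], shape[3])  # [y, x, z]
  if (noise$sigma == 0) return(array(0, d))
  if (noise$model == "white") {
    array(stats::rnorm(prod(d), sd = noise$sigma), d)
  } else {
    fwhm_px <- noise$kernel_fwhm / mean(spacing)
    out <- array(0, d)
    for (k in seq_len(d[3])) {
      out[, , k] <- correlated_noise_slice(d[1], d[2], noise$sigma, fwhm_px)
    }
    out
  }
}

#' Build a phantom bundle from a specification
#'
#' Paints the noiseless piecewise-constant volume, derives the ground-truth
#' organ masks (post-carving voxel sets), and adds the seeded noise
#' realization. Identical spec + seed gives a bit-identical bundle.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_bundle`: `volume` (noisy
#'   [ct_volume()]), `noiseless` ([ct_volume()]), `masks` (named list of
#'   [binary_mask()]), `spec`.
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_atvseg("`spec` must be a phantom_spec")
  d <- c(spec$shape[2], spec$shape[1], spec$shape[3])  # [y, x, z]
  paint <- array(0L, d)  # 0 = background, i = organs row i
  for (i in seq_len(nrow(spec$organs))) {
    o <- spec$organs[i, ]
    inside <- ellipsoid_mask(spec$shape, o$cx, o$cy, o$cz, o$ax, o$ay, o$az)
    paint[inside] <- i
  }
  noiseless <- array(spec$background_hu, d)
  for (i in seq_len(nrow(spec$organs))) {
    sel <- paint == i
    if (!any(sel)) {
      stop_atvseg("organ '", spec$organs$label[i],
                  "' has no voxels after carving by later structures")
    }
    noiseless[sel] <- spec$organs$hu[i]
  }
  masks <- list()
  for (i in seq_len(nrow(spec$organs))) {
    if (!isTRUE(spec$organs$mask[i])) next
    masks[[spec$organs$label[i]]] <-
      binary_mask(paint == i, spec$organs$label[i])
  }
  noise <- withr::with_seed(
    spec$seed,
    noise_volume(spec$shape, spec$spacing, spec$noise)
  )
  mk_vol <- function(a) ct_volume(a, spacing = spec$spacing,
                                  slice_thickness = spec$slice_thickness,
                                  metadata = list(kvp = 120))
  structure(
    list(volume = mk_vol(noiseless + noise), noiseless = mk_vol(noiseless),
         masks = masks, spec = spec),
    class = "phantom_bundle"
  )
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> %s; %d masks (%s); noise %s sigma = %g HU, seed %d\n",
              paste(x$spec$shape, collapse = "x"), length(x$masks),
              paste(names(x$masks), collapse = ", "),
              x$spec$noise$model, x$spec$noise$sigma, x$spec$seed))
  invisible(x)
}

#' Stack of uniform noisy patches
#'
#' Generates `n` independent seeded square patches of constant HU plus
#' noise — the standard input for noise-power-spectrum estimator checks.
#'
#' @param size Side length in pixels (>= 8).
#' @param hu Baseline HU of the patch.
#' @param noise Noise list as in [phantom_spec()].
#' @param seed Integer seed.
#' @param n Number of patches.
#' @param spacing Pixel spacing `(dx, dy)` mm (used by the correlated
#'   model's kernel width).
#' @return List of `n` numeric matrices.
#' @export
uniform_patch_stack <- function(size, hu = 0,
                                noise = list(model = "white", sigma = 20),
                                seed = 1L, n = 1L, spacing = c(1, 1)) {
  if (!is_count(size, 8L)) stop_atvseg("`size` must be an integer >= 8")
  if (!is_count(n, 1L)) stop_atvseg("`n` must be a positive count")
  noise$model <- match.arg(noise$model, c("white", "correlated"))
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      if (noise$sigma == 0) {
        matrix(hu, size, size)
      } else if (noise$model == "white") {
        matrix(hu + stats::rnorm(size * size, sd = noise$sigma), size, size)
      } else {
        fwhm_px <- noise$kernel_fwhm / mean(spacing)
        hu + correlated_noise_slice(size, size, noise$sigma, fwhm_px)
      }
    })
  })
}

#' Default thorax phantom presets
#'
#' The `"thorax-default"` preset is a 128 x 128 x 10 volume at 1 x 1 mm
#' in-plane spacing and 3 mm slice thickness emulating a non-contrast
#' planning CT of the thorax: two air-filled lungs (about -700 HU, given
#' slightly different values so an intensity window can tell them apart),
#' a heart (45 HU) and liver (55 HU) in soft tissue (30 HU background), a
#' deliberately low-contrast esophagus (35 HU, within 10 HU of background),
#' and a spinal cord (40 HU) inside a +700 HU vertebral bone ring (the bone
#' is painted but exports no mask). Six organ masks result.
#'
#' @param preset Preset name; currently `"thorax-default"`.
#' @param sigma White-noise standard deviation in HU (default 20).
#' @param seed Integer seed stored in the spec.
#' @return A [phantom_spec()].
#' @export
default_thorax_spec <- function(preset = "thorax-default", sigma = 20,
                                seed = 1L) {
  known <- c("thorax-default")
  if (!preset %in% known) {
    stop_atvseg("unknown preset '", preset, "'; available: ",
                paste(known, collapse = ", "))
  }
  organs <- tibble::tribble(
    ~label,        ~cx, ~cy,  ~cz, ~ax, ~ay, ~az, ~hu,  ~mask,
    "lung_right",   36,  58,  5.5,  24,  26,   7, -680,  TRUE,
    "lung_left",    92,  58,  5.5,  24,  26,   7, -740,  TRUE,
    "heart",        66,  78,  5.5,  18,  15,   6,   45,  TRUE,
    "esophagus",    64,  48,  5.5,   4,   5,   7,   35,  TRUE,
    "liver",        40,  92,  5.5,  28,  22,   6,   55,  TRUE,
    "bone",         64,  30,  5.5,  10,  10,   7,  700, FALSE,
    "spinal_cord",  64,  30,  5.5,   4,   4,   7,   40,  TRUE
  )
  phantom_spec(
    shape = c(128L, 128L, 10L),
    spacing = c(1, 1),
    slice_thickness = 3,
    organs = organs,
    background_hu = 30,
    noise = list(model = "white", sigma = sigma),
    seed = seed
  )
}

#' Liver ROI set matching the thorax-default preset
#'
#' Three square ROIs inside the liver, each extended over five adjacent
#' slices (15 patches in total) — the uniform-organ NPS measurement
#' protocol.
#'
#' @param size ROI side length in pixels (default 16, which fits inside
#'   the preset's liver on slices 3-7).
#' @return List of three [roi_spec()] objects.
#' @export
default_liver_rois <- function(size = 16L) {
  list(
    roi_spec(center = c(40, 92), size = size, slices = 3:7),
    roi_spec(center = c(32, 86), size = size, slices = 3:7),
    roi_spec(center = c(42, 100), size = size, slices = 3:7)
  )
}
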
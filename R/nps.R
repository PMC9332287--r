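#' Square ROI specification for noise measurements
#'
#' A square region of interest placed at a pixel position and replicated
#' over a range of consecutive slices, following the usual uniform-region
#' protocol for CT noise-power-spectrum estimation (several ROIs in a
#' homogeneous organ, extended over adjacent slices).
#'
#' @param center Pixel coordinates `(x, y)` of the ROI center (1-based,
#'   x = column, y = row).
#' @param size Side length in pixels (even sizes recommended).
#' @param slices Integer vector of slice indices (inclusive range).
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec(center = c(40, 92), size = 16, slices = 3:7)
#' @export
roi_spec <- function(center, size, slices) {
  center <- as.numeric(center)
  if (length(center) != 2L) stop_atvseg("`center` must be (x, y)")
  if (!is_count(size, 2L)) stop_atvseg("`size` must be an integer >= 2")
  slices <- as.integer(slices)
  if (length(slices) < 1L) stop_atvseg("`slices` must be nonempty")
  structure(list(center = center, size = as.integer(size), slices = slices),
            class = "roi_spec")
}

roi_rows_cols <- function(spec) {
  half_lo <- floor((spec$size - 1) / 2)
  x0 <- round(spec$center[1]) - half_lo
  y0 <- round(spec$center[2]) - half_lo
  list(rows = y0:(y0 + spec$size - 1L), cols = x0:(x0 + spec$size - 1L))
}

#' Extract ROI patches from a volume
#'
#' Returns one raw-HU patch per (spec, slice) pair — e.g. 3 ROIs over 5
#' slices yield 15 patches.
#'
#' @param volume A [ct_volume()].
#' @param specs A single [roi_spec()] or a list of them.
#' @return List of numeric matrices (HU).
#' @export
extract_rois <- function(volume, specs) {
  if (!inherits(volume, "ct_volume")) stop_atvseg("`volume` must be a ct_volume")
  if (inherits(specs, "roi_spec")) specs <- list(specs)
  d <- dim(volume$data)
  patches <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    rc <- roi_rows_cols(spec)
    for (k in spec$slices) {
      if (k < 1L || k > d[3] ||
          min(rc$rows) < 1L || max(rc$rows) > d[1] ||
          min(rc$cols) < 1L || max(rc$cols) > d[2]) {
        stop_atvseg(sprintf(
          "ROI %d (center %g,%g size %d) out of bounds on slice %d (volume %dx%dx%d)",
          si, spec$center[1], spec$center[2], spec$size, k, d[1], d[2], d[3]
        ))
      }
      patches[[length(patches) + 1L]] <- volume$data[rc$rows, rc$cols, k]
    }
  }
  patches
}

#' Remove a low-order polynomial trend from a patch
#'
#' Least-squares fits a 2D polynomial of the given order (0 = mean,
#' 1 = plane, 2 = full quadratic) and returns the residual, so slow anatomy
#' or shading gradients do not leak into the noise spectrum.
#'
#' @param patch Square numeric matrix (HU).
#' @param order Polynomial order, 0, 1 or 2 (default 2).
#' @return Residual matrix with (numerically) zero mean.
#' @export
detrend <- function(patch, order = 2L) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch)) {
    stop_atvseg("`patch` must be a square matrix")
  }
  if (!order %in% 0:2) stop_atvseg("`order` must be 0, 1 or 2")
  n <- nrow(patch)
  x <- rep(seq_len(n) - (n + 1) / 2, each = n)   # column coordinate
  y <- rep(seq_len(n) - (n + 1) / 2, times = n)  # row coordinate
  design <- switch(as.character(order),
    "0" = cbind(1),
    "1" = cbind(1, x, y),
    "2" = cbind(1, x, y, x^2, x * y, y^2)
  )
  fit <- stats::.lm.fit(design, as.vector(patch))
  matrix(fit$residuals, n, n)
}

fftshift2 <- function(m) {
  n1 <- nrow(m)
  n2 <- ncol(m)
  i <- c((floor(n1 / 2) + 1L):n1, 1L:floor(n1 / 2))
  j <- c((floor(n2 / 2) + 1L):n2, 1L:floor(n2 / 2))
  m[i, j]
}

fft_freq <- function(n, d) {
  # zero-centered DFT frequencies after fftshift; for even n the extreme
  # (most negative) value is the Nyquist frequency -1/(2d)
  k <- seq_len(n) - 1L
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  sort(k) / (n * d)
}

#' Two-dimensional noise power spectrum
#'
#' Ensemble NPS estimator over detrended ROI patches:
#' \deqn{NPS(f_x, f_y) = \frac{d_x d_y}{N^2}\,
#'   \left\langle |\mathrm{DFT}_{2D}(\mathrm{residual})|^2 \right\rangle}
#' zero-frequency centered, with axes in cycles/mm. Integrating the NPS over
#' both frequency axes recovers the residual pixel variance (Parseval).
#'
#' @param patches List of square residual matrices (same size), e.g.
#'   [detrend()] applied to [extract_rois()] output.
#' @param spacing Pixel spacing `(dx, dy)` in mm.
#' @return An object of class `nps_2d` with fields `values` (HU^2 mm^2
#'   matrix), `freq_x`, `freq_y` (mm^-1), `spacing`, `n_rois_averaged`.
#' @export
nps_2d <- function(patches, spacing = c(1, 1)) {
  if (is.matrix(patches)) patches <- list(patches)
  if (length(patches) == 0L) stop_atvseg("need at least one patch")
  n <- nrow(patches[[1]])
  ok <- vapply(patches, function(p) is.matrix(p) && all(dim(p) == n), logical(1))
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop_atvseg(sprintf("patch %d has size %s, expected %dx%d", bad,
                        paste(dim(patches[[bad]]), collapse = "x"), n, n))
  }
  spacing <- as.numeric(spacing)
  acc <- matrix(0, n, n)
  for (p in patches) acc <- acc + Mod(stats::fft(p))^2
  values <- fftshift2(acc / length(patches)) * spacing[1] * spacing[2] / (n * n)
  structure(
    list(
      values = values,
      freq_x = fft_freq(n, spacing[1]),
      freq_y = fft_freq(n, spacing[2]),
      spacing = spacing,
      n_rois_averaged = length(patches)
    ),
    class = "nps_2d"
  )
}

#' @export
print.nps_2d <- function(x, ...) {
  cat(sprintf(
    "<nps_2d> %dx%d bins from %d ROI(s); Nyquist %.3f mm^-1; total power %.4g HU^2\n",
    nrow(x$values), ncol(x$values), x$n_rois_averaged,
    max(abs(x$freq_x)), sum(x$values) * diff(x$freq_x[1:2]) * diff(x$freq_y[1:2])
  ))
  invisible(x)
}

#' Radial 1D profile of a 2D NPS
#'
#' Averages the 2D NPS over annular bins of radial frequency
#' \eqn{f_r = \sqrt{f_x^2 + f_y^2}}. The DC sample is excluded (it carries
#' detrending residue, not noise). Summaries: `peak_frequency` is the
#' center of the maximal bin, `mean_frequency` the power-weighted mean
#' \eqn{\sum f P(f) / \sum P(f)} over the profile.
#'
#' @param nps An `nps_2d` from [nps_2d()].
#' @param n_bins Number of radial bins (>= 2); default spans the radial
#'   range in steps of the smaller frequency-axis increment.
#' @return An object of class `nps_profile` with fields `freq_bins`
#'   (strictly increasing bin centers, mm^-1), `values` (HU^2 mm^2),
#'   `peak_frequency`, `peak_value`, `mean_frequency`.
#' @export
radial_profile <- function(nps, n_bins = NULL) {
  if (!inherits(nps, "nps_2d")) stop_atvseg("`nps` must be an nps_2d")
  fr <- sqrt(outer(nps$freq_y^2, nps$freq_x^2, `+`))
  rmax <- max(fr)
  step <- min(diff(nps$freq_x[1:2]), diff(nps$freq_y[1:2]))
  if (is.null(n_bins)) n_bins <- max(2L, ceiling(rmax / step))
  if (!is_count(n_bins, 2L)) stop_atvseg("`n_bins` must be an integer >= 2")
  breaks <- seq(0, rmax, length.out = n_bins + 1L)
  keep <- fr > 0  # exclude DC
  bin <- findInterval(fr[keep], breaks, rightmost.closed = TRUE)
  vals <- tapply(nps$values[keep], bin, mean)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  idx <- as.integer(names(vals))
  freq_bins <- centers[idx]
  values <- as.numeric(vals)
  structure(
    list(
      freq_bins = freq_bins,
      values = values,
      peak_frequency = freq_bins[which.max(values)],
      peak_value = max(values),
      mean_frequency = sum(freq_bins * values) / sum(values)
    ),
    class = "nps_profile"
  )
}

#' @export
print.nps_profile <- function(x, ...) {
  cat(sprintf(
    "<nps_profile> %d bins; peak %.4g HU^2mm^2 at %.3f mm^-1; mean frequency %.3f mm^-1\n",
    length(x$freq_bins), x$peak_value, x$peak_frequency, x$mean_frequency
  ))
  invisible(x)
}

#' @rdname radial_profile
#' @param x An `nps_profile`.
#' @param ... Unused.
#' @method tidy nps_profile
#' @export
tidy.nps_profile <- function(x, ...) {
  tibble::tibble(frequency = x$freq_bins, nps = x$values)
}

#' @rdname radial_profile
#' @method glance nps_profile
#' @export
glance.nps_profile <- function(x, ...) {
  tibble::tibble(
    peak_frequency = x$peak_frequency,
    peak_value = x$peak_value,
    mean_frequency = x$mean_frequency,
    n_bins = length(x$freq_bins)
  )
}

#' @rdname radial_profile
#' @param object An `nps_profile`.
#' @method autoplot nps_profile
#' @export
autoplot.nps_profile <- function(object, ...) {
  df <- tidy.nps_profile(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$nps)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mean_frequency, linetype = 2) +
    ggplot2::labs(x = expression(spatial ~ frequency ~ (mm^-1)),
                  y = expression(NPS ~ (HU^2 ~ mm^2)),
                  title = "Radial noise power spectrum",
                  subtitle = sprintf("peak %.3f mm^-1, mean %.3f mm^-1",
                                     object$peak_frequency,
                                     object$mean_frequency)) +
    ggplot2::theme_minimal()
}

#' One-call NPS summary of a volume
#'
#' Convenience wrapper: extract ROIs, detrend each patch, form the ensemble
#' 2D NPS and its radial profile.
#'
#' @inheritParams extract_rois
#' @param detrend_order Polynomial detrending order (0-2, default 2).
#' @param n_bins Passed to [radial_profile()].
#' @return A list with `nps` (`nps_2d`) and `profile` (`nps_profile`).
#' @export
nps_from_volume <- function(volume, specs, detrend_order = 2L, n_bins = NULL) {
  patches <- extract_rois(volume, specs)
  residuals <- lapply(patches, detrend, order = detrend_order)
  nps <- nps_2d(residuals, spacing = volume$spacing)
  list(nps = nps, profile = radial_profile(nps, n_bins))
}
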
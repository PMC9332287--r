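#' Denoiser configuration
#'
#' Bundles every tunable of the anisotropic total-variation (ATV) denoiser.
#' The objective is \deqn{R(V) = \sum_j w_j D(V_j)} where \eqn{D} is the
#' backward-difference gradient magnitude and \eqn{w_j} the sum of
#' conduction-coefficient weights \eqn{\exp[-((V_j - V_m)/\delta)^2]} over
#' the in-bounds 4-neighbors of pixel j. Minimization is by normalized
#' steepest descent \eqn{V^{t+1} = V^t - \lambda \nabla R / |\nabla R|} with
#' an adaptive step \eqn{\lambda} proportional to \eqn{\gamma \sqrt{\sum_j V_j^2}};
#' \eqn{\gamma} starts at `gamma_init` and is multiplied by `gamma_decay`
#' every time the objective increases (the step is kept).
#'
#' @param iterations Number of descent updates (default 20).
#' @param gamma_init Initial scaling parameter \eqn{\gamma} (default 1.0).
#' @param gamma_decay Multiplicative decay applied to \eqn{\gamma} on each
#'   recorded objective increase; in (0, 1), default 0.8.
#' @param delta_quantile Quantile of the per-pixel gradient-magnitude
#'   distribution defining the edge-stopping scale \eqn{\delta}; in (0, 1),
#'   default 0.80.
#' @param sqrt_epsilon Small positive HU value regularizing the
#'   non-differentiable square root of \eqn{D} at zero gradient
#'   (\eqn{D = \sqrt{g_x^2 + g_y^2 + \epsilon^2}}); default 1e-3.
#' @param delta_floor Lower bound on \eqn{\delta} in HU, preventing division
#'   by zero on constant inputs; default 1e-6.
#' @param boundary Out-of-range neighbor convention; only `"replicate"`
#'   (border values repeated, so boundary difference terms vanish).
#' @param weight_refresh `"per_iteration"` recomputes the weights from the
#'   current iterate each step; `"fixed_initial"` keeps the weights of the
#'   input image.
#' @param lambda_norm `"rms"` (default) takes \eqn{\lambda =
#'   \gamma\,\mathrm{scale}\,\sqrt{\sum_j V_j^2}/\sqrt{n}} — i.e. \eqn{\gamma}
#'   times the root-mean-square pixel value — so the update magnitude is
#'   independent of image size; `"sum"` uses the unnormalized
#'   \eqn{\gamma\sqrt{\sum_j V_j^2}} (see the methods vignette for why that
#'   choice diverges on realistic images).
#' @param lambda_scale Extra global multiplier on \eqn{\lambda} (default 1.0).
#' @return An object of class `denoiser_config`.
#' @examples
#' cfg <- denoiser_config()
#' cfg$iterations
#' @export
denoiser_config <- function(iterations = 20L,
                            gamma_init = 1.0,
                            gamma_decay = 0.8,
                            delta_quantile = 0.80,
                            sqrt_epsilon = 1e-3,
                            delta_floor = 1e-6,
                            boundary = "replicate",
                            weight_refresh = c("per_iteration", "fixed_initial"),
                            lambda_norm = c("rms", "sum"),
                            lambda_scale = 1.0) {
  if (!is_count(iterations, 0L)) stop_atvseg("`iterations` must be a count >= 0")
  if (!is_number(gamma_init) || gamma_init <= 0) {
    stop_atvseg("`gamma_init` must be positive")
  }
  if (!is_number(gamma_decay) || gamma_decay <= 0 || gamma_decay >= 1) {
    stop_atvseg("`gamma_decay` must lie in (0, 1)")
  }
  if (!is_number(delta_quantile) || delta_quantile <= 0 || delta_quantile >= 1) {
    stop_atvseg("`delta_quantile` must lie in (0, 1)")
  }
  if (!is_number(sqrt_epsilon) || sqrt_epsilon < 0) {
    stop_atvseg("`sqrt_epsilon` must be >= 0")
  }
  if (!is_number(delta_floor) || delta_floor <= 0) {
    stop_atvseg("`delta_floor` must be positive")
  }
  boundary <- match.arg(boundary, "replicate")
  structure(
    list(
      iterations = as.integer(iterations),
      gamma_init = gamma_init,
      gamma_decay = gamma_decay,
      delta_quantile = delta_quantile,
      sqrt_epsilon = sqrt_epsilon,
      delta_floor = delta_floor,
      boundary = boundary,
      weight_refresh = match.arg(weight_refresh),
      lambda_norm = match.arg(lambda_norm),
      lambda_scale = lambda_scale
    ),
    class = "denoiser_config"
  )
}

# backward differences with replicate boundary: the first column/row
# difference is identically zero because V(-1, y) := V(0, y)
backward_diffs <- function(v) {
  gx <- v - shift_matrix(v, 0L, 1L)  # V(x, y) - V(x - 1, y)
  gx[, 1L] <- 0
  gy <- v - shift_matrix(v, 1L, 0L)  # V(x, y) - V(x, y - 1)
  gy[1L, ] <- 0
  list(gx = gx, gy = gy)
}

#' Backward-difference gradient magnitude
#'
#' The discrete gradient transform \eqn{D(V(x,y)) = \sqrt{(V(x,y) -
#' V(x-1,y))^2 + (V(x,y) - V(x,y-1))^2 + \epsilon^2}} with a replicate
#' border (out-of-range neighbors take the border value, so their difference
#' terms vanish). With `sqrt_epsilon = 0` this is the exact magnitude;
#' a small positive \eqn{\epsilon} keeps the objective differentiable where
#' both differences are zero.
#'
#' @param slice A [ct_slice()] or numeric matrix of HU values.
#' @param sqrt_epsilon Differentiability guard in HU (default 0).
#' @return Matrix of \eqn{D} values (HU), all `>= sqrt_epsilon >= 0`.
#' @examples
#' backward_difference_gradient(matrix(c(0, 0, 0, 100), 2, 2))
#' @export
backward_difference_gradient <- function(slice, sqrt_epsilon = 0) {
  v <- pixel_matrix(slice)
  g <- backward_diffs(v)
  sqrt(g$gx^2 + g$gy^2 + sqrt_epsilon^2)
}

#' Edge-stopping scale from the gradient-magnitude distribution
#'
#' \eqn{\delta} is the value at `quantile` of the empirical cumulative
#' distribution of the per-pixel gradient magnitude of the slice (linear
#' interpolation between order statistics, i.e. [stats::quantile()] type 7).
#' Degenerate (e.g. constant) slices fall back to `delta_floor`.
#'
#' @inheritParams backward_difference_gradient
#' @param quantile Fraction in (0, 1); default 0.80.
#' @param delta_floor Minimum returned value in HU.
#' @return \eqn{\delta} in HU, `>= delta_floor`.
#' @export
estimate_delta <- function(slice, quantile = 0.80, delta_floor = 1e-6) {
  if (!is_number(quantile) || quantile <= 0 || quantile >= 1) {
    stop_atvseg("`quantile` must lie in (0, 1)")
  }
  d <- backward_difference_gradient(slice, sqrt_epsilon = 0)
  q <- stats::quantile(as.vector(d), probs = quantile, names = FALSE, type = 7)
  max(q, delta_floor)
}

#' Anisotropic conduction-coefficient weights
#'
#' Per-pixel weight \eqn{w_j = \sum_{m \in N_j} \exp[-((V_j - V_m)/\delta)^2]}
#' where \eqn{N_j} is the set of in-bounds first-order (4-connected)
#' neighbors: interior pixels have 4, edge pixels 3, corner pixels 2.
#' Neighbors across a strong edge (difference large against \eqn{\delta})
#' contribute almost nothing, so smoothing is suppressed there.
#'
#' @inheritParams backward_difference_gradient
#' @param delta Edge-stopping scale \eqn{\delta} in HU; must be positive.
#' @return Matrix of weights in `(0, |N_j|]`.
#' @export
anisotropic_weights <- function(slice, delta) {
  if (!is_number(delta) || delta <= 0) stop_atvseg("`delta` must be positive")
  v <- pixel_matrix(slice)
  nr <- nrow(v)
  nc <- ncol(v)
  w <- matrix(0, nr, nc)
  for (off in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    nb <- shift_matrix(v, off[1], off[2], fill = NA_real_)
    contrib <- exp(-((v - nb) / delta)^2)
    contrib[is.na(contrib)] <- 0  # out-of-bounds neighbor
    w <- w + contrib
  }
  w
}

#' ATV objective
#'
#' \eqn{R(V) = \sum_j w_j D(V_j)}: the weighted total variation of the
#' slice. Non-negative; zero exactly for constant slices when
#' `sqrt_epsilon = 0`.
#'
#' @inheritParams backward_difference_gradient
#' @param weights Weight matrix congruent with the slice (see
#'   [anisotropic_weights()]).
#' @return The scalar objective value in HU.
#' @export
atv_objective <- function(slice, weights, sqrt_epsilon = 0) {
  v <- pixel_matrix(slice)
  check_congruent(v, weights, what = "weights")
  sum(weights * backward_difference_gradient(v, sqrt_epsilon))
}

#' Gradient of the ATV objective (frozen weights)
#'
#' Analytic \eqn{\partial R / \partial V_j} with the weights treated as
#' constants (the lagged-diffusivity convention): each pixel appears in its
#' own \eqn{D} term and in the backward-difference terms of its forward x-
#' and y-neighbors. The returned gradient is not normalized; its
#' root-sum-square norm (used to normalize the descent update) is returned
#' alongside.
#'
#' @inheritParams atv_objective
#' @param sqrt_epsilon Differentiability guard; with a positive value the
#'   gradient of a constant slice is exactly zero rather than 0/0.
#' @return A list with `gradient` (matrix) and `norm` (scalar,
#'   \eqn{\sqrt{\sum_j (\partial R/\partial V_j)^2}}).
#' @export
atv_objective_gradient <- function(slice, weights, sqrt_epsilon = 1e-3) {
  v <- pixel_matrix(slice)
  check_congruent(v, weights, what = "weights")
  g <- backward_diffs(v)
  d <- sqrt(g$gx^2 + g$gy^2 + sqrt_epsilon^2)
  ratio_x <- ifelse(d > 0, weights * g$gx / d, 0)
  ratio_y <- ifelse(d > 0, weights * g$gy / d, 0)
  grad <- ratio_x + ratio_y
  nc <- ncol(v)
  nr <- nrow(v)
  # V_j also appears (negated) in the backward difference of its forward
  # neighbors (x+1, y) and (x, y+1)
  if (nc > 1L) grad[, -nc] <- grad[, -nc] - ratio_x[, -1L]
  if (nr > 1L) grad[-nr, ] <- grad[-nr, ] - ratio_y[-1L, ]
  list(gradient = grad, norm = sqrt(sum(grad^2)))
}

#' Adaptive step size
#'
#' \eqn{\lambda = \gamma \sqrt{\sum_j V_j^2}} over all pixels of the current
#' slice. This is the raw (unnormalized) form; inside [denoise_slice()] the
#' configured `lambda_norm`/`lambda_scale` are applied on top.
#'
#' @inheritParams backward_difference_gradient
#' @param gamma Current scaling parameter \eqn{\gamma}.
#' @return \eqn{\lambda} in HU.
#' @examples
#' step_size(matrix(3, 2, 2), gamma = 1)  # sqrt(4 * 9) = 6
#' @export
step_size <- function(slice, gamma) {
  v <- pixel_matrix(slice)
  gamma * sqrt(sum(v^2))
}

effective_lambda <- function(v, gamma, config) {
  base <- step_size(v, gamma) * config$lambda_scale
  if (config$lambda_norm == "rms") base / sqrt(length(v)) else base
}

#' Denoise a single CT slice
#'
#' Runs `config$iterations` normalized steepest-descent updates
#' \eqn{V^{t+1} = V^t - \lambda \nabla R(V^t)/|\nabla R(V^t)|} on the slice.
#' \eqn{\delta} is estimated once from the input slice; the weights are
#' refreshed per `config$weight_refresh`; after each update, if the
#' objective increased, \eqn{\gamma} is multiplied by `config$gamma_decay`
#' (the step itself is kept). The loop stops early when the gradient norm
#' is zero (e.g. on constant input).
#'
#' @param slice A [ct_slice()] or numeric HU matrix.
#' @param config A [denoiser_config()].
#' @return A list with `slice` (the denoised slice, same class as the
#'   input's pixel container wrapped as `ct_slice` when one was given) and
#'   `state`, an `atv_state` holding the full objective / \eqn{\lambda} /
#'   \eqn{\gamma} histories plus \eqn{\delta} (see [tidy.atv_state()]).
#' @examples
#' set.seed(1)
#' noisy <- matrix(50 + rnorm(32 * 32, sd = 20), 32, 32)
#' res <- denoise_slice(noisy, denoiser_config(iterations = 5))
#' res$state
#' @export
denoise_slice <- function(slice, config = denoiser_config()) {
  if (!inherits(config, "denoiser_config")) {
    stop_atvseg("`config` must be a denoiser_config")
  }
  was_slice <- inherits(slice, "ct_slice")
  v <- pixel_matrix(slice)

  delta <- estimate_delta(v, config$delta_quantile, config$delta_floor)
  w <- anisotropic_weights(v, delta)
  objective_at <- function(img) {
    wt <- if (config$weight_refresh == "per_iteration") {
      anisotropic_weights(img, delta)
    } else {
      w
    }
    list(r = atv_objective(img, wt, config$sqrt_epsilon), w = wt)
  }

  cur <- objective_at(v)
  gamma <- config$gamma_init
  r_hist <- cur$r
  lambda_hist <- numeric(0)
  gamma_hist <- numeric(0)
  t_done <- 0L

  if (config$iterations > 0L) {
    for (t in seq_len(config$iterations)) {
      gr <- atv_objective_gradient(v, cur$w, config$sqrt_epsilon)
      if (gr$norm == 0) break
      lambda <- effective_lambda(v, gamma, config)
      v <- v - lambda * gr$gradient / gr$norm
      nxt <- objective_at(v)
      if (nxt$r > r_hist[length(r_hist)]) gamma <- gamma * config$gamma_decay
      r_hist <- c(r_hist, nxt$r)
      lambda_hist <- c(lambda_hist, lambda)
      gamma_hist <- c(gamma_hist, gamma)
      cur <- nxt
      t_done <- t
    }
  }

  state <- structure(
    list(
      delta = delta,
      gamma = gamma,
      iteration = t_done,
      objective_history = r_hist,
      lambda_history = lambda_hist,
      gamma_history = gamma_hist,
      config = config
    ),
    class = "atv_state"
  )
  out <- if (was_slice) ct_slice(v, spacing = slice$spacing, index = slice$index) else v
  list(slice = out, state = state)
}

#' @export
print.atv_state <- function(x, ...) {
  cat(sprintf(
    "<atv_state> %d iterations, delta = %.4g HU, R: %.4g -> %.4g, final gamma = %.4g\n",
    x$iteration, x$delta,
    x$objective_history[1], x$objective_history[length(x$objective_history)],
    x$gamma
  ))
  invisible(x)
}

#' Tidy per-iteration denoiser diagnostics
#'
#' @param x An `atv_state` from [denoise_slice()].
#' @param ... Unused.
#' @return A tibble with one row per recorded iterate (iteration 0 is the
#'   input): `iteration`, `objective`, `lambda` (NA at iteration 0),
#'   `gamma`.
#' @method tidy atv_state
#' @export
tidy.atv_state <- function(x, ...) {
  n <- length(x$objective_history)
  tibble::tibble(
    iteration = seq_len(n) - 1L,
    objective = x$objective_history,
    lambda = c(NA_real_, x$lambda_history),
    gamma = c(x$config$gamma_init, x$gamma_history)
  )
}

#' One-row denoiser run summary
#'
#' @inheritParams tidy.atv_state
#' @return A tibble with `iterations`, `delta`, `objective_initial`,
#'   `objective_final`, `objective_ratio`, `n_gamma_decays`, `gamma_final`.
#' @method glance atv_state
#' @export
glance.atv_state <- function(x, ...) {
  r <- x$objective_history
  tibble::tibble(
    iterations = x$iteration,
    delta = x$delta,
    objective_initial = r[1],
    objective_final = r[length(r)],
    objective_ratio = r[length(r)] / r[1],
    n_gamma_decays = sum(diff(c(x$config$gamma_init, x$gamma_history)) < 0),
    gamma_final = x$gamma
  )
}

#' Plot the objective and step-size trajectory of a denoiser run
#'
#' @param object An `atv_state`.
#' @param ... Unused.
#' @return A ggplot: objective (and \eqn{\gamma}) against iteration.
#' @method autoplot atv_state
#' @export
autoplot.atv_state <- function(object, ...) {
  df <- tidy.atv_state(object)
  long <- tidyr::pivot_longer(df, c("objective", "gamma"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "ATV denoiser trajectory") +
    ggplot2::theme_minimal()
}

#' Denoise every slice of a volume
#'
#' Applies [denoise_slice()] independently to each axial slice (the
#' objective and its gradient are defined in 2D).
#'
#' @param volume A [ct_volume()].
#' @param config A [denoiser_config()].
#' @return A list with `volume` (denoised [ct_volume()]) and `states` (list
#'   of per-slice `atv_state` diagnostics).
#' @export
denoise_volume <- function(volume, config = denoiser_config()) {
  if (!inherits(volume, "ct_volume")) stop_atvseg("`volume` must be a ct_volume")
  out <- volume$data
  states <- vector("list", n_slices(volume))
  for (k in seq_len(n_slices(volume))) {
    res <- denoise_slice(out[, , k], config)
    out[, , k] <- res$slice
    states[[k]] <- res$state
  }
  list(
    volume = ct_volume(out, spacing = volume$spacing,
                       slice_thickness = volume$slice_thickness,
                       metadata = volume$metadata),
    states = states
  )
}

#' Export denoiser diagnostics as CSV
#'
#' Writes the per-iteration table of [tidy.atv_state()] (columns iteration,
#' objective, lambda, gamma; plus `slice` when given a list of states).
#'
#' @param states An `atv_state` or list of them (e.g. from
#'   [denoise_volume()]).
#' @param path Output CSV file.
#' @return Invisibly, the written tibble.
#' @export
write_objective_log <- function(states, path) {
  if (inherits(states, "atv_state")) states <- list(states)
  df <- purrr::list_rbind(
    purrr::imap(states, function(s, i) {
      dplyr::mutate(tidy.atv_state(s), slice = i, .before = 1)
    })
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
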
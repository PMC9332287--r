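# independent oracles used across tests

# central finite differences of the ATV objective with frozen weights
fd_objective_gradient <- function(v, w, sqrt_epsilon, h = 1e-4) {
  out <- matrix(0, nrow(v), ncol(v))
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      vp <- v; vp[i, j] <- vp[i, j] + h
      vm <- v; vm[i, j] <- vm[i, j] - h
      out[i, j] <- (atv_objective(vp, w, sqrt_epsilon) -
                      atv_objective(vm, w, sqrt_epsilon)) / (2 * h)
    }
  }
  out
}

# literal enumeration of all 2^n sign assignments of the signed-rank test,
# with the same zero-drop and midrank conventions as paired_wilcoxon()
brute_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14)
  r <- rank(abs(d))
  total <- sum(r)
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  count <- 0L
  for (code in 0:(2^n - 1)) {
    pos <- bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L) == 1L
    wp <- sum(r[pos])
    if (min(wp, total - wp) <= w_obs + 1e-9) count <- count + 1L
  }
  count / 2^n
}

# small two-organ phantom for fast structural tests
tiny_phantom_spec <- function(sigma = 0, seed = 1) {
  phantom_spec(
    shape = c(40L, 40L, 4L),
    spacing = c(1, 1),
    slice_thickness = 3,
    organs = tibble::tribble(
      ~label,  ~cx, ~cy, ~cz, ~ax, ~ay, ~az, ~hu,
      "blob",   14,  20, 2.5,   8,  10,   3, 200,
      "core",   28,  24, 2.5,   5,   5,   3, -300
    ),
    background_hu = 30,
    noise = list(model = "white", sigma = sigma),
    seed = seed
  )
}

tiny_windows <- function(radius = 0) {
  segmenter_config(
    tibble::tibble(organ = c("blob", "core"),
                   low = c(150, -350), high = c(250, -250)),
    morphology_radius = radius
  )
}
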
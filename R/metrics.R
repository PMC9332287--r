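#' Dice similarity coefficient between two masks
#'
#' \deqn{DSC = \frac{2 |A \cap B|}{|A| + |B|}} between two congruent binary
#' volumes, ranging from 0 (disjoint) to 1 (complete overlap). When both
#' masks are empty the coefficient is undefined (0/0) and an error is
#' raised rather than a value returned, so upstream segmentation failures
#' cannot masquerade as perfect agreement.
#'
#' @param a,b [binary_mask()] objects (or logical 3D arrays) with identical
#'   geometry; conventionally `a` is the reference (e.g. manual) volume and
#'   `b` the candidate.
#' @return An object of class `dsc_result`: fields `label`, `value`, and
#'   voxel counts `n_a`, `n_b`, `n_intersection`.
#' @examples
#' m <- array(FALSE, c(4, 4, 2)); m[1:2, 1:2, 1] <- TRUE
#' dice(binary_mask(m, "heart"), binary_mask(m, "heart"))$value  # 1
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "binary_mask")) a$voxels else a
  bv <- if (inherits(b, "binary_mask")) b$voxels else b
  if (!is.logical(av) || !is.logical(bv)) {
    stop_atvseg("`a` and `b` must be binary masks or logical arrays")
  }
  check_congruent(av, bv, what = "mask")
  na <- sum(av)
  nb <- sum(bv)
  if (na + nb == 0L) {
    stop_atvseg("DSC undefined: both masks are empty (0/0)")
  }
  ni <- sum(av & bv)
  label <- if (inherits(a, "binary_mask")) a$label
           else if (inherits(b, "binary_mask")) b$label else "mask"
  structure(
    list(label = label, value = 2 * ni / (na + nb),
         n_a = na, n_b = nb, n_intersection = ni),
    class = "dsc_result"
  )
}

#' @export
print.dsc_result <- function(x, ...) {
  cat(sprintf("<dsc_result> '%s': DSC = %.4f (|A| = %d, |B| = %d, |A&B| = %d)\n",
              x$label, x$value, x$n_a, x$n_b, x$n_intersection))
  invisible(x)
}

# exact null distribution of the positive signed-rank sum for given
# midranks, by shift convolution over doubled (integer) ranks; equivalent
# to enumerating all 2^n sign assignments
signed_rank_distribution <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1] <- 1
  for (s in ranks2) {
    g <- f
    g[(s + 1L):(total + 1L)] <- g[(s + 1L):(total + 1L)] + f[1:(total + 1L - s)]
    f <- g
  }
  f / sum(f)  # P(2 * W+ = 0 .. total)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided matched-pairs signed-rank test. Differences `x - y` equal to
#' zero are discarded (the classical convention); absolute differences are
#' ranked with midranks for ties; the statistic is the smaller of the
#' positive and negative rank sums. For `n_effective <= exact_threshold`
#' the p-value is exact over all `2^n` sign assignments
#' (`p = P(min(W+, W-) <= observed)` under the null); beyond that a normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used.
#'
#' @param x,y Equal-length numeric vectors of paired scores.
#' @param exact_threshold Largest `n_effective` for which the exact
#'   distribution is enumerated (default 25).
#' @return An object of class `wilcoxon_result`: `statistic` (min rank
#'   sum), `p_value`, `n_effective`, `method` (`"exact"` or
#'   `"normal_approximation"`).
#' @examples
#' paired_wilcoxon(1:6, rep(0, 6))$p_value  # 2/2^6 = 0.03125
#' @export
paired_wilcoxon <- function(x, y, exact_threshold = 25L) {
  if (length(x) != length(y)) stop_atvseg("`x` and `y` must have equal length")
  if (length(x) < 1L) stop_atvseg("need at least one pair")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop_atvseg("all paired differences are zero: no signed-rank test possible")
  }
  r <- rank(abs(d))  # midranks
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  total <- sum(r)

  if (n <= exact_threshold) {
    ranks2 <- as.integer(round(2 * r))
    dist <- signed_rank_distribution(ranks2)  # over 2*W+
    support <- seq_along(dist) - 1L
    w2 <- round(2 * w)
    tot2 <- round(2 * total)
    p <- sum(dist[pmin(support, tot2 - support) <= w2 + 1e-9])
    method <- "exact"
  } else {
    mu <- total / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu + 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal_approximation"
  }
  structure(
    list(statistic = w, p_value = p, n_effective = n, method = method),
    class = "wilcoxon_result"
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf(
    "<wilcoxon_result> W = %g, n = %d, two-sided p = %.5g (%s)\n",
    x$statistic, x$n_effective, x$p_value, x$method
  ))
  invisible(x)
}

#' @rdname paired_wilcoxon
#' @param x A `wilcoxon_result`.
#' @param ... Unused.
#' @method tidy wilcoxon_result
#' @export
tidy.wilcoxon_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_effective = x$n_effective, method = x$method)
}

#' Per-organ DSC comparison table for two methods
#'
#' Summarizes per-case DSC values of two segmentation methods across
#' organs: per-organ per-method averages, the paired Wilcoxon p-value for
#' the method difference, and an acceptability flag (average DSC >= 0.80 is
#' conventionally an acceptable match). When every case has identical
#' values under both methods for an organ, no test is possible and the
#' p-value is `NA` with `note = "no test"`.
#'
#' @param cases Long tibble/data frame with columns `case`, `organ`,
#'   `method`, `dsc`; exactly two methods, every (case, organ, method) cell
#'   present.
#' @param acceptable Averages at or above this flag an organ as acceptable
#'   (default 0.80).
#' @return An object of class `dsc_table`: `summary` (per-organ tibble) and
#'   `cases` (the input, ordered).
#' @export
dsc_table <- function(cases, acceptable = 0.80) {
  cases <- tibble::as_tibble(cases)
  need <- c("case", "organ", "method", "dsc")
  if (!all(need %in% names(cases))) {
    stop_atvseg("`cases` needs columns case, organ, method, dsc")
  }
  methods <- sort(unique(cases$method))
  if (length(methods) != 2L) stop_atvseg("exactly two methods are required")
  full <- tidyr::expand_grid(case = unique(cases$case),
                             organ = unique(cases$organ),
                             method = methods)
  missing <- dplyr::anti_join(full, cases, by = c("case", "organ", "method"))
  if (nrow(missing) > 0L) {
    m <- missing[1, ]
    stop_atvseg(sprintf("missing DSC cell: case '%s', organ '%s', method '%s'",
                        m$case, m$organ, m$method))
  }

  summary <- cases |>
    tidyr::pivot_wider(names_from = "method", values_from = "dsc") |>
    dplyr::group_by(.data$organ) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      mean_a = mean(.data[[methods[1]]]),
      mean_b = mean(.data[[methods[2]]]),
      p_value = tryCatch(
        paired_wilcoxon(.data[[methods[1]]], .data[[methods[2]]])$p_value,
        error = function(e) NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      note = ifelse(is.na(.data$p_value), "no test", ""),
      acceptable_a = .data$mean_a >= acceptable,
      acceptable_b = .data$mean_b >= acceptable
    )
  names(summary)[names(summary) == "mean_a"] <- paste0("mean_", methods[1])
  names(summary)[names(summary) == "mean_b"] <- paste0("mean_", methods[2])
  names(summary)[names(summary) == "acceptable_a"] <-
    paste0("acceptable_", methods[1])
  names(summary)[names(summary) == "acceptable_b"] <-
    paste0("acceptable_", methods[2])

  structure(
    list(summary = summary, methods = methods,
         cases = dplyr::arrange(cases, .data$organ, .data$case, .data$method)),
    class = "dsc_table"
  )
}

#' @export
print.dsc_table <- function(x, ...) {
  cat("<dsc_table> methods:", paste(x$methods, collapse = " vs "), "\n")
  print(x$summary)
  invisible(x)
}

#' @rdname dsc_table
#' @param x A `dsc_table`.
#' @param ... Unused.
#' @method tidy dsc_table
#' @export
tidy.dsc_table <- function(x, ...) x$summary

#' Serialize a DSC table in the organ-by-method layout
#'
#' Writes a CSV with one row per case, one column per organ/method pair,
#' plus `Average` and `p-value` footer rows.
#'
#' @param x A [dsc_table()].
#' @param path Output CSV file.
#' @return Invisibly, the written data frame.
#' @export
write_dsc_table <- function(x, path) {
  if (!inherits(x, "dsc_table")) stop_atvseg("`x` must be a dsc_table")
  wide <- x$cases |>
    dplyr::mutate(col = paste(.data$organ, .data$method, sep = "_")) |>
    dplyr::select("case", "col", "dsc") |>
    tidyr::pivot_wider(names_from = "col", values_from = "dsc")
  avg <- c(case = "Average", colMeans(wide[-1]))
  organs <- unique(x$cases$organ)
  pv <- x$summary$p_value[match(organs, x$summary$organ)]
  prow <- as.list(rep(NA_real_, ncol(wide) - 1L))
  names(prow) <- names(wide)[-1]
  for (i in seq_along(organs)) {
    prow[[paste(organs[i], x$methods[1], sep = "_")]] <- pv[i]
  }
  out <- rbind(
    data.frame(lapply(wide, as.character), check.names = FALSE),
    as.character(c(avg["case"], format(as.numeric(avg[-1]), digits = 6))),
    c("p-value", vapply(prow, function(v) {
      if (is.na(v)) "" else format(v, digits = 6)
    }, character(1)))
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
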
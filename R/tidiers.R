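#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an aperiodic power-law fit
#'
#' @param x An `aperiodic_fit` from [fit_aperiodic()].
#' @param ... Unused.
#' @return Tibble with one row per parameter (`slope`, `intercept`).
#' @export
tidy.aperiodic_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' One-row summary of an aperiodic fit
#'
#' @inheritParams tidy.aperiodic_fit
#' @return Tibble with `slope`, `intercept`, `rmse`, `n_bins`,
#'   `fit_lo_hz`, `fit_hi_hz`.
#' @export
glance.aperiodic_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, rmse = x$rmse,
                 n_bins = x$n_bins, fit_lo_hz = x$fit_range_hz[1],
                 fit_hi_hz = x$fit_range_hz[2])
}

#' Tidy a circular test result
#'
#' @param x A `circ_test` from [rayleigh_test()] or [watson_williams()].
#' @param ... Unused.
#' @return One-row tibble with `method`, `statistic`, `p.value`, `n`.
#' @export
tidy.circ_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p.value = x$p, n = sum(x$n))
}

#' Tidy a cluster permutation result
#'
#' @param x A `cluster_result` from [cluster_correct()].
#' @param ... Unused.
#' @return Tibble with one row per cluster: `cluster`, `n_members`,
#'   `first_unit`, `last_unit`, `mass`, `p.value`.
#' @export
tidy.cluster_result <- function(x, ...) {
  cl <- x$clusters
  tibble::tibble(cluster = seq_len(nrow(cl)),
                 n_members = lengths(cl$members),
                 first_unit = vapply(cl$members, min, numeric(1)),
                 last_unit = vapply(cl$members, max, numeric(1)),
                 mass = cl$mass, p.value = cl$p_corrected)
}

#' One-row summary of a cluster permutation result
#'
#' @inheritParams tidy.cluster_result
#' @return Tibble with `n_clusters`, `min_p`, `threshold_used`,
#'   `n_permutations`.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 min_p = if (nrow(x$clusters)) min(x$clusters$p_corrected)
                         else NA_real_,
                 threshold_used = x$threshold_used,
                 n_permutations = x$n_permutations)
}
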
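#' Rayleigh test of circular uniformity
#'
#' Tests whether angles are uniformly distributed on the circle using
#' the mean resultant length R-bar. The p-value uses the standard
#' approximation `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with
#' `R = n * R-bar`.
#'
#' @param angles_deg Angles in degrees (n >= 3).
#' @return Object of class `circ_test` with `statistic` (R-bar), `p`,
#'   `n`, `method`.
#' @export
rayleigh_test <- function(angles_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  n <- length(angles_deg)
  if (n < 3) stop("Rayleigh test needs at least 3 angles", call. = FALSE)
  rbar <- Mod(mean(exp(1i * angles_deg * pi / 180)))
  R <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  structure(list(statistic = rbar, p = min(1, p), n = n,
                 method = "rayleigh"),
            class = "circ_test")
}

# Maximum-likelihood von Mises concentration from a mean resultant
# length (Fisher's piecewise approximation).
kappa_from_rbar <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equal mean directions
#'
#' One-way Watson-Williams F test comparing the mean angles of two
#' samples, with the standard concentration-based correction factor
#' `1 + 3 / (8 kappa)`. Assumes reasonably concentrated samples; a
#' warning is issued when either group's resultant length falls below
#' 0.45.
#'
#' @param angles_a_deg,angles_b_deg Angles in degrees (each n >= 5).
#' @return Object of class `circ_test` with `statistic` (F), `p`, `n`
#'   (per-group sizes), `df`, `method`.
#' @export
watson_williams <- function(angles_a_deg, angles_b_deg) {
  a <- angles_a_deg[!is.na(angles_a_deg)] * pi / 180
  b <- angles_b_deg[!is.na(angles_b_deg)] * pi / 180
  na <- length(a); nb <- length(b)
  if (na < 5 || nb < 5) {
    stop("Watson-Williams needs at least 5 angles per group", call. = FALSE)
  }
  N <- na + nb
  Ra <- Mod(sum(exp(1i * a)))
  Rb <- Mod(sum(exp(1i * b)))
  R <- Mod(sum(exp(1i * c(a, b))))
  rw <- (Ra + Rb) / N
  if (rw < 0.45) {
    warning("resultant length < 0.45; Watson-Williams assumptions doubtful",
            call. = FALSE)
  }
  kappa <- kappa_from_rbar(rw)
  g <- 1 + 3 / (8 * kappa)
  Fstat <- g * ((N - 2) * (Ra + Rb - R)) / (N - Ra - Rb)
  Fstat <- max(0, Fstat)
  p <- stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)
  structure(list(statistic = Fstat, p = p, n = c(na, nb), df = c(1, N - 2),
                 method = "watson_williams"),
            class = "circ_test")
}

#' @export
print.circ_test <- function(x, ...) {
  if (x$method == "rayleigh") {
    cat(sprintf("Rayleigh test: R-bar = %.4f, n = %d, p = %.4g\n",
                x$statistic, x$n, x$p))
  } else {
    cat(sprintf("Watson-Williams: F(%d, %d) = %.4f, p = %.4g\n",
                x$df[1], x$df[2], x$statistic, x$p))
  }
  invisible(x)
}

#' Chain adjacency over an ordered frequency axis
#'
#' @param freqs Sorted frequency values (>= 2).
#' @return Logical adjacency matrix (consecutive frequencies are
#'   neighbours).
#' @export
frequency_adjacency <- function(freqs) {
  u <- length(freqs)
  if (u < 2) stop("need at least 2 frequencies", call. = FALSE)
  if (is.unsorted(freqs)) stop("frequencies must be sorted", call. = FALSE)
  adj <- matrix(FALSE, u, u)
  adj[cbind(1:(u - 1), 2:u)] <- TRUE
  adj[cbind(2:u, 1:(u - 1))] <- TRUE
  adj
}

#' Distance-based adjacency over 2-D electrode coordinates
#'
#' Electrodes within `max_dist` of each other are neighbours; the
#' default radius is 1.5 times the median nearest-neighbour distance.
#'
#' @param xy Two-column matrix of electrode coordinates (unique rows).
#' @param max_dist Neighbourhood radius; `NULL` for the default.
#' @return Logical adjacency matrix.
#' @export
electrode_adjacency <- function(xy, max_dist = NULL) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) stop("need at least 2 electrodes", call. = FALSE)
  if (anyDuplicated(xy)) stop("duplicate electrode coordinates", call. = FALSE)
  d <- as.matrix(stats::dist(xy))
  if (is.null(max_dist)) {
    diag(d) <- Inf
    max_dist <- 1.5 * stats::median(apply(d, 1, min))
    diag(d) <- 0
  }
  adj <- d <= max_dist & d > 0
  adj
}

# Connected components of the supra-threshold units under `adj`.
connected_clusters <- function(units, adj) {
  comps <- list()
  remaining <- units
  while (length(remaining)) {
    queue <- remaining[1]
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- intersect(which(adj[v, ]), remaining)
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

#' Cluster-based permutation correction
#'
#' Forms clusters of adjacent units whose statistic exceeds the
#' cluster-forming threshold (two-sided on `|stat|` by default), sums
#' the absolute statistics into a cluster mass, and compares each
#' observed mass against the permutation distribution of the maximum
#' cluster mass obtained by re-running the statistic on permuted data.
#' Corrected p-values use the +1 convention:
#' `p = (1 + #permutations with max mass >= observed) / (1 + n)`.
#'
#' @param unit_stats Numeric statistic per unit (e.g. per frequency bin
#'   or electrode).
#' @param adjacency Logical adjacency matrix from
#'   [frequency_adjacency()] or [electrode_adjacency()].
#' @param null_generator Function taking no arguments and returning one
#'   permuted `unit_stats` vector (e.g. from a group-label shuffle).
#' @param stat_threshold Cluster-forming threshold on the statistic.
#' @param n_permutations Number of permutations (default 500).
#' @param seed Integer seed (deterministic results for a fixed seed).
#' @param two_sided Cluster on `|stat|` (default) or on `stat` alone.
#' @return Object of class `cluster_result`: tibble `clusters` (columns
#'   `members` list-column, `mass`, `p_corrected`), plus
#'   `threshold_used` and `n_permutations`.
#' @export
cluster_correct <- function(unit_stats, adjacency, null_generator,
                            stat_threshold, n_permutations = 500,
                            seed = 1L, two_sided = TRUE) {
  val <- function(s) if (two_sided) abs(s) else s
  find_clusters <- function(s) {
    supra <- which(val(s) > stat_threshold)
    if (!length(supra)) return(list())
    connected_clusters(supra, adjacency)
  }
  mass_of <- function(s, comp) sum(val(s)[comp])
  obs_clusters <- find_clusters(unit_stats)
  set.seed(seed)
  null_max <- vapply(seq_len(n_permutations), function(k) {
    s <- null_generator()
    cl <- find_clusters(s)
    if (!length(cl)) return(0)
    max(vapply(cl, function(c_) mass_of(s, c_), numeric(1)))
  }, numeric(1))
  clusters <- tibble::tibble(
    members = obs_clusters,
    mass = vapply(obs_clusters, function(c_) mass_of(unit_stats, c_),
                  numeric(1))
  )
  clusters$p_corrected <- vapply(clusters$mass, function(m) {
    (1 + sum(null_max >= m)) / (1 + n_permutations)
  }, numeric(1))
  structure(list(clusters = clusters[order(-clusters$mass), ],
                 threshold_used = stat_threshold,
                 n_permutations = n_permutations),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), threshold %.3f, %d permutations\n",
              nrow(x$clusters), x$threshold_used, x$n_permutations))
  if (nrow(x$clusters)) {
    df <- x$clusters
    df$members <- vapply(df$members, function(m)
      paste(range(m), collapse = "-"), "")
    print(df)
  }
  invisible(x)
}

#' Welch two-sample t statistics per unit
#'
#' Default per-unit statistic for cluster correction: a Welch t contrast
#' of two groups of subject-level values at each unit.
#'
#' @param a,b Matrices (subjects x units) for the two groups.
#' @return Numeric t statistic per unit.
#' @export
unit_t_stats <- function(a, b) {
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var) / nrow(a)
  vb <- apply(b, 2, stats::var) / nrow(b)
  (ma - mb) / sqrt(va + vb)
}
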
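#' Dynamic-time-warping distance between two trajectories
#'
#' Classic unnormalized DTW: local cost `|a_i - b_j|`, allowed steps
#' `(i-1, j)`, `(i, j-1)`, `(i-1, j-1)`, boundary `D(1,1) = |a_1 - b_1|`,
#' returning `D(n, m)`. No window constraint and no path normalization, so
#' raw distances are comparable across gene profiles of a fixed length.
#'
#' @param a,b Numeric vectors (>= 2 points each, finite).
#' @return Nonnegative scalar distance.
#' @examples
#' dtw_distance(c(1, 3), c(1, 2, 3)) # 1
#' @export
dtw_distance <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("Trajectories need >= 2 points.")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("Trajectories must be finite.")
  }
  n <- length(a); m <- length(b)
  cost <- abs(outer(a, b, "-"))
  D <- matrix(Inf, n, m)
  D[1, 1] <- cost[1, 1]
  for (j in 2:m) D[1, j] <- D[1, j - 1] + cost[1, j]
  for (i in 2:n) {
    D[i, 1] <- D[i - 1, 1] + cost[i, 1]
    for (j in 2:m) {
      D[i, j] <- cost[i, j] + min(D[i - 1, j], D[i, j - 1], D[i - 1, j - 1])
    }
  }
  D[n, m]
}

#' Partition genes by DTW distance
#'
#' Strict-less-than split at the cutoff (a distance exactly at the cutoff
#' lands in the "above" set).
#'
#' @param distances Tibble with columns `gene` and `dtw`.
#' @param cutoff Positive cutoff, default 250.
#' @return List with `below` and `above` tibbles and `n_below` / `n_above`.
#' @export
dtw_partition <- function(distances, cutoff = 250) {
  stopifnot(is.data.frame(distances),
            all(c("gene", "dtw") %in% names(distances)))
  if (cutoff <= 0) abort("`cutoff` must be > 0.")
  below <- distances[distances$dtw < cutoff, , drop = FALSE]
  above <- distances[distances$dtw >= cutoff, , drop = FALSE]
  list(below = as_tibble(below), above = as_tibble(above),
       n_below = nrow(below), n_above = nrow(above))
}

#' Pearson trend correlation between two trajectories
#'
#' Pearson r on the shared pseudotime grid with a two-sided p-value from the
#' t-distribution on n - 2 degrees of freedom.
#'
#' @param a,b Numeric vectors on the same grid (>= 3 points, nonzero
#'   variance).
#' @return Tibble with `r`, `p`, `n`.
#' @export
trend_correlation <- function(a, b) {
  if (length(a) != length(b)) abort("Trajectories must share the grid.")
  n <- length(a)
  if (n < 3) abort("Need >= 3 points.")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Zero variance: correlation undefined.")
  }
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  tibble(r = r, p = p, n = n)
}

#' Compare a gene subset's DTW distances with the overall distribution
#'
#' Reports the medians of the subset and of the full gene set, and a
#' one-sided Wilcoxon rank-sum p-value for the subset having smaller
#' distances. A single-gene subset is flagged low-power.
#'
#' @param all_distances Tibble with `gene` and `dtw` for the full gene set.
#' @param subset_genes Character vector of subset gene IDs (non-empty,
#'   contained in the full set).
#' @return Tibble with `median_subset`, `median_all`, `p`, `n_subset`,
#'   `low_power`.
#' @export
background_distance_distribution <- function(all_distances, subset_genes) {
  stopifnot(is.data.frame(all_distances),
            all(c("gene", "dtw") %in% names(all_distances)))
  if (length(subset_genes) == 0) abort("Subset is empty.")
  if (!all(subset_genes %in% all_distances$gene)) {
    abort("Subset genes must be contained in the full set.")
  }
  sub <- all_distances$dtw[all_distances$gene %in% subset_genes]
  p <- suppressWarnings(
    wilcox.test(sub, all_distances$dtw, alternative = "less")$p.value
  )
  tibble(
    median_subset = median(sub),
    median_all = median(all_distances$dtw),
    p = p,
    n_subset = length(sub),
    low_power = length(sub) < 2
  )
}
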
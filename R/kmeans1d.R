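# Exact one-dimensional k-means for electrostatic-energy clustering.
#
# In one dimension the SSE-optimal k-means partition is contiguous in value
# order, so it can be found exactly by dynamic programming over sorted values
# (O(k n^2)) instead of Lloyd iteration, which only guarantees a local
# optimum. The optimal partition is itself a Lloyd fixed point: every point
# is nearest its own cluster's centroid and adjacent clusters are separated
# by the midpoint of their centroids.

#' Exact 1-D k-means clustering
#'
#' Clusters numeric values (electrostatic energies, kcal/mol) into `k`
#' groups minimizing within-cluster sum of squares, exactly. Cluster indices
#' are 0-based in value order: cluster 0 holds the lowest (most negative)
#' energies. Boundaries between clusters are the midpoints of adjacent
#' centroids.
#'
#' @param values Numeric vector to cluster.
#' @param k Number of clusters, `1 <= k <=` number of distinct values.
#' @param seed Ignored; accepted for call compatibility with stochastic
#'   clusterers (the dynamic program is deterministic).
#' @return An `ee_clustering`: `k`, increasing `centroids`, `boundaries`
#'   (`k - 1` midpoints), 0-based `assignment` aligned with `values`,
#'   cluster `sizes` and total `sse`.
#' @export
#' @examples
#' cl <- kmeans_1d(c(-4.8, -4.5, -4.2, -1.3, -1.0, 0.2, 0.4), k = 3)
#' cl$boundaries
kmeans_1d <- function(values, k, seed = NULL) {
  if (!is.numeric(values) || !length(values) || anyNA(values)) {
    abort("`values` must be a non-empty numeric vector without NAs.")
  }
  stopifnot_scalar_number(k, "k", lower = 1, integerish = TRUE)
  k <- as.integer(k)
  n_distinct <- length(unique(values))
  if (k > n_distinct) {
    abort(sprintf("k = %d exceeds the %d distinct value(s).", k, n_distinct))
  }
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  # SSE of sorted segments i..j (1-based, inclusive); vectorized over i
  seg_cost <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    s2 <- cs2[j + 1] - cs2[i]
    pmax(0, s2 - s^2 / (j - i + 1))
  }
  dp <- matrix(Inf, nrow = k, ncol = n)
  back <- matrix(0L, nrow = k, ncol = n)
  dp[1, ] <- seg_cost(1, seq_len(n))
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        i <- m:j
        cand <- dp[m - 1, i - 1] + seg_cost(i, j)
        best_i <- which.min(cand)
        dp[m, j] <- cand[best_i]
        back[m, j] <- i[best_i]
      }
    }
  }
  # recover segment starts
  starts <- integer(k)
  j <- n
  for (m in rev(seq_len(k))) {
    starts[m] <- if (m == 1) 1L else back[m, j]
    j <- starts[m] - 1L
  }
  ends <- c(starts[-1] - 1L, n)
  centroids <- vapply(seq_len(k), function(m) {
    mean(x[starts[m]:ends[m]])
  }, numeric(1))
  assignment_sorted <- rep(seq_len(k) - 1L, times = ends - starts + 1L)
  assignment <- integer(n)
  assignment[ord] <- assignment_sorted
  boundaries <- if (k > 1) (centroids[-k] + centroids[-1]) / 2 else numeric(0)
  structure(
    list(
      k = k,
      centroids = centroids,
      boundaries = boundaries,
      assignment = assignment,
      sizes = ends - starts + 1L,
      sse = dp[k, n],
      values = values
    ),
    class = "ee_clustering"
  )
}

#' @export
print.ee_clustering <- function(x, ...) {
  cat(sprintf("<ee_clustering: k = %d, SSE = %.4g>\n", x$k, x$sse))
  cat("  centroids:", paste(sprintf("%.3f", x$centroids), collapse = ", "), "\n")
  if (length(x$boundaries)) {
    cat("  boundaries:", paste(sprintf("%.3f", x$boundaries), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
#' @method tidy ee_clustering
tidy.ee_clustering <- function(x, ...) {
  tibble(
    cluster = seq_len(x$k) - 1L,
    centroid = x$centroids,
    size = x$sizes,
    lower = c(-Inf, x$boundaries),
    upper = c(x$boundaries, Inf)
  )
}

#' @export
#' @method glance ee_clustering
glance.ee_clustering <- function(x, ...) {
  tibble(k = x$k, sse = x$sse, n = length(x$assignment))
}

# 0-based cluster index of energies under a clustering's boundaries.
ee_cluster_index <- function(ee, clustering) {
  if (!length(clustering$boundaries)) return(rep(0L, length(ee)))
  findInterval(ee, clustering$boundaries)
}

#' Electrostatic-energy filter
#'
#' Pass/fail by energy-cluster membership: a pose passes in mode
#' `"lowest_cluster"` iff its electrostatic energy falls in cluster 0 (below
#' the first boundary), and in mode `"two_lowest_clusters"` iff it falls in
#' clusters 0 or 1.
#'
#' @param ee Numeric electrostatic energies (kcal/mol).
#' @param clustering An [kmeans_1d()] `ee_clustering` computed on the
#'   relevant pose population.
#' @param mode `"lowest_cluster"` or `"two_lowest_clusters"`.
#' @return A logical vector.
#' @export
ee_filter <- function(ee, clustering,
                      mode = c("lowest_cluster", "two_lowest_clusters")) {
  mode <- match.arg(mode)
  idx <- ee_cluster_index(ee, clustering)
  if (mode == "lowest_cluster") idx == 0L else idx <= 1L
}
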
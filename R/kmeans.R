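#' k-means++ centroid initialization
#'
#' Draws `k` initial centroids from the data points: the first uniformly at
#' random, each subsequent one with probability proportional to the squared
#' Euclidean distance to its nearest already-chosen centroid, so the seeds
#' spread out over the data.  Uses R's RNG stream; call `set.seed()` (or pass
#' a seed to the higher-level functions) for reproducibility.
#'
#' @param points numeric matrix, points in rows (pixels x channels).
#' @param k number of centroids, `1 <= k <= nrow(points)`.
#' @return a `k x ncol(points)` matrix of initial centroids.
#' @export
kmeans_pp_init <- function(points, k) {
  points <- as.matrix(points)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be positive")
  if (nrow(points) < k)
    stop("need at least k = ", k, " points, got ", nrow(points))
  idx <- .kmeanspp_cpp(points, k)
  points[idx, , drop = FALSE]
}

#' Lloyd iterations from fixed initial centroids
#'
#' Alternates nearest-centroid assignment (squared Euclidean distance, ties
#' broken toward the lowest cluster index) and centroid update (cluster mean)
#' until the assignment no longer changes or `max_iter` is reached.  A
#' cluster left empty during iteration is re-seeded to the point farthest
#' from that cluster's current centroid.  The within-cluster sum-of-squares
#' loss is non-increasing across iterations.
#'
#' @param points numeric matrix, points in rows.
#' @param init_centroids `k x ncol(points)` matrix of starting centroids.
#' @param max_iter maximum number of iterations (default 100).
#' @return an object of class `cluster_model`: list with `centroids`,
#'   `assignment` (1-based integer labels), `loss`, `n_iter`, `converged`,
#'   `loss_trace`.
#' @export
lloyd_iterate <- function(points, init_centroids, max_iter = 100L) {
  points <- as.matrix(points)
  init_centroids <- as.matrix(init_centroids)
  if (anyDuplicated(init_centroids))
    stop("initial centroids must be distinct")
  res <- .lloyd_cpp(points, init_centroids, as.integer(max_iter))
  structure(res, class = "cluster_model")
}

#' Replicated k-means with minimum-loss selection
#'
#' Runs `num_replicates` independent k-means++ initializations followed by
#' Lloyd iterations and keeps the replicate with the lowest within-cluster
#' sum-of-squares.  Replicate `r` seeds R's RNG with `seed + r`, so runs are
#' bit-reproducible for a fixed root seed.
#'
#' @param points numeric matrix, points in rows.
#' @param k number of clusters (`>= 2` for unmixing: fluorophores + background).
#' @param num_replicates independent restarts (default 10).
#' @param max_iter Lloyd iteration cap per replicate (default 100).
#' @param seed integer root seed, or `NULL` to draw from the current RNG state.
#' @return the best replicate's `cluster_model`, with `replicate_losses`
#'   recording every replicate's final loss.
#' @export
cluster_replicated <- function(points, k, num_replicates = 10L,
                               max_iter = 100L, seed = NULL) {
  points <- as.matrix(points)
  num_replicates <- as.integer(num_replicates)
  if (num_replicates < 1L) stop("'num_replicates' must be >= 1")
  best <- NULL
  losses <- numeric(num_replicates)
  for (r in seq_len(num_replicates)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + r)
    init <- unique(kmeans_pp_init(points, k))
    while (nrow(init) < k) {
      # degenerate draw (duplicated points); top up with distinct rows
      extra <- unique(rbind(init, kmeans_pp_init(points, k)))
      if (nrow(extra) == nrow(init))
        stop("fewer than k = ", k, " distinct feature vectors; ",
             "reduce the number of clusters")
      init <- extra[seq_len(min(k, nrow(extra))), , drop = FALSE]
    }
    model <- lloyd_iterate(points, init, max_iter)
    losses[r] <- model$loss
    if (is.null(best) || model$loss < best$loss) best <- model
  }
  best$replicate_losses <- losses
  best
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k = ", nrow(x$centroids), ", n = ",
      length(x$assignment), " points\n", sep = "")
  cat("  loss = ", format(x$loss), "; ", x$n_iter, " iteration(s); ",
      if (isTRUE(x$converged)) "converged" else "iteration cap reached",
      "\n", sep = "")
  invisible(x)
}
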
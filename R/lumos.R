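#' Blind spectral unmixing by k-means clustering
#'
#' Fits the unmixing model to a multichannel image: pixels are embedded in a
#' preprocessed feature space (median filter, optional per-pixel ratio
#' scaling, per-channel z-score), partitioned into
#' `k = n_fluorophores + 1 + extra_clusters` groups by replicated k-means++
#' (the `+ 1` is the background, which always forms its own cluster), and
#' each pixel's intensity — the maximum of its raw channel values — is
#' reassigned to the single output channel of its cluster.  No emission
#' spectra need to be known in advance, and the number of fluorophores may
#' exceed the number of detection channels.
#'
#' Output clusters are ordered by the channel in which their spectral
#' signature peaks (wavelength order), with the background — the cluster of
#' lowest mean raw intensity — last.  Structures labeled with two
#' fluorophores at once (colocalization) or autofluorescent regions carry
#' their own composite signatures and can be captured by requesting
#' `extra_clusters`.
#'
#' @param image a [multichannel_image] (or array coercible to one).
#' @param n_fluorophores number of fluorescent labels expected in the image.
#' @param extra_clusters additional clusters beyond fluorophores + background,
#'   e.g. one for a colocalized pair and/or one for autofluorescence.
#' @param channels optional 1-based indices restricting the fit to a subset
#'   of input channels (e.g. only the channels with bleed-through).
#' @param median_window 3 or 5 for the pre-clustering median filter, 0 to skip.
#' @param ratio_scale divide each pixel's channels by their sum before
#'   z-scoring (see [scale_pixel_ratios()]); off by default.
#' @param replicates number of independent k-means restarts (default 10).
#' @param max_iter Lloyd iteration cap per replicate (default 100).
#' @param seed integer root seed; replicate `r` uses `seed + r`.
#' @param extra_roles optional character vector (length `extra_clusters`)
#'   naming the extra clusters, e.g. `"colocalization"`, `"autofluorescence"`.
#' @return an object of class `lumos`; see [fitted.lumos()], [coef.lumos()],
#'   [cluster_labels()], [summary.lumos()].
#' @examples
#' scene <- generate_grid_scene(simulation_config(n_fluorophores = 3,
#'                                                image_size = c(64, 64)))
#' img <- render_scene(scene, seed = 1)$image
#' fit <- lumos(img, n_fluorophores = 3, seed = 1)
#' summary(fit)
#' @export
lumos <- function(image, n_fluorophores, extra_clusters = 0L, channels = NULL,
                  median_window = 3L, ratio_scale = FALSE, replicates = 10L,
                  max_iter = 100L, seed = NULL, extra_roles = NULL) {
  if (!inherits(image, "multichannel_image")) image <- multichannel_image(image)
  n_fluorophores <- as.integer(n_fluorophores)
  extra_clusters <- as.integer(extra_clusters)
  if (n_fluorophores < 1L) stop("'n_fluorophores' must be >= 1")
  if (extra_clusters < 0L) stop("'extra_clusters' must be >= 0")
  raw <- if (!is.null(channels)) select_channels(image, channels) else image
  k <- n_fluorophores + 1L + extra_clusters

  prep <- preprocess_features(raw, median_window = median_window,
                              ratio_scale = ratio_scale)
  model <- cluster_replicated(prep$features, k, num_replicates = replicates,
                              max_iter = max_iter, seed = seed)

  ## wavelength-order the clusters: fluorophores by ascending peak channel,
  ## background (lowest mean raw intensity) last
  sig <- spectral_signatures(raw, model)
  bg <- identify_background(model, raw)
  fl <- setdiff(seq_len(k), bg)
  fl <- fl[order(apply(sig$matrix[fl, , drop = FALSE], 1L, which.max), fl)]
  ord <- c(fl, bg)

  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  model$assignment <- relabel[model$assignment]
  model$centroids <- model$centroids[ord, , drop = FALSE]
  sig$matrix <- sig$matrix[ord, , drop = FALSE]

  roles <- c(rep("fluorophore", n_fluorophores),
             if (extra_clusters > 0L) {
               if (is.null(extra_roles)) rep("extra", extra_clusters)
               else {
                 stopifnot(length(extra_roles) == extra_clusters)
                 as.character(extra_roles)
               }
             },
             "background")
  rownames(sig$matrix) <- make.unique(roles, sep = "_")

  unmixed <- reconstruct_output(raw, model, roles = roles)
  structure(list(
    raw = raw,
    unmixed = unmixed,
    signatures = sig,
    roles = roles,
    background_index = k,
    model = model,
    k = k,
    n_fluorophores = n_fluorophores,
    preprocessing = prep[c("stats", "provenance")],
    options = list(replicates = as.integer(replicates),
                   max_iter = as.integer(max_iter),
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                   channels = channels,
                   median_window = as.integer(median_window),
                   ratio_scale = isTRUE(ratio_scale)),
    call = match.call()
  ), class = "lumos")
}

#' Winner-take-all output reconstruction
#'
#' Builds the k-channel unmixed image from the raw intensities and a hard
#' cluster assignment: output channel `i` at a pixel equals the maximum of
#' that pixel's raw channel intensities if the pixel belongs to cluster `i`,
#' and 0 otherwise.  Intensities are always read from the raw (unfiltered)
#' image, so exactly one output channel is nonzero per pixel (binary
#' abundance: one endmember per pixel).
#'
#' @param raw the raw [multichannel_image] the model was fitted to.
#' @param model a `cluster_model` (or an integer assignment vector/array).
#' @param roles optional per-cluster role tags stored with the result.
#' @return an `unmixed_image`: list with `data` (spatial dims x k array),
#'   `roles`, `background_index`.
#' @export
reconstruct_output <- function(raw, model, roles = NULL) {
  stopifnot(inherits(raw, "multichannel_image"))
  assignment <- if (inherits(model, "cluster_model")) model$assignment
                else as.integer(model)
  n <- prod(spatial_dim(raw))
  if (length(assignment) != n)
    stop("assignment length (", length(assignment),
         ") does not match the image's pixel count (", n, ")")
  k <- max(if (inherits(model, "cluster_model")) nrow(model$centroids)
           else assignment)
  m <- as_feature_matrix(raw)
  pixmax <- m[, 1L]
  for (c in seq_len(ncol(m))[-1L]) pixmax <- pmax(pixmax, m[, c])
  out <- matrix(0, nrow = n, ncol = k)
  out[cbind(seq_len(n), assignment)] <- pixmax
  structure(list(data = array(out, dim = c(spatial_dim(raw), k)),
                 roles = roles,
                 background_index = if (!is.null(roles))
                   match("background", roles) else NA_integer_),
            class = "unmixed_image")
}

#' Identify the background cluster
#'
#' The background is not subtracted by thresholding but simply treated as one
#' more cluster; it is recognized as the cluster whose member pixels have the
#' lowest mean raw intensity averaged over the input channels (ties broken
#' toward the lowest cluster index).
#'
#' @param model a `cluster_model`.
#' @param raw the raw [multichannel_image] the model was fitted to.
#' @return the 1-based index of the background cluster.
#' @export
identify_background <- function(model, raw) {
  stopifnot(inherits(raw, "multichannel_image"))
  k <- nrow(model$centroids)
  if (k < 2L) stop("background identification needs k >= 2")
  m <- as_feature_matrix(raw)
  mean_int <- vapply(seq_len(k), function(i) {
    rows <- model$assignment == i
    if (!any(rows)) Inf else mean(m[rows, , drop = FALSE])
  }, numeric(1))
  which.min(mean_int)  # which.min returns the first (lowest-index) minimum
}

#' Spectral signatures of the fitted clusters
#'
#' Row `i` is the mean raw intensity of cluster-`i` pixels in each input
#' channel, rescaled so the row maximum is 1 — the relative intensity of one
#' unmixed component across the detection channels.  These are the learned
#' analogues of the endmember spectra that linear unmixing would require as
#' prior knowledge.
#'
#' @param raw the raw [multichannel_image] the model was fitted to.
#' @param model a `cluster_model`.
#' @return a `spectral_signatures` object: list with `matrix` (k x C, each
#'   row max 1) and `mean_intensity` (k x C unnormalized means).
#' @export
spectral_signatures <- function(raw, model) {
  stopifnot(inherits(raw, "multichannel_image"))
  k <- nrow(model$centroids)
  m <- as_feature_matrix(raw)
  means <- matrix(0, nrow = k, ncol = ncol(m))
  for (i in seq_len(k)) {
    rows <- model$assignment == i
    if (!any(rows)) {
      warning("cluster ", i, " is empty; its signature is all zero")
    } else {
      means[i, ] <- colMeans(m[rows, , drop = FALSE])
    }
  }
  norm <- means
  rmax <- apply(norm, 1L, max)
  nz <- rmax > 0
  norm[nz, ] <- norm[nz, , drop = FALSE] / rmax[nz]
  colnames(norm) <- raw$channel_names
  structure(list(matrix = norm, mean_intensity = means),
            class = "spectral_signatures")
}

#' @export
print.spectral_signatures <- function(x, digits = 3, ...) {
  cat("Relative intensity per input channel (row max = 1):\n")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Cluster label image of a fitted unmixing model
#'
#' @param fit a `lumos` object.
#' @param background_zero recode the background cluster as 0 so fluorophore
#'   clusters are numbered 1..k-1 (the convention of ground-truth label
#'   images); otherwise labels are the raw 1..k assignment.
#' @return an integer array over the image's spatial dimensions.
#' @export
cluster_labels <- function(fit, background_zero = TRUE) {
  stopifnot(inherits(fit, "lumos"))
  lab <- fit$model$assignment
  if (background_zero) lab[lab == fit$background_index] <- 0L
  array(as.integer(lab), dim = spatial_dim(fit$raw))
}

#' @export
print.lumos <- function(x, ...) {
  cat("Blind k-means spectral unmixing fit\n")
  cat("  image: ", paste(spatial_dim(x$raw), collapse = " x "), " pixels, ",
      n_channels(x$raw), " channel(s)\n", sep = "")
  cat("  k = ", x$k, " (", x$n_fluorophores, " fluorophore(s) + background",
      if (x$k > x$n_fluorophores + 1L)
        paste0(" + ", x$k - x$n_fluorophores - 1L, " extra"),
      ")\n", sep = "")
  cat("  loss = ", format(x$model$loss), " after ", x$model$n_iter,
      " iteration(s) (best of ", x$options$replicates, " replicate(s))\n",
      sep = "")
  invisible(x)
}

#' Summary of a fitted unmixing model
#'
#' @param object a `lumos` object.
#' @param ... unused.
#' @return a `summary.lumos` with per-cluster pixel counts, the signature
#'   table, and fit diagnostics.
#' @export
summary.lumos <- function(object, ...) {
  counts <- tabulate(object$model$assignment, nbins = object$k)
  structure(list(k = object$k, roles = object$roles,
                 pixel_counts = counts,
                 signatures = object$signatures$matrix,
                 loss = object$model$loss,
                 n_iter = object$model$n_iter,
                 converged = object$model$converged,
                 replicate_losses = object$model$replicate_losses,
                 options = object$options),
            class = "summary.lumos")
}

#' @export
print.summary.lumos <- function(x, digits = 3, ...) {
  cat("Blind k-means spectral unmixing: k =", x$k, "clusters\n\n")
  tab <- data.frame(role = x$roles, pixels = x$pixel_counts,
                    round(x$signatures, digits), check.names = FALSE)
  print(tab)
  cat("\nloss:", format(x$loss), "| iterations:", x$n_iter,
      if (isTRUE(x$converged)) "(converged)" else "(iteration cap)", "\n")
  if (!is.null(x$replicate_losses))
    cat("replicate losses:",
        paste(format(x$replicate_losses, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Extract spectral signatures or feature-space centroids
#'
#' @param object a `lumos` object.
#' @param type `"signatures"` (relative raw intensity per channel, row max 1)
#'   or `"centroids"` (cluster centres in the preprocessed feature space).
#' @param ... unused.
#' @export
coef.lumos <- function(object, type = c("signatures", "centroids"), ...) {
  type <- match.arg(type)
  if (type == "signatures") object$signatures$matrix else object$model$centroids
}

#' Unmixed intensity image of a fit
#'
#' @param object a `lumos` object.
#' @param remove_background drop the background output channel.
#' @param ... unused.
#' @return spatial-dims x k (or k-1) array of winner-take-all intensities.
#' @export
fitted.lumos <- function(object, remove_background = FALSE, ...) {
  out <- object$unmixed$data
  if (remove_background) {
    nd <- length(dim(out))
    keep <- setdiff(seq_len(object$k), object$background_index)
    out <- if (nd == 3L) out[, , keep, drop = FALSE]
           else out[, , , keep, drop = FALSE]
  }
  out
}

#' Assign new pixels to the fitted clusters
#'
#' Applies the stored preprocessing (median filter, optional ratio scaling,
#' z-scoring with the training image's channel means and standard
#' deviations) to new data and assigns each pixel to the nearest centroid.
#'
#' @param object a `lumos` object.
#' @param newdata a [multichannel_image] with the same channel count as the
#'   training image, or a pixels x channels matrix of raw intensities (no
#'   median filtering is possible for a bare matrix).
#' @param ... unused.
#' @return an integer label array (image input) or vector (matrix input).
#' @export
predict.lumos <- function(object, newdata, ...) {
  if (missing(newdata)) return(cluster_labels(object, background_zero = FALSE))
  st <- object$preprocessing$stats
  prov <- object$preprocessing$provenance
  if (inherits(newdata, "multichannel_image")) {
    if (n_channels(newdata) != ncol(object$model$centroids))
      stop("'newdata' must have ", ncol(object$model$centroids), " channels")
    x <- if (prov$median_window %in% c(3L, 5L))
           median_filter(newdata, prov$median_window) else newdata
    m <- if (prov$ratio_scaled)
           matrix(scale_pixel_ratios(x), ncol = n_channels(x))
         else as_feature_matrix(x)
    out_dim <- spatial_dim(newdata)
  } else {
    m <- as.matrix(newdata)
    out_dim <- NULL
  }
  for (c in seq_len(ncol(m)))
    m[, c] <- if (st$sigma[c] > 0) (m[, c] - st$mu[c]) / st$sigma[c] else 0
  lab <- .assign_cpp(m, object$model$centroids)
  if (is.null(out_dim)) as.integer(lab) else array(as.integer(lab), out_dim)
}

#' Per-pixel clustering residuals
#'
#' Euclidean distance between each pixel's preprocessed feature vector and
#' its assigned centroid — large values flag pixels whose spectral signature
#' matches no learned component well (e.g. colocalized or autofluorescent
#' pixels when no extra cluster was requested).
#'
#' @param object a `lumos` object.
#' @param ... unused.
#' @return a numeric array over the image's spatial dimensions.
#' @export
residuals.lumos <- function(object, ...) {
  prep <- preprocess_features(object$raw,
                              median_window = object$preprocessing$provenance$median_window,
                              ratio_scale = object$preprocessing$provenance$ratio_scaled)
  d <- prep$features - object$model$centroids[object$model$assignment, , drop = FALSE]
  array(sqrt(rowSums(d * d)), dim = spatial_dim(object$raw))
}

#' Plot the spectral signatures of a fit
#'
#' One bar panel per cluster showing its relative intensity in each input
#' channel — the standard way unmixing results are reported alongside the
#' separated images.
#'
#' @param x a `lumos` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.lumos <- function(x, ...) {
  sig <- x$signatures$matrix
  k <- nrow(sig)
  chn <- colnames(sig)
  if (is.null(chn)) chn <- paste0("Ch", seq_len(ncol(sig)))
  op <- graphics::par(mfrow = c(ceiling(k / 3), min(k, 3)),
                      mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(k))
    graphics::barplot(sig[i, ], names.arg = chn, ylim = c(0, 1),
                      main = rownames(sig)[i], ...)
  invisible(x)
}
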
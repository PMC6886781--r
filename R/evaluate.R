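#' Optimally match predicted clusters to ground-truth labels
#'
#' Builds the contingency table of predicted versus true labels and finds the
#' one-to-one assignment (including background-to-background) that maximizes
#' the total number of agreeing pixels, via the Hungarian algorithm.  A
#' global matching avoids the degenerate many-to-one mappings a per-cluster
#' greedy rule can produce.
#'
#' @param pred_labels integer label image (array/matrix/vector).
#' @param truth_labels integer label image of the same shape.
#' @return a `cluster_matching`: list with `mapping` (named integer vector,
#'   predicted label -> truth label, `NA` for unmatched predictions),
#'   `agreement` (pixels explained) and `table` (the contingency table).
#' @export
match_clusters <- function(pred_labels, truth_labels) {
  if (!identical(dim(pred_labels), dim(truth_labels)) ||
      length(pred_labels) != length(truth_labels))
    stop("'pred_labels' and 'truth_labels' must have the same shape")
  pl <- sort(unique(as.vector(pred_labels)))
  tl <- sort(unique(as.vector(truth_labels)))
  tab <- table(factor(as.vector(pred_labels), levels = pl),
               factor(as.vector(truth_labels), levels = tl))
  m <- matrix(as.numeric(tab), nrow = length(pl), ncol = length(tl))
  # pad to square so solve_LSAP can leave surplus labels unmatched
  side <- max(dim(m))
  sq <- matrix(0, side, side)
  sq[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  sol <- as.integer(clue::solve_LSAP(sq, maximum = TRUE))
  mapping <- rep(NA_integer_, length(pl))
  names(mapping) <- pl
  for (i in seq_along(pl)) {
    j <- sol[i]
    if (j <= length(tl)) mapping[i] <- tl[j]
  }
  agreement <- sum(m[cbind(seq_along(pl),
                           match(mapping, tl)[seq_along(pl)])],
                   na.rm = TRUE)
  structure(list(mapping = mapping, agreement = agreement, table = tab),
            class = "cluster_matching")
}

#' Precision, recall and F1 of one binary mask against another
#'
#' Pixel-level precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and their
#' harmonic mean `F1 = 2PR / (P + R)`.  Conventions: both masks empty is a
#' vacuous success (all three are 1); an empty prediction against a nonempty
#' truth scores 0.
#'
#' @param pred_mask,truth_mask logical arrays of the same shape.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
f1_for_cluster <- function(pred_mask, truth_mask) {
  if (length(pred_mask) != length(truth_mask))
    stop("masks must have the same shape")
  pred_mask <- as.logical(pred_mask)
  truth_mask <- as.logical(truth_mask)
  tp <- sum(pred_mask & truth_mask)
  fp <- sum(pred_mask & !truth_mask)
  fn <- sum(!pred_mask & truth_mask)
  if (tp + fp + fn == 0L)
    return(c(precision = 1, recall = 1, f1 = 1))
  p <- if (tp + fp > 0L) tp / (tp + fp) else 0
  r <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Score an unmixing result against ground truth
#'
#' Matches predicted clusters to truth labels with [match_clusters()] and
#' reports per-label precision/recall/F1.  The headline metric is the F1
#' score of the smallest nonzero truth label (the minor structure): it is
#' the hardest cluster for k-means to keep separate, so it captures the
#' worst-case behaviour of the unmixing.
#'
#' @param pred a fitted [lumos()] model or an integer label image
#'   (0 = background).
#' @param truth_labels integer ground-truth label image (0 = background).
#' @return an `unmixing_evaluation`: list with `per_cluster` (data frame of
#'   truth label, matched prediction, pixel count, precision, recall, f1),
#'   `smallest_cluster_f1`, and `matching`.
#' @export
evaluate_unmixing <- function(pred, truth_labels) {
  pred_labels <- if (inherits(pred, "lumos")) cluster_labels(pred) else pred
  matching <- match_clusters(pred_labels, truth_labels)
  tl <- sort(unique(as.vector(truth_labels)))
  inv <- matching$mapping                       # pred -> truth
  rows <- lapply(tl, function(t) {
    p <- names(inv)[which(inv == t)]
    pmask <- if (length(p)) as.vector(pred_labels) == as.integer(p[1])
             else rep(FALSE, length(pred_labels))
    stats <- f1_for_cluster(pmask, as.vector(truth_labels) == t)
    data.frame(truth_label = t,
               pred_label = if (length(p)) as.integer(p[1]) else NA_integer_,
               pixels = sum(truth_labels == t),
               precision = stats[["precision"]], recall = stats[["recall"]],
               f1 = stats[["f1"]])
  })
  per_cluster <- do.call(rbind, rows)
  fg <- per_cluster[per_cluster$truth_label != 0L, , drop = FALSE]
  smallest <- if (nrow(fg)) fg$f1[which.min(fg$pixels)] else NA_real_
  structure(list(per_cluster = per_cluster,
                 smallest_cluster_f1 = smallest,
                 matching = matching),
            class = "unmixing_evaluation")
}

#' @export
print.unmixing_evaluation <- function(x, digits = 3, ...) {
  cat("Unmixing evaluation against ground truth\n")
  df <- x$per_cluster
  df[c("precision", "recall", "f1")] <- round(df[c("precision", "recall", "f1")],
                                              digits)
  print(df, row.names = FALSE)
  cat("smallest-cluster F1:", round(x$smallest_cluster_f1, digits), "\n")
  invisible(x)
}

#' Mander's colocalization coefficients from an unmixing fit
#'
#' When a colocalized pair of fluorophores A and B is captured as its own
#' cluster, the coefficients quantify what fraction of each fluorophore's
#' total raw intensity resides in the colocalized pixels:
#' `M_A = sum of raw A-channel intensity over colocalized pixels /
#' sum over (A-only and colocalized) pixels`, and symmetrically for B.
#' Raw intensities (not winner-take-all outputs) are used, following the
#' conventional definition.
#'
#' @param fit a fitted [lumos()] model with an extra colocalization cluster.
#' @param channel_a,channel_b 1-based raw input channels where fluorophores
#'   A and B are detected.
#' @param cluster_a,cluster_b,cluster_coloc cluster indices (in the fit's
#'   output ordering) of the A-only, B-only and colocalized clusters.
#' @return named numeric vector `c(M_A, M_B)` in percent (0-100); `NA` with
#'   a warning if a denominator is zero.
#' @export
manders_coefficients <- function(fit, channel_a, channel_b,
                                 cluster_a, cluster_b, cluster_coloc) {
  stopifnot(inherits(fit, "lumos"))
  m <- as_feature_matrix(fit$raw)
  lab <- fit$model$assignment
  co <- lab == cluster_coloc
  one <- function(channel, cluster) {
    num <- sum(m[co, channel])
    den <- sum(m[co | lab == cluster, channel])
    if (den == 0) {
      warning("zero total intensity in channel ", channel,
              "; coefficient undefined")
      return(NA_real_)
    }
    100 * num / den
  }
  c(M_A = one(channel_a, cluster_a), M_B = one(channel_b, cluster_b))
}
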
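#' Robustness sweep over a simulation parameter
#'
#' Drives the benchmark loop: for every value of the swept parameter and
#' every replicate, generate a grid scene, render it, unmix it blindly with
#' `k = n_fluorophores + 1`, match clusters to the ground truth, and record
#' the smallest-cluster F1.  Per-value means over replicates summarize the
#' sweep.  Everything is deterministic given `seed`: replicate `r` of value
#' `v_i` renders with seed `seed + 1000 * (i - 1) + r` and the same seed
#' roots the k-means replicates.
#'
#' @param param one of `"cluster_size_ratio"`, `"n_fluorophores"`, `"snr"`.
#' @param values vector of parameter values to sweep.
#' @param n_reps simulations per value (default 10).
#' @param base_config a [simulation_config()] supplying the fixed parameters.
#' @param seed integer root seed.
#' @param replicates,max_iter k-means options passed to [lumos()].
#' @param median_window pre-clustering median window passed to [lumos()].
#' @param verbose print one line per completed value.
#' @return a `lumos_sweep`: list with `results` (data frame: param, value,
#'   rep, seed, smallest_cluster_f1), `means` (data frame: value,
#'   mean_smallest_cluster_f1), `param`.
#' @export
run_sweep <- function(param = c("cluster_size_ratio", "n_fluorophores", "snr"),
                      values, n_reps = 10L, base_config = simulation_config(),
                      seed = 1L, replicates = 10L, max_iter = 100L,
                      median_window = 3L, verbose = FALSE) {
  param <- match.arg(param)
  stopifnot(inherits(base_config, "simulation_config"), length(values) >= 1L)
  rows <- vector("list", length(values) * n_reps)
  idx <- 0L
  for (i in seq_along(values)) {
    cfg_args <- unclass(base_config)
    cfg_args[[param]] <- values[i]
    cfg <- do.call(simulation_config, cfg_args)
    for (r in seq_len(n_reps)) {
      s <- as.integer(seed) + 1000L * (i - 1L) + r
      sim <- simulate_scene(cfg, seed = s)
      fit <- lumos(sim$image, n_fluorophores = cfg$n_fluorophores,
                   replicates = replicates, max_iter = max_iter,
                   median_window = median_window, seed = s)
      ev <- evaluate_unmixing(fit, sim$scene$labels)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(param = param, value = values[i], rep = r,
                                seed = s,
                                smallest_cluster_f1 = ev$smallest_cluster_f1)
    }
    if (verbose)
      message(param, " = ", values[i], ": mean smallest-cluster F1 = ",
              round(mean(vapply(rows[idx - seq_len(n_reps) + 1L],
                                function(x) x$smallest_cluster_f1,
                                numeric(1))), 3))
  }
  results <- do.call(rbind, rows)
  means <- stats::aggregate(smallest_cluster_f1 ~ value, data = results, FUN = mean)
  names(means)[2] <- "mean_smallest_cluster_f1"
  means <- means[match(values, means$value), , drop = FALSE]
  rownames(means) <- NULL
  structure(list(results = results, means = means, param = param),
            class = "lumos_sweep")
}

#' @export
print.lumos_sweep <- function(x, digits = 3, ...) {
  cat("Robustness sweep over", x$param, "(",
      max(x$results$rep), "replicate(s) per value )\n")
  m <- x$means
  m$mean_smallest_cluster_f1 <- round(m$mean_smallest_cluster_f1, digits)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Plot a robustness sweep
#'
#' Mean smallest-cluster F1 against the swept parameter, with the 0.9
#' success threshold marked.
#'
#' @param x a `lumos_sweep`.
#' @param log_x log-scale the x axis (natural for ratio and SNR sweeps).
#' @param ... passed to [graphics::plot()].
#' @export
plot.lumos_sweep <- function(x, log_x = x$param != "n_fluorophores", ...) {
  graphics::plot(x$means$value, x$means$mean_smallest_cluster_f1,
                 type = "b", pch = 16, log = if (log_x) "x" else "",
                 xlab = x$param, ylab = "mean smallest-cluster F1",
                 ylim = c(0, 1), ...)
  graphics::abline(h = 0.9, lty = 2, col = "grey40")
  invisible(x)
}
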
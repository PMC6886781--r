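# Small in-code fixtures shared across test files.

# a small, fast benchmark scene (4 fluorophores, 128 x 128)
small_config <- function(...) {
  args <- list(n_fluorophores = 4L, image_size = c(128L, 128L),
               cluster_size_ratio = 0.5, snr = 10)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# reference median filter: explicit reflect padding + median loops
median_filter_oracle <- function(x, window) {
  r <- window %/% 2
  reflect <- function(i, n) {
    z <- (i - 1) %% (2 * n)           # zero-based, nonnegative
    ifelse(z < n, z + 1, 2 * n - z)   # mirror with edge duplication
  }
  d <- dim(x)
  out <- x
  if (length(d) == 2L) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      ii <- reflect(i + (-r:r), d[1])
      jj <- reflect(j + (-r:r), d[2])
      out[i, j] <- stats::median(x[ii, jj])
    }
  } else {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      ii <- reflect(i + (-r:r), d[1])
      jj <- reflect(j + (-r:r), d[2])
      kk <- reflect(k + (-r:r), d[3])
      out[i, j, k] <- stats::median(x[ii, jj, kk])
    }
  }
  out
}

# brute-force k-means optimum: enumerate every assignment of n points
brute_force_kmeans <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (row in seq_len(nrow(grid))) {
    lab <- as.integer(grid[row, ])
    if (length(unique(lab)) < k) next
    loss <- 0
    for (c in seq_len(k)) {
      pts <- points[lab == c, , drop = FALSE]
      ctr <- colMeans(pts)
      loss <- loss + sum(sweep(pts, 2, ctr)^2)
    }
    if (loss < best) {
      best <- loss
      best_lab <- lab
    }
  }
  list(loss = best, assignment = best_lab)
}

# brute-force optimal label matching over all permutations (small k only)
brute_force_matching <- function(pred, truth) {
  pl <- sort(unique(as.vector(pred)))
  tl <- sort(unique(as.vector(truth)))
  stopifnot(length(pl) <= 6, length(pl) == length(tl))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- -1
  for (p in perms(seq_along(tl))) {
    agree <- sum(vapply(seq_along(pl), function(i)
      sum(pred == pl[i] & truth == tl[p[i]]), numeric(1)))
    if (agree > best) {
      best <- agree
      best_map <- stats::setNames(tl[p], pl)
    }
  }
  list(mapping = best_map, agreement = best)
}

# minimal stand-in fit for functions that only need raw + assignment
fake_fit <- function(raw, assignment) {
  structure(list(raw = raw,
                 model = list(assignment = as.integer(assignment))),
            class = "lumos")
}
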
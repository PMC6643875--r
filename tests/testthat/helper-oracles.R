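# Shared fixtures and independent brute-force oracles.

# tiny colony table builder: one plate, explicit sizes per condition
tiny_colonies <- function(sizes_by_condition, strain_ids = NULL,
                          plate_id = "p1", replicate = 1) {
  out <- list()
  for (cond in names(sizes_by_condition)) {
    sizes <- sizes_by_condition[[cond]]
    n <- length(sizes)
    if (is.null(strain_ids)) strain_ids <- sprintf("s%02d", seq_len(n))
    out[[cond]] <- data.frame(plate_id = plate_id, row = seq_len(n), col = 1L,
                              strain_id = strain_ids, condition = cond,
                              replicate = replicate, size = sizes,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# brute-force self-excluding windowed-median smoother (no recentering trick:
# recomputes everything from the definition)
oracle_smooth <- function(grid, window, min_neighbors) {
  nr <- nrow(grid); nc <- ncol(grid)
  half <- (window - 1) %/% 2
  adj <- grid
  adjusted <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    x <- grid[r, cc]
    if (is.na(x)) next
    neigh <- c()
    for (dr in -half:half) for (dc in -half:half) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc && !is.na(grid[rr, c2]))
        neigh <- c(neigh, grid[rr, c2])
    }
    if (length(neigh) >= min_neighbors) {
      adj[r, cc] <- x - median(neigh)
      adjusted[r, cc] <- TRUE
    }
  }
  shift <- median(grid, na.rm = TRUE) - median(adj, na.rm = TRUE)
  adj[adjusted] <- adj[adjusted] + shift
  adj
}

# run spatial_smooth on a plain matrix, return smoothed matrix
smooth_matrix <- function(grid, window = 7, min_neighbors = 8) {
  nr <- nrow(grid); nc <- ncol(grid)
  pos <- which(!is.na(grid), arr.ind = TRUE)
  df <- data.frame(plate_id = "p1", row = pos[, 1], col = pos[, 2],
                   strain_id = sprintf("s%04d", seq_len(nrow(pos))),
                   lgr = grid[pos], flags = "", stringsAsFactors = FALSE)
  cfg <- normalization_config(smoothing_window = window,
                              smoothing_min_neighbors = min_neighbors)
  out <- spatial_smooth(df, plate_geometry(nr, nc), cfg)
  res <- matrix(NA_real_, nr, nc)
  res[cbind(out$row, out$col)] <- out$lgr_smoothed
  res
}

# exhaustive UPGMA: recompute average inter-cluster distance from the raw
# matrix at every merge (no Lance-Williams update)
oracle_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dist_ij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dist_ij < best - 1e-15) { best <- dist_ij; bi <- i; bj <- j }
      }
    }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# random valid distance matrix (metric not required for UPGMA)
random_distance <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.05, 2), n, n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
  d
}

# a comfortably bimodal fit for hit-calling tests
demo_fit <- function(rho2 = 0.15, mu1 = 0, sigma1 = 0.2, mu2 = 1.0,
                     sigma2 = 0.4, n = 4000) {
  mixture_fit(rho2, mu1, sigma1, mu2, sigma2, n = n)
}
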
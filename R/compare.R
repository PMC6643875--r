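# Cross-screen analysis: the (rho2, mu2) screen-parameter summary,
# correlation-distance matrices, UPGMA clustering with Newick export, and
# frequent-flyer detection.

#' Screen-parameter summary table
#'
#' One row per screen with the fitted hit fraction (rho2), hit-peak mean
#' (mu2) and sd (sigma2): plotting rho2 against mu2 separates screens where
#' many strains are mildly affected from screens where few strains are
#' strongly affected. Screens whose fit lacks a usable hit peak are flagged.
#'
#' @param fits named list of [mixture_fit()] objects (names = screen names).
#' @param sort_by optional column to sort by, descending (e.g. "rho2").
#' @return data.frame(screen_name, rho2, mu2, sigma2, classification,
#'   flagged).
#' @export
screen_param_table <- function(fits, sort_by = NULL) {
  stopifnot(length(fits) >= 1)
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("screen_", seq_along(fits))
  out <- data.frame(
    screen_name = nm,
    rho2 = vapply(fits, function(f) f$rho2, numeric(1)),
    mu2 = vapply(fits, function(f) f$mu2, numeric(1)),
    sigma2 = vapply(fits, function(f) f$sigma2, numeric(1)),
    classification = vapply(fits, function(f) f$classification, character(1)),
    stringsAsFactors = FALSE
  )
  out$flagged <- out$classification != "hit_peak"
  if (!is.null(sort_by))
    out <- out[order(out[[sort_by]], decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise correlation distance
#'
#' `d = 1 - r` with r the Pearson correlation over pairwise-complete
#' entries, so d lies in `[0, 2]` (0 = identical profiles, 2 = perfectly
#' anticorrelated). `uncentered = TRUE` uses the cosine-style uncentered
#' correlation instead. Pairs sharing fewer than `min_overlap` strains and
#' zero-variance vectors are errors, never silently imputed.
#'
#' @param mat numeric matrix, strains in rows and screens in columns.
#' @param axis cluster `"screens"` (columns, default) or `"strains"` (rows).
#' @param min_overlap minimum shared non-missing entries per pair (default
#'   10).
#' @param uncentered use uncentered correlation (default FALSE).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(mat, axis = c("screens", "strains"),
                                 min_overlap = 10, uncentered = FALSE) {
  axis <- match.arg(axis)
  m <- if (axis == "screens") mat else t(mat)
  p <- ncol(m)
  if (p < 2) stop("need at least 2 ", axis)
  labels <- colnames(m)
  if (is.null(labels)) labels <- paste0(axis, "_", seq_len(p))
  d <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      if (sum(ok) < min_overlap)
        stop(sprintf("only %d shared strains between %s and %s (need >= %d)",
                     sum(ok), labels[i], labels[j], min_overlap))
      a <- m[ok, i]; b <- m[ok, j]
      if (uncentered) {
        den <- sqrt(sum(a^2) * sum(b^2))
        if (den == 0) stop("zero-norm vector: ", labels[if (sum(a^2) == 0) i
                                                        else j])
        r <- sum(a * b) / den
      } else {
        if (stats::sd(a) == 0) stop("zero variance in ", labels[i])
        if (stats::sd(b) == 0) stop("zero variance in ", labels[j])
        r <- stats::cor(a, b)
      }
      d[i, j] <- d[j, i] <- 1 - r
    }
  }
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates the two clusters with the smallest average inter-cluster
#' distance at each step (Lance-Williams update). Ties break
#' deterministically toward the lowest-index pair. Merge heights are
#' non-decreasing.
#'
#' @param distances symmetric distance matrix with labeled rows/columns.
#' @return A `linkage_tree`: list with `merges` (data.frame node_a, node_b,
#'   height, size; leaves are negative indices, internal nodes positive merge
#'   row numbers) and `labels`.
#' @export
average_linkage_cluster <- function(distances) {
  n <- nrow(distances)
  if (n < 2) stop("need at least 2 leaves")
  labels <- rownames(distances)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  d <- distances
  active <- seq_len(n)            # column indices still live
  node_id <- -seq_len(n)          # cluster id per live column
  sizes <- rep(1L, n)
  merges <- data.frame(node_a = integer(n - 1), node_b = integer(n - 1),
                       height = numeric(n - 1), size = integer(n - 1))
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- d[active[i], active[j]]
        if (dij < best_d - 1e-15) { best_d <- dij; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    ai <- active[i]; aj <- active[j]
    si <- sizes[ai]; sj <- sizes[aj]
    merges$node_a[step] <- node_id[ai]
    merges$node_b[step] <- node_id[aj]
    merges$height[step] <- best_d
    merges$size[step] <- si + sj
    # Lance-Williams average-linkage update into column ai
    for (m in active) {
      if (m == ai || m == aj) next
      new_d <- (si * d[ai, m] + sj * d[aj, m]) / (si + sj)
      d[ai, m] <- d[m, ai] <- new_d
    }
    sizes[ai] <- si + sj
    node_id[ai] <- step
    active <- active[-j]
  }
  structure(list(merges = merges, labels = labels), class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree: %d leaves, %d merges>\n",
              length(x$labels), nrow(x$merges)))
  invisible(x)
}

#' Convert a linkage tree to stats::hclust
#' @param tree a `linkage_tree`.
#' @return An object of class `hclust`.
#' @export
as_hclust <- function(tree) {
  m <- tree$merges
  structure(list(merge = cbind(m$node_a, m$node_b), height = m$height,
                 order = seq_along(tree$labels), labels = tree$labels,
                 method = "average", dist.method = "correlation"),
            class = "hclust")
}

#' Serialize a linkage tree to Newick
#'
#' The tree is ultrametric: a node's height above the leaves is half its
#' merge distance, and branch lengths are height differences.
#'
#' @param tree a `linkage_tree` from [average_linkage_cluster()].
#' @param path optional file to write to.
#' @return The Newick string (invisibly if written to `path`).
#' @export
to_newick <- function(tree, path = NULL) {
  m <- tree$merges
  node_height <- m$height / 2
  render <- function(node) {
    if (node < 0) return(list(text = tree$labels[-node], h = 0))
    a <- render(m$node_a[node]); b <- render(m$node_b[node])
    h <- node_height[node]
    list(text = sprintf("(%s:%.10g,%s:%.10g)",
                        a$text, h - a$h, b$text, h - b$h),
         h = h)
  }
  nw <- paste0(render(nrow(m))$text, ";")
  if (!is.null(path)) { writeLines(nw, path); return(invisible(nw)) }
  nw
}

#' Strains that hit in most screens ("frequent flyers")
#'
#' Strains scoring as hits in at least `min_fraction` of the screens in
#' which they were assayed, regardless of target location. These are
#' candidates for location-independent sensitivity rather than specific
#' interactions.
#'
#' @param hit_tables named list of hit-table data.frames (see
#'   [call_hits()]).
#' @param min_fraction required hit fraction (default 0.75).
#' @param method which hit call to count: `"auto"` (hit_q when available,
#'   else hit_z), `"q"` or `"z"`.
#' @return data.frame(strain_id, n_assayed, n_hit, hit_fraction) restricted
#'   to frequent flyers, sorted by hit_fraction descending.
#' @export
frequent_flyers <- function(hit_tables, min_fraction = 0.75,
                            method = c("auto", "q", "z")) {
  method <- match.arg(method)
  if (length(hit_tables) < 2) stop("need hit tables from >= 2 screens")
  per_screen <- lapply(hit_tables, function(h) {
    hit <- switch(method,
                  q = h$hit_q,
                  z = h$hit_z,
                  auto = ifelse(is.na(h$hit_q), h$hit_z, h$hit_q))
    data.frame(strain_id = h$strain_id, hit = hit, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_screen)
  all <- all[!is.na(all$hit), , drop = FALSE]
  agg <- lapply(split(all$hit, all$strain_id), function(h)
    c(n = length(h), hits = sum(h)))
  res <- data.frame(strain_id = names(agg),
                    n_assayed = vapply(agg, `[[`, numeric(1), "n"),
                    n_hit = vapply(agg, `[[`, numeric(1), "hits"),
                    stringsAsFactors = FALSE)
  res$hit_fraction <- res$n_hit / res$n_assayed
  res <- res[res$hit_fraction >= min_fraction, , drop = FALSE]
  res <- res[order(-res$hit_fraction, res$strain_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assemble a strain x screen LGR matrix from screen tables
#' @param screens named list of [screen_table()]s.
#' @param value which column to use (default "lgr_smoothed").
#' @return numeric matrix, strains in rows, screens in columns, NA where a
#'   strain is absent from a screen.
#' @export
screen_matrix <- function(screens, value = "lgr_smoothed") {
  stopifnot(length(screens) >= 2)
  nm <- names(screens)
  if (is.null(nm)) nm <- vapply(screens, function(s) s$screen_name,
                                character(1))
  strains <- sort(unique(unlist(lapply(screens,
                                       function(s) s$data$strain_id))))
  mat <- matrix(NA_real_, length(strains), length(screens),
                dimnames = list(strains, nm))
  for (k in seq_along(screens)) {
    d <- screens[[k]]$data
    mat[match(d$strain_id, strains), k] <- d[[value]]
  }
  mat
}
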
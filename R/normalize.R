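# Colony sizes -> per-strain LGRs: plate normalization, log growth ratios,
# spatial smoothing, duplicate aggregation and Z-transformation.

#' Normalization configuration
#'
#' @param plate_norm `"plate_median"` (primary screens: every physical plate
#'   is rescaled so its nonzero-size median is 1) or `"reference_strains"`
#'   (validation screens: the median of the GFP-free reference colonies on
#'   each physical plate is scaled to 1).
#' @param smoothing_window odd integer >= 3, side length (grid cells) of the
#'   square neighborhood used by [spatial_smooth()]. Default 7.
#' @param smoothing_min_neighbors minimum non-missing neighbors required to
#'   adjust a position; positions with fewer are left unadjusted and flagged.
#'   Must be <= smoothing_window^2 - 1. Default 8.
#' @param condition_summary how replicate sizes are summarized per condition
#'   before the log ratio: `"mean"` (default) or `"median"`.
#' @return A `normalization_config` list.
#' @export
normalization_config <- function(plate_norm = c("plate_median",
                                                "reference_strains"),
                                 smoothing_window = 7,
                                 smoothing_min_neighbors = 8,
                                 condition_summary = c("mean", "median")) {
  plate_norm <- match.arg(plate_norm)
  condition_summary <- match.arg(condition_summary)
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 3 || smoothing_window %% 2 == 0)
    stop("smoothing_window must be an odd integer >= 3")
  smoothing_min_neighbors <- as.integer(smoothing_min_neighbors)
  if (smoothing_min_neighbors < 1 ||
      smoothing_min_neighbors > smoothing_window^2 - 1)
    stop("smoothing_min_neighbors must be in [1, smoothing_window^2 - 1]")
  structure(list(plate_norm = plate_norm,
                 smoothing_window = smoothing_window,
                 smoothing_min_neighbors = smoothing_min_neighbors,
                 condition_summary = condition_summary,
                 log_base = "natural"),
            class = "normalization_config")
}

# physical plate key: one scanned plate = plate_id x condition x replicate
plate_key <- function(df) paste(df$plate_id, df$condition, df$replicate,
                                sep = "\r")

#' Rescale colony sizes plate by plate
#'
#' Each physical plate (a plate_id x condition x replicate combination) is
#' divided by a plate-level scale: the median of its nonzero colony sizes
#' (`plate_median` mode) or the median size of its GFP-free reference
#' colonies (`reference_strains` mode; references are identified by the
#' [gfp_free_prefix()] strain-id prefix). Idempotent: renormalizing changes
#' nothing.
#'
#' @param observations colony observation data.frame.
#' @param config a [normalization_config()].
#' @return The observations with `size` rescaled (plate medians equal 1).
#' @export
plate_normalize <- function(observations, config = normalization_config()) {
  key <- plate_key(observations)
  scale <- vapply(split(seq_len(nrow(observations)), key), function(idx) {
    sizes <- observations$size[idx]
    if (config$plate_norm == "reference_strains") {
      ref <- is_gfp_free(observations$strain_id[idx])
      if (sum(ref) == 0)
        stop("no GFP-free reference colonies on plate ",
             observations$plate_id[idx[1]], " (", observations$condition[idx[1]],
             ", replicate ", observations$replicate[idx[1]], ")")
      if (sum(ref) < 3)
        stop("fewer than 3 GFP-free reference colonies on plate ",
             observations$plate_id[idx[1]])
      sizes <- sizes[ref]
    }
    nz <- sizes[sizes > 0]
    if (length(nz) == 0)
      stop("plate ", observations$plate_id[idx[1]],
           " has no nonzero colonies (",
           observations$condition[idx[1]], ", replicate ",
           observations$replicate[idx[1]], ")")
    stats::median(nz)
  }, numeric(1))
  observations$size <- observations$size / scale[key]
  observations
}

summarize_sizes <- function(sizes, how) {
  nz <- sizes[sizes > 0]
  if (length(nz) == 0) return(list(value = NA_real_, n_dead = length(sizes),
                                   n = length(sizes)))
  v <- if (how == "median") stats::median(nz) else mean(nz)
  list(value = v, n_dead = sum(sizes == 0), n = length(sizes))
}

#' Compute position-level log growth ratios
#'
#' For every arrayed position, the LGR is the mean over available control
#' conditions c of `ln(mean_size(control c) / mean_size(experimental))`,
#' where each condition's size is the arithmetic mean of its nonzero
#' replicates (zero = dead colony). Positive LGR = growth defect. The layout
#' is paired: a position's controls are the colonies at the same
#' (plate_id, row, col) in the control conditions.
#'
#' Flags: `dead` (all experimental replicates zero; LGR is NA, never +Inf),
#' `control_failure` (some control condition all-zero at that position),
#' `sick` (at least half the experimental replicates dead but not all; still
#' scored).
#'
#' @param observations plate-normalized colony observations containing an
#'   `experimental` condition and at least one of `control_a` / `control_b`.
#' @param config a [normalization_config()].
#' @return data.frame with columns plate_id, row, col, strain_id, lgr, flags.
#' @export
compute_lgr <- function(observations, config = normalization_config()) {
  conds <- unique(observations$condition)
  if (!("experimental" %in% conds))
    stop("no 'experimental' condition in observations")
  controls <- intersect(c("control_a", "control_b"), conds)
  if (length(controls) == 0)
    stop("no control condition (control_a/control_b) in observations")
  pos_key <- paste(observations$plate_id, observations$row, observations$col,
                   sep = "\r")
  exp_idx <- which(observations$condition == "experimental")
  first_exp <- exp_idx[!duplicated(pos_key[exp_idx])]
  keys <- pos_key[first_exp]
  # per-condition mean of nonzero replicate sizes (median on request)
  cond_summary <- function(cond) {
    idx <- which(observations$condition == cond)
    k <- pos_key[idx]
    sizes <- observations$size[idx]
    nz <- sizes > 0
    if (config$condition_summary == "median") {
      vals <- vapply(split(sizes[nz], k[nz]), stats::median, numeric(1))
      means <- vals[match(keys, names(vals))]
    } else {
      sums <- rowsum(sizes * nz, k)
      cnts <- rowsum(as.numeric(nz), k)
      m <- match(keys, rownames(sums))
      means <- (sums / ifelse(cnts == 0, NA, cnts))[m, 1]
    }
    n_tot_m <- rowsum(rep(1, length(idx)), k)
    mm <- match(keys, rownames(n_tot_m))
    n_dead <- rowsum(as.numeric(!nz), k)[mm, 1]
    n_tot <- n_tot_m[mm, 1]
    n_dead[is.na(n_dead)] <- 0
    n_tot[is.na(n_tot)] <- 0
    list(mean = unname(means), n_dead = unname(n_dead), n = unname(n_tot))
  }
  s_exp <- cond_summary("experimental")
  ctrl_means <- vapply(controls, function(cc) cond_summary(cc)$mean,
                       numeric(length(keys)))
  ctrl_means <- matrix(ctrl_means, nrow = length(keys))
  log_ratio <- log(ctrl_means) - log(s_exp$mean)
  n_ok <- rowSums(!is.na(log_ratio))
  lgr <- ifelse(n_ok > 0, rowMeans(log_ratio, na.rm = TRUE), NA_real_)
  lgr[is.na(s_exp$mean)] <- NA_real_
  dead <- is.na(s_exp$mean)
  sick <- !dead & s_exp$n_dead > 0 & 2 * s_exp$n_dead >= s_exp$n
  ctrl_fail <- rowSums(is.na(ctrl_means)) > 0
  flags <- mapply(function(d, s, cf) {
    paste(c(if (cf) "control_failure", if (d) "dead", if (s) "sick"),
          collapse = ";")
  }, dead, sick, ctrl_fail)
  res <- data.frame(plate_id = observations$plate_id[first_exp],
                    row = observations$row[first_exp],
                    col = observations$col[first_exp],
                    strain_id = observations$strain_id[first_exp],
                    lgr = lgr, flags = unname(flags),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Aggregate duplicate library copies of a strain
#'
#' Libraries can contain multiple copies of the same strain at distinct
#' plate positions; their (smoothed) LGRs are combined by arithmetic mean.
#' Flags of the copies are unioned.
#'
#' @param lgr_df data.frame with columns strain_id, lgr and optionally flags.
#' @return data.frame with one row per strain: strain_id, lgr, n_copies,
#'   flags.
#' @export
aggregate_duplicates <- function(lgr_df) {
  id <- lgr_df$strain_id
  ok <- !is.na(lgr_df$lgr)
  sums <- rowsum(ifelse(ok, lgr_df$lgr, 0), id)
  cnts <- rowsum(as.numeric(ok), id)
  n_copies <- rowsum(rep(1L, length(id)), id)
  strains <- rownames(sums)
  lgr <- ifelse(cnts[, 1] > 0, sums[, 1] / cnts[, 1], NA_real_)
  flags <- rep("", length(strains))
  if ("flags" %in% names(lgr_df)) {
    flagged <- nzchar(lgr_df$flags)
    if (any(flagged)) {
      fl <- vapply(split(lgr_df$flags[flagged], id[flagged]), function(f) {
        u <- unique(unlist(strsplit(f, ";", fixed = TRUE)))
        paste(u[nzchar(u)], collapse = ";")
      }, character(1))
      flags[match(names(fl), strains)] <- fl
    }
  }
  res <- data.frame(strain_id = strains, lgr = unname(lgr),
                    n_copies = as.integer(n_copies[, 1]), flags = flags,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Spatial smoothing of plate LGRs by self-excluding windowed medians
#'
#' Removes smooth spatial artifacts (gradients from uneven growth or imaging)
#' from per-position LGRs. For each position, the local background is the
#' median LGR in the centered `smoothing_window` x `smoothing_window`
#' neighborhood excluding the position itself; the adjusted value is
#' `raw - local_median`, and adjusted values are then recentered so that the
#' plate-wide median is preserved. Self-exclusion keeps an isolated hit from
#' erasing itself. Positions with fewer than `smoothing_min_neighbors`
#' non-missing neighbors are left unadjusted and flagged `unsmoothed`.
#'
#' @param lgr_df position-level LGR data.frame from [compute_lgr()].
#' @param geometry a [plate_geometry()].
#' @param config a [normalization_config()].
#' @return `lgr_df` with an added `lgr_smoothed` column and updated flags.
#' @export
spatial_smooth <- function(lgr_df, geometry,
                           config = normalization_config()) {
  w <- config$smoothing_window
  if (w > geometry$n_rows || w > geometry$n_cols)
    stop(sprintf("smoothing window %d exceeds plate geometry %dx%d",
                 w, geometry$n_rows, geometry$n_cols))
  half <- (w - 1L) %/% 2L
  lgr_df$lgr_smoothed <- NA_real_
  for (pid in unique(lgr_df$plate_id)) {
    idx <- which(lgr_df$plate_id == pid)
    grid <- matrix(NA_real_, geometry$n_rows, geometry$n_cols)
    grid[cbind(lgr_df$row[idx], lgr_df$col[idx])] <- lgr_df$lgr[idx]
    plate_median <- stats::median(grid, na.rm = TRUE)
    adj <- rep(NA_real_, length(idx))
    adjusted <- rep(FALSE, length(idx))
    for (k in seq_along(idx)) {
      r <- lgr_df$row[idx[k]]; cc <- lgr_df$col[idx[k]]
      x <- grid[r, cc]
      if (is.na(x)) next
      rr <- max(1L, r - half):min(geometry$n_rows, r + half)
      cr <- max(1L, cc - half):min(geometry$n_cols, cc + half)
      neigh <- grid[rr, cr]
      neigh <- neigh[-((match(cc, cr) - 1L) * length(rr) + match(r, rr))]
      neigh <- neigh[!is.na(neigh)]
      if (length(neigh) < config$smoothing_min_neighbors) {
        adj[k] <- x
      } else {
        adj[k] <- x - stats::median(neigh)
        adjusted[k] <- TRUE
      }
    }
    # recenter the adjusted positions so the plate-wide median is preserved
    if (any(adjusted)) {
      shift <- plate_median - stats::median(adj, na.rm = TRUE)
      adj[adjusted] <- adj[adjusted] + shift
    }
    lgr_df$lgr_smoothed[idx] <- adj
    if (any(!adjusted & !is.na(lgr_df$lgr[idx]))) {
      k <- idx[!adjusted & !is.na(lgr_df$lgr[idx])]
      lgr_df$flags[k] <- ifelse(nzchar(lgr_df$flags[k]),
                                paste0(lgr_df$flags[k], ";unsmoothed"),
                                "unsmoothed")
    }
  }
  lgr_df
}

#' Z-transformation
#'
#' Standardizes values to sample mean 0 and sample standard deviation 1
#' (denominator n - 1). Order-preserving and affine-invariant.
#'
#' @param x numeric vector, length >= 2, nonzero variance (NAs tolerated and
#'   propagated).
#' @return numeric vector of Z-scores.
#' @export
z_transform <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("z_transform needs at least 2 non-missing values")
  s <- stats::sd(x[ok])
  if (s == 0) stop("z_transform: zero variance")
  (x - mean(x[ok])) / s
}

#' Probability mass of the standard normal on (-z, z)
#'
#' The coverage convention behind the classical `|Z| < 2` interval used to
#' call hits: for z = 2 the mass is 0.9545, i.e. at least the nominal 95%.
#'
#' @param z positive threshold in standard deviations (default 2).
#' @return probability in (0, 1).
#' @export
z_interval_mass <- function(z = 2) {
  stopifnot(z > 0)
  stats::pnorm(z) - stats::pnorm(-z)
}
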
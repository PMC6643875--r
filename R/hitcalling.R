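# Posterior hit probabilities q(x), the L_q and L_Z cutoffs, hit calling,
# and validation-rate / false-positive-rate prediction.

check_hit_peak <- function(fit, what) {
  if (!identical(fit$classification, "hit_peak"))
    stop(what, " requires a hit_peak fit (got '", fit$classification,
         "'); use the Z-based cutoff for this screen")
  invisible(TRUE)
}

#' Posterior probability of belonging to the hit peak
#'
#' q(x) is the conditional probability that a strain with measured LGR x
#' belongs to Component 2 (the hit peak):
#' `q(x) = rho2 f2(x) / [(1 - rho2) f1(x) + rho2 f2(x)]`.
#' Evaluated in log space so it is stable arbitrarily far from both means.
#'
#' @param x numeric LGR(s); must be finite.
#' @param fit a [mixture_fit()] classified `hit_peak` (override with
#'   `check = FALSE` for diagnostics).
#' @param check enforce the hit_peak precondition (default TRUE).
#' @return Probabilities in (0, 1).
#' @export
q_posterior <- function(x, fit, check = TRUE) {
  if (any(!is.finite(x))) stop("q_posterior: x must be finite")
  if (check) check_hit_peak(fit, "q_posterior")
  if (fit$rho2 <= 0) return(rep(0, length(x)))
  if (fit$rho2 >= 1) return(rep(1, length(x)))
  l1 <- log1p(-fit$rho2) + stats::dnorm(x, fit$mu1, fit$sigma1, log = TRUE)
  l2 <- log(fit$rho2)   + stats::dnorm(x, fit$mu2, fit$sigma2, log = TRUE)
  stats::plogis(l2 - l1)
}

#' LGR cutoff where the hit posterior crosses a threshold
#'
#' L_q is the smallest LGR in `[mu1, mu2]` with `q(x) = q_threshold`; at the
#' default threshold 0.5 a strain at the cutoff is equally likely to come
#' from either component. Located by bisection to |dx| < 1e-9 on the first
#' sign change of a dense grid over `[mu1, mu2]` (with unequal variances
#' q can also cross outside the means; only the between-means crossing is a
#' meaningful cutoff).
#'
#' @param fit a `hit_peak` [mixture_fit()].
#' @param q_threshold posterior threshold in (0, 1), default 0.5.
#' @return The cutoff LGR.
#' @export
lq_cutoff <- function(fit, q_threshold = 0.5) {
  stopifnot(q_threshold > 0, q_threshold < 1)
  check_hit_peak(fit, "lq_cutoff")
  f <- function(x) q_posterior(x, fit) - q_threshold
  if (f(fit$mu1) >= 0)
    stop("components indistinguishable: q(mu1) already >= ", q_threshold)
  grid <- seq(fit$mu1, fit$mu2, length.out = 512)
  fg <- f(grid)
  k <- which(fg >= 0)[1]
  if (is.na(k))
    stop("components indistinguishable: q(x) < ", q_threshold,
         " on all of [mu1, mu2]")
  lo <- grid[k - 1]; hi <- grid[k]
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' LGR cutoff where the Z-transformation reaches a threshold
#'
#' `L_Z = mean(lgrs) + z_threshold * sd(lgrs)` (sample sd, n - 1).
#'
#' @param lgrs numeric LGRs (NAs dropped).
#' @param z_threshold Z threshold, default 2.
#' @return The cutoff LGR.
#' @export
lz_cutoff <- function(lgrs, z_threshold = 2) {
  x <- lgrs[is.finite(lgrs)]
  if (length(x) < 2) stop("lz_cutoff needs at least 2 finite values")
  s <- stats::sd(x)
  if (s == 0) stop("lz_cutoff: zero variance")
  mean(x) + z_threshold * s
}

#' Cutoff set for one screen
#'
#' @param fit a [mixture_fit()].
#' @param lgrs smoothed per-strain LGRs of the screen.
#' @param z_threshold Z cutoff (default 2).
#' @param q_threshold posterior cutoff (default 0.5).
#' @return list with L_Z, L_q (NA unless the fit is `hit_peak`), and the
#'   thresholds used.
#' @export
cutoff_set <- function(fit, lgrs, z_threshold = 2, q_threshold = 0.5) {
  L_q <- if (identical(fit$classification, "hit_peak"))
    lq_cutoff(fit, q_threshold) else NA_real_
  list(L_Z = lz_cutoff(lgrs, z_threshold), L_q = L_q,
       z_threshold = z_threshold, q_threshold = q_threshold)
}

#' Call hits for a screen
#'
#' Flags every strain under both the Z cutoff (`z_score >= z_threshold`) and
#' the posterior cutoff (`q >= q_threshold`); both comparisons are closed at
#' the boundary. For fits without a usable hit peak, the q/pv columns and
#' `hit_q` are NA with a warning — the Z-based list is then authoritative.
#' Growth enhancers (`z_score <= -z_threshold`) are annotated separately and
#' are never hits: they rarely reproduced in validation.
#'
#' @param screen a [screen_table()] with smoothed LGRs and Z-scores.
#' @param fit the screen's [mixture_fit()].
#' @param cutoffs a [cutoff_set()]; computed from `fit` and the screen when
#'   omitted.
#' @param flags optional data.frame (strain_id, flags) carried through from
#'   [compute_lgr()] / [aggregate_duplicates()].
#' @return A hit-table data.frame (see [write_hit_table()]).
#' @export
call_hits <- function(screen, fit, cutoffs = NULL, flags = NULL) {
  d <- screen$data
  if (is.null(cutoffs)) cutoffs <- cutoff_set(fit, d$lgr_smoothed)
  use_q <- identical(fit$classification, "hit_peak")
  if (!use_q)
    warning("fit classified '", fit$classification,
            "': q-based hit calls unavailable, Z-based list is authoritative")
  finite <- is.finite(d$lgr_smoothed)
  q <- rep(NA_real_, nrow(d)); pv <- rep(NA_real_, nrow(d))
  if (use_q) {
    q[finite] <- q_posterior(d$lgr_smoothed[finite], fit)
    pv[finite] <- pv_validation(d$lgr_smoothed[finite], fit)
  }
  fl <- rep("", nrow(d))
  if (!is.null(flags)) {
    m <- match(d$strain_id, flags$strain_id)
    fl <- ifelse(is.na(m), "", flags$flags[m])
  }
  hits <- data.frame(
    strain_id = d$strain_id,
    lgr = d$lgr_smoothed,
    z_score = d$z_score,
    q = q, pv = pv,
    hit_z = d$z_score >= cutoffs$z_threshold,
    hit_q = if (use_q) q >= cutoffs$q_threshold else NA,
    enhancer = d$z_score <= -cutoffs$z_threshold,
    flags = fl,
    stringsAsFactors = FALSE
  )
  attr(hits, "cutoffs") <- cutoffs
  hits
}

#' Predicted probability of validation
#'
#' Baseline definition: `pV(x) = q(x)`, the posterior probability of being a
#' true hit; the predicted false-positive rate at x is `1 - pV(x)`. The
#' optional noise-aware variant additionally requires that a true hit's
#' higher-replicate re-measurement clears the validation threshold: it
#' multiplies by `P(N(x, sigma_m^2 / n_reps) > threshold)`, with the
#' per-measurement sd `sigma_m` taken as `sigma1 * sqrt(n_reps_primary)`
#' (attributing the null-peak spread to primary-screen replicate noise).
#'
#' @param x LGR value(s) measured in the primary screen.
#' @param fit a `hit_peak` [mixture_fit()].
#' @param noise_aware use the re-measurement variant (default FALSE).
#' @param threshold validation threshold (required if `noise_aware`).
#' @param n_reps_primary,n_reps_validation replicate counts (defaults 4, 16).
#' @return Probabilities in (0, 1).
#' @export
pv_validation <- function(x, fit, noise_aware = FALSE, threshold = NULL,
                          n_reps_primary = 4, n_reps_validation = 16) {
  q <- q_posterior(x, fit)
  if (!noise_aware) return(q)
  if (is.null(threshold))
    stop("noise_aware pV needs the validation threshold")
  sigma_m <- fit$sigma1 * sqrt(n_reps_primary)
  p_clear <- stats::pnorm(threshold, mean = x,
                          sd = sigma_m / sqrt(n_reps_validation),
                          lower.tail = FALSE)
  q * p_clear
}

#' Predicted false-positive-rate curve
#'
#' @param grid LGR grid.
#' @param fit a `hit_peak` [mixture_fit()].
#' @return data.frame(lgr, predicted_fpr) with `predicted_fpr = 1 - pV`.
#' @export
predict_fpr <- function(grid, fit) {
  data.frame(lgr = grid, predicted_fpr = 1 - pv_validation(grid, fit))
}

#' Validation threshold from GFP-free control LGRs
#'
#' A strain validates if its high-replicate re-screen LGR exceeds a cutoff
#' set by GFP-free controls: `mean + 2 sd` of the control LGRs by default,
#' or their 95th percentile with `method = "percentile"`.
#'
#' @param gfp_free_lgrs numeric vector, >= 20 values required.
#' @param method `"mean_sd"` (default) or `"percentile"`.
#' @param z sd multiplier for `mean_sd` (default 2).
#' @param probs percentile for `"percentile"` (default 0.95).
#' @return The threshold LGR.
#' @export
validation_threshold <- function(gfp_free_lgrs, method = c("mean_sd",
                                                           "percentile"),
                                 z = 2, probs = 0.95) {
  method <- match.arg(method)
  x <- gfp_free_lgrs[is.finite(gfp_free_lgrs)]
  if (length(x) < 20)
    stop("validation_threshold needs >= 20 GFP-free control LGRs, got ",
         length(x))
  if (method == "percentile") return(stats::quantile(x, probs, names = FALSE))
  s <- stats::sd(x)
  if (s == 0) return(x[1])
  mean(x) + z * s
}

#' Empirical false-positive rate in bins of primary-screen LGR
#'
#' Strains with validation records are binned by their primary-screen LGR;
#' the empirical FPR per bin is the fraction of strains that failed to
#' validate. Bins holding fewer than `min_count` strains are flagged
#' low-confidence.
#'
#' @param lgrs named numeric vector: primary-screen LGR per strain_id.
#' @param validation data.frame(strain_id, validated) — the validation
#'   outcome of the re-screen; every record must match a screened strain.
#' @param breaks bin edges, or a single bin width (bins then cover the LGR
#'   range of the validated set).
#' @param min_count minimum strains per confident bin (default 10).
#' @return data.frame(bin_lo, bin_hi, n, n_validated, empirical_fpr,
#'   low_confidence).
#' @export
empirical_fpr_binned <- function(lgrs, validation, breaks = 0.1,
                                 min_count = 10) {
  if (nrow(validation) == 0) stop("empty validation set")
  if (is.null(names(lgrs))) stop("lgrs must be named by strain_id")
  m <- match(validation$strain_id, names(lgrs))
  if (any(is.na(m)))
    stop("validation record for unscreened strain: ",
         validation$strain_id[which(is.na(m))[1]])
  x <- lgrs[m]
  if (length(breaks) == 1) {
    lo <- floor(min(x) / breaks) * breaks
    hi <- ceiling(max(x) / breaks) * breaks
    breaks <- seq(lo, hi + breaks / 2, by = breaks)
  }
  bin <- cut(x, breaks, include.lowest = TRUE)
  tab <- lapply(split(seq_along(x), bin), function(idx) {
    if (length(idx) == 0) return(NULL)
    data.frame(n = length(idx),
               n_validated = sum(validation$validated[idx]))
  })
  keep <- !vapply(tab, is.null, logical(1))
  res <- do.call(rbind, tab[keep])
  lev <- which(keep)
  res$bin_lo <- breaks[lev]
  res$bin_hi <- breaks[lev + 1]
  res$empirical_fpr <- 1 - res$n_validated / res$n
  res$low_confidence <- res$n < min_count
  rownames(res) <- NULL
  res[, c("bin_lo", "bin_hi", "n", "n_validated", "empirical_fpr",
          "low_confidence")]
}
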
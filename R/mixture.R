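# Two-component Gaussian mixture fitting by EM, model comparison against a
# single normal, and fit-quality classification.
#
# The model: f(x) = (1 - rho2) N(x; mu1, sigma1^2) + rho2 N(x; mu2, sigma2^2),
# with Component 1 the central (empirical-null) peak of unaffected strains
# and Component 2 the right-shifted hit peak (label convention mu2 >= mu1).

#' Fitting configuration
#'
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts number of random quantile-split initializations.
#' @param variance_floor_frac variance floor as a fraction of the sample
#'   variance; prevents singular-likelihood collapse onto single points.
#' @param seed integer seed governing the random starts.
#' @param classify_mu2_min minimum peak separation (mu2 - mu1) in units of
#'   sigma1 for a fit to count as having a hit peak.
#' @param classify_sigma2_max maximum sigma2 / sigma1 ratio before a fit is
#'   classified `high_variance` (high Component-2 variance screens predicted
#'   validation poorly).
#' @return A `fit_config` list.
#' @export
fit_config <- function(tol = 1e-8, max_iter = 1000, n_starts = 10,
                       variance_floor_frac = 1e-4, seed = 1L,
                       classify_mu2_min = 2.0, classify_sigma2_max = 4.0) {
  stopifnot(tol > 0, n_starts >= 1, max_iter >= 1, variance_floor_frac > 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts),
                 variance_floor_frac = variance_floor_frac,
                 seed = as.integer(seed),
                 classify_mu2_min = classify_mu2_min,
                 classify_sigma2_max = classify_sigma2_max),
            class = "fit_config")
}

#' Construct a mixture fit object directly
#'
#' Mostly useful for tests and for evaluating cutoffs at externally supplied
#' parameters. `fit_mixture()` is the estimation entry point.
#'
#' @param rho2 mixing proportion of Component 2 in `[0, 1]`.
#' @param mu1,sigma1 Component 1 (central peak) mean and sd.
#' @param mu2,sigma2 Component 2 (hit peak) mean and sd; `mu2 >= mu1`.
#' @param n sample size the fit refers to (used by classification).
#' @param config a [fit_config()] supplying classification thresholds.
#' @param loglik,n_iter,converged,loglik_trace optional diagnostics.
#' @return An object of class `mixture_fit`.
#' @export
mixture_fit <- function(rho2, mu1, sigma1, mu2, sigma2, n = NA_integer_,
                        config = fit_config(), loglik = NA_real_,
                        n_iter = NA_integer_, converged = NA,
                        loglik_trace = numeric(0)) {
  stopifnot(rho2 >= 0, rho2 <= 1, sigma1 > 0, sigma2 > 0)
  if (mu2 < mu1) {  # relabel so Component 2 is the right peak
    tmp <- c(mu1, sigma1); mu1 <- mu2; sigma1 <- sigma2
    mu2 <- tmp[1]; sigma2 <- tmp[2]; rho2 <- 1 - rho2
  }
  fit <- structure(list(rho2 = rho2, mu1 = mu1, sigma1 = sigma1,
                        mu2 = mu2, sigma2 = sigma2, loglik = loglik,
                        n = n, n_iter = n_iter, converged = converged,
                        loglik_trace = loglik_trace,
                        classification = NA_character_),
                   class = "mixture_fit")
  fit$classification <- classify_fit(fit, config)
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<mixture_fit: rho2=%.4f mu1=%.4f sigma1=%.4f ",
                     "mu2=%.4f sigma2=%.4f loglik=%.2f [%s]>\n"),
              x$rho2, x$mu1, x$sigma1, x$mu2, x$sigma2, x$loglik,
              x$classification))
  invisible(x)
}

# one EM run from a given initialization; returns fit diagnostics
em_run <- function(x, init, tol, max_iter, var_floor) {
  n <- length(x)
  rho2 <- init$rho2; mu <- c(init$mu1, init$mu2)
  sig2 <- pmax(c(init$sigma1, init$sigma2)^2, var_floor)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step (log space)
    l1 <- log1p(-rho2) + stats::dnorm(x, mu[1], sqrt(sig2[1]), log = TRUE)
    l2 <- log(rho2)   + stats::dnorm(x, mu[2], sqrt(sig2[2]), log = TRUE)
    m <- pmax(l1, l2)
    lse <- m + log(exp(l1 - m) + exp(l2 - m))
    ll <- sum(lse)
    trace[iter] <- ll
    if (is.finite(ll) && is.finite(ll_old)) {
      rel <- abs(ll - ll_old) / (abs(ll_old) + .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
    if (iter >= max_iter) break
    ll_old <- ll
    g2 <- exp(l2 - lse)           # responsibility of Component 2
    g1 <- 1 - g2
    # M step with variance floor
    w2 <- sum(g2); w1 <- n - w2
    rho2 <- w2 / n
    rho2 <- min(max(rho2, 1e-12), 1 - 1e-12)
    mu[1] <- sum(g1 * x) / max(w1, .Machine$double.eps)
    mu[2] <- sum(g2 * x) / max(w2, .Machine$double.eps)
    sig2[1] <- max(sum(g1 * (x - mu[1])^2) / max(w1, .Machine$double.eps),
                   var_floor)
    sig2[2] <- max(sum(g2 * (x - mu[2])^2) / max(w2, .Machine$double.eps),
                   var_floor)
  }
  list(rho2 = rho2, mu1 = mu[1], sigma1 = sqrt(sig2[1]),
       mu2 = mu[2], sigma2 = sqrt(sig2[2]),
       loglik = trace[iter], n_iter = iter, converged = converged,
       trace = trace)
}

#' Fit the two-component Gaussian mixture by EM
#'
#' Runs `n_starts` EM fits initialized by quantile splits (Component 2
#' seeded from a random top fraction between 5% and 30% of the data) and
#' returns the best-log-likelihood fit, relabeled so `mu2 >= mu1`. Ties in
#' log-likelihood break toward the smallest `rho2` (the most conservative
#' hit fraction). The per-iteration log-likelihood trace is stored and is
#' non-decreasing (EM monotonicity).
#'
#' @param lgrs numeric vector of (smoothed) per-strain LGRs; at least 50
#'   finite values required.
#' @param config a [fit_config()].
#' @return A [mixture_fit()] with diagnostics and classification.
#' @export
fit_mixture <- function(lgrs, config = fit_config()) {
  x <- lgrs[is.finite(lgrs)]
  n <- length(x)
  if (n < 50) stop("insufficient data: need >= 50 finite LGRs, got ", n)
  var_floor <- config$variance_floor_frac * stats::var(x)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)
  qs <- stats::runif(config$n_starts, 0.05, 0.30)
  best <- NULL
  for (s in seq_len(config$n_starts)) {
    cut <- stats::quantile(x, 1 - qs[s], names = FALSE)
    top <- x[x > cut]; rest <- x[x <= cut]
    if (length(top) < 2 || length(rest) < 2) next
    init <- list(rho2 = length(top) / n,
                 mu1 = mean(rest), sigma1 = max(stats::sd(rest), 1e-8),
                 mu2 = mean(top),  sigma2 = max(stats::sd(top), 1e-8))
    run <- em_run(x, init, config$tol, config$max_iter, var_floor)
    # rho2 after the mu2 >= mu1 relabeling, for the conservative tie-break
    run$rho2_right <- if (run$mu2 >= run$mu1) run$rho2 else 1 - run$rho2
    if (is.null(best) ||
        run$loglik > best$loglik + 1e-9 * abs(best$loglik) ||
        (abs(run$loglik - best$loglik) <= 1e-9 * abs(best$loglik) &&
         run$rho2_right < best$rho2_right))
      best <- run
  }
  if (is.null(best)) stop("all EM starts failed")
  fit <- mixture_fit(best$rho2, best$mu1, best$sigma1, best$mu2, best$sigma2,
                     n = n, config = config, loglik = best$loglik,
                     n_iter = best$n_iter, converged = best$converged,
                     loglik_trace = best$trace)
  # degenerate collapse: a component pinned at the floor with ~no mass
  at_floor <- (min(fit$sigma1, fit$sigma2)^2 <= var_floor * (1 + 1e-8))
  if (at_floor && min(fit$rho2, 1 - fit$rho2) < 1 / n) {
    fit$converged <- FALSE
    fit$classification <- "no_hit_peak"
  }
  fit
}

#' Classify the quality of a mixture fit
#'
#' `no_hit_peak`: the fitted peaks are closer than `classify_mu2_min` null
#' standard deviations, or Component 2 carries less than 1/n of the mass —
#' the screen has too few hits for the empirical-Bayes machinery, and a
#' Z-transformation is the appropriate tool. `high_variance`: sigma2 exceeds
#' `classify_sigma2_max` times sigma1 — such screens validated poorly and
#' the posterior should not be trusted. Otherwise `hit_peak`.
#'
#' @param fit a [mixture_fit()].
#' @param config a [fit_config()].
#' @return One of `"hit_peak"`, `"no_hit_peak"`, `"high_variance"`.
#' @export
classify_fit <- function(fit, config = fit_config()) {
  sep <- (fit$mu2 - fit$mu1) / fit$sigma1
  rho_min <- if (is.na(fit$n)) 0 else 1 / fit$n
  if (sep < config$classify_mu2_min || fit$rho2 < rho_min) return("no_hit_peak")
  if (fit$sigma2 / fit$sigma1 > config$classify_sigma2_max)
    return("high_variance")
  "hit_peak"
}

#' Mixture and component densities
#'
#' @param x numeric vector of LGRs.
#' @param fit a [mixture_fit()].
#' @param k component index (1 = central/null peak, 2 = hit peak).
#' @return Density values.
#' @export
mixture_density <- function(x, fit) {
  (1 - fit$rho2) * component_density(x, fit, 1) +
    fit$rho2 * component_density(x, fit, 2)
}

#' @rdname mixture_density
#' @export
component_density <- function(x, fit, k) {
  stopifnot(k %in% c(1, 2))
  if (k == 1) stats::dnorm(x, fit$mu1, fit$sigma1)
  else stats::dnorm(x, fit$mu2, fit$sigma2)
}

#' Compare the mixture against a single-normal model
#'
#' Fits the maximum-likelihood single normal to the same data and reports
#' the log-likelihood difference and the BIC difference (mixture - normal;
#' negative favors the mixture). The mixture has 5 free parameters, the
#' normal 2.
#'
#' @param lgrs the data the fit was computed on.
#' @param fit a [mixture_fit()] from [fit_mixture()].
#' @return list with loglik_mixture, loglik_normal, delta_loglik, bic_mixture,
#'   bic_normal, delta_bic.
#' @export
compare_unimodal <- function(lgrs, fit) {
  x <- lgrs[is.finite(lgrs)]
  n <- length(x)
  mu <- mean(x)
  sigma_ml <- sqrt(sum((x - mu)^2) / n)   # MLE, denominator n
  ll_norm <- sum(stats::dnorm(x, mu, sigma_ml, log = TRUE))
  ll_mix <- sum(log(mixture_density(x, fit)))
  bic_mix <- -2 * ll_mix + 5 * log(n)
  bic_norm <- -2 * ll_norm + 2 * log(n)
  list(loglik_mixture = ll_mix, loglik_normal = ll_norm,
       delta_loglik = ll_mix - ll_norm,
       bic_mixture = bic_mix, bic_normal = bic_norm,
       delta_bic = bic_mix - bic_norm)
}
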
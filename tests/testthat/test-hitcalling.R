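test_that("q_posterior matches closed forms and symmetry", {
  sym <- demo_fit(0.5, 0, 0.3, 1, 0.3)
  expect_equal(q_posterior(0.5, sym), 0.5, tolerance = 1e-12)

  # direct high-precision evaluation at x = 0: equal variances reduce to a
  # logistic in the exponent (mu2^2 - 2 x mu2) / (2 sigma^2)
  q0 <- 1 / (1 + exp((1^2 - 2 * 0 * 1) / (2 * 0.3^2)))
  expect_equal(q_posterior(0, sym), q0, tolerance = 1e-12)
  expect_equal(q0, 0.00385, tolerance = 1e-3)

  expect_error(q_posterior(Inf, sym), "finite")
  expect_error(q_posterior(0.5, demo_fit(0.2, 0, 0.2, 0.1, 0.2)),
               "hit_peak")
})

test_that("q_posterior is stable far from both means (log space)", {
  fit <- demo_fit(0.15, 0, 0.2, 1, 0.4)
  far_right <- fit$mu2 + 50 * fit$sigma2
  expect_equal(q_posterior(far_right, fit), 1, tolerance = 1e-12)
  # with sigma2 > sigma1 the wide component also dominates the far-left
  # tail; the value must still be finite, in [0,1], and match the exact
  # log-ratio computed by hand
  far_left <- fit$mu1 - 50 * fit$sigma1
  ql <- q_posterior(far_left, fit)
  expect_true(is.finite(ql) && ql >= 0 && ql <= 1)
  lr <- (log(0.15) + dnorm(far_left, 1, 0.4, log = TRUE)) -
    (log(0.85) + dnorm(far_left, 0, 0.2, log = TRUE))
  expect_equal(ql, plogis(lr), tolerance = 1e-12)
})

test_that("q_posterior equals the brute-force density ratio on a dense grid", {
  set.seed(12)
  for (k in 1:20) {
    rho2 <- runif(1, 0.05, 0.4)
    s1 <- runif(1, 0.1, 0.3); s2 <- runif(1, s1 + 0.05, 0.8)
    mu2 <- runif(1, 3 * s1, 2)
    fit <- mixture_fit(rho2, 0, s1, mu2, s2)
    if (!identical(fit$classification, "hit_peak")) next
    grid <- seq(-1, mu2 + 2, length.out = 200)
    brute <- rho2 * dnorm(grid, mu2, s2) /
      ((1 - rho2) * dnorm(grid, 0, s1) + rho2 * dnorm(grid, mu2, s2))
    expect_equal(q_posterior(grid, fit), brute, tolerance = 1e-10)
  }
})

test_that("lq_cutoff: symmetry, monotonicity, grid oracle, root quality", {
  sym <- demo_fit(0.5, 0, 0.3, 1, 0.3)
  expect_equal(lq_cutoff(sym), 0.5, tolerance = 1e-8)

  rare <- demo_fit(0.2, 0, 0.3, 1, 0.3)
  expect_gt(lq_cutoff(rare), 0.5)  # shifts toward the rarer component

  fit <- demo_fit(0.15, 0, 0.2, 1.0, 0.4)
  grid <- seq(fit$mu1, fit$mu2, by = 1e-6)
  oracle <- grid[which(q_posterior(grid, fit) >= 0.5)[1]]
  expect_equal(lq_cutoff(fit), oracle, tolerance = 2e-6)
  expect_lt(abs(q_posterior(lq_cutoff(fit), fit) - 0.5), 1e-8)

  # monotone decreasing in rho2
  cuts <- vapply(c(0.05, 0.1, 0.2, 0.4),
                 function(r) lq_cutoff(demo_fit(r, 0, 0.2, 1, 0.4)),
                 numeric(1))
  expect_true(all(diff(cuts) < 0))

  # indistinguishable components: q(mu1) already above threshold
  big <- mixture_fit(0.99, 0, 0.3, 0.7, 0.3)
  expect_error(lq_cutoff(big), "indistinguishable")
})

test_that("lz_cutoff closed form and equivariance", {
  set.seed(13)
  x <- rnorm(200, 0, 0.3)
  expect_equal(lz_cutoff(x), mean(x) + 2 * sd(x), tolerance = 1e-12)
  expect_equal(lz_cutoff(x + 0.7), lz_cutoff(x) + 0.7, tolerance = 1e-12)
  expect_error(lz_cutoff(rep(0.2, 50)), "zero variance")
})

test_that("call_hits flags hits at closed boundaries and handles fallbacks", {
  lgr <- c(-0.1, 0.2, 0.5, 1.2, 2.0)
  z <- z_transform(lgr)
  d <- data.frame(strain_id = letters[1:5], lgr_raw = lgr,
                  lgr_smoothed = lgr, z_score = z)
  st <- screen_table("demo", d)
  fit <- demo_fit(0.15, 0, 0.2, 1.0, 0.4)
  cut <- cutoff_set(fit, lgr)
  hits <- call_hits(st, fit, cut)
  expect_identical(hits$hit_z, z >= cut$z_threshold)
  expect_identical(hits$hit_q, q_posterior(lgr, fit) >= 0.5)
  expect_identical(hits$enhancer, z <= -2)

  # a strain exactly at L_Z is a hit (>= convention)
  base <- seq(-0.3, 0.6, length.out = 19)
  at <- uniroot(function(v) {
    y <- c(base, v); v - mean(y) - 2 * sd(y)
  }, c(0.6, 10), tol = 1e-12)$root
  lgr_at <- c(base, at)
  d2 <- data.frame(strain_id = sprintf("s%02d", 1:20), lgr_raw = lgr_at,
                   lgr_smoothed = lgr_at, z_score = z_transform(lgr_at))
  hits2 <- call_hits(screen_table("demo2", d2), fit,
                     cutoff_set(fit, lgr_at))
  expect_true(hits2$hit_z[20])

  # all LGRs far below both cutoffs: no hits
  low <- seq(-0.4, 0.05, length.out = 60)
  d3 <- data.frame(strain_id = sprintf("s%02d", 1:60), lgr_raw = low,
                   lgr_smoothed = low, z_score = z_transform(low))
  hits3 <- call_hits(screen_table("low", d3), fit,
                     cutoff_set(fit, low, z_threshold = 3))
  expect_equal(sum(hits3$hit_q), 0)

  # no_hit_peak fit: hit_q is NA with a warning, Z list is authoritative
  flat <- mixture_fit(0.2, 0, 0.2, 0.1, 0.2)
  expect_warning(hits4 <- call_hits(st, flat, cutoff_set(flat, lgr)),
                 "authoritative")
  expect_true(all(is.na(hits4$hit_q)))
  expect_false(any(is.na(hits4$hit_z)))
})

test_that("pv_validation: baseline is q, complement gives predicted FPR", {
  fit <- demo_fit(0.15, 0, 0.2, 1.0, 0.4)
  lq <- lq_cutoff(fit)
  expect_equal(pv_validation(lq, fit), 0.5, tolerance = 1e-8)
  # where predicted FPR is 20%, pV is 0.8
  curve <- predict_fpr(seq(0, 1.5, by = 1e-4), fit)
  x20 <- curve$lgr[which(curve$predicted_fpr <= 0.2)[1]]
  expect_equal(pv_validation(x20, fit), 0.8, tolerance = 1e-3)
  # noise-aware variant never exceeds the baseline
  expect_lte(pv_validation(0.6, fit, noise_aware = TRUE, threshold = 0.3),
             pv_validation(0.6, fit))
})

test_that("predicted FPR is monotone non-increasing between the means", {
  fit <- demo_fit(0.15, 0, 0.2, 1.0, 0.4)
  grid <- seq(fit$mu1, fit$mu2, length.out = 300)
  expect_true(all(diff(predict_fpr(grid, fit)$predicted_fpr) <= 1e-12))
})

test_that("validation_threshold from GFP-free controls", {
  expect_equal(validation_threshold(rep(0.05, 25)), 0.05)  # sd 0 edge
  set.seed(14)
  x <- rnorm(20000, 0, 0.1)
  expect_equal(validation_threshold(x), 0.2, tolerance = 0.01)
  expect_equal(validation_threshold(x + 0.3), validation_threshold(x) + 0.3,
               tolerance = 1e-12)
  expect_error(validation_threshold(rnorm(10)), ">= 20")
  # percentile option
  expect_equal(validation_threshold(x, method = "percentile"),
               quantile(x, 0.95, names = FALSE))
})

test_that("empirical_fpr_binned computes per-bin failure fractions", {
  lgrs <- setNames(seq(0.05, 1.95, by = 0.1), sprintf("s%02d", 1:20))
  val <- data.frame(strain_id = names(lgrs),
                    validated = rep(c(TRUE, FALSE), 10))
  out <- empirical_fpr_binned(lgrs, val, breaks = c(0, 1, 2), min_count = 10)
  expect_equal(out$n, c(10, 10))
  expect_equal(out$empirical_fpr, c(0.5, 0.5))
  expect_false(any(out$low_confidence))

  all_good <- val; all_good$validated <- TRUE
  out2 <- empirical_fpr_binned(lgrs, all_good, breaks = c(0, 2))
  expect_equal(out2$empirical_fpr, 0)

  # 3 of 10 failing -> 0.30
  v3 <- val[1:10, ]; v3$validated <- c(rep(TRUE, 7), rep(FALSE, 3))
  out3 <- empirical_fpr_binned(lgrs[1:10], v3, breaks = c(0, 1.5))
  expect_equal(out3$empirical_fpr, 0.3)
  expect_true(out3$low_confidence == FALSE)

  expect_error(empirical_fpr_binned(lgrs, val[0, ]), "empty")
  bad <- rbind(val, data.frame(strain_id = "ghost", validated = TRUE))
  expect_error(empirical_fpr_binned(lgrs, bad), "ghost")
})

test_that("q cutoff has wider hit-count dynamic range than Z (simulated)", {
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2), function(rho) {
    x <- local({ set.seed(round(1000 * rho) + 17)
      hit <- runif(2000) < rho
      ifelse(hit, rnorm(2000, 1.0, 0.4), rnorm(2000, 0, 0.2)) })
    fit <- fit_mixture(x, fit_config(seed = 17))
    lq <- lq_cutoff(fit)
    lz <- lz_cutoff(x)
    c(q = sum(x >= lq), z = sum(x >= lz))
  }, numeric(2))
  expect_gt(diff(range(counts["q", ])), diff(range(counts["z", ])))
})
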
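test_that("plate_normalize scales each physical plate to unit median", {
  df <- tiny_colonies(list(experimental = c(2, 4, 6)))
  out <- plate_normalize(df)
  expect_equal(out$size, c(1/2, 1, 3/2))

  # already at unit median: identity
  expect_equal(plate_normalize(out)$size, out$size)

  # idempotence on arbitrary data
  df2 <- tiny_colonies(list(experimental = c(3, 9, 27, 81)))
  once <- plate_normalize(df2)
  expect_equal(plate_normalize(once)$size, once$size, tolerance = 1e-14)
})

test_that("plates with different medians become comparable", {
  a <- tiny_colonies(list(experimental = c(5, 10, 15)), plate_id = "pA")
  b <- tiny_colonies(list(experimental = c(10, 20, 30)), plate_id = "pB")
  out <- plate_normalize(rbind(a, b))
  expect_equal(out$size[out$plate_id == "pA"],
               out$size[out$plate_id == "pB"])
})

test_that("plate_normalize error cases", {
  dead <- tiny_colonies(list(experimental = c(0, 0, 0)))
  expect_error(plate_normalize(dead), "no nonzero")
  df <- tiny_colonies(list(experimental = c(2, 4, 6)))
  expect_error(
    plate_normalize(df, normalization_config(plate_norm =
                                               "reference_strains")),
    "GFP-free")
})

test_that("reference_strains mode scales by the GFP-free colonies", {
  df <- tiny_colonies(list(experimental = c(2, 4, 6, 10, 20, 30)),
                      strain_ids = c("a", "b", "c", "gfp_free_1",
                                     "gfp_free_2", "gfp_free_3"))
  out <- plate_normalize(df, normalization_config(plate_norm =
                                                    "reference_strains"))
  # gfp-free median is 20 -> all sizes divided by 20
  expect_equal(out$size, df$size / 20)
})

test_that("compute_lgr matches closed forms and averages per-control logs", {
  # control mean equals experimental mean -> 0
  df <- tiny_colonies(list(experimental = c(4, 4), control_a = c(4, 4)))
  expect_equal(compute_lgr(df)$lgr, c(0, 0))

  # control mean = 2 x experimental -> ln 2
  df <- tiny_colonies(list(experimental = 3, control_a = 6))
  expect_equal(compute_lgr(df)$lgr, log(2), tolerance = 1e-12)

  # per-control ratios e^1 and e^3 -> average of logs = 2
  df <- tiny_colonies(list(experimental = 1, control_a = exp(1),
                           control_b = exp(3)))
  expect_equal(compute_lgr(df)$lgr, 2, tolerance = 1e-12)
})

test_that("compute_lgr is antisymmetric under swapping with one control", {
  set.seed(4)
  sizes_e <- runif(6, 50, 500); sizes_c <- runif(6, 50, 500)
  fwd <- tiny_colonies(list(experimental = sizes_e, control_a = sizes_c))
  rev <- tiny_colonies(list(experimental = sizes_c, control_a = sizes_e))
  expect_equal(compute_lgr(fwd)$lgr, -compute_lgr(rev)$lgr,
               tolerance = 1e-12)
})

test_that("dead, sick and control-failure strains are flagged not infinite", {
  base <- list(
    experimental = data.frame(plate_id = "p1", row = 1:3, col = 1L,
                              strain_id = c("dead", "sick", "ctlfail"),
                              condition = "experimental", replicate = 1L,
                              size = c(0, 0, 100), stringsAsFactors = FALSE),
    rep2 = data.frame(plate_id = "p1", row = 1:3, col = 1L,
                      strain_id = c("dead", "sick", "ctlfail"),
                      condition = "experimental", replicate = 2L,
                      size = c(0, 80, 100), stringsAsFactors = FALSE),
    ctl = data.frame(plate_id = "p1", row = 1:3, col = 1L,
                     strain_id = c("dead", "sick", "ctlfail"),
                     condition = "control_a", replicate = 1L,
                     size = c(100, 100, 0), stringsAsFactors = FALSE))
  obs <- do.call(rbind, c(base, list(make.row.names = FALSE)))
  out <- compute_lgr(obs)
  out <- out[match(c("dead", "sick", "ctlfail"), out$strain_id), ]
  expect_true(is.na(out$lgr[1]))
  expect_match(out$flags[1], "dead")
  expect_true(is.finite(out$lgr[2]))
  expect_match(out$flags[2], "sick")
  expect_true(is.na(out$lgr[3]))
  expect_match(out$flags[3], "control_failure")
})

test_that("aggregate_duplicates averages copies and records counts", {
  df <- data.frame(strain_id = c("a", "a", "b"), lgr = c(1, 2, 5),
                   stringsAsFactors = FALSE)
  out <- aggregate_duplicates(df)
  expect_equal(out$lgr[out$strain_id == "a"], 1.5)
  expect_equal(out$n_copies[out$strain_id == "a"], 2L)
  expect_equal(out$lgr[out$strain_id == "b"], 5)

  # idempotence on x,x,x and identity for single copies
  set.seed(1)
  x <- rnorm(1)
  df <- data.frame(strain_id = rep("z", 3), lgr = rep(x, 3))
  expect_equal(aggregate_duplicates(df)$lgr, x)
})

test_that("spatial smoothing: identity, gradients, outliers, oracle", {
  # spatially uniform plate unchanged
  flat <- matrix(0.3, 9, 9)
  expect_equal(smooth_matrix(flat, 3, 3), flat)

  # constant row-gradient, no hits: interior becomes constant
  grad <- matrix(rep(seq(0, 0.8, length.out = 9), each = 9), 9, 9,
                 byrow = FALSE)
  grad <- t(grad)  # gradient along rows
  sm <- smooth_matrix(grad, 3, 3)
  interior <- sm[3:7, 3:7]
  expect_lt(max(interior) - min(interior), 1e-12)

  # single outlier on a flat plate survives self-exclusion
  spike <- matrix(0.1, 9, 9); spike[5, 5] <- 3
  sm <- smooth_matrix(spike, 3, 3)
  expect_equal(sm[5, 5], 3, tolerance = 1e-12)
  expect_equal(sm[1, 1], 0.1, tolerance = 1e-12)

  # random plates match the brute-force oracle exactly
  set.seed(7)
  for (k in 1:5) {
    g <- matrix(rnorm(81, 0, 0.3), 9, 9)
    g[sample(81, 5)] <- NA  # some missing positions
    expect_equal(smooth_matrix(g, 5, 6), oracle_smooth(g, 5, 6),
                 tolerance = 1e-12)
  }
})

test_that("spatial smoothing preserves the plate median and rejects huge windows", {
  set.seed(21)
  g <- matrix(rnorm(16 * 24, 0.2, 0.3), 16, 24)
  sm <- smooth_matrix(g, 7, 8)
  expect_equal(median(sm), median(g), tolerance = 1e-9)
  df <- data.frame(plate_id = "p1", row = 1, col = 1, strain_id = "s",
                   lgr = 0.1, flags = "")
  expect_error(spatial_smooth(df, plate_geometry(4, 4),
                              normalization_config(smoothing_window = 7)),
               "exceeds")
})

test_that("z_transform matches the hand computation and is affine-invariant", {
  z <- z_transform(1:5)
  expect_equal(z, c(-2, -1, 0, 1, 2) / sqrt(2.5), tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  set.seed(8)
  x <- rnorm(40)
  expect_equal(z_transform(3.7 * x + 11), z_transform(x), tolerance = 1e-12)
  expect_identical(order(z_transform(x)), order(x))  # order-preserving
  expect_error(z_transform(rep(1, 10)), "zero variance")

  # a data point sitting at mean + 2 sd scores exactly 2
  x[1] <- uniroot(function(v) { y <- c(v, x[-1]); v - mean(y) - 2 * sd(y) },
                  c(0, 100), tol = 1e-12)$root
  expect_equal(z_transform(x)[1], 2, tolerance = 1e-8)
})

test_that("smoothing then z keeps hit ranks on gradient-free plates", {
  cfg <- sim_config(n_genes = 350, rho2_true = 0.1, gradient_amplitude = 0,
                    duplicate_fraction = 0, n_gfp_free = 24, seed = 31)
  sim <- simulate_screen(cfg)
  a <- analyze_screen(sim$observations, cfg$geometry, fit = FALSE)
  d <- a$screen$data
  # z is a monotone map of the smoothed LGRs
  expect_identical(order(d$z_score), order(d$lgr_smoothed))
  # and smoothing barely perturbs ranks when there is no artifact
  expect_gt(cor(d$lgr_raw, d$lgr_smoothed, method = "spearman"), 0.95)
})

test_that("smoothing reduces null-gene error when a gradient is injected", {
  restored <- vapply(1:3, function(s) {
    errs <- vapply(c(0, 0.5), function(ga) {
      cfg <- sim_config(n_genes = 800, rho2_true = 0.1,
                        gradient_amplitude = ga, duplicate_fraction = 0,
                        seed = 100 + s)
      sim <- simulate_screen(cfg)
      a <- analyze_screen(sim$observations, cfg$geometry, fit = FALSE)
      m <- match(sim$truth$strain_id, a$screen$data$strain_id)
      null <- sim$truth$component == 1
      c(raw = mean(abs(a$screen$data$lgr_raw[m][null]), na.rm = TRUE),
        sm = mean(abs(a$screen$data$lgr_smoothed[m][null]), na.rm = TRUE))
    }, numeric(2))
    # with the gradient, smoothing must beat raw
    expect_lt(errs["sm", 2], errs["raw", 2])
    # fraction of the gradient-attributable degradation removed
    lost <- errs["raw", 2] - errs["raw", 1]
    expect_gt(lost, 0)
    1 - (errs["sm", 2] - errs["sm", 1]) / lost
  }, numeric(1))
  expect_gte(mean(restored), 0.8)
})
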
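# Plate-level screen simulator: lognormal colony sizes with plate offsets
# and smooth spatial gradients, a mixture-structured gene-effect
# distribution (null peak + right-shifted hit peak), replicate noise, and
# matched high-replicate validation re-screens with ground truth.

#' Simulation configuration
#'
#' The generative model for the log colony size of gene g at plate position
#' (r, c) under condition k is
#' `log(base_size) + plate_offset + gradient(r, c) - theta_g [experimental
#' only] + N(0, sigma_noise^2)`,
#' where `theta_g = 0` for null genes and `theta_g ~ N(mu2_true,
#' sigma2_true^2)` truncated at 0 for hits (growth defects only). Controls
#' share the plate layout (paired design); the gradient field and plate
#' offset are drawn independently for every physical plate copy, the way
#' drying and incubator artifacts actually arise.
#'
#' @param n_genes number of library genes.
#' @param geometry a [plate_geometry()] (default 16 x 24, 384 format).
#' @param n_replicates_primary replicates in the primary screen (default 4).
#' @param n_replicates_validation replicates in re-screens (default 16).
#' @param rho2_true fraction of genes that are hits (default 0.15).
#' @param mu2_true,sigma2_true hit-effect distribution, LGR units (defaults
#'   1.0, 0.35).
#' @param sigma_noise per-colony log-size noise sd (default 0.33, which with
#'   4 replicates and two controls yields a null LGR sd near 0.2).
#' @param plate_offset_sd sd of per-physical-plate log-scale offsets
#'   (default 0.15).
#' @param gradient_amplitude maximum additive log-size tilt across a plate
#'   (default 0.2; set 0 for artifact-free plates).
#' @param duplicate_fraction fraction of genes arrayed twice (default 0.05).
#' @param n_gfp_free GFP-free reference colonies per plate (default 8).
#' @param base_size median healthy colony size, arbitrary pixel units
#'   (default 500).
#' @param dead_rate probability a colony fails entirely (size 0; default 0).
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 4000, geometry = plate_geometry(16, 24),
                       n_replicates_primary = 4,
                       n_replicates_validation = 16,
                       rho2_true = 0.15, mu2_true = 1.0, sigma2_true = 0.35,
                       sigma_noise = 0.33, plate_offset_sd = 0.15,
                       gradient_amplitude = 0.2, duplicate_fraction = 0.05,
                       n_gfp_free = 8, base_size = 500, dead_rate = 0,
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(rho2_true >= 0, rho2_true <= 1, sigma_noise > 0,
            sigma2_true > 0, duplicate_fraction >= 0, dead_rate >= 0,
            dead_rate < 1)
  structure(list(n_genes = as.integer(n_genes), geometry = geometry,
                 n_replicates_primary = as.integer(n_replicates_primary),
                 n_replicates_validation = as.integer(n_replicates_validation),
                 rho2_true = rho2_true, mu2_true = mu2_true,
                 sigma2_true = sigma2_true, sigma_noise = sigma_noise,
                 plate_offset_sd = plate_offset_sd,
                 gradient_amplitude = gradient_amplitude,
                 duplicate_fraction = duplicate_fraction,
                 n_gfp_free = as.integer(n_gfp_free),
                 base_size = base_size, dead_rate = dead_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected null-LGR standard deviation under the noise model
#'
#' With per-colony log-size noise sd `sigma_noise`, `n_replicates` replicates
#' averaged per condition and `n_controls` control conditions averaged into
#' the LGR, the null LGR sd is approximately
#' `sigma_noise * sqrt((1 + 1/n_controls) / n_replicates)`.
#'
#' @param sigma_noise per-colony log-size noise sd.
#' @param n_replicates replicates per condition.
#' @param n_controls control conditions averaged (default 2).
#' @return The approximate null LGR sd.
#' @export
lgr_noise_sd <- function(sigma_noise, n_replicates, n_controls = 2) {
  sigma_noise * sqrt((1 + 1 / n_controls) / n_replicates)
}

#' Invert the noise model: generator settings for target LGR mixture
#'
#' Given the mixture parameters the *measured* LGR distribution should have
#' (null sd `sigma1`, hit-component mean `mu2` and sd `sigma2`), returns the
#' per-colony noise sd and true-effect spread that produce them:
#' measurement noise adds in quadrature to the true-effect spread, so
#' `sigma2_true = sqrt(sigma2^2 - sigma1^2)`.
#'
#' @param rho2,mu2,sigma1,sigma2 target measured-mixture parameters.
#' @param n_replicates primary-screen replicates.
#' @param n_controls control conditions (default 2).
#' @return list(rho2_true, mu2_true, sigma2_true, sigma_noise).
#' @export
sim_params_for_lgr_mixture <- function(rho2, mu2, sigma1, sigma2,
                                       n_replicates = 4, n_controls = 2) {
  if (sigma2 <= sigma1)
    stop("target sigma2 must exceed sigma1 (noise adds in quadrature)")
  list(rho2_true = rho2, mu2_true = mu2,
       sigma2_true = sqrt(sigma2^2 - sigma1^2),
       sigma_noise = sigma1 / sqrt((1 + 1 / n_controls) / n_replicates))
}

# deterministic RNG scope: run code under a seed, restore global state
with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# assign strain positions across plates; gfp-free references get reserved
# random positions on every plate
build_layout <- function(strain_ids, geometry, n_gfp_free) {
  ppp <- geometry$n_rows * geometry$n_cols
  usable <- ppp - n_gfp_free
  if (usable < 1)
    stop("geometry too small: ", ppp, " positions but ", n_gfp_free,
         " reserved for GFP-free references")
  n_plates <- ceiling(length(strain_ids) / usable)
  rows <- list()
  pos_all <- expand.grid(row = seq_len(geometry$n_rows),
                         col = seq_len(geometry$n_cols))
  idx <- 1L
  for (p in seq_len(n_plates)) {
    pid <- sprintf("p%03d", p)
    perm <- sample.int(ppp)
    gfp_pos <- perm[seq_len(n_gfp_free)]
    n_here <- min(usable, length(strain_ids) - idx + 1L)
    strain_pos <- perm[n_gfp_free + seq_len(n_here)]
    gfp_ids <- sprintf("%s_%s_r%02dc%02d", gfp_free_prefix(), pid,
                       pos_all$row[gfp_pos], pos_all$col[gfp_pos])
    rows[[p]] <- data.frame(
      plate_id = pid,
      row = c(pos_all$row[strain_pos], pos_all$row[gfp_pos]),
      col = c(pos_all$col[strain_pos], pos_all$col[gfp_pos]),
      strain_id = c(strain_ids[idx:(idx + n_here - 1L)], gfp_ids),
      stringsAsFactors = FALSE)
    idx <- idx + n_here
  }
  do.call(rbind, rows)
}

# smooth linear tilt, drawn independently per physical plate: every plate
# copy (condition x replicate) grows and dries on its own, so its artifact
# field is its own -- this is what makes spatial smoothing worthwhile
make_gradient <- function(amplitude) {
  ang <- stats::runif(1, 0, 2 * pi)
  list(u = cos(ang), v = sin(ang), amplitude = amplitude)
}

grad_at <- function(g, row, col, geometry) {
  if (g$amplitude == 0) return(rep(0, length(row)))
  rs <- if (geometry$n_rows > 1) (row - 1) / (geometry$n_rows - 1) - 0.5
        else rep(0, length(row))
  cs <- if (geometry$n_cols > 1) (col - 1) / (geometry$n_cols - 1) - 0.5
        else rep(0, length(col))
  g$amplitude * (g$u * rs + g$v * cs)
}

draw_effects <- function(strain_ids, config, hit_strains = NULL) {
  n <- length(strain_ids)
  if (is.null(hit_strains)) {
    is_hit <- stats::runif(n) < config$rho2_true
  } else {
    is_hit <- strain_ids %in% hit_strains
  }
  theta <- numeric(n)
  k <- sum(is_hit)
  if (k > 0) {
    draw <- stats::rnorm(k, config$mu2_true, config$sigma2_true)
    while (any(draw <= 0))   # truncate at 0: growth defects only
      draw[draw <= 0] <- stats::rnorm(sum(draw <= 0), config$mu2_true,
                                      config$sigma2_true)
    theta[is_hit] <- draw
  }
  data.frame(strain_id = strain_ids,
             component = ifelse(is_hit, 2L, 1L),
             theta = theta, stringsAsFactors = FALSE)
}

emit_colonies <- function(layout, theta_by_strain, config,
                          conditions, n_replicates) {
  geometry <- config$geometry
  plate_ids <- unique(layout$plate_id)
  plate_rows <- lapply(plate_ids, function(p) which(layout$plate_id == p))
  names(plate_rows) <- plate_ids
  theta <- theta_by_strain[layout$strain_id]
  theta[is.na(theta)] <- 0   # gfp-free references carry no effect
  out <- vector("list", length(conditions) * n_replicates)
  i <- 0L
  for (cond in conditions) {
    for (rep_k in seq_len(n_replicates)) {
      i <- i + 1L
      offs <- stats::rnorm(length(plate_ids), 0, config$plate_offset_sd)
      names(offs) <- plate_ids
      g <- numeric(nrow(layout))
      for (pid in plate_ids) {
        k <- plate_rows[[pid]]
        g[k] <- grad_at(make_gradient(config$gradient_amplitude),
                        layout$row[k], layout$col[k], geometry)
      }
      effect <- if (cond == "experimental") theta else 0
      logsize <- log(config$base_size) + offs[layout$plate_id] + g -
        effect + stats::rnorm(nrow(layout), 0, config$sigma_noise)
      size <- exp(logsize)
      if (config$dead_rate > 0)
        size[stats::runif(nrow(layout)) < config$dead_rate] <- 0
      out[[i]] <- data.frame(plate_id = layout$plate_id, row = layout$row,
                             col = layout$col, strain_id = layout$strain_id,
                             condition = cond, replicate = rep_k,
                             size = size, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a primary screen
#'
#' Generates colony observations for the experimental condition, two control
#' conditions and per-plate GFP-free reference colonies, plus the ground
#' truth (component label and true effect theta per gene). Deterministic for
#' a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param hit_strains optional character vector planting the exact hit set
#'   (overrides the Binomial(rho2_true) draw; theta still drawn from the
#'   hit-effect distribution).
#' @return list(observations = colony data.frame, truth = data.frame(
#'   strain_id, component, theta), layout = position assignments).
#' @export
simulate_screen <- function(config, hit_strains = NULL) {
  with_seed(config$seed, {
    n_dup <- round(config$duplicate_fraction * config$n_genes)
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    dup_ids <- if (n_dup > 0) sample(genes, n_dup) else character(0)
    strain_positions <- sample(c(genes, dup_ids))
    layout <- build_layout(strain_positions, config$geometry,
                           config$n_gfp_free)
    truth <- draw_effects(genes, config, hit_strains)
    theta <- stats::setNames(truth$theta, truth$strain_id)
    obs <- emit_colonies(layout, theta, config,
                         c("experimental", "control_a", "control_b"),
                         config$n_replicates_primary)
    validate_colony_table(obs, config$geometry)
    list(observations = obs, truth = truth, layout = layout)
  })
}

#' Simulate a validation re-screen
#'
#' Re-arrays the selected strains at `n_replicates_validation` replicates
#' with fresh noise under the same generative model and true effects, with
#' GFP-free reference colonies on every plate for normalization and
#' thresholding.
#'
#' @param truth the `truth` data.frame from [simulate_screen()].
#' @param selected character vector of strain ids to re-screen (must all be
#'   known to `truth`).
#' @param config the [sim_config()] of the primary screen.
#' @param seed seed for the re-screen (default `config$seed + 1000`).
#' @return list(observations, truth = truth rows for the selected strains).
#' @export
simulate_validation <- function(truth, selected, config,
                                seed = config$seed + 1000L) {
  unknown <- setdiff(selected, truth$strain_id)
  if (length(unknown) > 0)
    stop("unknown strain in validation selection: ", unknown[1])
  with_seed(seed, {
    layout <- build_layout(sample(selected), config$geometry,
                           config$n_gfp_free)
    theta <- stats::setNames(truth$theta, truth$strain_id)
    obs <- emit_colonies(layout, theta, config,
                         c("experimental", "control_a", "control_b"),
                         config$n_replicates_validation)
    validate_colony_table(obs, config$geometry)
    list(observations = obs,
         truth = truth[truth$strain_id %in% selected, , drop = FALSE])
  })
}

#' Write a fixed-seed fixture suite
#'
#' Emits small deterministic screens exercising the regimes the analysis
#' distinguishes: an "SPB-like" screen (many strong hits: high rho2, high
#' mu2), a "few-hit" screen (rho2 = 0.02, the regime where the mixture finds
#' no hit peak and a Z-transformation is appropriate), a gradient-heavy
#' plate set, and an 8-screen LGR matrix in which 5 screens share a planted
#' hit set (for clustering tests).
#'
#' @param out_dir writable directory.
#' @param n_genes genes per fixture screen (default 800, desk scale).
#' @return Named character vector of written file paths.
#' @export
make_fixture_suite <- function(out_dir, n_genes = 800) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  emit <- function(name, sim) {
    p <- file.path(out_dir, paste0(name, "_colonies.tsv"))
    write_colony_table(sim$observations, p,
                       comments = paste0("fixture: ", name))
    tp <- file.path(out_dir, paste0(name, "_truth.tsv"))
    utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(stats::setNames(p, name), stats::setNames(tp, paste0(name, "_truth")))
  }
  spb <- simulate_screen(sim_config(n_genes = n_genes, rho2_true = 0.2,
                                    mu2_true = 1.2, gradient_amplitude = 0.1,
                                    seed = 101L))
  paths <- c(paths, emit("spb_like", spb))
  # few weak hits: the regime without a well-defined hit peak, where the
  # Z-transformation is the right tool
  few <- simulate_screen(sim_config(n_genes = n_genes, rho2_true = 0.02,
                                    mu2_true = 0.3, gradient_amplitude = 0.1,
                                    seed = 102L))
  paths <- c(paths, emit("few_hit", few))
  grad <- simulate_screen(sim_config(n_genes = n_genes, rho2_true = 0.1,
                                     gradient_amplitude = 0.5, seed = 103L))
  paths <- c(paths, emit("gradient_heavy", grad))
  # 8-screen matrix: screens 1-5 share a planted hit set, 6-8 do not
  shared_hits <- sprintf("g%05d", seq_len(round(0.15 * n_genes)))
  screens <- list()
  for (k in 1:8) {
    hit_set <- if (k <= 5) shared_hits else NULL
    cfg <- sim_config(n_genes = n_genes, rho2_true = 0.15,
                      gradient_amplitude = 0.1, seed = 200L + k)
    sim <- simulate_screen(cfg, hit_strains = hit_set)
    st <- analyze_screen(sim$observations, cfg$geometry,
                         screen_name = sprintf("screen_%d", k))$screen
    screens[[sprintf("screen_%d", k)]] <- st
    p <- file.path(out_dir, sprintf("matrix_screen_%d.tsv", k))
    write_screen_table(st, p)
    paths <- c(paths, stats::setNames(p, sprintf("matrix_screen_%d", k)))
  }
  paths
}
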
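# Pipeline composition and command-line entry point.

#' Analyze one screen from colony observations
#'
#' Runs the full per-screen pipeline in order: plate normalization ->
#' position-level LGRs -> spatial smoothing -> duplicate aggregation ->
#' Z-transformation -> mixture fit -> fit classification -> cutoffs -> hit
#' calls. GFP-free reference colonies are excluded from the gene list; their
#' LGRs are returned for validation thresholding. Hit calling follows the
#' fit classification: the posterior cutoff for `hit_peak` fits, the Z
#' cutoff otherwise.
#'
#' @param observations colony observation data.frame.
#' @param geometry a [plate_geometry()].
#' @param norm_config a [normalization_config()].
#' @param fit_cfg a [fit_config()].
#' @param screen_name name recorded on the screen table.
#' @param z_threshold,q_threshold cutoff thresholds (defaults 2, 0.5).
#' @param n_replicates recorded on the screen table metadata.
#' @param fit whether to fit the mixture and call hits (default TRUE).
#' @return list(screen, fit, cutoffs, hits, gfp_free_lgrs, positions,
#'   method) where `method` is "q" or "z" depending on the fit
#'   classification.
#' @export
analyze_screen <- function(observations, geometry,
                           norm_config = normalization_config(),
                           fit_cfg = fit_config(),
                           screen_name = "screen",
                           z_threshold = 2, q_threshold = 0.5,
                           n_replicates = NA_integer_, fit = TRUE) {
  normalized <- plate_normalize(observations, norm_config)
  positions <- compute_lgr(normalized, norm_config)
  positions <- spatial_smooth(positions, geometry, norm_config)
  is_ref <- is_gfp_free(positions$strain_id)
  gfp_free_lgrs <- positions$lgr_smoothed[is_ref]
  genes <- positions[!is_ref, , drop = FALSE]
  agg_raw <- aggregate_duplicates(
    data.frame(strain_id = genes$strain_id, lgr = genes$lgr,
               flags = genes$flags, stringsAsFactors = FALSE))
  agg_sm <- aggregate_duplicates(
    data.frame(strain_id = genes$strain_id, lgr = genes$lgr_smoothed,
               stringsAsFactors = FALSE))
  z <- rep(NA_real_, nrow(agg_sm))
  ok <- is.finite(agg_sm$lgr)
  z[ok] <- z_transform(agg_sm$lgr[ok])
  screen <- screen_table(screen_name,
                         data.frame(strain_id = agg_sm$strain_id,
                                    lgr_raw = agg_raw$lgr,
                                    lgr_smoothed = agg_sm$lgr,
                                    z_score = z, stringsAsFactors = FALSE),
                         n_replicates = n_replicates,
                         provenance = "screenmix::analyze_screen")
  out <- list(screen = screen, gfp_free_lgrs = gfp_free_lgrs,
              positions = positions,
              flags = agg_raw[, c("strain_id", "flags")])
  if (fit) {
    out$fit <- fit_mixture(agg_sm$lgr, fit_cfg)
    out$cutoffs <- cutoff_set(out$fit, agg_sm$lgr, z_threshold, q_threshold)
    out$hits <- suppressWarnings(
      call_hits(screen, out$fit, out$cutoffs, flags = out$flags))
    out$method <- if (identical(out$fit$classification, "hit_peak")) "q"
                  else "z"
  }
  out
}

#' Run the full pipeline on a colony table file
#'
#' Reads colonies, runs [analyze_screen()], and writes the screen table, fit
#' summary, hit table, predicted-FPR curve and a JSON run manifest into
#' `out_dir`. Re-running with identical inputs and seed reproduces identical
#' outputs.
#'
#' @param colony_path colony TSV path.
#' @param geometry a [plate_geometry()] or "16x24"-style string.
#' @param out_dir output directory (created if needed).
#' @param screen_name screen name.
#' @param seed seed for the mixture fit starts.
#' @param norm_config,fit_cfg stage configurations.
#' @return The [analyze_screen()] result, invisibly; files in `out_dir`.
#' @export
run_pipeline <- function(colony_path, geometry, out_dir,
                         screen_name = "screen", seed = 1L,
                         norm_config = normalization_config(),
                         fit_cfg = fit_config(seed = seed)) {
  if (is.character(geometry)) geometry <- parse_geometry(geometry)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obs <- read_colony_table(colony_path, geometry)
  res <- analyze_screen(obs, geometry, norm_config, fit_cfg, screen_name)
  write_screen_table(res$screen, file.path(out_dir, "screen.tsv"))
  write_fit_summary(stats::setNames(list(res$fit), screen_name),
                    file.path(out_dir, "fit.tsv"))
  write_hit_table(res$hits, file.path(out_dir, "hits.tsv"),
                  comments = sprintf("method: %s", res$method))
  if (identical(res$fit$classification, "hit_peak")) {
    grid <- seq(res$fit$mu1, res$fit$mu2 + 2 * res$fit$sigma2,
                length.out = 101)
    utils::write.table(predict_fpr(grid, res$fit),
                       file.path(out_dir, "fpr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "run",
                 params = list(screen_name = screen_name,
                               geometry = sprintf("%dx%d", geometry$n_rows,
                                                  geometry$n_cols),
                               plate_norm = norm_config$plate_norm,
                               smoothing_window =
                                 norm_config$smoothing_window),
                 seed = seed, inputs = colony_path)
  invisible(res)
}

#' Write / read a mixture-fit summary table
#' @param fits named list of [mixture_fit()]s.
#' @param path TSV path.
#' @return `path` invisibly (write); a data.frame (read).
#' @export
write_fit_summary <- function(fits, path) {
  df <- screen_param_table(fits)
  full <- data.frame(
    screen_name = df$screen_name,
    rho2 = df$rho2,
    mu1 = vapply(fits, function(f) f$mu1, numeric(1)),
    sigma1 = vapply(fits, function(f) f$sigma1, numeric(1)),
    mu2 = df$mu2, sigma2 = df$sigma2,
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    n = vapply(fits, function(f) as.numeric(f$n), numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    classification = df$classification,
    stringsAsFactors = FALSE)
  utils::write.table(full, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fit_summary
#' @export
read_fit_summary <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_manifest <- function(out_dir, subcommand, params, seed, inputs) {
  checksums <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(subcommand = subcommand, params = params, seed = seed,
                   input_checksums = checksums,
                   tool = "screenmix",
                   version = as.character(utils::packageVersion("screenmix")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# minimal flat "key: value" YAML reader for simulate configs
parse_flat_yaml <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+):\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3) stop("cannot parse config line: ", m[1])
    v <- m[3]
    num <- suppressWarnings(as.numeric(v))
    out[[m[2]]] <- if (!is.na(num)) num else v
  }
  out
}

#' Command-line entry point
#'
#' `screenmix_cli(c("run", "--colonies", "x.tsv", ...))`. Subcommands:
#' `simulate`, `normalize`, `fit`, `hits`, `fpr`, `compare`, `run`. Designed
#' to be driven from a wrapper script via
#' `Rscript -e 'screenmix::screenmix_cli()'`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return 0 on success, invisibly.
#' @export
screenmix_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: screenmix <simulate|normalize|fit|hits|fpr|compare|run> ...")
  sub <- args[1]; rest <- args[-1]
  opt_list <- list(
    optparse::make_option("--colonies", type = "character"),
    optparse::make_option("--screen", type = "character"),
    optparse::make_option("--fit", type = "character"),
    optparse::make_option("--validation", type = "character"),
    optparse::make_option("--matrix", type = "character"),
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--geometry", type = "character",
                          default = "16x24"),
    optparse::make_option("--plate-norm", type = "character",
                          default = "plate_median", dest = "plate_norm"),
    optparse::make_option("--smooth-window", type = "integer", default = 7,
                          dest = "smooth_window"),
    optparse::make_option("--starts", type = "integer", default = 10),
    optparse::make_option("--method", type = "character", default = "both"),
    optparse::make_option("--axis", type = "character", default = "screens"),
    optparse::make_option("--bins", type = "double", default = 0.1),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--name", type = "character", default = "screen"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--out-dir", type = "character", dest = "out_dir"),
    optparse::make_option("--out-tree", type = "character",
                          dest = "out_tree"),
    optparse::make_option("--log-level", type = "character",
                          default = "info", dest = "log_level")
  )
  opts <- optparse::parse_args(optparse::OptionParser(option_list = opt_list),
                               args = rest)
  geometry <- parse_geometry(opts$geometry)
  norm_cfg <- normalization_config(plate_norm = opts$plate_norm,
                                   smoothing_window = opts$smooth_window)
  switch(sub,
    simulate = {
      if (is.null(opts$config) || is.null(opts$out_dir))
        stop("simulate needs --config and --out-dir")
      cfg_vals <- parse_flat_yaml(opts$config)
      cfg_vals$seed <- if (!is.null(cfg_vals$seed)) cfg_vals$seed
                       else opts$seed
      known <- names(formals(sim_config))
      cfg <- do.call(sim_config, cfg_vals[intersect(names(cfg_vals), known)])
      sim <- simulate_screen(cfg)
      dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_colony_table(sim$observations,
                         file.path(opts$out_dir, "colonies.tsv"))
      utils::write.table(sim$truth, file.path(opts$out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(opts$out_dir, "simulate", cfg_vals, cfg$seed,
                     opts$config)
    },
    normalize = {
      if (is.null(opts$colonies) || is.null(opts$out))
        stop("normalize needs --colonies and --out")
      obs <- read_colony_table(opts$colonies, geometry)
      res <- analyze_screen(obs, geometry, norm_cfg, screen_name = opts$name,
                            fit = FALSE)
      write_screen_table(res$screen, opts$out)
      write_manifest(dirname(opts$out), "normalize",
                     list(geometry = opts$geometry,
                          plate_norm = opts$plate_norm,
                          smooth_window = opts$smooth_window),
                     opts$seed, opts$colonies)
    },
    fit = {
      if (is.null(opts$screen) || is.null(opts$out))
        stop("fit needs --screen and --out")
      st <- read_screen_table(opts$screen)
      fit <- fit_mixture(st$data$lgr_smoothed,
                         fit_config(seed = opts$seed,
                                    n_starts = opts$starts))
      write_fit_summary(stats::setNames(list(fit), st$screen_name), opts$out)
      write_manifest(dirname(opts$out), "fit",
                     list(starts = opts$starts), opts$seed, opts$screen)
    },
    hits = {
      if (is.null(opts$screen) || is.null(opts$fit) || is.null(opts$out))
        stop("hits needs --screen, --fit and --out")
      st <- read_screen_table(opts$screen)
      fs <- read_fit_summary(opts$fit)
      fit <- mixture_fit(fs$rho2[1], fs$mu1[1], fs$sigma1[1], fs$mu2[1],
                         fs$sigma2[1], n = fs$n[1])
      hits <- suppressWarnings(call_hits(st, fit))
      write_hit_table(hits, opts$out)
      write_manifest(dirname(opts$out), "hits", list(method = opts$method),
                     opts$seed, c(opts$screen, opts$fit))
    },
    fpr = {
      if (is.null(opts$fit) || is.null(opts$out))
        stop("fpr needs --fit and --out")
      fs <- read_fit_summary(opts$fit)
      fit <- mixture_fit(fs$rho2[1], fs$mu1[1], fs$sigma1[1], fs$mu2[1],
                         fs$sigma2[1], n = fs$n[1])
      grid <- seq(fit$mu1, fit$mu2 + 2 * fit$sigma2, by = opts$bins)
      utils::write.table(predict_fpr(grid, fit), opts$out, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_manifest(dirname(opts$out), "fpr", list(bins = opts$bins),
                     opts$seed, opts$fit)
    },
    compare = {
      if (is.null(opts$matrix) || is.null(opts$out_tree))
        stop("compare needs --matrix and --out-tree")
      mat <- as.matrix(utils::read.delim(opts$matrix, row.names = 1))
      d <- correlation_distance(mat, axis = opts$axis)
      tree <- average_linkage_cluster(d)
      to_newick(tree, opts$out_tree)
      write_manifest(dirname(opts$out_tree), "compare",
                     list(axis = opts$axis), opts$seed, opts$matrix)
    },
    run = {
      if (is.null(opts$colonies) || is.null(opts$out_dir))
        stop("run needs --colonies and --out-dir")
      run_pipeline(opts$colonies, geometry, opts$out_dir,
                   screen_name = opts$name, seed = opts$seed,
                   norm_config = norm_cfg,
                   fit_cfg = fit_config(seed = opts$seed,
                                        n_starts = opts$starts))
    },
    stop("unknown subcommand: ", sub)
  )
  invisible(0L)
}
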
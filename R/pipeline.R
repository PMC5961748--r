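#' Run configuration
#'
#' All tunable parameters of a pipeline run in one place. Every field is
#' echoed into the run manifest, and [run_pipeline_from_manifest()]
#' reproduces a run bit-identically for its CSV/JSON outputs.
#'
#' @param pixel_size micrometres per pixel of the mask.
#' @param min_spur_factor spur-pruning threshold ([prune_network()]).
#' @param rheology list: `kind = "newtonian"` with `mu`, or
#'   `kind = "carreau_yasuda"` with `mu0`, `mu_inf`, `lambda`, `a`, `n`;
#'   `kind = "default_blood"` loads the shipped literature parameters.
#' @param bcs data frame (or list) with `x`, `y` (px), `pressure` (Pa),
#'   `role` — positions are matched to network terminals.
#' @param tolerance_deg against-flow window half-width (default 45).
#' @param threshold_frac sensor threshold level (default 0.60).
#' @param n_bins sensor WSS bins (default 8).
#' @param max_distance_um cell-to-flow matching radius.
#' @param sample_spacing_um WSS sampling step.
#' @param seed seed for any stochastic analysis step.
#' @param regions optional polygon list or file path for region labels.
#' @return a `run_config` list.
#' @export
run_config <- function(pixel_size, bcs, min_spur_factor = 2,
                       rheology = list(kind = "newtonian", mu = 3.5e-3),
                       tolerance_deg = 45, threshold_frac = 0.60,
                       n_bins = 8, max_distance_um = 25,
                       sample_spacing_um = 2, seed = 1L, regions = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

config_rheology <- function(rh) {
  switch(rh$kind,
         newtonian = newtonian(rh$mu),
         carreau_yasuda = carreau_yasuda(rh$mu0, rh$mu_inf, rh$lambda,
                                         rh$a, rh$n),
         default_blood = default_blood_rheology(),
         stop("unknown rheology kind: ", rh$kind))
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$bcs <- as.data.frame(raw$bcs)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full mask-to-statistics pipeline
#'
#' Executes build (skeletonize, graph, radii, prune), solve (network
#' hemodynamics), attach (cells to local WSS) and analyze (directionality,
#' polar histogram + Kuiper, sensor curve, slope fits), writing tables,
#' figures, a machine-readable `results.json` and a `manifest.json` under
#' `out_dir`. Degree-4 junction diagnostics are surfaced as prominent
#' warnings: such nodes usually mean non-coplanar vessels appear merged in
#' the projection and local hemodynamics are unreliable.
#'
#' @param mask a [binary_mask] or path readable by [read_mask()].
#' @param cells a cell point table (data frame or CSV path with pixel
#'   coordinates, see [load_cell_points()]).
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with all intermediate objects.
#' @export
run_pipeline <- function(mask, cells, config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)

  if (is.character(mask)) {
    mask_path <- mask
    mask <- read_mask(mask, config$pixel_size)
  } else mask_path <- NULL
  cells_path <- if (is.character(cells)) cells else NULL

  net <- stage("build-network", {
    n <- build_network(mask, config$min_spur_factor)
    flagged <- diagnose_overlaps(n)
    if (length(flagged))
      warning("coplanarity check failed: ", length(flagged),
              " junction(s) with >= 4 segments (nodes ",
              paste(flagged, collapse = ", "),
              "); vessels crossing at different depths appear connected ",
              "in the planar projection and local hemodynamics there are ",
              "unreliable", call. = FALSE)
    n
  })
  write_network(net, file.path(out_dir, "network"))

  bcs <- stage("solve-flow", match_bc_nodes(net, as.data.frame(config$bcs)))
  rheo <- config_rheology(config$rheology)
  sol <- stage("solve-flow", solve_flow(net, bcs, rheo))
  utils::write.csv(sol$nodes, file.path(out_dir, "node_pressures.csv"),
                   row.names = FALSE)
  utils::write.csv(sol$edges, file.path(out_dir, "edge_flow.csv"),
                   row.names = FALSE)
  samples <- wss_vector_field(net, sol, config$sample_spacing_um)
  utils::write.csv(samples, file.path(out_dir, "wss_samples.csv"),
                   row.names = FALSE)

  pairs <- stage("attach-flow", {
    cr <- load_cell_points(cells, config$pixel_size)
    if (!is.null(config$regions)) cr <- assign_regions(cr, config$regions)
    p <- map_cells_to_flow(cr, net, sol, config$max_distance_um,
                           config$sample_spacing_um)
    attr(p, "cell_records") <- cr
    p
  })
  utils::write.csv(
    pairs[, c("cell_id", "region", "px", "py", "tx", "ty", "theta_deg",
              "t_mag_pa", "s", "matched")],
    file.path(out_dir, "cells_with_flow.csv"), row.names = FALSE)

  res <- stage("analyze", {
    dirtab <- directionality_table(pairs, group_by = "region",
                                   tolerance_deg = config$tolerance_deg)
    th <- pairs$theta_deg[pairs$matched & !is.na(pairs$theta_deg)]
    ph <- polar_histogram(th)
    kuip <- kuiper_one_sample(th, seed = config$seed)
    rayl <- rayleigh_test(th)
    sens <- sensor_analysis(pairs, n_bins = config$n_bins,
                            tolerance_deg = config$tolerance_deg,
                            threshold_frac = config$threshold_frac)
    slopes <- scalar_product_slopes(pairs)
    list(directionality = dirtab, polar = ph, kuiper = kuip,
         rayleigh = rayl, sensor = sens, slopes = slopes)
  })
  utils::write.csv(res$directionality, file.path(out_dir, "directionality.csv"),
                   row.names = FALSE)
  utils::write.csv(res$sensor$bins, file.path(out_dir, "sensor_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(kuiper_uniform = unclass(res$kuiper),
         rayleigh = res$rayleigh),
    file.path(out_dir, "kuiper.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(res$slopes),
                       file.path(out_dir, "slope_fits.json"),
                       auto_unbox = TRUE, digits = NA)

  calib <- caliber_histogram(net)
  wssh <- wss_histogram(net, sol)
  utils::write.csv(data.frame(break_lo = calib$breaks[-length(calib$breaks)],
                              break_hi = calib$breaks[-1L],
                              length_um = calib$counts),
                   file.path(out_dir, "caliber_hist.csv"), row.names = FALSE)
  utils::write.csv(data.frame(break_lo = wssh$breaks[-length(wssh$breaks)],
                              break_hi = wssh$breaks[-1L],
                              length_um = wssh$counts),
                   file.path(out_dir, "wss_hist.csv"), row.names = FALSE)

  results <- list(
    n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
    degree4_nodes = diagnose_overlaps(net),
    unperfused_edges = identify_unperfused(net, bcs),
    solver_iterations = sol$iterations,
    wss_pa = list(min = wssh$min, median = wssh$median, max = wssh$max),
    n_cells = nrow(pairs), n_matched = sum(pairs$matched),
    directionality = res$directionality,
    kuiper_uniform = unclass(res$kuiper),
    rayleigh = res$rayleigh,
    tau_star_pa = res$sensor$tau_star,
    tau_star_reason = res$sensor$reason,
    slopes = unclass(res$slopes))
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  manifest <- list(
    package_version = as.character(utils::packageVersion("vaspol")),
    mask = mask_path, cells = cells_path,
    config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  # figures (PDF: deterministic headless rendering; excluded from hashing)
  fig <- function(name, expr) {
    grDevices::pdf(file.path(fig_dir, name), width = 6, height = 5)
    on.exit(grDevices::dev.off())
    force(expr)
  }
  cr <- attr(pairs, "cell_records")
  fig("overlay.pdf", plot_overlay(mask, cr, samples))
  fig("polar_histogram.pdf", plot_polar_histogram(res$polar))
  fig("sensor_curve.pdf", plot_sensor_curve(res$sensor))
  fig("slope_scatter.pdf", plot_slope_scatter(pairs, res$slopes))
  fig("caliber_histogram.pdf",
      plot_weighted_hist(calib, "vessel diameter (um)", "caliber histogram"))
  fig("wss_histogram.pdf",
      plot_weighted_hist(wssh, "WSS (Pa)", "WSS histogram"))

  invisible(list(mask = mask, network = net, bcs = bcs, solution = sol,
                 samples = samples, pairs = pairs, analyses = res,
                 results = results, out_dir = out_dir))
}

#' Re-run a pipeline from its manifest
#'
#' Reads `manifest.json` from a previous run and repeats the run with the
#' identical configuration. CSV/JSON outputs are bit-identical across
#' repeats.
#'
#' @param manifest_path path to a `manifest.json`.
#' @param out_dir output directory for the repeat run.
#' @return see [run_pipeline()].
#' @export
run_pipeline_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  cfg$bcs <- as.data.frame(cfg$bcs)
  if (!is.null(cfg$regions) && is.data.frame(cfg$regions))
    cfg$regions <- lapply(split(cfg$regions, cfg$regions$label),
                          function(d) list(label = d$label[1], x = d$x, y = d$y))
  config <- do.call(run_config,
                    cfg[intersect(names(cfg), names(formals(run_config)))])
  if (is.null(man$mask) || is.null(man$cells))
    stop("manifest lacks input paths; rerun requires file-based inputs")
  run_pipeline(man$mask, man$cells, config, out_dir)
}

#' Hash the reproducible outputs of a run
#'
#' MD5 of every CSV/JSON file in a run directory (figures excluded), for
#' manifest-reproducibility checks.
#'
#' @param out_dir a run output directory.
#' @return named character vector of MD5 hashes.
#' @export
hash_run_outputs <- function(out_dir) {
  files <- sort(list.files(out_dir, pattern = "\\.(csv|json)$",
                           full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- basename(files)
  h
}
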
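#' Default run configuration
#'
#' A plain nested list (YAML-serialisable) holding every generator, flow,
#' oxygen and analysis parameter. Physiological defaults: haematocrit 0.45,
#' plasma viscosity 1.2 mPa.s, target perfusion 55 mL/100mL/min, inlet PO2
#' 90 mmHg, maximum metabolic rate 6.72e-4 cm^3 O2/cm^3/s, hypoxia threshold
#' 10 mmHg, 15 um tissue voxels, 25 um beads, 10 columns, hypoxic-intensity
#' radii 50-500 um in steps of 50. The capillary generator settings are
#' calibrated so that assembled columns reproduce the reference column
#' geometry (vessel density ~10846/mm^3, vascular volume fraction ~2.82%).
#'
#' @param seed base seed; column k uses `seed + k` offsets for its cube and
#'   arteriole.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_columns = 10L,
    bead_diameter = 25,
    generator = list(
      edge_um = 375,
      n_stack = 4L,
      cube_density = 9290,
      lattice_spacing = 62.5,
      diameter_law = list(mean = 6.8, sd = 0.8, min = 4, max = 10),
      arteriole = list(depth = 1400, inlet_diameter = 30),
      outflow_diameter_factor = 0.7,
      bottom_outflow_factor = 0.7,
      branching = arteriole_branching_spec()
    ),
    hemo = list(haematocrit = 0.45, plasma_viscosity = 1.2,
                target_perfusion = 55),
    oxy = list(voxel_um = 15, max_element_um = 30),
    gx_breaks = seq(0, 1000, by = 10),
    radii = seq(50, 500, by = 50)
  )
}

#' Read / write a configuration as YAML
#'
#' @param config a configuration list.
#' @param path YAML file.
#' @return `write_config`: `path` invisibly; `read_config`: the list.
#' @export
write_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

config_hemo <- function(config) do.call(hemo_params, config$hemo)
config_oxy <- function(config) do.call(oxy_params, config$oxy)

#' Generate one cortical column from a configuration
#'
#' @param config configuration list (see [default_config()]).
#' @param column integer column index (drives the seeds).
#' @return an assembled column [vessel_graph()].
#' @export
generate_column <- function(config, column = 1L) {
  gc <- config$generator
  seed_cube <- config$seed + column
  seed_art <- config$seed + column + 500000L
  cube <- generate_capillary_cube(
    edge_length = gc$edge_um, target_density = gc$cube_density,
    diameter_law = gc$diameter_law, seed = seed_cube,
    lattice_spacing = gc$lattice_spacing)
  bs <- do.call(arteriole_branching_spec,
                config$generator$branching[names(formals(arteriole_branching_spec))[
                  names(formals(arteriole_branching_spec)) %in%
                    names(config$generator$branching)]])
  art <- generate_arteriole_tree(
    depth = gc$arteriole$depth, inlet_diameter = gc$arteriole$inlet_diameter,
    branching_spec = bs, seed = seed_art,
    centre_xy = rep(gc$edge_um / 2, 2),
    max_depth = gc$edge_um * gc$n_stack)
  assemble_column(art, cube, n_stack = gc$n_stack,
                  outflow_diameter_factor = gc$outflow_diameter_factor,
                  bottom_outflow_factor = gc$bottom_outflow_factor)
}

#' Simulate a batch of columns end to end
#'
#' For each column: generate, calibrate flow to the target perfusion, solve
#' healthy oxygen transport, enumerate trapping sites, run every occlusion
#' scenario and compute the spatial statistics (pixel Gx against the
#' scenario's bead with baseline-hypoxia exclusion; hypoxic intensity around
#' the bead; type classification).
#'
#' @param config configuration list.
#' @param n_columns number of columns (defaults to the config value).
#' @param columns explicit column indices to simulate (overrides
#'   `n_columns`); results keep the same order.
#' @param progress print per-column progress lines.
#' @return list of per-column results: `column` (graph), `stats`
#'   ([network_stats()]), `batch` ([run_scenarios()] output), `gx_curves`,
#'   `intensity_curves`, `types`, `aggregate` ([aggregate_column()] output),
#'   `perfusion_drops`.
#' @export
simulate_column_batch <- function(config = default_config(),
                                  n_columns = NULL, columns = NULL,
                                  progress = FALSE) {
  if (is.null(n_columns)) n_columns <- config$n_columns
  if (is.null(columns)) columns <- seq_len(n_columns)
  hemo <- config_hemo(config)
  oxy <- config_oxy(config)
  lapply(columns, function(k) {
    col <- generate_column(config, k)
    batch <- run_scenarios(col, hemo, oxy, config$bead_diameter)
    ok <- vapply(batch$scenarios, function(s) is.null(s$error), logical(1))
    gx_curves <- list(); int_curves <- list(); drops <- numeric(0)
    for (s in batch$scenarios[ok]) {
      gx_curves[[length(gx_curves) + 1L]] <-
        pixel_gx(s$mask, matrix(s$bead, 1), s$oxygen$grid,
                 baseline_mask = batch$healthy$mask,
                 breaks = config$gx_breaks)
      int_curves[[length(int_curves) + 1L]] <-
        hypoxic_intensity(s$mask, s$bead, s$oxygen$grid, radii = config$radii)
      drops <- c(drops, s$perfusion_drop)
    }
    agg <- if (length(int_curves) > 0)
      aggregate_column(gx_curves, int_curves, breaks = config$gx_breaks)
    else NULL
    types <- lapply(int_curves, classify_intensity)
    if (progress)
      message(sprintf("column %d: %d sites, %d scenarios ok", k,
                      nrow(batch$sites), sum(ok)))
    list(column = col, stats = network_stats(col), batch = batch,
         gx_curves = gx_curves, intensity_curves = int_curves,
         types = types, aggregate = agg, perfusion_drops = drops)
  })
}

#' Cross-column mean Gx curve
#'
#' Averages the per-column pooled Gx curves (each column pools its scenarios'
#' voxel distances first), as used for the simulation-versus-experiment
#' comparison curves.
#'
#' @param results output of [simulate_column_batch()].
#' @return a `gx_curve` data.frame (mean over columns).
#' @export
mean_gx_curve <- function(results) {
  curves <- Filter(Negate(is.null), lapply(results, function(r)
    if (!is.null(r$aggregate)) r$aggregate$gx else NULL))
  stopifnot(length(curves) >= 1)
  fr <- rowMeans(sapply(curves, function(cu) cu$fraction))
  out <- data.frame(distance = curves[[1]]$distance, fraction = fr)
  class(out) <- c("gx_curve", "data.frame")
  out
}

#' Run the full simulation pipeline and write artifacts
#'
#' Writes, per column: the vessel graph (CSV pair + JSON header), the healthy
#' flow solution, a scenario manifest (JSON) and the tidy spatial-statistic
#' curves (CSV); plus a cross-column summary CSV, the mean curves, and the
#' resolved configuration (YAML) beside the outputs. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config configuration list.
#' @param outdir output directory.
#' @param write_grids also write each scenario's PO2 grid and hypoxia mask as
#'   TIFF stacks (large; off by default).
#' @return the summary data.frame, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_config(), outdir, write_grids = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(outdir, "config.yaml"))
  results <- simulate_column_batch(config)
  summary_rows <- list()
  for (k in seq_along(results)) {
    r <- results[[k]]
    cdir <- file.path(outdir, sprintf("column_%02d", k))
    write_vessel_graph(r$column, file.path(cdir, "graph"))
    write_flow_solution(r$batch$healthy$flow, file.path(cdir, "healthy_flow"))
    write_scenario_manifest(r$batch, file.path(cdir, "scenarios.json"))
    if (!is.null(r$aggregate)) {
      write_curves(list(gx = r$aggregate$gx), file.path(cdir, "gx.csv"))
      write_curves(stats::setNames(r$intensity_curves,
                                   sprintf("scenario_%02d", seq_along(r$intensity_curves))),
                   file.path(cdir, "intensity.csv"))
    }
    if (write_grids) {
      write_tissue_grid(r$batch$healthy$oxygen$grid,
                        file.path(cdir, "healthy_po2"))
      for (i in seq_along(r$batch$scenarios)) {
        s <- r$batch$scenarios[[i]]
        if (is.null(s$error))
          write_mask(s$mask, s$oxygen$grid,
                     file.path(cdir, sprintf("hypoxia_%02d", i)))
      }
    }
    tt <- table(factor(vapply(r$types, `[[`, character(1), "type"),
                       levels = c("A", "B")))
    summary_rows[[k]] <- data.frame(
      column = k,
      n_sites = nrow(r$batch$sites),
      n_ok = length(r$gx_curves),
      vessel_density = r$stats$vessel_density,
      volume_fraction = r$stats$volume_fraction,
      type_A = as.integer(tt["A"]), type_B = as.integer(tt["B"]),
      gx50 = if (!is.null(r$aggregate)) gx_crossing(r$aggregate$gx, 0.5) else NA,
      gx90 = if (!is.null(r$aggregate)) gx_crossing(r$aggregate$gx, 0.9) else NA,
      mean_perfusion_drop = mean(r$perfusion_drops))
  }
  summary <- do.call(rbind, summary_rows)
  data.table::fwrite(summary, file.path(outdir, "summary.csv"))
  mg <- mean_gx_curve(results)
  data.table::fwrite(mg, file.path(outdir, "mean_gx.csv"))
  invisible(summary)
}

#' Analyse an experimental-style dataset
#'
#' The image-side pipeline: downsample the section stack to the analysis
#' grid, compute the pixel-based Gx function of the hypoxia mask against the
#' bead set, the hypoxic-intensity curve and type classification around every
#' bead, and Monte-Carlo control intensities at matched point density --
#' exactly the code path applied to simulated columns.
#'
#' @param stack a [section_stack()].
#' @param beads matrix (n x 3) or data.frame (`x_um`, `y_um`, `z_um`) of bead
#'   centres.
#' @param n_controls number of Monte-Carlo control replicates.
#' @param radii intensity radii (um).
#' @param gx_breaks Gx distance grid (um).
#' @param seed seed for the control points.
#' @return list with `grid`, `mask`, `gx`, `intensity` (per bead), `types`,
#'   `mean_intensity`, `control_intensity` (per replicate mean curves) and
#'   `type_table`.
#' @export
run_experiment_analysis <- function(stack, beads, n_controls = 10,
                                    radii = seq(50, 500, by = 50),
                                    gx_breaks = seq(0, 1000, by = 10),
                                    seed = 1L) {
  ds <- downsample_to_analysis_grid(stack)
  if (is.data.frame(beads))
    beads <- as.matrix(beads[, c("x_um", "y_um", "z_um")])
  beads <- matrix(beads, ncol = 3)
  gx <- pixel_gx(ds$mask, beads, ds$grid, breaks = gx_breaks)
  ints <- lapply(seq_len(nrow(beads)), function(i)
    hypoxic_intensity(ds$mask, beads[i, ], ds$grid, radii = radii))
  types <- lapply(ints, classify_intensity)
  fr <- sapply(ints, function(cu) cu$fraction)
  mean_int <- data.frame(radius = radii,
                         fraction = rowMeans(matrix(fr, nrow = length(radii)),
                                             na.rm = TRUE))
  vol_mm3 <- sum(ds$grid$indomain) * prod(ds$grid$spacing) / .UM3_PER_MM3
  density <- nrow(beads) / vol_mm3
  ctrl <- monte_carlo_controls(ds$grid, density, n_controls, seed)
  ctrl_int <- lapply(ctrl, function(pts) {
    ic <- lapply(seq_len(nrow(pts)), function(i)
      hypoxic_intensity(ds$mask, pts[i, ], ds$grid, radii = radii))
    fr <- sapply(ic, function(cu) cu$fraction)
    data.frame(radius = radii,
               fraction = rowMeans(matrix(fr, nrow = length(radii)),
                                   na.rm = TRUE))
  })
  tt <- table(
    type = factor(vapply(types, `[[`, character(1), "type"), levels = c("A", "B")),
    subtype = factor(vapply(types, `[[`, character(1), "subtype"),
                     levels = c("local", "no-local")))
  list(grid = ds$grid, mask = ds$mask, gx = gx, intensity = ints,
       types = types, mean_intensity = mean_int,
       control_intensity = ctrl_int, type_table = tt)
}
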
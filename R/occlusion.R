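#' Enumerate bead trapping sites in a column
#'
#' A bead entering at the arteriole inlet travels with the flow and lodges at
#' the inlet of the first vessel it reaches whose diameter is below the bead
#' size. Sites are all arteriole segments with `diameter < bead_diameter`
#' whose upstream node is reachable from the inlet along flow-directed
#' segments of diameter `>= bead_diameter`. No transport model weights the
#' paths: every distinct site carries equal probability. Capillaries and
#' connectors are not trapping sites (they are only reachable through a
#' narrower arteriole, where the bead already lodged).
#'
#' @param graph an assembled column [vessel_graph()].
#' @param flow the healthy `flow_solution` (bead follows flow directions).
#' @param bead_diameter bead size (um), default 25.
#' @return data.frame, one row per site, ordered by segment id: `seg_id`,
#'   `seg_row`, bead position `x`, `y`, `z` (the trapped segment's upstream
#'   node), upstream node id and the site's `diameter`. Zero rows (with a
#'   warning) if the tree never tapers below the bead size.
#' @export
enumerate_trapping_sites <- function(graph, flow, bead_diameter = 25) {
  nodes <- graph$nodes; seg <- graph$segments
  ia <- match(seg$from, nodes$id); ib <- match(seg$to, nodes$id)
  Q <- flow$flow
  qtol <- 1e-9 * max(abs(Q), .Machine$double.eps)
  up <- ifelse(Q >= 0, ia, ib)
  dn <- ifelse(Q >= 0, ib, ia)

  out_by_node <- split(seq_len(nrow(seg)), up)
  inlet_idx <- which(nodes$id == graph$inlet)
  visited <- rep(FALSE, nrow(nodes))
  visited[inlet_idx] <- TRUE
  frontier <- inlet_idx
  sites <- integer(0)
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      for (s in out_by_node[[as.character(u)]]) {
        if (abs(Q[s]) <= qtol) next
        if (seg$diameter[s] >= bead_diameter) {
          v <- dn[s]
          if (!visited[v]) { visited[v] <- TRUE; nxt <- c(nxt, v) }
        } else if (seg$kind[s] == "arteriole") {
          sites <- c(sites, s)
        }
      }
    }
    frontier <- nxt
  }
  sites <- sort(unique(sites))
  if (length(sites) == 0) {
    warning("no trapping site: the arteriole tree never tapers below the bead size")
    return(data.frame(seg_id = integer(0), seg_row = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      up_node = integer(0), diameter = numeric(0)))
  }
  u <- up[sites]
  data.frame(seg_id = seg$id[sites], seg_row = sites,
             x = nodes$x[u], y = nodes$y[u], z = nodes$z[u],
             up_node = nodes$id[u], diameter = seg$diameter[sites])
}

#' Apply a single-bead blockage to a column
#'
#' The trapped segment is kept in the geometry (distance statistics still see
#' it) but flagged occluded, which zeroes its conductance in [solve_flow()].
#'
#' @param graph a column [vessel_graph()].
#' @param site one row of [enumerate_trapping_sites()] output (or a segment
#'   row index).
#' @return the modified `vessel_graph`.
#' @export
apply_blockage <- function(graph, site) {
  row <- if (is.data.frame(site)) site$seg_row[1] else site
  graph$segments$occluded[row] <- TRUE
  graph
}

#' Run every single-bead occlusion scenario of a column
#'
#' For each trapping site: block the segment, re-solve flow at the healthy
#' calibrated inlet pressure (no re-calibration -- perfusion drops are
#' meaningful only at fixed driving pressure), re-solve oxygen transport and
#' derive the hypoxia mask. Solver failures are isolated per scenario.
#'
#' @param column an assembled column [vessel_graph()].
#' @param hemo [hemo_params()].
#' @param oxy [oxy_params()].
#' @param bead_diameter bead size (um).
#' @param include_healthy also return the no-bead baseline (always computed;
#'   this flag controls whether it is included in the scenario list).
#' @return list with `healthy` (flow, oxygen solution, baseline hypoxia
#'   mask, calibrated inlet pressure), `sites`, and `scenarios` -- one entry
#'   per site with the blocked `flow`, `oxygen`, `mask`, `perfusion_drop` and
#'   `bead` position (or an `error` string for failed scenarios).
#' @export
run_scenarios <- function(column, hemo = hemo_params(), oxy = oxy_params(),
                          bead_diameter = 25, include_healthy = FALSE) {
  cal <- calibrate_perfusion(column, hemo)
  ctx <- oxygen_context(column, oxy)
  healthy_ox <- solve_oxygen(column, cal$flow, oxy, ctx = ctx, hemo = hemo)
  baseline_mask <- hypoxia_mask(healthy_ox$grid, oxy$hypoxia_threshold)
  sites <- enumerate_trapping_sites(column, cal$flow, bead_diameter)

  scenarios <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    scenarios[[i]] <- tryCatch({
      gb <- apply_blockage(column, sites[i, ])
      fb <- solve_flow(gb, hemo, inlet_pressure = cal$inlet_pressure)
      ob <- solve_oxygen(gb, fb, oxy, ctx = ctx, hemo = hemo,
                         init = healthy_ox)
      list(site = sites[i, ],
           bead = c(sites$x[i], sites$y[i], sites$z[i]),
           flow = fb, oxygen = ob,
           mask = hypoxia_mask(ob$grid, oxy$hypoxia_threshold),
           perfusion_drop = 1 - fb$inlet_flow / cal$flow$inlet_flow)
    }, error = function(e) list(site = sites[i, ], error = conditionMessage(e)))
  }
  failed <- vapply(scenarios, function(s) !is.null(s$error), logical(1))
  if (any(failed))
    warning(sprintf("%d of %d scenarios failed", sum(failed), length(failed)))
  list(healthy = list(flow = cal$flow, oxygen = healthy_ox,
                      mask = baseline_mask,
                      inlet_pressure = cal$inlet_pressure),
       sites = sites, scenarios = scenarios)
}

#' Write a scenario batch manifest as JSON
#'
#' @param batch output of [run_scenarios()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario_manifest <- function(batch, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(batch$scenarios, function(s) {
    if (!is.null(s$error))
      return(list(seg_id = s$site$seg_id, error = s$error))
    list(seg_id = s$site$seg_id, bead_um = s$bead,
         perfusion_drop = s$perfusion_drop,
         hypoxic_voxels = sum(s$mask),
         converged = s$oxygen$converged)
  })
  jsonlite::write_json(list(schema = "arteriox/scenario_manifest/1",
                            healthy_inlet_pressure = batch$healthy$inlet_pressure,
                            healthy_hypoxic_voxels = sum(batch$healthy$mask),
                            scenarios = rows),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
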
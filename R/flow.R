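#' Haemodynamic parameters
#'
#' @param haematocrit discharge haematocrit (dimensionless, in `[0, 1)`).
#' @param plasma_viscosity plasma viscosity (mPa.s).
#' @param target_perfusion column perfusion target (mL blood / 100 mL tissue
#'   / min) used by [calibrate_perfusion()].
#' @return list of class `hemo_params`.
#' @export
hemo_params <- function(haematocrit = 0.45, plasma_viscosity = 1.2,
                        target_perfusion = 55) {
  stopifnot(haematocrit >= 0, haematocrit < 1, plasma_viscosity > 0,
            target_perfusion > 0)
  structure(list(haematocrit = haematocrit,
                 plasma_viscosity = plasma_viscosity,
                 target_perfusion = target_perfusion),
            class = "hemo_params")
}

#' Apparent blood viscosity in a microvessel
#'
#' In-vitro empirical law for the relative apparent viscosity of blood as a
#' function of tube diameter and discharge haematocrit (Pries-Secomb in-vitro
#' formulation), scaled by the plasma viscosity. At zero haematocrit the
#' relative viscosity is exactly 1.
#'
#' @param diameter vessel diameter (um), vectorised.
#' @param haematocrit discharge haematocrit.
#' @param plasma_viscosity plasma viscosity (mPa.s).
#' @return apparent viscosity (mPa.s).
#' @export
apparent_viscosity <- function(diameter, haematocrit = 0.45,
                               plasma_viscosity = 1.2) {
  if (any(diameter <= 0)) stop("diameter must be positive")
  D <- diameter
  mu45 <- 220 * exp(-1.3 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
  f <- 1 / (1 + 1e-11 * D^12)
  C <- (0.8 + exp(-0.075 * D)) * (-1 + f) + f
  H <- haematocrit
  rel <- 1 + (mu45 - 1) * ((1 - H)^C - 1) / ((1 - 0.45)^C - 1)
  plasma_viscosity * rel
}

#' Poiseuille conductance of a cylindrical segment
#'
#' `pi r^4 / (8 mu L)` converted to the package's canonical flow units.
#'
#' @param diameter vessel diameter (um).
#' @param length vessel length (um).
#' @param viscosity apparent viscosity (mPa.s).
#' @return conductance in um^3 / (s.mmHg), vectorised.
#' @export
segment_conductance <- function(diameter, length, viscosity) {
  if (any(length <= 0)) stop("segment length must be positive")
  if (any(viscosity <= 0)) stop("viscosity must be positive")
  pi * (diameter / 2)^4 / (8 * viscosity * length) * .COND_UM3_S_MMHG
}

#' Solve steady network blood flow
#'
#' Poiseuille flow on a vessel graph: node pressures solve the weighted graph
#' Laplacian system with Dirichlet conditions (all boundary nodes at the
#' reference pressure 0, the inlet at `inlet_pressure`). Occluded segments
#' have zero conductance. Flow in a segment is positive from `from` to `to`.
#'
#' @param graph a [vessel_graph()] with an inlet and boundary nodes flagged.
#' @param params [hemo_params()].
#' @param inlet_pressure inlet-to-boundary pressure difference (mmHg).
#' @return object of class `flow_solution`: node pressures (mmHg), segment
#'   flows (um^3/s), segment viscosities (mPa.s), inlet flow, perfusion
#'   (mL/100mL/min, from the box volume) and the mass-conservation residual.
#' @export
solve_flow <- function(graph, params = hemo_params(), inlet_pressure = 10) {
  nodes <- graph$nodes; seg <- graph$segments
  if (is.na(graph$inlet)) stop("graph has no inlet")
  if (!any(nodes$is_boundary)) stop("graph has no boundary nodes")

  mu <- apparent_viscosity(seg$diameter, params$haematocrit,
                           params$plasma_viscosity)
  g <- segment_conductance(seg$diameter, seg$length, mu)
  g[seg$occluded] <- 0

  n <- nrow(nodes)
  ia <- match(seg$from, nodes$id); ib <- match(seg$to, nodes$id)
  fixed <- nodes$is_boundary | nodes$id == graph$inlet
  pfix <- ifelse(nodes$id == graph$inlet, inlet_pressure, 0)

  # weighted Laplacian, solved on the free nodes
  act <- g > 0
  L <- Matrix::sparseMatrix(
    i = c(ia[act], ib[act], ia[act], ib[act]),
    j = c(ib[act], ia[act], ia[act], ib[act]),
    x = c(-g[act], -g[act], g[act], g[act]),
    dims = c(n, n))
  free <- which(!fixed)
  p <- pfix
  if (length(free) > 0) {
    Lff <- L[free, free, drop = FALSE]
    b <- -L[free, which(fixed), drop = FALSE] %*% pfix[fixed]
    sol <- tryCatch(Matrix::solve(Lff, b),
                    error = function(e) stop("singular flow system (disconnected component?): ",
                                             conditionMessage(e)))
    p[free] <- as.numeric(sol)
  }

  Q <- g * (p[ia] - p[ib])
  # mass conservation at free nodes
  net <- rep(0, n)
  net <- net + unname(tapply(c(-Q, Q), c(ia, ib), sum)[as.character(seq_len(n))])
  net[is.na(net)] <- 0
  flux_scale <- max(sum(abs(Q)), .Machine$double.eps)
  residual <- if (length(free)) max(abs(net[free])) / flux_scale else 0

  ii <- which(nodes$id == graph$inlet)
  inlet_flow <- -net[ii]   # net outflow from the inlet node into the network
  perfusion <- inlet_flow / prod(graph$box) * .PERFUSION_FACTOR

  structure(list(node_id = nodes$id, pressure = p, segment_id = seg$id,
                 flow = Q, viscosity = mu, conductance = g,
                 inlet_flow = inlet_flow, perfusion = perfusion,
                 inlet_pressure = inlet_pressure, residual = residual),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d nodes, %d segments\n",
              length(x$pressure), length(x$flow)))
  cat(sprintf("  inlet pressure %.4g mmHg, inlet flow %.4g um^3/s, perfusion %.4g mL/100mL/min\n",
              x$inlet_pressure, x$inlet_flow, x$perfusion))
  cat(sprintf("  mass-conservation residual %.2e\n", x$residual))
  invisible(x)
}

#' Calibrate the inlet pressure to a target perfusion
#'
#' The viscosity law does not depend on flow, so the network is linear and the
#' calibration is a single rescale of a unit-pressure solve.
#'
#' @inheritParams solve_flow
#' @return list with `inlet_pressure` (mmHg) and the calibrated
#'   `flow_solution`.
#' @export
calibrate_perfusion <- function(graph, params = hemo_params()) {
  unit <- solve_flow(graph, params, inlet_pressure = 1)
  if (unit$inlet_flow <= 0) stop("zero inlet flow at unit pressure")
  target_q <- params$target_perfusion * prod(graph$box) / .PERFUSION_FACTOR
  scale <- target_q / unit$inlet_flow
  sol <- unit
  sol$pressure <- unit$pressure * scale
  sol$flow <- unit$flow * scale
  sol$inlet_flow <- unit$inlet_flow * scale
  sol$perfusion <- unit$perfusion * scale
  sol$inlet_pressure <- scale
  list(inlet_pressure = scale, flow = sol)
}

#' Export a flow solution as CSV tables plus a JSON summary
#'
#' @param flow a `flow_solution`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_flow_solution <- function(flow, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.frame(id = flow$node_id, pressure_mmHg = flow$pressure),
                     file.path(dir, "node_pressure.csv"))
  data.table::fwrite(data.frame(id = flow$segment_id, flow_um3_s = flow$flow,
                                viscosity_mPas = flow$viscosity),
                     file.path(dir, "segment_flow.csv"))
  jsonlite::write_json(list(schema = "arteriox/flow_solution/1",
                            inlet_pressure_mmHg = flow$inlet_pressure,
                            inlet_flow_um3_s = flow$inlet_flow,
                            perfusion_mL_100mL_min = flow$perfusion,
                            residual = flow$residual),
                       file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
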
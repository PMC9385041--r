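#' Assemble a cortical column from an arteriole tree and a capillary cube
#'
#' Stacks `n_stack` copies of a periodic capillary cube along z to fill the
#' column depth. Segments that wrap across a z face become straight segments
#' joining consecutive copies; wrap segments crossing the outer faces are cut
#' at the face, leaving stub nodes that are flagged as pressure boundaries.
#' The arteriole tree is trimmed at the column faces (a crossing segment is
#' split at the intersection point and everything beyond is discarded), and
#' every arteriole terminal -- leaf or trimmed end -- is joined to the nearest
#' interior capillary node by a connector segment carrying the terminal's
#' diameter.
#'
#' @param arteriole a rooted arteriole [vessel_graph()] (root at z = 0).
#' @param cube a periodic capillary [vessel_graph()].
#' @param n_stack number of cube copies stacked in z (default 4).
#' @param outflow_diameter_factor diameter multiplier applied to the cut
#'   boundary stub segments. Values below 1 emulate the resistance of the
#'   capillary-venule transition at the column boundary, which distributes
#'   perfusion more evenly across the capillary bed.
#' @param bottom_outflow_factor separate multiplier for the stubs on the
#'   bottom face (z = depth): the column continues into deeper tissue there
#'   rather than draining into a venous boundary, so a smaller value is
#'   physiologically apt. Defaults to `outflow_diameter_factor`.
#' @return a connected column `vessel_graph` with a single inlet.
#' @export
assemble_column <- function(arteriole, cube, n_stack = 4L,
                            outflow_diameter_factor = 0.7,
                            bottom_outflow_factor = NULL) {
  if (is.null(bottom_outflow_factor))
    bottom_outflow_factor <- outflow_diameter_factor
  if (!cube$periodic) stop("cube must be periodic")
  if (is.na(arteriole$inlet)) stop("arteriole must have an inlet")
  edge <- cube$box[1]
  zdepth <- n_stack * edge
  box <- c(edge, edge, zdepth)
  if (max(arteriole$nodes$z) > zdepth)
    stop("arteriole deeper than the column box")

  nn <- nrow(cube$nodes)
  cpos <- as.matrix(cube$nodes[, c("x", "y", "z")])

  nx <- ny <- nz <- numeric(0); nb <- logical(0); nk <- character(0)
  for (k in 0:(n_stack - 1L)) {
    nx <- c(nx, cpos[, 1]); ny <- c(ny, cpos[, 2]); nz <- c(nz, cpos[, 3] + k * edge)
    nb <- c(nb, rep(FALSE, nn)); nk <- c(nk, rep("capillary", nn))
  }
  new_node <- function(p, boundary, kind) {
    nx[length(nx) + 1L] <<- p[1]; ny[length(ny) + 1L] <<- p[2]
    nz[length(nz) + 1L] <<- p[3]
    nb[length(nb) + 1L] <<- boundary; nk[length(nk) + 1L] <<- kind
    length(nx)
  }
  sf <- integer(0); st <- integer(0); sd <- numeric(0); sk <- character(0)
  add_edge <- function(from, to, diameter, kind) {
    sf[length(sf) + 1L] <<- from; st[length(st) + 1L] <<- to
    sd[length(sd) + 1L] <<- diameter; sk[length(sk) + 1L] <<- kind
  }

  odf <- outflow_diameter_factor
  bdf <- bottom_outflow_factor
  cs <- cube$segments
  wrapped <- cs$wrap_x != 0L | cs$wrap_y != 0L | cs$wrap_z != 0L
  if (any(cs$wrap_x < 0 | cs$wrap_y < 0 | cs$wrap_z < 0 |
          cs$wrap_x > 1 | cs$wrap_y > 1 | cs$wrap_z > 1))
    stop("only wrap components 0/1 are supported")

  # split the straight line A -> B at the plane coord[ax] = bound
  face_point <- function(A, B, ax, bound) {
    t <- (bound - A[ax]) / (B[ax] - A[ax])
    A + t * (B - A)
  }

  for (k in 0:(n_stack - 1L)) {
    off <- k * nn
    zoff <- c(0, 0, k * edge)
    for (s in seq_len(nrow(cs))) {
      fa <- cs$from[s]; ta <- cs$to[s]
      A <- cpos[fa, ] + zoff
      if (!wrapped[s]) {
        add_edge(off + fa, off + ta, cs$diameter[s], "capillary")
      } else if (cs$wrap_z[s] == 1L) {
        B <- cpos[ta, ] + zoff + c(0, 0, edge)
        if (k < n_stack - 1L) {
          add_edge(off + fa, (k + 1L) * nn + ta, cs$diameter[s], "capillary")
        } else {
          stub <- new_node(face_point(A, B, 3L, zdepth), TRUE, "capillary")
          add_edge(off + fa, stub, bdf * cs$diameter[s], "capillary")
        }
        if (k == 0L) {
          # entry half descending through the cortical surface to the re-entry node
          Av <- cpos[fa, ] - c(0, 0, edge)
          Bv <- cpos[ta, ]
          stub <- new_node(face_point(Av, Bv, 3L, 0), TRUE, "capillary")
          add_edge(stub, ta, odf * cs$diameter[s], "capillary")
        }
      } else {
        ax <- if (cs$wrap_x[s] == 1L) 1L else 2L
        B <- cpos[ta, ] + zoff; B[ax] <- B[ax] + edge
        stub1 <- new_node(face_point(A, B, ax, edge), TRUE, "capillary")
        add_edge(off + fa, stub1, odf * cs$diameter[s], "capillary")
        Av <- cpos[fa, ] + zoff; Av[ax] <- Av[ax] - edge
        Bv <- cpos[ta, ] + zoff
        stub2 <- new_node(face_point(Av, Bv, ax, 0), TRUE, "capillary")
        add_edge(stub2, off + ta, odf * cs$diameter[s], "capillary")
      }
    }
  }
  n_cap_nodes <- length(nx)

  # ---- arteriole: trim at the column faces, then import ----
  an <- arteriole$nodes; as_ <- arteriole$segments
  apos <- as.matrix(an[, c("x", "y", "z")])
  inside <- function(p, tol = 1e-9) {
    p[1] >= -tol && p[1] <= edge + tol && p[2] >= -tol && p[2] <= edge + tol &&
      p[3] >= -tol && p[3] <= zdepth + tol
  }
  clip_t <- function(A, B) {
    # first exit parameter of the ray A->B through the box [0,edge]^2 x [0,zdepth]
    ts <- c()
    bounds <- list(c(1, 0), c(1, edge), c(2, 0), c(2, edge), c(3, 0), c(3, zdepth))
    for (bd in bounds) {
      D <- B[bd[1]] - A[bd[1]]
      if (abs(D) < 1e-12) next
      t <- (bd[2] - A[bd[1]]) / D
      if (t > 1e-9 && t <= 1 + 1e-9) {
        P <- A + t * (B - A)
        if (inside(P, tol = 1e-6)) ts <- c(ts, t)
      }
    }
    if (length(ts) == 0) NA_real_ else min(ts)
  }

  state <- rep("in", nrow(an))          # in | clipped | dropped
  node_map <- rep(NA_integer_, nrow(an))
  root_local <- match(arteriole$inlet, an$id)
  ord <- order(as_$id)
  kept_child_count <- integer(nrow(an))
  term_diam <- rep(NA_real_, nrow(an))
  node_map[root_local] <- new_node(apos[root_local, ], FALSE, "arteriole")

  for (s in ord) {
    fa <- match(as_$from[s], an$id); ta <- match(as_$to[s], an$id)
    if (state[fa] %in% c("dropped", "clipped")) { state[ta] <- "dropped"; next }
    A <- apos[fa, ]; B <- apos[ta, ]
    if (inside(B)) {
      node_map[ta] <- new_node(B, FALSE, "arteriole")
      add_edge(node_map[fa], node_map[ta], as_$diameter[s], "arteriole")
      kept_child_count[fa] <- kept_child_count[fa] + 1L
      term_diam[ta] <- as_$diameter[s]
    } else {
      t <- clip_t(A, B)
      if (is.na(t)) { state[ta] <- "dropped"; next }
      P <- A + t * (B - A)
      if (sqrt(sum((P - A)^2)) < 1e-6) { state[ta] <- "dropped"; next }
      node_map[ta] <- new_node(P, FALSE, "arteriole")
      add_edge(node_map[fa], node_map[ta], as_$diameter[s], "arteriole")
      kept_child_count[fa] <- kept_child_count[fa] + 1L
      term_diam[ta] <- as_$diameter[s]
      state[ta] <- "clipped"
    }
  }
  kept <- which(!is.na(node_map))
  terminals <- kept[(kept_child_count[kept] == 0L & kept != root_local)]
  if (length(terminals) == 0) stop("arteriole tree fully trimmed away")

  # ---- connectors: each terminal joins the nearest interior capillary node ----
  interior_cap <- which(!nb[seq_len(n_cap_nodes)])
  capm <- cbind(nx[interior_cap], ny[interior_cap], nz[interior_cap])
  for (tn in terminals) {
    p <- c(nx[node_map[tn]], ny[node_map[tn]], nz[node_map[tn]])
    d2 <- (capm[, 1] - p[1])^2 + (capm[, 2] - p[2])^2 + (capm[, 3] - p[3])^2
    j <- interior_cap[which.min(d2)]
    add_edge(node_map[tn], j, term_diam[tn], "connector")
  }

  nodes <- data.frame(id = seq_along(nx), x = nx, y = ny, z = nz,
                      is_boundary = nb, kind = nk)
  segments <- data.frame(id = seq_along(sf), from = sf, to = st, diameter = sd,
                         length = 0, kind = sk, wrap_x = 0L, wrap_y = 0L,
                         wrap_z = 0L, occluded = FALSE)
  g <- structure(list(nodes = nodes, segments = segments, box = box,
                      inlet = node_map[root_local], periodic = FALSE,
                      origin = c(0, 0, 0),
                      meta = list(cube_seed = cube$meta$seed,
                                  arteriole_seed = arteriole$meta$seed,
                                  n_stack = n_stack)),
                 class = "vessel_graph")
  g$segments$length <- segment_chord_length(g)
  # drop zero-length degenerates (possible if a node sits on a face)
  bad <- g$segments$length < 1e-9
  if (any(bad)) {
    g$segments <- g$segments[!bad, , drop = FALSE]
    g$segments$id <- seq_len(nrow(g$segments))
  }
  validate_vessel_graph(g)
  g
}

#' Geometric summary statistics of a cortical column
#'
#' @param column an assembled column [vessel_graph()].
#' @return list with `surface_density` (penetrating arterioles per mm^2 of
#'   cortical surface), `vessel_density` (segments per mm^3) and
#'   `volume_fraction` (dimensionless vascular volume fraction,
#'   sum of pi r^2 L over the box volume).
#' @export
network_stats <- function(column) {
  area_mm2 <- column$box[1] * column$box[2] / 1e6
  vol_mm3 <- prod(column$box) / .UM3_PER_MM3
  n_art <- if (is.na(column$inlet)) 0L else 1L
  seg <- column$segments
  if (nrow(seg) == 0)
    return(list(surface_density = n_art / area_mm2, vessel_density = 0,
                volume_fraction = 0))
  vol_um3 <- sum(pi * (seg$diameter / 2)^2 * seg$length)
  list(surface_density = n_art / area_mm2,
       vessel_density = nrow(seg) / vol_mm3,
       volume_fraction = vol_um3 / prod(column$box))
}

#' Bead load arithmetic
#'
#' Converts an observed microsphere number density into the blood-clot volume
#' it represents: the volume fraction of beads per unit tissue, the total bead
#' volume in a perfusion territory, and that volume as a percentage of a
#' reference thrombus.
#'
#' @param bead_density beads per mm^3 of tissue.
#' @param bead_diameter bead diameter (um).
#' @param territory_volume perfusion territory (mL).
#' @param reference_thrombus reference thrombus volume (mL).
#' @return list with `volume_fraction` (mL beads / mL tissue), `total_volume`
#'   (mL) and `percent_of_reference`.
#' @export
bead_volume_arithmetic <- function(bead_density, bead_diameter,
                                   territory_volume = 100,
                                   reference_thrombus = 0.17) {
  if (any(c(bead_density, bead_diameter, territory_volume,
            reference_thrombus) <= 0))
    stop("all inputs must be positive")
  bead_vol_mm3 <- pi / 6 * bead_diameter^3 / .UM3_PER_MM3
  fraction <- bead_density * bead_vol_mm3           # mm3 beads / mm3 = mL/mL
  total <- fraction * territory_volume
  list(volume_fraction = fraction, total_volume = total,
       percent_of_reference = 100 * total / reference_thrombus)
}
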
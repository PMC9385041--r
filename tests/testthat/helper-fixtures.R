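# Shared fixtures, built in code. Everything is deterministic under the seeds
# fixed here.

# a hand-built three-cylinder chain with known radii and lengths
three_cylinder_graph <- function() {
  nodes <- data.frame(id = 1:4,
                      x = c(10, 110, 110, 110),
                      y = 50,
                      z = c(0, 0, 80, 160),
                      is_boundary = FALSE, kind = "capillary")
  segs <- data.frame(id = 1:3, from = c(1, 2, 3), to = c(2, 3, 4),
                     diameter = c(10, 8, 6), length = c(100, 80, 80),
                     kind = "capillary", wrap_x = 0L, wrap_y = 0L,
                     wrap_z = 0L, occluded = FALSE)
  vessel_graph(nodes, segs, box = c(200, 100, 200))
}

# straight chain: inlet -> mid -> boundary, two identical segments
series_chain_graph <- function(diameter = 10, seg_len = 100) {
  nodes <- data.frame(id = 1:3, x = 50, y = 50,
                      z = c(0, seg_len, 2 * seg_len),
                      is_boundary = c(FALSE, FALSE, TRUE),
                      kind = "arteriole")
  segs <- data.frame(id = 1:2, from = c(1, 2), to = c(2, 3),
                     diameter = diameter, length = seg_len,
                     kind = "arteriole", wrap_x = 0L, wrap_y = 0L,
                     wrap_z = 0L, occluded = FALSE)
  vessel_graph(nodes, segs, box = c(100, 100, 2 * seg_len), inlet = 1L)
}

# symmetric Y: inlet trunk splits into two identical daughters
symmetric_y_graph <- function(trunk_d = 30, daughter_d = 20) {
  nodes <- data.frame(id = 1:4,
                      x = c(100, 100, 50, 150),
                      y = 100,
                      z = c(0, 100, 200, 200),
                      is_boundary = c(FALSE, FALSE, TRUE, TRUE),
                      kind = "arteriole")
  segs <- data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
                     diameter = c(trunk_d, daughter_d, daughter_d), length = 0,
                     kind = "arteriole", wrap_x = 0L, wrap_y = 0L,
                     wrap_z = 0L, occluded = FALSE)
  g <- structure(list(nodes = nodes, segments = segs,
                      box = c(200, 200, 200), inlet = 1L,
                      periodic = FALSE, origin = c(0, 0, 0), meta = list()),
                 class = "vessel_graph")
  g$segments$length <- arteriox:::segment_chord_length(g)
  validate_vessel_graph(g)
  g
}

# random small resistor network fixture with an inlet and several boundary
# nodes; n_nodes <= 50 so a dense oracle is cheap
random_flow_fixture <- function(seed, n_nodes = 20) {
  set.seed(seed)
  pos <- matrix(runif(3 * n_nodes, 0, 300), ncol = 3)
  pos[1, ] <- c(150, 150, 0)
  pos[, 3][1] <- 0
  # random connected graph: spanning chain plus extra edges
  from <- 1:(n_nodes - 1); to <- 2:n_nodes
  extra <- matrix(sample(n_nodes, 2 * n_nodes, replace = TRUE), ncol = 2)
  extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
  from <- c(from, extra[, 1]); to <- c(to, extra[, 2])
  dup <- duplicated(cbind(pmin(from, to), pmax(from, to)))
  from <- from[!dup]; to <- to[!dup]
  nodes <- data.frame(id = seq_len(n_nodes), x = pos[, 1], y = pos[, 2],
                      z = pos[, 3],
                      is_boundary = c(FALSE, rep(FALSE, n_nodes - 4),
                                      TRUE, TRUE, TRUE),
                      kind = "capillary")
  segs <- data.frame(id = seq_along(from), from = from, to = to,
                     diameter = runif(length(from), 5, 20),
                     length = pmax(sqrt(rowSums((pos[from, , drop = FALSE] -
                                                   pos[to, , drop = FALSE])^2)), 10),
                     kind = "capillary", wrap_x = 0L, wrap_y = 0L,
                     wrap_z = 0L, occluded = FALSE)
  structure(list(nodes = nodes, segments = segs, box = c(300, 300, 300),
                 inlet = 1L, periodic = FALSE, origin = c(0, 0, 0),
                 meta = list()),
            class = "vessel_graph")
}

# dense-solver oracle: solve the same Dirichlet resistor problem with plain
# base-R linear algebra, independently of the package's sparse path
dense_flow_oracle <- function(graph, params, inlet_pressure) {
  nodes <- graph$nodes; seg <- graph$segments
  mu <- apparent_viscosity(seg$diameter, params$haematocrit,
                           params$plasma_viscosity)
  g <- pi * (seg$diameter / 2)^4 / (8 * mu * seg$length) * 1e3 * 133.322
  g[seg$occluded] <- 0
  n <- nrow(nodes)
  L <- matrix(0, n, n)
  ia <- match(seg$from, nodes$id); ib <- match(seg$to, nodes$id)
  for (k in seq_along(g)) {
    L[ia[k], ia[k]] <- L[ia[k], ia[k]] + g[k]
    L[ib[k], ib[k]] <- L[ib[k], ib[k]] + g[k]
    L[ia[k], ib[k]] <- L[ia[k], ib[k]] - g[k]
    L[ib[k], ia[k]] <- L[ib[k], ia[k]] - g[k]
  }
  fixed <- nodes$is_boundary | nodes$id == graph$inlet
  pfix <- ifelse(nodes$id == graph$inlet, inlet_pressure, 0)
  free <- which(!fixed)
  p <- pfix
  p[free] <- solve(L[free, free], -L[free, fixed, drop = FALSE] %*% pfix[fixed])
  Q <- g * (p[ia] - p[ib])
  list(pressure = p, flow = Q)
}

# small column (one cube stack, shallow tree) for oxygen-solver tests
tiny_column <- function(seed = 3) {
  cube <- generate_capillary_cube(edge_length = 150, target_density = 55000,
                                  diameter_law = list(mean = 7, sd = 0.5,
                                                      min = 4, max = 10),
                                  seed = seed, lattice_spacing = 37.5)
  art <- generate_arteriole_tree(
    depth = 100, inlet_diameter = 30,
    branching_spec = arteriole_branching_spec(
      n_offshoots_range = c(2L, 2L), branch_length_range = c(30, 50),
      offshoot_generations = 1L),
    seed = seed + 1, centre_xy = c(75, 75), max_depth = 150)
  assemble_column(art, cube, n_stack = 1L)
}

# desk-scale configuration for end-to-end runs in tests
mini_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$generator$edge_um <- 150
  cfg$generator$n_stack <- 2L
  cfg$generator$lattice_spacing <- 37.5
  cfg$generator$cube_density <- 55000
  cfg$generator$arteriole$depth <- 250
  cfg$generator$branching$n_offshoots_range <- c(7L, 9L)
  cfg$generator$branching$branch_length_range <- c(30, 60)
  cfg$generator$branching$offshoot_generations <- 1L
  cfg$oxy <- list(voxel_um = 30, max_element_um = 100, max_iter = 60)
  cfg
}
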
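#' Generate a periodic capillary cube
#'
#' Builds a statistically representative capillary network inside a cube that
#' tiles space periodically in all three axes. Nodes are placed on a jittered
#' cubic lattice; every lattice node is first connected to its +x/+y/+z
#' neighbours (periodically), then edges are deleted at random -- never a
#' bridge of the periodic graph, and never a bridge of the non-wrapping
#' subgraph, so both the periodic cube and a single non-periodic copy stay
#' connected -- until the requested segment count is reached. Capillary
#' diameters are drawn from a truncated normal law whose default mean keeps
#' all capillaries well below the 25 um bead size.
#'
#' The requested `target_density` is met exactly in segment count terms
#' (`round(target_density * volume)` segments); if the lattice cannot reach it
#' the generator fails loudly rather than undershooting.
#'
#' @param edge_length cube edge (um).
#' @param target_density target segment density (segments/mm^3).
#' @param diameter_law list with `mean`, `sd`, `min`, `max` (um) for the
#'   truncated normal capillary diameter distribution.
#' @param seed integer seed; identical seeds give bit-identical graphs.
#' @param lattice_spacing nominal lattice pitch (um) controlling mean segment
#'   length; the actual pitch is `edge_length / round(edge_length / lattice_spacing)`.
#' @param jitter_frac node jitter as a fraction of the lattice pitch.
#' @return a periodic [vessel_graph()].
#' @export
generate_capillary_cube <- function(edge_length = 375,
                                    target_density = 9290,
                                    diameter_law = list(mean = 6.8, sd = 0.8,
                                                        min = 4, max = 10),
                                    seed = 1L,
                                    lattice_spacing = 62.5,
                                    jitter_frac = 0.2) {
  if (edge_length <= 0) stop("edge_length must be positive")
  if (target_density <= 0) stop("target_density must be positive")
  withr::local_seed(as.integer(seed))

  vol_mm3 <- (edge_length / 1e3)^3
  target_n <- round(target_density * vol_mm3)
  n <- max(2L, as.integer(round(edge_length / lattice_spacing)))
  full_n <- 3L * n^3
  if (target_n > full_n)
    stop(sprintf("target density needs %d segments but the lattice offers %d",
                 target_n, full_n))
  if (target_n < n^3)
    stop("target density too low for a connected lattice network")
  h <- edge_length / n

  # jittered lattice nodes
  idx <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1))
  nn <- nrow(idx)
  pos <- cbind((idx$i + 0.5) * h, (idx$j + 0.5) * h, (idx$k + 0.5) * h) +
    matrix(stats::runif(3 * nn, -jitter_frac * h, jitter_frac * h), ncol = 3)
  node_of <- function(i, j, k) 1L + (i %% n) + (j %% n) * n + (k %% n) * n^2

  # full periodic 6-neighbour edge set (+x, +y, +z from every node)
  from <- integer(0); to <- integer(0); wrap <- matrix(0L, 0, 3)
  for (ax in 1:3) {
    di <- c(ax == 1, ax == 2, ax == 3)
    f <- node_of(idx$i, idx$j, idx$k)
    t <- node_of(idx$i + di[1], idx$j + di[2], idx$k + di[3])
    w <- matrix(0L, nn, 3)
    hi <- switch(ax, idx$i, idx$j, idx$k) == n - 1L
    w[hi, ax] <- 1L
    from <- c(from, f); to <- c(to, t); wrap <- rbind(wrap, w)
  }

  keep <- rep(TRUE, length(from))
  n_delete <- full_n - target_n
  interior <- rowSums(abs(wrap)) == 0L
  make_ig <- function(sel) {
    igraph::graph_from_edgelist(cbind(from[sel], to[sel]), directed = FALSE)
  }
  deleted <- 0L
  while (deleted < n_delete) {
    cur <- which(keep)
    # protected: bridges of the periodic graph, and bridges of the
    # non-wrapping subgraph (so a single cube copy stays connected too)
    gp <- make_ig(keep)
    br_p <- cur[igraph::bridges(gp)]
    gi_sel <- keep & interior
    gi <- make_ig(gi_sel)
    br_i <- which(gi_sel)[igraph::bridges(gi)]
    cand <- setdiff(cur, union(br_p, br_i))
    if (length(cand) == 0)
      stop("target density unattainable: no deletable edge keeps the network connected")
    keep[cand[sample.int(length(cand), 1L)]] <- FALSE
    deleted <- deleted + 1L
  }

  from <- from[keep]; to <- to[keep]; wrap <- wrap[keep, , drop = FALSE]
  ns <- length(from)
  dl <- diameter_law
  diam <- pmin(pmax(stats::rnorm(ns, dl$mean, dl$sd), dl$min), dl$max)

  nodes <- data.frame(id = seq_len(nn), x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      is_boundary = FALSE, kind = "capillary")
  segments <- data.frame(id = seq_len(ns), from = from, to = to,
                         diameter = diam, length = 0, kind = "capillary",
                         wrap_x = wrap[, 1], wrap_y = wrap[, 2],
                         wrap_z = wrap[, 3], occluded = FALSE)
  g <- structure(list(nodes = nodes, segments = segments,
                      box = rep(edge_length, 3), inlet = NA_integer_,
                      periodic = TRUE, origin = c(0, 0, 0),
                      meta = list(seed = as.integer(seed),
                                  target_density = target_density,
                                  lattice_n = n, diameter_law = dl)),
                 class = "vessel_graph")
  g$segments$length <- segment_chord_length(g)
  validate_vessel_graph(g)
  g
}
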
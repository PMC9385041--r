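#' Default branching specification for the penetrating arteriole generator
#'
#' The trunk tapers geometrically from the inlet diameter to
#' `trunk_end_diameter` over the trunk segments between side offshoots; the
#' offshoot count is drawn uniformly from `n_offshoots_range`. Offshoot root
#' diameters are a uniform fraction (`offshoot_ratio_range`) of the local
#' trunk diameter, and offshoot subtrees bifurcate for
#' `offshoot_generations` generations with Murray-law daughters
#' (`murray_exponent`, flow split drawn from `split_range`). With the default
#' taper (30 to 20 um) the trunk falls below the 25 um bead size near
#' mid-depth -- matching the deep lodging sites seen in vivo -- and the
#' number of distinct 25 um first-trap sites per assembled column falls in
#' the 6-15 range.
#'
#' @return a list of branching parameters.
#' @export
arteriole_branching_spec <- function(n_offshoots_range = c(9L, 12L),
                                     trunk_end_diameter = 20,
                                     offshoot_ratio_range = c(0.75, 0.95),
                                     offshoot_generations = 3L,
                                     murray_exponent = 3,
                                     split_range = c(0.35, 0.65),
                                     min_diameter = 5,
                                     branch_length_range = c(80, 160),
                                     offshoot_polar_range = c(55, 85),
                                     trunk_wobble = 10) {
  as.list(environment())
}

#' Generate a penetrating arteriole tree
#'
#' A rooted, strictly diameter-decreasing bifurcating tree descending from the
#' cortical surface (z = 0): a tapering trunk with lateral-descending
#' offshoot subtrees. Geometry may extend beyond the lateral faces of the
#' destination column; [assemble_column()] trims it.
#'
#' @param depth trunk depth (um), must not exceed the column depth.
#' @param inlet_diameter inlet diameter (um). Values not exceeding the 25 um
#'   bead size are allowed but flagged with a warning (the bead would lodge at
#'   the inlet in every scenario).
#' @param branching_spec see [arteriole_branching_spec()]. Set
#'   `n_offshoots_range = c(0, 0)` for a bare tapering trunk.
#' @param seed integer seed.
#' @param centre_xy lateral position of the inlet (um).
#' @param max_depth column depth (um) used as a validity bound.
#' @return a [vessel_graph()] whose inlet is the tree root. Node ids are
#'   1-based; segment metadata records each segment's parent for trimming.
#' @export
generate_arteriole_tree <- function(depth = 1400,
                                    inlet_diameter = 30,
                                    branching_spec = arteriole_branching_spec(),
                                    seed = 1L,
                                    centre_xy = c(187.5, 187.5),
                                    max_depth = 1500) {
  if (depth > max_depth) stop("arteriole depth exceeds the column depth")
  if (depth <= 0) stop("depth must be positive")
  if (inlet_diameter <= 25)
    warning("inlet diameter <= 25 um: a bead would lodge at the inlet")
  bs <- branching_spec
  withr::local_seed(as.integer(seed))

  nodes <- list()   # rows: id, x, y, z
  segs <- list()    # rows: from, to, diameter, parent_seg
  add_node <- function(p) {
    nodes[[length(nodes) + 1L]] <<- p
    length(nodes)
  }
  add_seg <- function(from, to, diameter, parent) {
    segs[[length(segs) + 1L]] <<- c(from, to, diameter, parent)
    length(segs)
  }

  root <- add_node(c(centre_xy, 0))
  n_off <- if (bs$n_offshoots_range[2] == 0) 0L else
    sample(bs$n_offshoots_range[1]:bs$n_offshoots_range[2], 1L)
  n_trunk <- if (n_off > 0) n_off + 1L else 6L
  taper <- (bs$trunk_end_diameter / inlet_diameter)^(1 / (n_trunk - 1L))
  spacing <- depth / n_trunk

  # grow one offshoot subtree; returns nothing, appends via closures
  grow <- function(node, pos, dir, diameter, gen, parent_seg) {
    len <- stats::runif(1, bs$branch_length_range[1], bs$branch_length_range[2])
    new_pos <- pos + dir * len
    new_pos[3] <- min(new_pos[3], max_depth - 1)  # never below the box
    child <- add_node(new_pos)
    sid <- add_seg(node, child, diameter, parent_seg)
    if (gen >= bs$offshoot_generations || diameter < bs$min_diameter) return(invisible())
    u <- stats::runif(1, bs$split_range[1], bs$split_range[2])
    d1 <- diameter * u^(1 / bs$murray_exponent)
    d2 <- diameter * (1 - u)^(1 / bs$murray_exponent)
    for (d in c(d1, d2)) {
      if (d < bs$min_diameter) next
      ndir <- dir + 0.55 * random_unit_vector()
      ndir[3] <- abs(ndir[3]) * 0.6 + 0.1   # keep descending gently
      ndir <- ndir / sqrt(sum(ndir^2))
      grow(child, new_pos, ndir, d, gen + 1L, sid)
    }
    invisible()
  }

  cur_node <- root
  cur_pos <- c(centre_xy, 0)
  parent_of_trunk <- 0
  for (i in seq_len(n_trunk)) {
    d_i <- inlet_diameter * taper^(i - 1)
    nxt_pos <- cur_pos + c(stats::runif(2, -bs$trunk_wobble, bs$trunk_wobble), spacing)
    nxt <- add_node(nxt_pos)
    sid <- add_seg(cur_node, nxt, d_i, parent_of_trunk)
    if (i <= n_off) {
      ratio <- stats::runif(1, bs$offshoot_ratio_range[1], bs$offshoot_ratio_range[2])
      d_off <- ratio * d_i
      phi <- stats::runif(1, 0, 2 * pi)
      theta <- stats::runif(1, bs$offshoot_polar_range[1], bs$offshoot_polar_range[2]) * pi / 180
      dir <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
      if (d_off >= bs$min_diameter) grow(nxt, nxt_pos, dir, d_off, 1L, sid)
    }
    cur_node <- nxt
    cur_pos <- nxt_pos
    parent_of_trunk <- sid
  }

  nd <- do.call(rbind, nodes)
  sg <- do.call(rbind, segs)
  nodes_df <- data.frame(id = seq_len(nrow(nd)), x = nd[, 1], y = nd[, 2],
                         z = nd[, 3], is_boundary = FALSE, kind = "arteriole")
  seg_df <- data.frame(id = seq_len(nrow(sg)), from = as.integer(sg[, 1]),
                       to = as.integer(sg[, 2]), diameter = sg[, 3],
                       length = 0, kind = "arteriole",
                       wrap_x = 0L, wrap_y = 0L, wrap_z = 0L, occluded = FALSE,
                       parent_seg = as.integer(sg[, 4]))
  if (!any(seg_df$diameter < 25))
    stop("degenerate tree: no segment tapers below the 25 um bead size")

  # bounding box hugs the untrimmed tree (it is trimmed to a column at assembly)
  origin <- c(min(nodes_df$x) - 1, min(nodes_df$y) - 1, 0)
  box <- pmax(c(max(nodes_df$x) + 1 - origin[1],
                max(nodes_df$y) + 1 - origin[2], max_depth), 1)
  g <- structure(list(nodes = nodes_df, segments = seg_df, box = box,
                      inlet = root, periodic = FALSE, origin = origin,
                      meta = list(seed = as.integer(seed), depth = depth,
                                  inlet_diameter = inlet_diameter,
                                  n_offshoots = n_off, spec = bs)),
                 class = "vessel_graph")
  g$segments$length <- segment_chord_length(g)
  validate_vessel_graph(g)
  g
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
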
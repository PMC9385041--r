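test_that("assembled columns are connected, boxed, single-inlet", {
  cfg <- default_config(1)
  col <- generate_column(cfg, 2)
  expect_true(all(col$nodes$x >= -1e-6 & col$nodes$x <= 375 + 1e-6))
  expect_true(all(col$nodes$z >= -1e-6 & col$nodes$z <= 1500 + 1e-6))
  expect_true(arteriox:::graph_is_connected(col))
  expect_equal(col$nodes$z[match(col$inlet, col$nodes$id)], 0)
  # every arteriole terminal gained a connector
  expect_gt(sum(col$segments$kind == "connector"), 0)
  # boundary nodes all lie exactly on a face
  b <- col$nodes[col$nodes$is_boundary, ]
  on_face <- abs(b$x) < 1e-6 | abs(b$x - 375) < 1e-6 |
    abs(b$y) < 1e-6 | abs(b$y - 375) < 1e-6 |
    abs(b$z) < 1e-6 | abs(b$z - 1500) < 1e-6
  expect_true(all(on_face))
})

test_that("an arteriole fully inside the box is never trimmed", {
  cube <- generate_capillary_cube(seed = 21)
  spec <- arteriole_branching_spec(n_offshoots_range = c(0L, 0L))
  art <- generate_arteriole_tree(branching_spec = spec, seed = 5)
  col <- assemble_column(art, cube)
  # bare trunk: all arteriole segments survive, plus one connector at the tip
  expect_equal(sum(col$segments$kind == "arteriole"), nrow(art$segments))
  expect_equal(sum(col$segments$kind == "connector"), 1)
})

test_that("assembly never creates new trapping sites", {
  # sites in the column are at most the untrimmed tree's first sub-25
  # segments plus trimming cut-points
  cfg <- default_config(3)
  for (k in 1:3) {
    cube <- generate_capillary_cube(seed = cfg$seed + k)
    art <- generate_arteriole_tree(seed = cfg$seed + k + 500000L)
    col <- assemble_column(art, cube)
    # first sub-25 segments of the untrimmed tree by parent traversal
    seg <- art$segments
    first_sub <- 0L
    for (s in seq_len(nrow(seg))) {
      if (seg$diameter[s] >= 25) next
      par <- seg$parent_seg[s]
      upstream_wide <- TRUE
      while (par > 0) {
        if (seg$diameter[par] < 25) { upstream_wide <- FALSE; break }
        par <- seg$parent_seg[par]
      }
      if (upstream_wide) first_sub <- first_sub + 1L
    }
    cal <- calibrate_perfusion(col)
    sites <- enumerate_trapping_sites(col, cal$flow)
    expect_lte(nrow(sites), first_sub)
  }
})

test_that("network_stats reproduces the single-arteriole surface density", {
  cfg <- default_config(1)
  col <- generate_column(cfg, 1)
  st <- network_stats(col)
  expect_equal(st$surface_density, 1 / 0.375^2, tolerance = 1e-12)
  expect_equal(st$surface_density, 7.111, tolerance = 1e-3)
  expect_gt(st$volume_fraction, 0)
  expect_lt(st$volume_fraction, 1)
})

test_that("volume fraction matches hand arithmetic on three cylinders", {
  g <- three_cylinder_graph()
  st <- network_stats(g)
  hand <- (pi * 5^2 * 100 + pi * 4^2 * 80 + pi * 3^2 * 80) /
    (200 * 100 * 200)
  expect_equal(st$volume_fraction, hand, tolerance = 1e-12)
  expect_equal(st$vessel_density, 3 / (200 * 100 * 200 / 1e9),
               tolerance = 1e-9)
})

test_that("an empty graph reports zero density and fraction", {
  g <- three_cylinder_graph()
  g$segments <- g$segments[0, ]
  st <- network_stats(g)
  expect_equal(st$vessel_density, 0)
  expect_equal(st$volume_fraction, 0)
})

test_that("bead volume arithmetic reproduces the worked example", {
  out <- bead_volume_arithmetic(bead_density = 2.03, bead_diameter = 25,
                                territory_volume = 100,
                                reference_thrombus = 0.17)
  expect_equal(out$volume_fraction, 1.66e-5, tolerance = 0.005)
  expect_equal(out$total_volume, 1.66e-3, tolerance = 0.005)
  expect_equal(out$percent_of_reference, 1, tolerance = 0.03)
  expect_error(bead_volume_arithmetic(-1, 25), "positive")
})
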
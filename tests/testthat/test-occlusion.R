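test_that("a tapering trunk traps the bead at the first narrow segment", {
  # 30 -> 20 um trunk with no branches: exactly one site
  nodes <- data.frame(id = 1:4, x = 50, y = 50, z = c(0, 100, 200, 300),
                      is_boundary = c(FALSE, FALSE, FALSE, TRUE),
                      kind = "arteriole")
  segs <- data.frame(id = 1:3, from = 1:3, to = 2:4,
                     diameter = c(30, 27, 20), length = 100,
                     kind = "arteriole", wrap_x = 0L, wrap_y = 0L,
                     wrap_z = 0L, occluded = FALSE)
  g <- vessel_graph(nodes, segs, box = c(100, 100, 300), inlet = 1L)
  fl <- solve_flow(g, inlet_pressure = 5)
  sites <- enumerate_trapping_sites(g, fl)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$seg_id, 3)
  expect_equal(sites$z, 200)   # the trapped segment's upstream node
})

test_that("a symmetric tree with two narrow daughters yields two sites", {
  g <- symmetric_y_graph(trunk_d = 30, daughter_d = 20)
  fl <- solve_flow(g, inlet_pressure = 5)
  sites <- enumerate_trapping_sites(g, fl)
  expect_equal(nrow(sites), 2)
  expect_setequal(sites$seg_id, c(2, 3))
})

test_that("a tree that never narrows warns and returns an empty set", {
  g <- symmetric_y_graph(trunk_d = 40, daughter_d = 30)
  fl <- solve_flow(g, inlet_pressure = 5)
  expect_warning(sites <- enumerate_trapping_sites(g, fl), "never tapers")
  expect_equal(nrow(sites), 0)
})

test_that("blockage zeroes the trapped segment and only reduces perfusion", {
  g <- symmetric_y_graph(trunk_d = 30, daughter_d = 20)
  fl <- solve_flow(g, inlet_pressure = 5)
  sites <- enumerate_trapping_sites(g, fl)
  gb <- apply_blockage(g, sites[1, ])
  fb <- solve_flow(gb, inlet_pressure = 5)
  expect_identical(fb$flow[sites$seg_row[1]], 0)
  expect_lte(fb$inlet_flow, fl$inlet_flow)
  # blocking an already stagnant segment changes nothing
  g0 <- random_flow_fixture(11)
  f0 <- solve_flow(g0, inlet_pressure = 5)
  idle <- which.min(abs(f0$flow))
  if (abs(f0$flow[idle]) < 1e-9 * max(abs(f0$flow))) {
    gb0 <- g0; gb0$segments$occluded[idle] <- TRUE
    fb0 <- solve_flow(gb0, inlet_pressure = 5)
    expect_equal(fb0$flow, f0$flow, tolerance = 1e-12)
  }
})

test_that("enumeration is canonical and respects flow direction", {
  cfg <- default_config(4)
  col <- generate_column(cfg, 1)
  cal <- calibrate_perfusion(col)
  a <- enumerate_trapping_sites(col, cal$flow)
  b <- enumerate_trapping_sites(col, cal$flow)
  expect_identical(a, b)
  expect_true(all(diff(a$seg_id) > 0))
  # every site's upstream node is reached through >= 25 um segments: verify
  # by walking up the flow field from the site's upstream node
  seg <- col$segments
  Q <- cal$flow$flow
  ia <- match(seg$from, col$nodes$id); ib <- match(seg$to, col$nodes$id)
  up <- ifelse(Q >= 0, ia, ib); dn <- ifelse(Q >= 0, ib, ia)
  for (i in seq_len(nrow(a))) {
    node <- match(a$up_node[i], col$nodes$id)
    hops <- 0
    while (col$nodes$id[node] != col$inlet && hops < 1000) {
      feeder <- which(dn == node & abs(Q) > 1e-9 * max(abs(Q)) &
                        seg$diameter >= 25)
      expect_gt(length(feeder), 0)
      # follow the widest feeder upward
      node <- up[feeder[which.max(abs(Q[feeder]))]]
      hops <- hops + 1
    }
    expect_lt(hops, 1000)
  }
})
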
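# Solver tests run on a small single-cube column (see helper-fixtures.R) at a
# coarse grid so the whole file stays fast.

tiny_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      col <- tiny_column(seed = 3)
      cal <- calibrate_perfusion(col)
      cache <<- list(col = col, cal = cal)
    }
    cache
  }
})

test_that("zero metabolism gives a uniform field at the inlet PO2", {
  ts <- tiny_setup()
  prm <- oxy_params(M0 = 0, voxel_um = 30, max_element_um = 80)
  ox <- solve_oxygen(ts$col, ts$cal$flow, prm)
  expect_true(ox$converged)
  expect_lt(max(abs(ox$grid$po2 - 90)), 1e-3)
  expect_equal(sum(ox$elements$q), 0, tolerance = 1e-15)
})

test_that("the converged solution conserves oxygen and oxygenates tissue", {
  ts <- tiny_setup()
  prm <- oxy_params(voxel_um = 30, max_element_um = 80)
  ox <- solve_oxygen(ts$col, ts$cal$flow, prm)
  expect_true(ox$converged)
  expect_lt(ox$balance, 0.01)
  # healthy tissue: small hypoxic fraction
  expect_lt(ox$hypoxic_fraction, 0.05)
  expect_gt(mean(ox$grid$po2), 20)
  expect_lt(mean(ox$grid$po2), 90)
})

test_that("blood PO2 never increases along unbranched delivering runs", {
  ts <- tiny_setup()
  prm <- oxy_params(voxel_um = 30, max_element_um = 40)
  ox <- solve_oxygen(ts$col, ts$cal$flow, prm)
  el <- ox$elements
  q <- ts$cal$flow$flow
  for (s in unique(el$seg)) {
    rows <- el[el$seg == s & el$active, ]
    if (nrow(rows) < 2 || any(rows$q < 0)) next
    ord <- if (q[s] >= 0) order(rows$within) else order(-rows$within)
    expect_true(all(diff(rows$blood_po2[ord]) <= 1e-6))
  }
})

test_that("doubling all source strengths doubles the source field", {
  ts <- tiny_setup()
  prm <- oxy_params(voxel_um = 30, max_element_um = 80)
  ctx <- oxygen_context(ts$col, prm)
  set.seed(1)
  q <- runif(nrow(ctx$elements), 0, 1e-11)
  f1 <- as.numeric(crossprod(ctx$Gts, q))
  f2 <- as.numeric(crossprod(ctx$Gts, 2 * q))
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
})

test_that("a line source in a block matches the closed-form field", {
  # single straight vessel, constant consumption (P0 -> 0 limit); the field
  # at mid-plane voxels must match the analytic line-source plus the
  # uniform-sink potential integrated over the voxel set
  L <- 800; W <- 240
  nodes <- data.frame(id = 1:2, x = W / 2, y = W / 2, z = c(0, L),
                      is_boundary = c(FALSE, TRUE), kind = "arteriole")
  segs <- data.frame(id = 1, from = 1, to = 2, diameter = 20, length = L,
                     kind = "arteriole", wrap_x = 0L, wrap_y = 0L,
                     wrap_z = 0L, occluded = FALSE)
  g <- vessel_graph(nodes, segs, box = c(W, W, L), inlet = 1)
  fl <- solve_flow(g, inlet_pressure = 5)
  prm <- oxy_params(voxel_um = 20, max_element_um = 10, P0 = 1e-4,
                    M0 = 2e-4)
  ox <- solve_oxygen(g, fl, prm, q_rel_tol = 1e-12)
  expect_true(ox$converged)
  expect_lt(ox$balance, 1e-4)

  K <- prm$D_t * prm$alpha_t
  cen <- voxel_centres(ox$grid)
  radial <- sqrt((cen[, 1] - W / 2)^2 + (cen[, 2] - W / 2)^2)
  sel <- which(abs(cen[, 3] - L / 2) < 11 & radial > 19 & radial < 105)
  sel <- sel[unique(round(seq(1, length(sel), length.out = 40)))]
  qtot <- sum(ox$elements$q)
  Mvox <- prm$M0 * prod(ox$grid$spacing) / 1e12
  r0 <- (3 * prod(ox$grid$spacing) / (4 * pi))^(1 / 3) / 1e4
  for (i in sel) {
    p <- cen[i, ]
    ql <- qtot / (L / 1e4)
    r <- max(radial[i], 10) / 1e4
    line <- ql / (4 * pi * K) *
      (asinh((L - p[3]) / 1e4 / r) - asinh((0 - p[3]) / 1e4 / r))
    d <- sqrt((cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2 +
                (cen[, 3] - p[3])^2) / 1e4
    sink <- sum(ifelse(d < r0, 3 / (2 * r0), 1 / d)) * Mvox / (4 * pi * K)
    pred <- line - sink + ox$offset
    expect_lt(abs(pred - ox$grid$po2[i]) / abs(ox$grid$po2[i]), 0.02)
  }
})

test_that("halving the voxel edge changes the hypoxic fraction moderately", {
  # discretisation sensitivity, documented rather than asserted to converge:
  # compare a blocked tiny column at 30 um and 15 um voxels
  ts <- tiny_setup()
  sites <- enumerate_trapping_sites(ts$col, ts$cal$flow)
  gb <- apply_blockage(ts$col, sites[1, ])
  fb <- solve_flow(gb, inlet_pressure = ts$cal$inlet_pressure)
  frac <- vapply(c(30, 15), function(vx) {
    prm <- oxy_params(voxel_um = vx, max_element_um = 80)
    ox <- solve_oxygen(gb, fb, prm)
    ox$hypoxic_fraction
  }, numeric(1))
  if (max(frac) > 0) {
    expect_lt(abs(frac[2] - frac[1]) / max(max(frac), 0.01), 0.5)
  } else succeed("no hypoxia at either resolution")
})

test_that("non-convergence is an explicit warning with residual history", {
  ts <- tiny_setup()
  prm <- oxy_params(voxel_um = 30, max_element_um = 80, max_iter = 2)
  expect_warning(ox <- solve_oxygen(ts$col, ts$cal$flow, prm),
                 "did not converge")
  expect_false(ox$converged)
  expect_length(ox$residuals, 2)
})
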
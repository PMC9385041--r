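test_that("the viscosity law behaves physically", {
  # zero haematocrit recovers the plasma viscosity exactly
  expect_equal(apparent_viscosity(8, haematocrit = 0, plasma_viscosity = 1.2),
               1.2, tolerance = 1e-12)
  # monotone in haematocrit
  expect_gt(apparent_viscosity(10, 0.45), apparent_viscosity(10, 0.2))
  # frozen regression value of the in-vitro law at D = 10 um, H = 0.45
  expect_equal(apparent_viscosity(10, 0.45, 1.2), 1.594088014662356,
               tolerance = 1e-12)
  expect_error(apparent_viscosity(0), "positive")
})

test_that("conductance follows the r^4 Poiseuille law", {
  g1 <- segment_conductance(10, 100, 1.2)
  g2 <- segment_conductance(20, 100, 1.2)
  expect_equal(g2 / g1, 16, tolerance = 1e-12)
  # hand-computed pi r^4/(8 mu L) with unit conversion: r=5, L=100, mu=1.2
  expect_equal(segment_conductance(10, 100, 1.2), 272684.51546998595,
               tolerance = 1e-10)
  expect_error(segment_conductance(10, 0, 1.2), "length")
})

test_that("two identical segments in series halve the pressure", {
  g <- series_chain_graph()
  sol <- solve_flow(g, inlet_pressure = 10)
  expect_equal(sol$pressure[2], 5, tolerance = 1e-12)
  expect_lt(sol$residual, 1e-10)
})

test_that("a symmetric bifurcation splits the flow exactly", {
  g <- symmetric_y_graph()
  sol <- solve_flow(g, inlet_pressure = 4)
  expect_equal(sol$flow[2], sol$flow[3], tolerance = 1e-12)
  expect_equal(sol$flow[1], sol$flow[2] + sol$flow[3], tolerance = 1e-9)
})

test_that("the sparse solver matches a dense oracle on random fixtures", {
  hp <- hemo_params()
  for (seed in c(1, 2, 3, 4)) {
    g <- random_flow_fixture(seed)
    sol <- solve_flow(g, hp, inlet_pressure = 7)
    ora <- dense_flow_oracle(g, hp, inlet_pressure = 7)
    scale <- max(abs(ora$flow))
    expect_lt(max(abs(sol$flow - ora$flow)) / scale, 1e-10)
    expect_lt(max(abs(sol$pressure - ora$pressure)) / 7, 1e-10)
  }
})

test_that("flows are linear in the driving pressure and scale with conductance", {
  g <- random_flow_fixture(5)
  a <- solve_flow(g, inlet_pressure = 3)
  b <- solve_flow(g, inlet_pressure = -3)
  expect_equal(a$flow, -b$flow, tolerance = 1e-12)
  # multiplying all conductances by c (diameter by c^(1/4)) leaves pressures
  # unchanged and scales flows by c
  g2 <- g
  g2$segments$diameter <- g$segments$diameter * 2^(1 / 4)
  s1 <- solve_flow(g, hemo_params(haematocrit = 0), inlet_pressure = 3)
  s2 <- solve_flow(g2, hemo_params(haematocrit = 0), inlet_pressure = 3)
  expect_equal(s2$pressure, s1$pressure, tolerance = 1e-9)
  expect_lt(max(abs(s2$flow - 2 * s1$flow)) / max(abs(s1$flow)), 1e-9)
})

test_that("occluding a segment zeroes its flow and cannot raise inlet flow", {
  g <- random_flow_fixture(6)
  base <- solve_flow(g, inlet_pressure = 5)
  carrying <- which.max(abs(base$flow))
  g2 <- g
  g2$segments$occluded[carrying] <- TRUE
  blocked <- solve_flow(g2, inlet_pressure = 5)
  expect_identical(blocked$flow[carrying], 0)
  expect_lte(blocked$inlet_flow, base$inlet_flow + 1e-9)
})

test_that("global balance: inlet flow equals boundary outflow", {
  cfg <- default_config(1)
  col <- generate_column(cfg, 1)
  sol <- solve_flow(col, inlet_pressure = 2)
  nodes <- col$nodes; seg <- col$segments
  ia <- match(seg$from, nodes$id); ib <- match(seg$to, nodes$id)
  out_at <- rep(0, nrow(nodes))
  for (k in seq_along(sol$flow)) {
    out_at[ia[k]] <- out_at[ia[k]] + sol$flow[k]
    out_at[ib[k]] <- out_at[ib[k]] - sol$flow[k]
  }
  boundary_out <- -sum(out_at[nodes$is_boundary])
  expect_lt(abs(sol$inlet_flow - boundary_out) / sol$inlet_flow, 1e-8)
  expect_lt(sol$residual, 1e-8)
})

test_that("perfusion calibration is exact and linear", {
  cfg <- default_config(1)
  col <- generate_column(cfg, 3)
  cal <- calibrate_perfusion(col)
  expect_lt(abs(cal$flow$perfusion - 55) / 55, 1e-6)
  # column volume 0.2109 mm^3 at 55 mL/100mL/min needs ~0.116 mm^3/min
  expect_equal(cal$flow$inlet_flow * 60 / 1e9,
               55 / 6000 * 0.2109375 * 60, tolerance = 1e-6)
  hp2 <- hemo_params(target_perfusion = 110)
  cal2 <- calibrate_perfusion(col, hp2)
  expect_equal(cal2$inlet_pressure / cal$inlet_pressure, 2, tolerance = 1e-9)
})

test_that("degenerate flow problems error", {
  g <- series_chain_graph()
  g$nodes$is_boundary[] <- FALSE
  expect_error(solve_flow(g), "boundary")
  g2 <- series_chain_graph()
  g2$inlet <- NA_integer_
  expect_error(solve_flow(g2), "inlet")
})
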
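test_that("pixel Gx equals the all-pairs brute-force oracle exactly", {
  for (seed in c(1, 2, 3)) {
    f <- random_mask_grid(seed)
    set.seed(seed + 100)
    pts <- cbind(runif(5, 0, 180), runif(5, 0, 180), runif(5, 0, 500))
    gx <- pixel_gx(f$mask, pts, f$grid)
    expect_equal(gx$fraction, brute_gx(f$mask, pts, f$grid),
                 tolerance = 1e-12)
    expect_true(all(diff(gx$fraction) >= 0))
    expect_true(all(gx$fraction >= 0 & gx$fraction <= 1))
  }
})

test_that("Gx handles the degenerate cases the definition implies", {
  grid <- tissue_grid(c(5, 5, 5), spacing = c(10, 10, 10))
  mask <- array(FALSE, c(5, 5, 5))
  # single hypoxic voxel exactly at the bead: jump to 1 above d = 0
  mask[3, 3, 3] <- TRUE
  bead <- matrix(c(25, 25, 25), 1)  # the voxel centre
  gx <- pixel_gx(mask, bead, grid, breaks = c(0, 5, 10))
  expect_equal(gx$fraction, c(0, 1, 1))   # P(delta < 0) = 0, then 1
  # two voxels at 100 and 300 um from the only bead
  grid2 <- tissue_grid(c(41, 1, 1), spacing = c(10, 10, 10))
  mask2 <- array(FALSE, c(41, 1, 1))
  mask2[c(11, 31), 1, 1] <- TRUE            # centres at 105, 305
  bead2 <- matrix(c(5, 5, 5), 1)            # centre of voxel 1
  gx2 <- pixel_gx(mask2, bead2, grid2, breaks = c(50, 150, 250, 350))
  expect_equal(gx2$fraction, c(0, 0.5, 0.5, 1))
  # empty hypoxic set: explicit zero curve with a flag
  gx3 <- pixel_gx(array(FALSE, c(5, 5, 5)), bead, grid)
  expect_true(attr(gx3, "empty"))
  expect_true(all(gx3$fraction == 0))
  expect_error(pixel_gx(mask, matrix(numeric(0), ncol = 3), grid), "point")
})

test_that("baseline-hypoxic voxels are excluded from Gx only", {
  f <- random_mask_grid(7)
  baseline <- array(FALSE, dim(f$mask))
  baseline[f$mask][1:5] <- TRUE   # mark a few mask voxels as baseline
  pts <- matrix(c(90, 90, 250), 1)
  gx <- pixel_gx(f$mask, pts, f$grid, baseline_mask = baseline)
  expect_equal(gx$fraction, brute_gx(f$mask, pts, f$grid, baseline),
               tolerance = 1e-12)
})

test_that("hypoxic intensity equals exhaustive voxel counting", {
  radii <- seq(50, 500, by = 50)
  for (seed in c(4, 5)) {
    f <- random_mask_grid(seed, dims = c(10, 10, 10))
    centre <- c(80, 75, 240)
    hi <- hypoxic_intensity(f$mask, centre, f$grid, radii)
    expect_equal(hi$fraction, brute_intensity(f$mask, centre, f$grid, radii),
                 tolerance = 1e-12)
    ok <- !is.na(hi$fraction)
    expect_true(all(hi$fraction[ok] >= 0 & hi$fraction[ok] <= 1))
  }
})

test_that("intensity extremes and missing radii behave as defined", {
  grid <- tissue_grid(c(8, 8, 8), spacing = c(20, 20, 20))
  full <- array(TRUE, c(8, 8, 8))
  hi <- hypoxic_intensity(full, c(80, 80, 80), grid)
  expect_true(all(hi$fraction == 1))
  none <- array(FALSE, c(8, 8, 8))
  hi0 <- hypoxic_intensity(none, c(80, 80, 80), grid)
  expect_true(all(hi0$fraction == 0))
  # no in-domain voxel within the smallest radius: missing, not zero
  grid$indomain[] <- FALSE
  grid$indomain[1, 1, 1] <- TRUE
  hi_na <- hypoxic_intensity(none, c(150, 150, 150), grid,
                             radii = c(50, 100))
  expect_true(is.na(hi_na$fraction[1]))
})

test_that("type classification implements the slope dichotomy", {
  mk <- function(v50, v100) {
    cu <- data.frame(radius = seq(50, 500, 50),
                     fraction = c(v50, v100, rep(0.1, 8)))
    class(cu) <- c("intensity_curve", "data.frame")
    cu
  }
  expect_equal(classify_intensity(mk(0.8, 0.4)),
               list(type = "A", subtype = "local"))
  expect_equal(classify_intensity(mk(0.0, 0.15)),
               list(type = "B", subtype = "local"))
  # full hypoxia within 100 um is type A; none is type B no-local
  expect_equal(classify_intensity(mk(1, 1))$type, "A")
  expect_equal(classify_intensity(mk(0, 0)),
               list(type = "B", subtype = "no-local"))
  # flat with partial hypoxia falls in the residual class B
  expect_equal(classify_intensity(mk(0.3, 0.3))$type, "B")
  expect_error(classify_intensity(mk(NA, 0.3)), "50 and 100")
})

test_that("aggregation pools distances and averages intensities", {
  f <- random_mask_grid(9)
  pts <- matrix(c(60, 60, 100), 1)
  gx1 <- pixel_gx(f$mask, pts, f$grid)
  f2 <- random_mask_grid(10)
  gx2 <- pixel_gx(f2$mask, pts, f2$grid)
  mk <- function(v) {
    cu <- data.frame(radius = seq(50, 500, 50), fraction = v)
    class(cu) <- c("intensity_curve", "data.frame")
    cu
  }
  agg <- aggregate_column(list(gx1, gx2), list(mk(0.2), mk(0.4)))
  expect_equal(agg$intensity$fraction, rep(0.3, 10), tolerance = 1e-12)
  pooled <- c(attr(gx1, "distances"), attr(gx2, "distances"))
  expect_equal(agg$gx$fraction,
               vapply(agg$gx$distance, function(b) mean(pooled < b),
                      numeric(1)), tolerance = 1e-12)
  # a single scenario aggregates to itself
  agg1 <- aggregate_column(list(gx1), list(mk(0.2)))
  expect_equal(agg1$gx$fraction, gx1$fraction, tolerance = 1e-12)
})

test_that("Monte-Carlo controls have the right count, domain and mean", {
  grid <- tissue_grid(c(10, 10, 10), spacing = c(20, 20, 20))
  vol_mm3 <- 1000 * 20^3 / 1e9
  density <- 25 / vol_mm3
  reps <- monte_carlo_controls(grid, density, n_replicates = 3, seed = 8)
  expect_length(reps, 3)
  for (pts in reps) {
    expect_equal(nrow(pts), 25)
    expect_true(all(pts >= 0 & pts <= 200))
  }
  # law of large numbers: control intensity at a large radius approaches the
  # domain's overall hypoxic fraction
  set.seed(99)
  mask <- array(runif(1000) < 0.3, c(10, 10, 10))
  reps <- monte_carlo_controls(grid, density, n_replicates = 30, seed = 9)
  vals <- vapply(reps, function(pts) {
    mean(vapply(seq_len(nrow(pts)), function(i)
      hypoxic_intensity(mask, pts[i, ], grid,
                        radii = c(300))$fraction, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(vals) - mean(mask)), 0.03)
  # reproducible per seed
  a <- monte_carlo_controls(grid, density, 1, seed = 5)
  b <- monte_carlo_controls(grid, density, 1, seed = 5)
  expect_identical(a, b)
})
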
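test_that("section stacks place content at slab centres and round-trip", {
  imgs <- lapply(1:10, function(k) matrix(runif(100 * 100) < 0.1, 100, 100))
  stk <- section_stack(imgs)
  expect_equal(stk$z_centres, seq(25, 475, by = 50))
  path <- file.path(withr::local_tempdir(), "stack")
  write_section_stack(stk, path)
  stk2 <- load_stack(path)
  expect_identical(stk2$images, stk$images)
  expect_identical(stk2$tissue, stk$tissue)
  expect_equal(stk2$pixel_size, stk$pixel_size)
})

test_that("hypoxia pixels outside the tissue mask are cleared and counted", {
  img <- matrix(FALSE, 20, 20); img[5, 5] <- img[15, 15] <- TRUE
  tis <- matrix(TRUE, 20, 20); tis[15, 15] <- FALSE
  expect_message(stk <- section_stack(list(img), list(tis)), "cleared 1")
  expect_false(stk$images[[1]][15, 15])
  expect_true(stk$images[[1]][5, 5])
})

test_that("stacks with mismatched shapes or metadata fail", {
  expect_error(section_stack(list(matrix(TRUE, 5, 5), matrix(TRUE, 6, 5))),
               "share dimensions")
  path <- file.path(withr::local_tempdir(), "s")
  stk <- section_stack(list(matrix(runif(25) < .5, 5, 5)))
  write_section_stack(stk, path)
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  hdr$pixel_size_um <- NULL
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(load_stack(path), "metadata")
})

test_that("downsampling follows the majority rule with ties hypoxic", {
  px <- 3.033
  block <- function(frac) {
    m <- matrix(FALSE, 5, 5)
    if (frac > 0) m[seq_len(round(25 * frac))] <- TRUE
    m
  }
  img <- matrix(FALSE, 10, 10)
  img[1:5, 1:5] <- block(1)          # all ones -> hypoxic
  img[6:10, 1:5] <- block(0)         # all zeros -> not
  img[1:5, 6:10] <- matrix(rep(c(TRUE, FALSE), length.out = 25), 5, 5) # 13/25
  img[6:10, 6:10] <- block(0.48)     # 12/25 -> below half
  stk <- section_stack(list(img), pixel_size = px)
  ds <- downsample_to_analysis_grid(stk, target_xy = 5 * px)
  expect_identical(dim(ds$mask), c(2L, 2L, 1L))
  expect_true(ds$mask[1, 1, 1])
  expect_false(ds$mask[2, 1, 1])
  expect_true(ds$mask[1, 2, 1])      # 13/25 >= half: tie-side hypoxic
  expect_false(ds$mask[2, 2, 1])
  expect_equal(ds$grid$spacing, c(5 * px, 5 * px, 50))
  # the "any" rule marks every block containing hypoxia
  ds2 <- downsample_to_analysis_grid(stk, target_xy = 5 * px, rule = "any")
  expect_true(ds2$mask[2, 2, 1])
  # non-integer pooling factor is rejected
  expect_error(downsample_to_analysis_grid(stk, target_xy = 10), "integer")
})

test_that("downsampling never creates hypoxia from an empty block", {
  set.seed(3)
  img <- matrix(runif(50 * 50) < 0.2, 50, 50)
  img[1:10, ] <- FALSE
  stk <- section_stack(list(img))
  ds <- downsample_to_analysis_grid(stk)
  expect_true(all(!ds$mask[1:2, , 1]))
})

test_that("bead CSVs are validated against the tissue domain", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "beads.csv")
  grid <- tissue_grid(c(10, 10, 4), spacing = c(15, 15, 50))
  grid$indomain[1, 1, 1] <- FALSE
  df <- data.frame(x_um = c(50, 3, 1e4), y_um = c(50, 4, 50),
                   z_um = c(100, 20, 100))
  data.table::fwrite(df, f)
  expect_message(pts <- load_beads(f, grid), "rejected 2")
  expect_equal(nrow(pts), 1)
  expect_equal(attr(pts, "rejected"), 2L)
  # an empty file gives an explicit empty set
  f2 <- file.path(tmp, "empty.csv")
  data.table::fwrite(df[0, ], f2)
  expect_message(p0 <- load_beads(f2), "no points")
  expect_equal(nrow(p0), 0)
})

test_that("synthetic fixtures honour their construction", {
  # blobs centred on beads: type A local around every bead
  fx <- generate_synthetic_experiment(n_beads = 4, displacement = 0,
                                      blob_radius_um = 90,
                                      section_px = c(400, 400),
                                      min_separation_um = 350, seed = 2)
  ds <- downsample_to_analysis_grid(fx$stack)
  cls <- lapply(seq_len(nrow(fx$beads)), function(i) {
    classify_intensity(hypoxic_intensity(
      ds$mask, unlist(fx$beads[i, ]), ds$grid))
  })
  expect_true(all(vapply(cls, `[[`, character(1), "type") == "A"))
  expect_true(all(vapply(cls, `[[`, character(1), "subtype") == "local"))

  # far-displaced blobs: type B, no local hypoxia
  fx2 <- generate_synthetic_experiment(n_beads = 4, displacement = 300,
                                       blob_radius_um = 75,
                                       section_px = c(800, 800),
                                       min_separation_um = 700, seed = 3)
  ds2 <- downsample_to_analysis_grid(fx2$stack)
  cls2 <- lapply(seq_len(nrow(fx2$beads)), function(i) {
    classify_intensity(hypoxic_intensity(
      ds2$mask, unlist(fx2$beads[i, ]), ds2$grid))
  })
  expect_true(all(vapply(cls2, `[[`, character(1), "type") == "B"))
  expect_true(all(vapply(cls2, `[[`, character(1), "subtype") == "no-local"))
  expect_equal(fx2$truth$displacement, rep(300, 4))
})

test_that("planted displacement is recovered by the Gx 50% crossing", {
  hits <- vapply(1:4, function(seed) {
    fx <- generate_synthetic_experiment(n_beads = 4, displacement = 300,
                                        blob_radius_um = 75,
                                        section_px = c(800, 800),
                                        min_separation_um = 700, seed = seed)
    ds <- downsample_to_analysis_grid(fx$stack)
    gx <- pixel_gx(ds$mask, as.matrix(fx$beads), ds$grid)
    gx_crossing(gx, 0.5)
  }, numeric(1))
  expect_true(all(abs(hits - 300) <= 10))
})
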
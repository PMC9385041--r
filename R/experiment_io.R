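#' Section stack of segmented experimental images
#'
#' An ordered set of binary maximum-intensity-projection images, one per
#' coronal section: hypoxia masks plus a tissue-domain mask per section.
#' Images are matrices indexed `[x, y]` in pixels; each section's content sits
#' at the centre of its 50 um slab, so section k has z-centre
#' `(k - 1/2) * thickness`.
#'
#' @param images list of binary matrices (hypoxia), all the same dimension.
#' @param tissue optional list of binary matrices (tissue domain); default all
#'   tissue. Hypoxia pixels outside the tissue mask are cleared (and counted).
#' @param pixel_size xy pixel size (um), default 3.033.
#' @param thickness section thickness (um), default 50.
#' @return object of class `section_stack`.
#' @export
section_stack <- function(images, tissue = NULL, pixel_size = 3.033,
                          thickness = 50) {
  stopifnot(length(images) >= 1, pixel_size > 0, thickness > 0)
  d <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), d), logical(1))))
    stop("all sections must share dimensions")
  if (is.null(tissue)) tissue <- lapply(images, function(m) {
    x <- m; x[] <- TRUE; x
  })
  if (!all(vapply(tissue, function(m) identical(dim(m), d), logical(1))))
    stop("tissue masks must share the image dimensions")
  images <- lapply(images, function(m) m > 0)
  tissue <- lapply(tissue, function(m) m > 0)
  dropped <- 0L
  for (k in seq_along(images)) {
    out <- images[[k]] & !tissue[[k]]
    if (any(out)) {
      dropped <- dropped + sum(out)
      images[[k]][out] <- FALSE
    }
  }
  if (dropped > 0)
    message(sprintf("cleared %d hypoxia pixels outside the tissue mask", dropped))
  structure(list(images = images, tissue = tissue, pixel_size = pixel_size,
                 thickness = thickness,
                 z_centres = (seq_along(images) - 0.5) * thickness),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<section_stack> %d sections of %d x %d px (%.4g um/px, %.4g um thick)\n",
              length(x$images), d[1], d[2], x$pixel_size, x$thickness))
  invisible(x)
}

#' Write / load a section stack (multi-page binary TIFF + JSON metadata)
#'
#' @param stack a [section_stack()].
#' @param path base path: writes `<path>.tif` (hypoxia), `<path>_tissue.tif`
#'   and `<path>.json`.
#' @return base path (write) / `section_stack` (load).
#' @export
write_section_stack <- function(stack, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(lapply(stack$images, function(m) t(m * 1)),
                  paste0(path, ".tif"), bits.per.sample = 8L)
  tiff::writeTIFF(lapply(stack$tissue, function(m) t(m * 1)),
                  paste0(path, "_tissue.tif"), bits.per.sample = 8L)
  jsonlite::write_json(list(schema = "arteriox/section_stack/1",
                            n_sections = length(stack$images),
                            pixel_size_um = stack$pixel_size,
                            section_thickness_um = stack$thickness),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_section_stack
#' @export
load_stack <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(hdr$pixel_size_um) || is.null(hdr$section_thickness_um))
    stop("incomplete stack metadata")
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  imgs <- lapply(pages, function(p) t(p) > 0.5)
  tis <- NULL
  tf <- paste0(path, "_tissue.tif")
  if (file.exists(tf)) {
    tp <- tiff::readTIFF(tf, all = TRUE)
    if (!is.list(tp)) tp <- list(tp)
    tis <- lapply(tp, function(p) t(p) > 0.5)
  }
  section_stack(imgs, tis, hdr$pixel_size_um, hdr$section_thickness_um)
}

# sum over f x f pixel blocks of a matrix whose dims are multiples of f
block_sum <- function(M, f) {
  nx <- nrow(M); ny <- ncol(M)
  B <- colSums(array(M, c(f, nx %/% f, ny)))          # (nx/f) x ny
  t(colSums(array(t(B), c(f, ny %/% f, nx %/% f))))   # (nx/f) x (ny/f)
}

#' Downsample a section stack to the analysis grid
#'
#' Pools `f x f` pixel blocks of each section into one voxel, where `f` is
#' the (integer) ratio of the target xy spacing to the pixel size (5 for the
#' defaults, giving 15.165 x 15.165 x 50 um voxels). A voxel is hypoxic iff
#' at least half of its in-tissue pixels are hypoxic (ties count as hypoxic;
#' `rule = "any"` marks a voxel hypoxic if any pixel is); it is in-domain iff
#' at least half of its block is tissue. Downsampling never creates hypoxia
#' in a block that had none. Trailing pixels not filling a block are cropped.
#'
#' @param stack a [section_stack()].
#' @param target_xy target voxel xy edge (um).
#' @param rule pooling rule for hypoxia, `"majority"` (default) or `"any"`.
#' @return list with `mask` (logical hypoxia array) and `grid` (the
#'   [tissue_grid()] carrying spacing and the tissue domain).
#' @export
downsample_to_analysis_grid <- function(stack, target_xy = 15.165,
                                        rule = c("majority", "any")) {
  rule <- match.arg(rule)
  f <- target_xy / stack$pixel_size
  if (abs(f - round(f)) > 1e-6)
    stop("target spacing must be an integer multiple of the pixel size")
  f <- as.integer(round(f))
  d <- dim(stack$images[[1]])
  nx <- (d[1] %/% f); ny <- (d[2] %/% f)
  if (nx < 1 || ny < 1) stop("sections smaller than one analysis voxel")
  nz <- length(stack$images)
  mask <- array(FALSE, c(nx, ny, nz))
  dom <- array(FALSE, c(nx, ny, nz))
  cx <- seq_len(nx * f); cy <- seq_len(ny * f)
  for (k in seq_len(nz)) {
    tiss <- block_sum(stack$tissue[[k]][cx, cy] * 1, f)
    hyp <- block_sum((stack$images[[k]][cx, cy] & stack$tissue[[k]][cx, cy]) * 1, f)
    dom[, , k] <- tiss >= f^2 / 2
    mask[, , k] <- if (rule == "majority") tiss > 0 & hyp >= tiss / 2
    else hyp > 0
  }
  grid <- tissue_grid(c(nx, ny, nz),
                      spacing = c(target_xy, target_xy, stack$thickness),
                      indomain = dom)
  list(mask = mask & dom, grid = grid)
}

#' Load microsphere centres from a CSV export
#'
#' Expects columns `x_um`, `y_um`, `z_um`. Points outside the tissue domain of
#' `grid` are rejected and reported.
#'
#' @param path CSV file.
#' @param grid optional [tissue_grid()] for domain validation.
#' @return matrix (n x 3) of accepted points with attribute `rejected`
#'   (number rejected); zero rows (with a message) for an empty file.
#' @export
load_beads <- function(path, grid = NULL) {
  df <- as.data.frame(data.table::fread(path))
  if (nrow(df) == 0) {
    message("bead file contains no points")
    out <- matrix(numeric(0), ncol = 3)
    colnames(out) <- c("x", "y", "z")
    attr(out, "rejected") <- 0L
    return(out)
  }
  if (!all(c("x_um", "y_um", "z_um") %in% names(df)))
    stop("bead CSV must have columns x_um, y_um, z_um")
  pts <- as.matrix(df[, c("x_um", "y_um", "z_um")])
  colnames(pts) <- c("x", "y", "z")
  rejected <- 0L
  if (!is.null(grid)) {
    vi <- floor(sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")) + 1
    ok <- vi[, 1] >= 1 & vi[, 1] <= grid$dim[1] &
      vi[, 2] >= 1 & vi[, 2] <= grid$dim[2] &
      vi[, 3] >= 1 & vi[, 3] <= grid$dim[3]
    ok[ok] <- grid$indomain[vi[ok, , drop = FALSE]]
    rejected <- sum(!ok)
    if (rejected > 0)
      message(sprintf("rejected %d bead(s) outside the tissue domain", rejected))
    pts <- pts[ok, , drop = FALSE]
  }
  attr(pts, "rejected") <- rejected
  pts
}

#' Generate a synthetic experimental fixture
#'
#' Emulates a segmented microembolisation dataset: beads are planted in a
#' tissue mask (an ellipse per section) and each bead receives one hypoxic
#' blob (a disk in the bead's own section) displaced laterally by a stated
#' displacement law, plus optional unrelated background blobs. The true
#' bead-blob displacements are recorded so recovery of the displacement
#' distribution by the spatial statistics can be tested. Blobs reaching
#' beyond the tissue are clipped (and the clipped pixel count recorded).
#'
#' @param n_beads number of beads.
#' @param displacement either a single distance (um) applied to every bead,
#'   or `c(min, max)` for a uniform law; 0 centres every blob on its bead.
#' @param blob_radius_um hypoxic blob radius (um).
#' @param background_blobs number of unrelated blobs.
#' @param n_sections,section_px,pixel_size,thickness stack geometry.
#' @param min_separation_um minimum bead-bead distance (um).
#' @param seed integer seed.
#' @return list with `stack` (a [section_stack()]), `beads` (data.frame
#'   `x_um`, `y_um`, `z_um`) and `truth` (per-bead displacement and blob
#'   centre, plus the clipped pixel count).
#' @export
generate_synthetic_experiment <- function(n_beads = 8,
                                          displacement = 300,
                                          blob_radius_um = 75,
                                          background_blobs = 0,
                                          n_sections = 10,
                                          section_px = c(660, 660),
                                          pixel_size = 3.033,
                                          thickness = 50,
                                          min_separation_um = 800,
                                          seed = 1L) {
  withr::local_seed(as.integer(seed))
  nx <- section_px[1]; ny <- section_px[2]
  ex <- nx * pixel_size / 2; ey <- ny * pixel_size / 2
  px <- (seq_len(nx) - 0.5) * pixel_size
  py <- (seq_len(ny) - 0.5) * pixel_size
  tis <- outer(((px - ex) / (0.96 * ex))^2, ((py - ey) / (0.96 * ey))^2, "+") <= 1
  tissue <- lapply(seq_len(n_sections), function(k) tis)
  images <- lapply(seq_len(n_sections), function(k) {
    m <- tis; m[] <- FALSE; m
  })

  draw_disp <- function() {
    if (length(displacement) == 2) stats::runif(1, displacement[1], displacement[2])
    else displacement
  }
  margin <- max(displacement) + blob_radius_um + 2 * pixel_size
  beads <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(beads) < n_beads && tries < 20000) {
    tries <- tries + 1
    p <- c(stats::runif(1, margin, nx * pixel_size - margin),
           stats::runif(1, margin, ny * pixel_size - margin))
    if (((p[1] - ex) / (0.96 * ex - margin))^2 +
        ((p[2] - ey) / (0.96 * ey - margin))^2 > 1) next
    if (nrow(beads) > 0 &&
        min((beads[, 1] - p[1])^2 + (beads[, 2] - p[2])^2) < min_separation_um^2) next
    k <- sample.int(n_sections, 1)
    beads <- rbind(beads, c(p, (k - 0.5) * thickness))
  }
  if (nrow(beads) < n_beads)
    stop("could not place the requested beads with the given separation")

  paint_disk <- function(img, cx, cy, r) {
    i1 <- max(1L, floor((cx - r) / pixel_size)); i2 <- min(nx, ceiling((cx + r) / pixel_size))
    j1 <- max(1L, floor((cy - r) / pixel_size)); j2 <- min(ny, ceiling((cy + r) / pixel_size))
    ii <- i1:i2; jj <- j1:j2
    sub <- outer((px[ii] - cx)^2, (py[jj] - cy)^2, "+") <= r^2
    img[ii, jj] <- img[ii, jj] | sub
    img
  }

  truth <- data.frame(bead = seq_len(n_beads), displacement = NA_real_,
                      blob_x = NA_real_, blob_y = NA_real_, blob_z = NA_real_)
  for (b in seq_len(n_beads)) {
    dsp <- draw_disp()
    phi <- stats::runif(1, 0, 2 * pi)
    bc <- beads[b, 1:2] + dsp * c(cos(phi), sin(phi))
    k <- as.integer(round(beads[b, 3] / thickness + 0.5))
    images[[k]] <- paint_disk(images[[k]], bc[1], bc[2], blob_radius_um)
    truth$displacement[b] <- dsp
    truth$blob_x[b] <- bc[1]; truth$blob_y[b] <- bc[2]
    truth$blob_z[b] <- beads[b, 3]
  }
  for (g in seq_len(background_blobs)) {
    k <- sample.int(n_sections, 1)
    cx <- stats::runif(1, margin, nx * pixel_size - margin)
    cy <- stats::runif(1, margin, ny * pixel_size - margin)
    images[[k]] <- paint_disk(images[[k]], cx, cy, blob_radius_um)
  }

  clipped <- sum(vapply(seq_len(n_sections),
                        function(k) sum(images[[k]] & !tissue[[k]]), numeric(1)))
  stk <- suppressMessages(section_stack(images, tissue, pixel_size, thickness))
  list(stack = stk,
       beads = data.frame(x_um = beads[, 1], y_um = beads[, 2], z_um = beads[, 3]),
       truth = truth, clipped_pixels = clipped)
}
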
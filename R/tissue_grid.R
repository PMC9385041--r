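#' Tissue voxel grid
#'
#' A rectilinear voxel grid holding a tissue PO2 field and an in-domain flag
#' per voxel. Arrays are indexed `[x, y, z]`; voxel centres are at
#' `origin + (i - 1/2) * spacing`. Spacings may differ per axis (experimental
#' stacks use 15.165 x 15.165 x 50 um voxels, simulations 15 um isotropic).
#'
#' @param dim integer length-3 voxel counts.
#' @param spacing numeric length-3 voxel edge lengths (um).
#' @param origin numeric length-3 lower corner (um).
#' @param po2 optional numeric array of tissue PO2 (mmHg).
#' @param indomain optional logical array marking voxels inside the tissue
#'   domain (default: all).
#' @return object of class `tissue_grid`.
#' @export
tissue_grid <- function(dim, spacing, origin = c(0, 0, 0), po2 = NULL,
                        indomain = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim > 0), length(spacing) == 3,
            all(spacing > 0))
  if (is.null(indomain)) indomain <- array(TRUE, dim)
  stopifnot(all(base::dim(indomain) == dim))
  if (!is.null(po2)) stopifnot(all(base::dim(po2) == dim))
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), po2 = po2,
                 indomain = indomain),
            class = "tissue_grid")
}

#' Build the voxel grid tiling a bounding box
#'
#' Each axis uses `round(box / voxel_um)` voxels with the edge adjusted so the
#' grid tiles the box exactly (isotropic 15 um tiles the default column with
#' no adjustment).
#'
#' @param box numeric length-3 box (um).
#' @param voxel_um requested voxel edge (um).
#' @return a [tissue_grid()].
#' @export
grid_for_box <- function(box, voxel_um = 15) {
  n <- pmax(1L, as.integer(round(box / voxel_um)))
  tissue_grid(n, box / n)
}

#' Voxel centre coordinates
#'
#' @param grid a [tissue_grid()].
#' @return matrix `prod(dim) x 3` of centres (um), in array linearisation
#'   order (x fastest).
#' @export
voxel_centres <- function(grid) {
  cx <- grid$origin[1] + (seq_len(grid$dim[1]) - 0.5) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(grid$dim[2]) - 0.5) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(grid$dim[3]) - 0.5) * grid$spacing[3]
  as.matrix(expand.grid(x = cx, y = cy, z = cz))
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("<tissue_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g um\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (!is.null(x$po2))
    cat(sprintf("  PO2: median %.3g mmHg [%.3g, %.3g]\n",
                stats::median(x$po2), min(x$po2), max(x$po2)))
  cat(sprintf("  in-domain voxels: %d / %d\n", sum(x$indomain), prod(x$dim)))
  invisible(x)
}

#' Hypoxia mask of a solved tissue grid
#'
#' Strictly `PO2 < threshold`; voxels outside the tissue domain are never
#' hypoxic.
#'
#' @param grid a [tissue_grid()] with a PO2 field.
#' @param threshold hypoxia threshold (mmHg), default 10.
#' @return logical array of `grid$dim`.
#' @export
hypoxia_mask <- function(grid, threshold = 10) {
  if (is.null(grid$po2)) stop("grid has no PO2 field")
  grid$po2 < threshold & grid$indomain
}

#' Write / read a tissue grid as a TIFF stack plus a JSON header
#'
#' The PO2 field is stored as a multi-page 32-bit TIFF (one page per z slab),
#' affinely rescaled to `[0, 1]`; offset and scale are recorded in the JSON
#' sidecar together with origin, spacing and dimensions. The in-domain mask is
#' written alongside as an 8-bit binary TIFF.
#'
#' @param grid a [tissue_grid()].
#' @param path base path; writes `<path>.tif`, `<path>_domain.tif`,
#'   `<path>.json`.
#' @return the base path, invisibly.
#' @export
write_tissue_grid <- function(grid, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  po2 <- if (is.null(grid$po2)) array(0, grid$dim) else grid$po2
  lo <- min(po2); hi <- max(po2)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(grid$dim[3]), function(k)
    t((po2[, , k] - lo) / scale))   # TIFF rows = y
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32L)
  dpages <- lapply(seq_len(grid$dim[3]), function(k)
    t(grid$indomain[, , k] * 1))
  tiff::writeTIFF(dpages, paste0(path, "_domain.tif"), bits.per.sample = 8L)
  jsonlite::write_json(
    list(schema = "arteriox/tissue_grid/1", dim = grid$dim,
         spacing_um = grid$spacing, origin_um = grid$origin,
         po2_offset = lo, po2_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tissue_grid
#' @export
read_tissue_grid <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(hdr$dim)
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  po2 <- array(0, d)
  for (k in seq_len(d[3])) po2[, , k] <- t(pages[[k]]) * hdr$po2_scale + hdr$po2_offset
  dpages <- tiff::readTIFF(paste0(path, "_domain.tif"), all = TRUE)
  dom <- array(TRUE, d)
  for (k in seq_len(d[3])) dom[, , k] <- t(dpages[[k]]) > 0.5
  tissue_grid(d, hdr$spacing_um, hdr$origin_um, po2 = po2, indomain = dom)
}

#' Write a binary mask as an 8-bit TIFF stack with a JSON header
#'
#' @param mask logical 3D array.
#' @param grid the [tissue_grid()] the mask lives on (for spacing metadata).
#' @param path base path; writes `<path>.tif` and `<path>.json`.
#' @return the base path, invisibly.
#' @export
write_mask <- function(mask, grid, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(seq_len(dim(mask)[3]), function(k) t(mask[, , k] * 1))
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 8L)
  jsonlite::write_json(
    list(schema = "arteriox/mask/1", dim = dim(mask),
         spacing_um = grid$spacing, origin_um = grid$origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(hdr$dim)
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mask <- array(FALSE, d)
  for (k in seq_len(d[3])) mask[, , k] <- t(pages[[k]]) > 0.5
  attr(mask, "spacing_um") <- hdr$spacing_um
  attr(mask, "origin_um") <- hdr$origin_um
  mask
}
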
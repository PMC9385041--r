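#' Pixel-based Gx function
#'
#' Empirical cumulative distribution of the Euclidean distances from every
#' in-domain hypoxic voxel centre to its nearest microsphere:
#' `Gx(d) = P(delta < d)`. Voxels hypoxic under the healthy baseline can be
#' excluded via `baseline_mask`. Distances respect anisotropic voxel spacing.
#'
#' @param mask logical hypoxia array on `grid`.
#' @param points matrix (n x 3) of microsphere centres (um), or a data.frame
#'   with `x`, `y`, `z` columns.
#' @param grid the [tissue_grid()] carrying spacing/origin and the domain.
#' @param baseline_mask optional logical array of baseline-hypoxic voxels to
#'   exclude.
#' @param breaks distance grid (um) on which the CDF is reported.
#' @return data.frame of class `gx_curve` with `distance` and `fraction`;
#'   attributes `distances` (the raw per-voxel nearest distances) and `empty`
#'   (TRUE when no hypoxic voxel remained, in which case the curve is zero).
#' @export
pixel_gx <- function(mask, points, grid, baseline_mask = NULL,
                     breaks = seq(0, 1000, by = 10)) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(points, ncol = 3)
  if (nrow(points) == 0) stop("at least one point is required")
  sel <- mask & grid$indomain
  if (!is.null(baseline_mask)) sel <- sel & !baseline_mask
  idx <- which(as.logical(sel))
  if (length(idx) == 0) {
    curve <- data.frame(distance = breaks, fraction = 0)
    class(curve) <- c("gx_curve", "data.frame")
    attr(curve, "distances") <- numeric(0)
    attr(curve, "empty") <- TRUE
    return(curve)
  }
  cen <- voxel_centres(grid)[idx, , drop = FALSE]
  d <- nearest_point_distance(cen, points)
  curve <- data.frame(distance = breaks,
                      fraction = vapply(breaks, function(b) mean(d < b),
                                        numeric(1)))
  class(curve) <- c("gx_curve", "data.frame")
  attr(curve, "distances") <- d
  attr(curve, "empty") <- FALSE
  curve
}

# distance from each row of `x` to the nearest row of `pts`, chunked
nearest_point_distance <- function(x, pts) {
  n <- nrow(x)
  out <- numeric(n)
  step <- max(1L, floor(2e7 / nrow(pts)))
  for (a in seq(1L, n, by = step)) {
    b <- min(a + step - 1L, n)
    d2 <- outer(x[a:b, 1], pts[, 1], "-")^2 +
      outer(x[a:b, 2], pts[, 2], "-")^2 +
      outer(x[a:b, 3], pts[, 3], "-")^2
    out[a:b] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' First crossing of a cumulative curve
#'
#' @param curve a `gx_curve` (or any data.frame with `distance`, `fraction`).
#' @param level target cumulative fraction.
#' @return the first grid distance at which `fraction >= level`, or `NA` if
#'   never reached.
#' @export
gx_crossing <- function(curve, level = 0.5) {
  i <- which(curve$fraction >= level)
  if (length(i) == 0) NA_real_ else curve$distance[min(i)]
}

#' Hypoxic intensity around a point
#'
#' Volume fraction of hypoxic tissue in spheres of increasing radius around a
#' microsphere: at each radius, the number of in-domain hypoxic voxel centres
#' within the radius over the number of in-domain voxel centres within it.
#' Radii with no in-domain voxel give `NA` (reported missing, not zero).
#'
#' @param mask logical hypoxia array on `grid`.
#' @param centre numeric length-3 point (um).
#' @param grid the [tissue_grid()].
#' @param radii sphere radii (um); the standard grid is 50 to 500 by 50.
#' @return data.frame of class `intensity_curve` with `radius` and `fraction`.
#' @export
hypoxic_intensity <- function(mask, centre, grid,
                              radii = seq(50, 500, by = 50)) {
  cen <- voxel_centres(grid)
  dom <- as.logical(grid$indomain)
  d2 <- (cen[, 1] - centre[1])^2 + (cen[, 2] - centre[2])^2 +
    (cen[, 3] - centre[3])^2
  hyp <- as.logical(mask) & dom
  frac <- vapply(radii, function(r) {
    inside <- d2 <= r^2 & dom
    n <- sum(inside)
    if (n == 0) NA_real_ else sum(hyp[inside]) / n
  }, numeric(1))
  curve <- data.frame(radius = radii, fraction = frac)
  class(curve) <- c("intensity_curve", "data.frame")
  attr(curve, "centre") <- centre
  curve
}

#' Classify a hypoxic-intensity curve
#'
#' Type A (local hypoxia pattern): the curve falls from 50 to 100 um, or the
#' first 100 um are fully hypoxic. Type B (distal pattern): the curve rises,
#' or the first 100 um contain no hypoxia. A flat curve with partial hypoxia
#' is classified B (the residual class). The subtype is `"local"` when any
#' hypoxic voxel lies within 100 um of the centre, else `"no-local"`.
#'
#' @param curve an `intensity_curve` with values at 50 and 100 um.
#' @return list with `type` (`"A"`/`"B"`) and `subtype`
#'   (`"local"`/`"no-local"`).
#' @export
classify_intensity <- function(curve) {
  v50 <- curve$fraction[curve$radius == 50]
  v100 <- curve$fraction[curve$radius == 100]
  if (length(v50) != 1 || length(v100) != 1 || is.na(v50) || is.na(v100))
    stop("curve must carry values at radii 50 and 100 um")
  type <- if (v50 == 1 && v100 == 1) "A"
  else if (v50 == 0 && v100 == 0) "B"
  else if (v100 < v50) "A"
  else "B"
  subtype <- if (v100 > 0) "local" else "no-local"
  list(type = type, subtype = subtype)
}

#' Aggregate the spatial statistics of one column's scenario batch
#'
#' Gx distances are pooled over scenarios before forming the CDF (each
#' scenario contributes its hypoxic voxels against its own bead); intensity
#' curves are averaged unweighted, consistent with equal blockage
#' probabilities. Types are counted per scenario.
#'
#' @param gx_curves list of `gx_curve` objects (with their distance
#'   attributes).
#' @param intensity_curves list of `intensity_curve` objects.
#' @param breaks distance grid for the pooled Gx.
#' @return list with `gx` (pooled `gx_curve`), `intensity` (mean curve) and
#'   `type_counts` (table over "A"/"B" and subtypes).
#' @export
aggregate_column <- function(gx_curves, intensity_curves,
                             breaks = seq(0, 1000, by = 10)) {
  stopifnot(length(gx_curves) >= 1, length(intensity_curves) >= 1)
  pooled <- unlist(lapply(gx_curves, attr, "distances"))
  if (length(pooled) == 0) {
    gx <- data.frame(distance = breaks, fraction = 0)
    attr(gx, "empty") <- TRUE
  } else {
    gx <- data.frame(distance = breaks,
                     fraction = vapply(breaks, function(b) mean(pooled < b),
                                       numeric(1)))
    attr(gx, "empty") <- FALSE
  }
  class(gx) <- c("gx_curve", "data.frame")
  attr(gx, "distances") <- pooled

  radii <- intensity_curves[[1]]$radius
  fr <- sapply(intensity_curves, function(cu) cu$fraction)
  fr <- matrix(fr, nrow = length(radii))
  mean_int <- data.frame(radius = radii,
                         fraction = rowMeans(fr, na.rm = TRUE))
  class(mean_int) <- c("intensity_curve", "data.frame")

  cls <- lapply(intensity_curves, classify_intensity)
  type_counts <- table(
    type = vapply(cls, `[[`, character(1), "type"),
    subtype = vapply(cls, `[[`, character(1), "subtype"))
  list(gx = gx, intensity = mean_int, type_counts = type_counts)
}

#' Monte-Carlo control point sets
#'
#' Random control points uniform over the in-domain voxels of a grid, with
#' the count set by a target density (as used to test whether measured
#' bead-hypoxia correlations exceed chance).
#'
#' @param grid a [tissue_grid()] whose `indomain` defines the sampling region.
#' @param density points per mm^3.
#' @param n_replicates number of independent replicates.
#' @param seed integer seed.
#' @return list of `n_replicates` matrices (n x 3, um).
#' @export
monte_carlo_controls <- function(grid, density, n_replicates = 1, seed = 1L) {
  if (density <= 0) stop("density must be positive")
  withr::local_seed(as.integer(seed))
  dom_idx <- which(as.logical(grid$indomain))
  vol_mm3 <- length(dom_idx) * prod(grid$spacing) / .UM3_PER_MM3
  n_pts <- round(density * vol_mm3)
  cen <- voxel_centres(grid)
  lapply(seq_len(n_replicates), function(r) {
    vox <- sample(dom_idx, n_pts, replace = TRUE)
    jit <- matrix(stats::runif(3 * n_pts, -0.5, 0.5), ncol = 3) *
      matrix(grid$spacing, n_pts, 3, byrow = TRUE)
    cen[vox, , drop = FALSE] + jit
  })
}

#' Write curves as tidy CSV
#'
#' @param curves named list of `gx_curve`/`intensity_curve` data.frames.
#' @param path output CSV; columns: the curve's own columns plus `id`.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(names(curves), function(nm) {
    df <- as.data.frame(curves[[nm]])
    df$id <- nm
    df
  }))
  data.table::fwrite(rows, path)
  invisible(path)
}
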
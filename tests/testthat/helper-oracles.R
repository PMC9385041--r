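# brute-force spatial-statistic oracles, shared across test files

brute_gx <- function(mask, points, grid, baseline = NULL,
                     breaks = seq(0, 1000, 10)) {
  sel <- mask & grid$indomain
  if (!is.null(baseline)) sel <- sel & !baseline
  cen <- voxel_centres(grid)[which(as.logical(sel)), , drop = FALSE]
  d <- apply(cen, 1, function(p)
    min(sqrt(colSums((t(points) - p)^2))))
  vapply(breaks, function(b) mean(d < b), numeric(1))
}

brute_intensity <- function(mask, centre, grid, radii) {
  cen <- voxel_centres(grid)
  d <- sqrt(colSums((t(cen) - centre)^2))
  dom <- as.logical(grid$indomain)
  hyp <- as.logical(mask) & dom
  vapply(radii, function(r) {
    inside <- d <= r & dom
    if (!any(inside)) NA_real_ else sum(hyp[inside]) / sum(inside)
  }, numeric(1))
}

random_mask_grid <- function(seed, dims = c(12, 12, 10), p = 0.15) {
  set.seed(seed)
  grid <- tissue_grid(dims, spacing = c(15.165, 15.165, 50))
  grid$indomain <- array(runif(prod(dims)) > 0.1, dims)
  mask <- array(runif(prod(dims)) < p, dims)
  list(grid = grid, mask = mask)
}

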
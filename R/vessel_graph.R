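#' Vascular network graph
#'
#' The central geometric/topological container of the package: a set of nodes
#' with 3D positions (um) and straight cylindrical segments joining them.
#' Segments carry a diameter, a length and a kind (`"arteriole"`,
#' `"capillary"` or `"connector"`). Periodic networks (capillary cubes) record
#' for each segment an integer wrap vector: a segment with wrap `(1, 0, 0)`
#' leaves the +x face and re-enters at the -x face, and its stored length is
#' the minimum-image length.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (um). Optional
#'   columns `is_boundary` (logical, pressure boundary for the flow solver)
#'   and `kind` are added with defaults if missing.
#' @param segments data.frame with columns `id`, `from`, `to`, `diameter`,
#'   `length` (um), `kind`. Optional columns `wrap_x`, `wrap_y`, `wrap_z`
#'   (integer wrap vector, periodic graphs only) and `occluded` (logical)
#'   default to zero / `FALSE`.
#' @param box numeric length-3 bounding box (um).
#' @param inlet node id of the arteriole inlet, or `NA` for networks without
#'   one (e.g. a bare capillary cube).
#' @param periodic logical; `TRUE` for capillary cubes that tile space.
#' @param origin lower corner of the bounding box (um); assembled columns and
#'   cubes use the default `c(0, 0, 0)`, an untrimmed arteriole tree may not.
#' @param meta list of provenance information (seed, generator spec).
#'
#' @return An object of class `vessel_graph`.
#' @seealso [generate_capillary_cube()], [generate_arteriole_tree()],
#'   [assemble_column()], [write_vessel_graph()]
#' @export
vessel_graph <- function(nodes, segments, box, inlet = NA_integer_,
                         periodic = FALSE, origin = c(0, 0, 0), meta = list()) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  if (is.null(nodes$is_boundary)) nodes$is_boundary <- FALSE
  if (is.null(nodes$kind)) nodes$kind <- "capillary"
  for (w in c("wrap_x", "wrap_y", "wrap_z")) {
    if (is.null(segments[[w]])) segments[[w]] <- 0L
  }
  if (is.null(segments$occluded)) segments$occluded <- FALSE
  g <- structure(
    list(nodes = nodes, segments = segments, box = as.numeric(box),
         inlet = inlet, periodic = isTRUE(periodic),
         origin = as.numeric(origin), meta = meta),
    class = "vessel_graph"
  )
  validate_vessel_graph(g)
  g
}

#' Validate a vessel_graph
#'
#' Checks referential integrity, positive diameters/lengths, segment lengths
#' at least the (minimum-image) Euclidean node distance, node positions inside
#' the bounding box, connectivity, and that any inlet node lies on the top
#' face (z = 0).
#'
#' @param g a `vessel_graph`.
#' @param tol relative geometric tolerance.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_vessel_graph <- function(g, tol = 1e-6) {
  nodes <- g$nodes; seg <- g$segments
  stopifnot(is.numeric(g$box), length(g$box) == 3L, all(g$box > 0))
  if (nrow(seg) > 0) {
    if (!all(seg$from %in% nodes$id) || !all(seg$to %in% nodes$id))
      stop("segment references a missing node id")
    if (any(seg$diameter <= 0)) stop("non-positive segment diameter")
    if (any(seg$length <= 0)) stop("non-positive segment length")
    d <- segment_chord_length(g)
    if (any(seg$length < d * (1 - tol) - 1e-9))
      stop("segment length below Euclidean node distance")
  }
  pad <- tol * max(g$box)
  o <- if (is.null(g$origin)) c(0, 0, 0) else g$origin
  inside <- nodes$x >= o[1] - pad & nodes$x <= o[1] + g$box[1] + pad &
    nodes$y >= o[2] - pad & nodes$y <= o[2] + g$box[2] + pad &
    nodes$z >= o[3] - pad & nodes$z <= o[3] + g$box[3] + pad
  if (!all(inside)) stop("node positions outside the bounding box")
  if (!is.na(g$inlet)) {
    if (!g$inlet %in% nodes$id) stop("inlet node id not present")
    zi <- nodes$z[match(g$inlet, nodes$id)]
    if (abs(zi) > pad) stop("inlet node must lie on the top face (z = 0)")
  }
  if (nrow(seg) > 0 && !graph_is_connected(g))
    stop("vessel graph is not connected")
  invisible(g)
}

# Euclidean chord length of each segment, honouring periodic wrap vectors:
# the effective 'to' endpoint is translated by wrap * box.
segment_chord_length <- function(g) {
  nodes <- g$nodes; seg <- g$segments
  ia <- match(seg$from, nodes$id); ib <- match(seg$to, nodes$id)
  dx <- nodes$x[ib] + seg$wrap_x * g$box[1] - nodes$x[ia]
  dy <- nodes$y[ib] + seg$wrap_y * g$box[2] - nodes$y[ia]
  dz <- nodes$z[ib] + seg$wrap_z * g$box[3] - nodes$z[ia]
  sqrt(dx^2 + dy^2 + dz^2)
}

graph_is_connected <- function(g) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(g$segments$from),
               to = as.character(g$segments$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(g$nodes$id))
  )
  igraph::is_connected(ig)
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d segments%s\n",
              nrow(x$nodes), nrow(x$segments),
              if (x$periodic) " (periodic)" else ""))
  cat(sprintf("  box: %g x %g x %g um\n", x$box[1], x$box[2], x$box[3]))
  if (!is.na(x$inlet)) cat(sprintf("  inlet node: %d\n", x$inlet))
  tab <- table(x$segments$kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a vessel graph as two CSV tables plus a JSON header
#'
#' `nodes.csv` (id, x, y, z, is_boundary, kind), `segments.csv` (id, from, to,
#' diameter, length, kind, wrap components, occluded) and `header.json`
#' (inlet, box, periodic flag, metadata). The round trip is lossless.
#'
#' @param g a `vessel_graph`.
#' @param dir directory to write into (created if needed).
#' @return `write_vessel_graph` returns `dir` invisibly; `read_vessel_graph`
#'   returns the reconstructed `vessel_graph`.
#' @export
write_vessel_graph <- function(g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(full_precision(g$nodes), file.path(dir, "nodes.csv"))
  data.table::fwrite(full_precision(g$segments), file.path(dir, "segments.csv"))
  hdr <- list(inlet = if (is.na(g$inlet)) NULL else g$inlet,
              box = g$box, periodic = g$periodic,
              origin = if (is.null(g$origin)) c(0, 0, 0) else g$origin,
              meta = g$meta, schema = "arteriox/vessel_graph/1")
  jsonlite::write_json(hdr, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_vessel_graph
#' @export
read_vessel_graph <- function(dir) {
  nodes <- as.data.frame(data.table::fread(file.path(dir, "nodes.csv")))
  segments <- as.data.frame(data.table::fread(file.path(dir, "segments.csv")))
  hdr <- jsonlite::read_json(file.path(dir, "header.json"), simplifyVector = TRUE)
  inlet <- suppressWarnings(as.integer(hdr$inlet))
  if (length(inlet) == 0) inlet <- NA_integer_
  vessel_graph(nodes, segments, box = unlist(hdr$box),
               inlet = if (is.na(inlet)) NA_integer_ else as.integer(inlet),
               periodic = isTRUE(hdr$periodic),
               origin = if (is.null(hdr$origin)) c(0, 0, 0) else unlist(hdr$origin),
               meta = if (is.null(hdr$meta)) list() else hdr$meta)
}

# doubles serialised with 17 significant digits round-trip exactly
full_precision <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
  }
  df
}
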
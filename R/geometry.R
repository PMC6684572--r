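#' Build the rectangular lateral-root cell grid
#'
#' Constructs the model tissue: a rectangular grid of `n_cols` x `n_rows`
#' quadrilateral cells made of vertices connected by linear wall springs.
#' Each grid box stands for a single cell, the basic space-discretisation
#' unit of the model. The tip of the organ is at minimum x, the base (the
#' junction with the main root) at maximum x; the right-most column of
#' vertices is fixed in the x-direction so that all growth is accommodated
#' away from the main root. Row 0 is the lowermost (gravity-side) flank;
#' gravity points along (0, -1).
#'
#' At construction every wall's resting length equals its current length, so
#' the spring lattice is at rest and the net spring force on every vertex is
#' zero (turgor pressure is not yet balanced; see
#' [relax_to_equilibrium()]).
#'
#' @param n_cols,n_rows number of cell columns (along the organ axis) and
#'   rows (across the flanks); both at least 2.
#' @param cell_width,cell_height cell dimensions in micrometres.
#' @param stiffness spring stiffness shared by all walls (the model constant
#'   `k_x`).
#' @return An object of class `lr_tissue`: a list with vertex positions
#'   (`pos`, an (n_cols+1)(n_rows+1) x 2 matrix in micrometres), velocities
#'   (`vel`), `fixed_x` flags, wall endpoint indices (`wall_from`,
#'   `wall_to`), resting lengths (`wall_rest`), orientations
#'   (`wall_orient`, "axial" or "transverse"), material row/column labels,
#'   per-cell wall and vertex index matrices in counter-clockwise order,
#'   cell `zone` labels and `elongating` flags, grid metadata and
#'   `sim_time`.
#' @examples
#' tis <- build_lr_grid(20, 6, 10, 10)
#' tis
#' @seealso [assign_zones()], [run_scenario()]
#' @export
build_lr_grid <- function(n_cols = 20L, n_rows = 6L, cell_width = 10,
                          cell_height = 10, stiffness = 0.9) {
  if (!is.numeric(n_cols) || !is.numeric(n_rows) ||
      n_cols < 2 || n_rows < 2 ||
      n_cols != round(n_cols) || n_rows != round(n_rows))
    stop("n_cols and n_rows must be integers >= 2")
  if (!is.numeric(cell_width) || !is.numeric(cell_height) ||
      cell_width <= 0 || cell_height <= 0)
    stop("cell_width and cell_height must be positive")
  if (!is.numeric(stiffness) || stiffness <= 0)
    stop("stiffness must be positive")
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)

  ncv <- n_cols + 1L   # vertex columns
  nrv <- n_rows + 1L   # vertex rows
  vid <- function(r, c) r * ncv + c + 1L  # r in 0..n_rows, c in 0..n_cols

  v_col <- rep(0:n_cols, times = nrv)
  v_row <- rep(0:n_rows, each = ncv)
  pos <- cbind(x = v_col * cell_width, y = v_row * cell_height)
  nv <- nrow(pos)

  # axial walls: along x, rows 0..n_rows, cols 0..n_cols-1
  ar <- rep(0:n_rows, each = n_cols)
  ac <- rep(0:(n_cols - 1L), times = nrv)
  a_from <- vid(ar, ac); a_to <- vid(ar, ac + 1L)
  n_axial <- length(a_from)
  # transverse walls: along y, rows 0..n_rows-1, cols 0..n_cols
  tr <- rep(0:(n_rows - 1L), each = ncv)
  tc <- rep(0:n_cols, times = n_rows)
  t_from <- vid(tr, tc); t_to <- vid(tr + 1L, tc)

  wall_from <- c(a_from, t_from)
  wall_to <- c(a_to, t_to)
  wall_orient <- rep(c("axial", "transverse"), c(n_axial, length(t_from)))
  wall_row <- c(ar, tr)
  wall_col <- c(ac, tc)
  wall_rest <- ifelse(wall_orient == "axial", cell_width, cell_height)

  a_id <- function(r, c) r * n_cols + c + 1L
  t_id <- function(r, c) n_axial + r * ncv + c + 1L

  cr <- rep(0:(n_rows - 1L), each = n_cols)
  cc <- rep(0:(n_cols - 1L), times = n_rows)
  # counter-clockwise: bottom axial, right transverse, top axial, left transverse
  cell_walls <- cbind(a_id(cr, cc), t_id(cr, cc + 1L),
                      a_id(cr + 1L, cc), t_id(cr, cc))
  cell_verts <- cbind(vid(cr, cc), vid(cr, cc + 1L),
                      vid(cr + 1L, cc + 1L), vid(cr + 1L, cc))

  structure(list(
    pos = pos,
    vel = matrix(0, nv, 2, dimnames = list(NULL, c("x", "y"))),
    fixed_x = v_col == n_cols,
    v_row = v_row, v_col = v_col,
    wall_from = wall_from, wall_to = wall_to,
    wall_rest = wall_rest, wall_orient = wall_orient,
    wall_row = wall_row, wall_col = wall_col,
    wall_stiff = rep(stiffness, length(wall_from)),
    cell_row = cr, cell_col = cc,
    cell_walls = cell_walls, cell_verts = cell_verts,
    zone = rep("elongation", length(cr)),
    elongating = rep(TRUE, length(cr)),
    n_cols = n_cols, n_rows = n_rows,
    cell_width = cell_width, cell_height = cell_height,
    gravity = c(0, -1),
    sim_time = 0
  ), class = "lr_tissue")
}

#' Assign tip and elongation zones along the organ axis
#'
#' Splits the tissue into a non-growing tip zone and an elongation zone
#' along the x-axis. A cell belongs to the tip zone when the distance of its
#' centre from the tip (minimum-x) end of the organ is less than
#' `tip_zone_length`; all other cells form the elongation zone and have
#' their `elongating` flag set (scenario modifiers may later clear
#' individual flags, see [scenario_field()]).
#'
#' @param tissue an `lr_tissue`.
#' @param tip_zone_length length of the tip zone in micrometres; must lie in
#'   `[0, n_cols * cell_width)`.
#' @return The tissue with updated `zone` and `elongating` fields.
#' @export
assign_zones <- function(tissue, tip_zone_length) {
  stopifnot(inherits(tissue, "lr_tissue"))
  organ_len <- tissue$n_cols * tissue$cell_width
  if (!is.numeric(tip_zone_length) || tip_zone_length < 0 ||
      tip_zone_length >= organ_len)
    stop("tip_zone_length must lie in [0, organ length)")
  centre_x <- (tissue$cell_col + 0.5) * tissue$cell_width
  tip <- centre_x < tip_zone_length
  tissue$zone <- ifelse(tip, "tip", "elongation")
  tissue$elongating <- !tip
  tissue
}

#' Polygon areas of all cells (shoelace formula)
#'
#' @param tissue an `lr_tissue`.
#' @return numeric vector of signed areas (positive for the counter-clockwise
#'   cell orientation used throughout) in square micrometres.
#' @export
cell_areas <- function(tissue) {
  v <- tissue$cell_verts
  x <- matrix(tissue$pos[v, 1], nrow(v), 4)
  y <- matrix(tissue$pos[v, 2], nrow(v), 4)
  xs <- x[, c(2, 3, 4, 1), drop = FALSE]
  ys <- y[, c(2, 3, 4, 1), drop = FALSE]
  0.5 * rowSums(x * ys - xs * y)
}

# current lengths of all walls
wall_lengths <- function(tissue) {
  d <- tissue$pos[tissue$wall_to, , drop = FALSE] -
    tissue$pos[tissue$wall_from, , drop = FALSE]
  sqrt(rowSums(d * d))
}

# per-cell axial length: mean of the cell's two axial wall current lengths
cell_axial_lengths <- function(tissue) {
  len <- wall_lengths(tissue)
  axial <- tissue$wall_orient[tissue$cell_walls[, 1]] == "axial"  # cols 1,3
  0.5 * (len[tissue$cell_walls[, 1]] + len[tissue$cell_walls[, 3]])
}

#' @export
print.lr_tissue <- function(x, ...) {
  cat(sprintf(
    "Lateral-root tissue: %d x %d cells (%g x %g um), %d vertices, %d walls\n",
    x$n_cols, x$n_rows, x$cell_width, x$cell_height,
    nrow(x$pos), length(x$wall_from)))
  cat(sprintf("  zones: %d tip, %d elongation (%d elongating); t = %.3f h\n",
              sum(x$zone == "tip"), sum(x$zone == "elongation"),
              sum(x$elongating), x$sim_time))
  invisible(x)
}

#' Serialize a tissue snapshot to JSON
#'
#' Writes vertex positions, wall endpoint pairs with resting lengths, and
#' cell wall-id lists with zone labels as schema-versioned JSON (units:
#' micrometres).
#'
#' @param tissue an `lr_tissue`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tissue_to_json <- function(tissue, path = NULL) {
  obj <- list(
    schema = "rootbend-tissue/1",
    units = "um",
    n_cols = tissue$n_cols, n_rows = tissue$n_rows,
    cell_width = tissue$cell_width, cell_height = tissue$cell_height,
    sim_time = tissue$sim_time,
    gravity = tissue$gravity,
    vertices = list(position = unname(tissue$pos),
                    fixed_x = tissue$fixed_x),
    walls = list(from = tissue$wall_from, to = tissue$wall_to,
                 resting_length = tissue$wall_rest,
                 orientation = tissue$wall_orient,
                 stiffness = tissue$wall_stiff,
                 row = tissue$wall_row, col = tissue$wall_col),
    cells = list(walls = unname(tissue$cell_walls),
                 vertices = unname(tissue$cell_verts),
                 row = tissue$cell_row, col = tissue$cell_col,
                 zone = tissue$zone, elongating = tissue$elongating)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a tissue from its JSON snapshot
#'
#' @param path file path or JSON string produced by [tissue_to_json()].
#' @return An `lr_tissue`.
#' @export
tissue_from_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  if (!identical(o$schema, "rootbend-tissue/1"))
    stop("unrecognised tissue JSON schema: ", o$schema)
  pos <- matrix(as.numeric(o$vertices$position), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  ncv <- o$n_cols + 1L
  structure(list(
    pos = pos,
    vel = matrix(0, nrow(pos), 2, dimnames = list(NULL, c("x", "y"))),
    fixed_x = as.logical(o$vertices$fixed_x),
    v_row = rep(0:o$n_rows, each = ncv),
    v_col = rep(0:o$n_cols, times = o$n_rows + 1L),
    wall_from = as.integer(o$walls$from), wall_to = as.integer(o$walls$to),
    wall_rest = as.numeric(o$walls$resting_length),
    wall_orient = as.character(o$walls$orientation),
    wall_row = as.integer(o$walls$row), wall_col = as.integer(o$walls$col),
    wall_stiff = as.numeric(o$walls$stiffness),
    cell_row = as.integer(o$cells$row), cell_col = as.integer(o$cells$col),
    cell_walls = matrix(as.integer(o$cells$walls), ncol = 4),
    cell_verts = matrix(as.integer(o$cells$vertices), ncol = 4),
    zone = as.character(o$cells$zone),
    elongating = as.logical(o$cells$elongating),
    n_cols = as.integer(o$n_cols), n_rows = as.integer(o$n_rows),
    cell_width = o$cell_width, cell_height = o$cell_height,
    gravity = as.numeric(o$gravity),
    sim_time = o$sim_time
  ), class = "lr_tissue")
}

#' Draw the cell mesh
#'
#' Base-graphics rendering of the tissue: cell polygons coloured by zone
#' (elongating cells darker), with the gravity direction indicated.
#'
#' @param x an `lr_tissue`.
#' @param col_tip,col_elong fill colours for tip-zone and elongation-zone
#'   cells.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lr_tissue <- function(x, col_tip = "grey85", col_elong = "palegreen3",
                           ...) {
  p <- x$pos
  graphics::plot(p, type = "n", asp = 1, xlab = "x (um)", ylab = "y (um)",
                 ...)
  for (i in seq_len(nrow(x$cell_verts))) {
    v <- x$cell_verts[i, ]
    fill <- if (x$zone[i] == "tip") col_tip else col_elong
    if (x$zone[i] != "tip" && !x$elongating[i]) fill <- "palegreen1"
    graphics::polygon(p[v, 1], p[v, 2], col = fill, border = "grey30")
  }
  invisible(x)
}
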
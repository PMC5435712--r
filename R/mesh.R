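#' Triangulated vessel surface mesh
#'
#' Construct a `surface_mesh` from vertex coordinates and triangle
#' connectivity. Per-node lumped areas are computed by barycentric lumping:
#' each triangle contributes one third of its area to each of its three
#' nodes, so node areas are strictly positive for every referenced node and
#' sum exactly to the total triangle area. Zero-area (degenerate) triangles
#' are dropped with a warning before lumping.
#'
#' Geometry is stored in millimetres; lumped areas are in mm^2.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param triangles integer matrix, one row per triangle, three 1-based
#'   vertex indices per row.
#' @param wall_mask optional logical vector (length = number of vertices):
#'   `TRUE` for nodes on the vessel wall proper. Inlet/outlet cap nodes can
#'   be excluded here; when `NULL` every node is treated as wall.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `triangles`, `node_areas`, `wall_mask`.
#' @export
surface_mesh <- function(vertices, triangles, wall_mask = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("`vertices` must have three columns (x, y, z)")
  if (any(!is.finite(vertices))) stop("`vertices` contains non-finite coordinates")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L) stop("`triangles` must have three columns")
  if (nrow(triangles) == 0L) stop("empty mesh: no triangles")
  n <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > n)) {
    stop("triangle indices out of range 1..", n)
  }

  areas <- triangle_areas(vertices, triangles)
  degen <- areas <= .Machine$double.eps * 100
  if (any(degen)) {
    warning(sum(degen), " degenerate (zero-area) triangle(s) dropped")
    triangles <- triangles[!degen, , drop = FALSE]
    areas <- areas[!degen]
    if (nrow(triangles) == 0L) stop("empty mesh: all triangles degenerate")
  }

  node_areas <- numeric(n)
  for (k in 1:3) {
    s <- rowsum(areas / 3, group = triangles[, k])
    idx <- as.integer(rownames(s))
    node_areas[idx] <- node_areas[idx] + s[, 1]
  }

  if (is.null(wall_mask)) {
    wall_mask <- rep(TRUE, n)
  } else {
    wall_mask <- as.logical(wall_mask)
    if (length(wall_mask) != n) stop("`wall_mask` length must match vertex count")
  }

  structure(
    list(vertices = vertices, triangles = triangles,
         node_areas = node_areas, wall_mask = wall_mask),
    class = "surface_mesh"
  )
}

# areas of all triangles via cross product, mm^2
triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "nodes,", nrow(x$triangles),
      "triangles, total area", format(sum(x$node_areas)), "mm^2,",
      sum(x$wall_mask), "wall nodes\n")
  invisible(x)
}

#' Named node region on a surface mesh
#'
#' A region mask is a named, deduplicated subset of the wall nodes of a
#' [surface_mesh()] (for example `inner_arch`, `outer_arch`, `whole_wall`).
#' Masks with different names may overlap.
#'
#' @param name character label for the region.
#' @param node_ids integer vector of 1-based node indices; deduplicated.
#' @param mesh the [surface_mesh()] the mask belongs to.
#' @return An object of class `region_mask` with elements `name`, `node_ids`.
#' @export
region_mask <- function(name, node_ids, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is.character(name) || length(name) != 1L) stop("`name` must be a single string")
  node_ids <- sort(unique(as.integer(node_ids)))
  if (length(node_ids) == 0L) stop("region mask '", name, "' is empty")
  if (any(node_ids < 1L) || any(node_ids > nrow(mesh$vertices))) {
    stop("mask '", name, "' has node ids outside the mesh")
  }
  if (!all(mesh$wall_mask[node_ids])) {
    stop("mask '", name, "' includes non-wall (cap) nodes")
  }
  structure(list(name = name, node_ids = node_ids), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("region_mask '", x$name, "': ", length(x$node_ids), " nodes\n", sep = "")
  invisible(x)
}

#' Area of a mesh region
#'
#' Sums the barycentric lumped node areas over the nodes of a region mask.
#' With masks that partition the wall nodes, region areas add up exactly to
#' the total wall area.
#'
#' @param mesh a [surface_mesh()].
#' @param mask a [region_mask()] on `mesh`.
#' @return Region area in mm^2.
#' @export
region_area <- function(mesh, mask) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(mask, "region_mask"))
  if (length(mask$node_ids) == 0L) stop("empty mask")
  if (any(mask$node_ids > nrow(mesh$vertices))) stop("mask does not fit this mesh")
  sum(mesh$node_areas[mask$node_ids])
}

#' Whole-wall region of a mesh
#'
#' Convenience constructor for the mask containing every wall node.
#'
#' @param mesh a [surface_mesh()].
#' @return A [region_mask()] named `"whole_wall"`.
#' @export
whole_wall_mask <- function(mesh) {
  region_mask("whole_wall", which(mesh$wall_mask), mesh)
}
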
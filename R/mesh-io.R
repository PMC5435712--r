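#' Load a triangulated surface mesh from file
#'
#' Reads an STL file (ASCII or binary, auto-detected) or a legacy-VTK
#' POLYDATA file and returns a [surface_mesh()]. STL stores one vertex
#' triple per facet, so coincident vertices are merged (coordinates rounded
#' to 1e-6 mm for the merge key) to recover shared connectivity before node
#' areas are lumped.
#'
#' @param path file path.
#' @param format `"stl"` or `"vtk"`; defaults to the file extension.
#' @return A [surface_mesh()] with `wall_mask` set to all nodes (cap labels
#'   are not representable in plain STL/VTK polydata).
#' @export
load_mesh <- function(path, format = c("auto", "stl", "vtk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", vtk = "vtk", vtp = "vtk",
                     stop("cannot infer mesh format from extension '", ext, "'"))
  }
  raw <- switch(format, stl = read_stl_raw(path), vtk = read_vtk_polydata(path))
  if (nrow(raw$triangles) == 0L) stop("empty mesh: no triangles in ", path)
  surface_mesh(raw$vertices, raw$triangles)
}

# STL facet soup -> merged vertices + connectivity
read_stl_raw <- function(path) {
  if (stl_is_ascii(path)) {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
      stop("malformed ASCII STL: ", path)
    }
    coords <- t(vapply(strsplit(trimws(vlines), "\\s+"), function(f) {
      as.numeric(f[2:4])
    }, numeric(3)))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(ntri) || is.na(ntri) || ntri <= 0L) stop("malformed binary STL: ", path)
    rec <- readBin(con, "raw", ntri * 50L)
    if (length(rec) < ntri * 50L) stop("truncated binary STL: ", path)
    rec <- matrix(rec, nrow = 50L)
    floats <- readBin(as.vector(rec[1:48, ]), "double", n = 12L * ntri,
                      size = 4L, endian = "little")
    floats <- matrix(floats, ncol = 12L, byrow = TRUE)  # normal + 3 vertices
    coords <- rbind(floats[, 4:6, drop = FALSE],
                    floats[, 7:9, drop = FALSE],
                    floats[, 10:12, drop = FALSE])
    # interleave back to facet order v1,v2,v3 per triangle
    ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
    coords <- coords[ord, , drop = FALSE]
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates in STL: ", path)
  key <- paste(round(coords[, 1] * 1e6), round(coords[, 2] * 1e6),
               round(coords[, 3] * 1e6))
  first <- !duplicated(key)
  vertices <- coords[first, , drop = FALSE]
  idx <- match(key, key[first])
  triangles <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = vertices, triangles = triangles)
}

stl_is_ascii <- function(path) {
  head <- readBin(path, "raw", 512L)
  if (!length(head)) stop("empty file: ", path)
  txt <- rawToChar(head[head != as.raw(0)])
  if (!validUTF8(txt)) return(FALSE)    # binary payload
  startsWith(trimws(tolower(txt)), "solid") && grepl("facet", tolower(txt))
}

#' Write a surface mesh as ASCII STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  nx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  ny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  nrm[nrm == 0] <- 1
  fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
  lines <- c(
    "solid wssmetrics",
    as.vector(rbind(
      sprintf("  facet normal %s", sprintf("%.9g %.9g %.9g", nx / nrm, ny / nrm, nz / nrm)),
      "    outer loop",
      sprintf("      vertex %s", fmt(a)),
      sprintf("      vertex %s", fmt(b)),
      sprintf("      vertex %s", fmt(c_)),
      "    endloop",
      "  endfacet")),
    "endsolid wssmetrics")
  writeLines(lines, path)
  invisible(path)
}

#' Write a surface mesh (with optional point data) as legacy VTK polydata
#'
#' Produces an ASCII legacy `.vtk` POLYDATA file; scalar point-data arrays
#' (for example TAWSS/OSI/RRT metric values) are attached as named SCALARS.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param point_data named list of numeric vectors (one value per node).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0",
               "wssmetrics surface",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      vals <- as.numeric(point_data[[nm]])
      if (length(vals) != n) stop("point_data '", nm, "' length != node count")
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", vals), con)
    }
  }
  invisible(path)
}

# minimal legacy-VTK POLYDATA reader (POINTS + POLYGONS, ASCII)
read_vtk_polydata <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)
  if (!length(ip)) stop("no POINTS section in VTK file: ", path)
  n <- as.integer(strsplit(trimws(txt[ip[1]]), "\\s+")[[1]][2])
  nums <- scan(text = paste(txt[(ip[1] + 1):length(txt)], collapse = "\n"),
               what = numeric(), n = 3L * n, quiet = TRUE)
  vertices <- matrix(nums, ncol = 3L, byrow = TRUE)
  ig <- grep("^POLYGONS", txt)
  if (!length(ig)) stop("no POLYGONS section in VTK file: ", path)
  hdr <- as.integer(strsplit(trimws(txt[ig[1]]), "\\s+")[[1]][2:3])
  conn <- scan(text = paste(txt[(ig[1] + 1):length(txt)], collapse = "\n"),
               what = integer(), n = hdr[2], quiet = TRUE)
  tris <- list(); i <- 1L
  while (i <= length(conn)) {
    k <- conn[i]
    if (k != 3L) stop("non-triangle polygon (", k, " vertices) in ", path)
    tris[[length(tris) + 1L]] <- conn[(i + 1L):(i + 3L)] + 1L
    i <- i + k + 1L
  }
  list(vertices = vertices, triangles = do.call(rbind, tris))
}

#' Read or write region masks
#'
#' Masks are serialized either as a one-column CSV (`node_id`, 1-based) or
#' as JSON (`{"name": ..., "node_ids": [...]}`).
#'
#' @param mask a [region_mask()].
#' @param path file path ending in `.csv` or `.json`.
#' @param mesh mesh the mask belongs to (needed to validate on read).
#' @param name region name used when reading from CSV (which stores none).
#' @return `write_mask` returns `path` invisibly; `read_mask` a [region_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(data.frame(node_id = mask$node_ids), path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(name = mask$name, node_ids = mask$node_ids),
                         path, auto_unbox = TRUE)
  } else stop("mask path must end in .csv or .json")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, mesh, name = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path)
    if (!"node_id" %in% names(df)) stop("mask CSV needs a node_id column")
    region_mask(name %||% tools::file_path_sans_ext(basename(path)),
                df$node_id, mesh)
  } else if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    region_mask(name %||% obj$name, obj$node_ids, mesh)
  } else stop("mask path must end in .csv or .json")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
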
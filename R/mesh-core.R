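#' Triangle surface of a vessel bifurcation
#'
#' A `vessel_surface` is a triangle mesh in millimetres: an `n x 3` matrix
#' of vertex coordinates and an `m x 3` integer matrix of 1-based face
#' indices with consistent (outward) orientation. A valid vessel surface is
#' manifold and open only at the vessel ends, i.e. its boundary edges form
#' exactly three closed loops (MPA inlet, RPA outlet, LPA outlet). Openings
#' may carry branch labels.
#'
#' @param vertices numeric matrix, n x 3, mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param opening_labels optional character vector naming the boundary
#'   loops, e.g. `c("MPA", "RPA", "LPA")`, matched to loops by the order
#'   returned by [boundary_loops()].
#' @return object of class `vessel_surface`.
#' @export
vessel_surface <- function(vertices, faces, opening_labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) < 4) stop("vessel_surface: too few faces")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("vessel_surface: face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 opening_labels = opening_labels),
            class = "vessel_surface")
}

#' @export
print.vessel_surface <- function(x, ...) {
  bl <- boundary_loops(x)
  cat(sprintf("<vessel_surface: %d vertices, %d faces, %d opening(s)>\n",
              nrow(x$vertices), nrow(x$faces), length(bl)))
  invisible(x)
}

# undirected edge keys of all faces; each row of faces yields 3 edges
.edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Boundary loops of a surface
#'
#' Edges used by exactly one face are boundary edges; they are chained into
#' closed loops. A watertight mesh has none; a valid vessel surface has
#' exactly three. Loops are ordered by decreasing enclosed vertex count and
#' returned as vertex index cycles.
#'
#' @param surface a [vessel_surface()].
#' @return list of integer vectors (vertex indices, closed implicitly).
#' @export
boundary_loops <- function(surface) {
  ek <- .edge_keys(surface$faces)
  key <- paste(ek[, 1], ek[, 2])
  tab <- table(key)
  if (any(tab > 2)) stop("non-manifold surface: edge shared by >2 faces")
  bkey <- names(tab)[tab == 1]
  if (length(bkey) == 0) return(list())
  be <- do.call(rbind, strsplit(bkey, " "))
  be <- matrix(as.integer(be), ncol = 2)
  # adjacency: each boundary vertex appears in exactly 2 boundary edges
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  if (any(lengths(adj) != 2))
    stop("boundary is not a disjoint union of simple loops")
  loops <- list()
  unvisited <- new.env(parent = emptyenv())
  for (v in names(adj)) assign(v, TRUE, envir = unvisited)
  for (start in as.integer(names(adj))) {
    if (!isTRUE(mget(as.character(start), envir = unvisited,
                     ifnotfound = FALSE)[[1]])) next
    loop <- integer(0)
    prev <- NA_integer_
    cur <- start
    repeat {
      loop <- c(loop, cur)
      assign(as.character(cur), FALSE, envir = unvisited)
      nb <- adj[[as.character(cur)]]
      nxt <- if (is.na(prev)) nb[1] else nb[nb != prev][1]
      prev <- cur
      cur <- nxt
      if (cur == start) break
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops[order(-lengths(loops))]
}

#' Validate a vessel surface
#'
#' Checks manifoldness (every edge in at most two faces), consistent face
#' orientation (every interior edge traversed once in each direction) and
#' the expected number of openings.
#'
#' @param surface a [vessel_surface()].
#' @param n_openings required number of boundary loops (default 3).
#' @return invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_surface <- function(surface, n_openings = 3) {
  f <- surface$faces
  dir_e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  dkey <- paste(dir_e[, 1], dir_e[, 2])
  if (anyDuplicated(dkey))
    stop("inconsistently oriented faces: directed edge repeated")
  bl <- boundary_loops(surface)  # also checks manifoldness
  if (length(bl) != n_openings)
    stop(sprintf("surface has %d opening(s), expected %d",
                 length(bl), n_openings))
  invisible(TRUE)
}

#' Rigid motions and scaling of a surface
#'
#' @param surface a [vessel_surface()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric.
#' @param scale positive scalar.
#' @return transformed [vessel_surface()].
#' @export
transform_surface <- function(surface, rotation = diag(3),
                              translation = c(0, 0, 0), scale = 1) {
  stopifnot(scale > 0)
  v <- scale * surface$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  vessel_surface(v, surface$faces, surface$opening_labels)
}

#' Signed volume enclosed by a watertight surface
#'
#' Divergence-theorem volume: sum of signed tetrahedron volumes spanned by
#' the origin and each face. Positive for outward-oriented surfaces.
#'
#' @param surface a [vessel_surface()] with no boundary edges.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(surface) {
  if (length(boundary_loops(surface)) != 0)
    stop("mesh_volume: surface is not watertight")
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Write / read a triangle mesh
#'
#' ASCII STL, PLY and OBJ. STL stores no connectivity, so vertices are
#' re-welded on read by exact coordinate match; PLY and OBJ round-trip the
#' index structure.
#'
#' @param surface a [vessel_surface()].
#' @param path file path; format from extension `.stl`, `.ply`, `.obj`.
#' @return `write_mesh`: invisibly `path`; `read_mesh`: a [vessel_surface()].
#' @export
write_mesh <- function(surface, path) {
  ext <- tolower(tools::file_ext(path))
  v <- surface$vertices
  f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "stl") {
    a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    n <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
    nn <- sqrt(rowSums(n^2)); nn[nn == 0] <- 1
    n <- n / nn
    writeLines("solid pabifurc", con)
    tx <- sprintf(
      "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
      n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3],
      b[, 1], b[, 2], b[, 3], cc[, 1], cc[, 2], cc[, 3])
    writeLines(tx, con)
    writeLines("endsolid pabifurc", con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else stop("write_mesh: unsupported extension '", ext, "'")
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    ln <- readLines(path)
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", ln, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", ln, value = TRUE)))
    i0 <- which(ln == "end_header")
    v <- matrix(scan(text = ln[(i0 + 1):(i0 + nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
    fr <- matrix(scan(text = ln[(i0 + nv + 1):(i0 + nv + nf)], quiet = TRUE),
                 ncol = 4, byrow = TRUE)
    return(vessel_surface(v, fr[, 2:4] + 1L))
  }
  if (ext == "obj") {
    ln <- readLines(path)
    v <- matrix(scan(text = sub("^v ", "", grep("^v ", ln, value = TRUE)),
                     quiet = TRUE), ncol = 3, byrow = TRUE)
    f <- matrix(scan(text = sub("^f ", "", grep("^f ", ln, value = TRUE)),
                     quiet = TRUE), ncol = 3, byrow = TRUE)
    return(vessel_surface(v, f))
  }
  if (ext == "stl") {
    ln <- readLines(path)
    vx <- grep("^\\s*vertex", ln, value = TRUE)
    co <- matrix(scan(text = sub("^\\s*vertex", "", vx), quiet = TRUE),
                 ncol = 3, byrow = TRUE)
    key <- paste(co[, 1], co[, 2], co[, 3])
    uid <- match(key, unique(key))
    v <- co[!duplicated(key), , drop = FALSE]
    f <- matrix(uid, ncol = 3, byrow = TRUE)
    return(vessel_surface(v, f))
  }
  stop("read_mesh: unsupported extension '", ext, "'")
}
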
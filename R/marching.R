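# Iso-surface extraction by marching tetrahedra on a Freudenthal-decomposed
# regular grid. The six-tetrahedra decomposition around the (0,0,0)-(1,1,1)
# cube diagonal tiles space consistently, so the extracted zero level set is
# a watertight manifold triangle mesh (provided no sample is exactly zero;
# zeros are nudged). Face orientation is determined combinatorially from the
# orientation sign of each tetrahedron and the parity of the inside-vertex
# selection, giving globally consistent outward winding.

# tetrahedra as cube-corner ids, corner id = dx + 2*dy + 4*dz, and the sign
# of det(v1-v0, v2-v0, v3-v0) for each (grid axes right-handed)
.tet_table <- rbind(
  c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
  c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))
.tet_sign <- c(+1, -1, -1, +1, +1, -1)

# parity of the arrangement (a, rest ascending) for a single selected
# position, and of (a, b, rest ascending) for a selected pair a < b
.parity1 <- c(+1, -1, +1, -1)
.parity2 <- matrix(0, 4, 4)
.parity2[1, 2] <- +1; .parity2[1, 3] <- -1; .parity2[1, 4] <- +1
.parity2[2, 3] <- +1; .parity2[2, 4] <- -1; .parity2[3, 4] <- +1

#' Extract the zero level set of a sampled scalar field
#'
#' @param values numeric array `length(x) x length(y) x length(z)` of field
#'   samples (negative inside).
#' @param x,y,z strictly increasing grid coordinate vectors (mm).
#' @return list with `vertices` (n x 3 matrix, mm) and `faces` (m x 3,
#'   outward-oriented).
#' @keywords internal
march_tetrahedra <- function(values, x, y, z) {
  nx <- length(x); ny <- length(y); nz <- length(z)
  stopifnot(all(dim(values) == c(nx, ny, nz)))
  v <- as.vector(values)
  v[v == 0] <- 1e-12
  inside <- v < 0

  # linear offsets of the 8 cube corners (id = dx + 2 dy + 4 dz)
  off <- c(0L, 1L, nx, nx + 1L, nx * ny, nx * ny + 1L,
           nx * ny + nx, nx * ny + nx + 1L)

  # base linear index of each cube = its (i, j, k) corner
  i <- rep.int(seq_len(nx - 1L), (ny - 1L) * (nz - 1L))
  jk <- rep(seq_len((ny - 1L) * (nz - 1L)), each = nx - 1L)
  j <- (jk - 1L) %% (ny - 1L) + 1L
  k <- (jk - 1L) %/% (ny - 1L) + 1L
  base <- i + (j - 1L) * nx + (k - 1L) * nx * ny

  cnt <- integer(length(base))
  for (o in off) cnt <- cnt + inside[base + o]
  base <- base[cnt > 0L & cnt < 8L]
  if (length(base) == 0) stop("level set does not intersect the grid")

  ea <- vector("list", 64); eb <- vector("list", 64); nseg <- 0L
  emit_tri <- function(p1a, p1b, p2a, p2b, p3a, p3b, fwd) {
    # triangle corners as grid-edge (a, b) pairs; `fwd` FALSE swaps 2 and 3
    if (any(!fwd)) {
      t2a <- p2a; t2b <- p2b
      p2a[!fwd] <- p3a[!fwd]; p2b[!fwd] <- p3b[!fwd]
      p3a[!fwd] <- t2a[!fwd]; p3b[!fwd] <- t2b[!fwd]
    }
    nseg <<- nseg + 1L
    ea[[nseg]] <<- c(rbind(p1a, p2a, p3a))
    eb[[nseg]] <<- c(rbind(p1b, p2b, p3b))
  }

  for (tt in seq_len(nrow(.tet_table))) {
    corn <- .tet_table[tt, ]
    g <- cbind(base + off[corn[1] + 1L], base + off[corn[2] + 1L],
               base + off[corn[3] + 1L], base + off[corn[4] + 1L])
    ins <- matrix(inside[g], ncol = 4)
    ncut <- rowSums(ins)
    # single separated corner: one triangle on edges (a,b) (a,c) (a,d)
    for (a in 1:4) {
      sel <- which((ncut == 1L & ins[, a]) | (ncut == 3L & !ins[, a]))
      if (!length(sel)) next
      o <- setdiff(1:4, a)
      caseflip <- ifelse(ins[sel, a], 1, -1)   # 3-inside case flips
      fwd <- (.tet_sign[tt] * .parity1[a] * caseflip) > 0
      emit_tri(g[sel, a], g[sel, o[1]], g[sel, a], g[sel, o[2]],
               g[sel, a], g[sel, o[3]], fwd)
    }
    # two-two split: quad on edges (a,c) (a,d) (b,d) (b,c)
    for (a in 1:3) for (b in (a + 1):4) {
      sel <- which(ncut == 2L & ins[, a] & ins[, b])
      if (!length(sel)) next
      cd <- setdiff(1:4, c(a, b))
      fwd <- rep((.tet_sign[tt] * .parity2[a, b]) > 0, length(sel))
      ga <- g[sel, a]; gb <- g[sel, b]
      gc <- g[sel, cd[1]]; gd <- g[sel, cd[2]]
      emit_tri(ga, gc, ga, gd, gb, gd, fwd)
      emit_tri(ga, gc, gb, gd, gb, gc, fwd)
    }
  }

  edge_a <- unlist(ea); edge_b <- unlist(eb)
  # weld: one mesh vertex per crossed grid edge
  np <- as.numeric(nx) * ny * nz
  key <- pmin(edge_a, edge_b) * np + pmax(edge_a, edge_b)
  uk <- unique(key)
  vid <- match(key, uk)
  first <- match(uk, key)
  ga <- edge_a[first]; gb <- edge_b[first]
  dec <- function(g) {
    g0 <- g - 1L
    cbind(x[g0 %% nx + 1L],
          y[(g0 %/% nx) %% ny + 1L],
          z[g0 %/% (nx * ny) + 1L])
  }
  pa <- dec(ga); pb <- dec(gb)
  va <- v[ga]; vb <- v[gb]
  t <- va / (va - vb)
  verts <- pa + t * (pb - pa)
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  list(vertices = verts, faces = faces[ok, , drop = FALSE])
}
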
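#' Plane cross-section of a vessel surface
#'
#' Intersects the surface with the plane through `origin` with unit
#' `normal`, chains the crossing segments into closed loops, and returns
#' the loop that contains the in-plane projection of `origin`, as a
#' `section_polygon`: an ordered counter-clockwise vertex loop in plane
#' coordinates.
#'
#' If the plane cuts the vessel in more than one loop (e.g. distal of the
#' carina) a condition of class `pabifurc_multiloop` is signalled -- the
#' plane-placement search relies on it -- unless `all_loops = TRUE`, in
#' which case every loop is returned. Loops whose closest vertex is farther
#' than `max_loop_dist` from the origin are ignored (an infinite plane can
#' graze unrelated parts of the vessel).
#'
#' @param surface a [vessel_surface()].
#' @param origin point on the plane, mm.
#' @param normal plane normal (normalized internally).
#' @param all_loops return all loops instead of signalling.
#' @param max_loop_dist ignore loops entirely farther than this from
#'   `origin` (mm, default `Inf`).
#' @return a `section_polygon` (list with `origin`, `normal`, `u`, `v`,
#'   `xy`), or a list of them when `all_loops = TRUE`.
#' @export
cross_section <- function(surface, origin, normal, all_loops = FALSE,
                          max_loop_dist = Inf) {
  B <- .plane_basis(normal)
  v <- surface$vertices
  d <- (v[, 1] - origin[1]) * B$n[1] + (v[, 2] - origin[2]) * B$n[2] +
       (v[, 3] - origin[3]) * B$n[3]
  d[d == 0] <- 1e-12
  f <- surface$faces
  s1 <- d[f[, 1]] > 0; s2 <- d[f[, 2]] > 0; s3 <- d[f[, 3]] > 0
  crossing <- which((s1 | s2 | s3) & !(s1 & s2 & s3))
  if (length(crossing) == 0)
    stop("cross_section: plane does not intersect the surface")

  # for each crossing triangle, the two crossed edges; an edge key
  # identifies the intersection point, so segments chain by shared keys
  fc <- f[crossing, , drop = FALSE]
  dc <- cbind(d[fc[, 1]], d[fc[, 2]], d[fc[, 3]])
  seg_a <- integer(0); seg_b <- integer(0)   # edge ids per segment end
  ed_v1 <- integer(0); ed_v2 <- integer(0)   # edge vertex pairs (unique)
  ekey <- character(0)
  edge_pts <- list()
  pair <- list(c(1, 2), c(2, 3), c(3, 1))
  cross_edges <- matrix(NA_integer_, nrow(fc), 2)
  got <- integer(nrow(fc))
  all_e1 <- integer(0); all_e2 <- integer(0); all_fi <- integer(0)
  for (pp in pair) {
    cr <- which((dc[, pp[1]] > 0) != (dc[, pp[2]] > 0))
    all_e1 <- c(all_e1, fc[cr, pp[1]]); all_e2 <- c(all_e2, fc[cr, pp[2]])
    all_fi <- c(all_fi, cr)
  }
  key <- paste(pmin(all_e1, all_e2), pmax(all_e1, all_e2))
  uk <- unique(key)
  eid <- match(key, uk)
  # intersection point of each unique crossed edge
  first <- match(uk, key)
  p1 <- v[all_e1[first], , drop = FALSE]; p2 <- v[all_e2[first], , drop = FALSE]
  d1 <- d[all_e1[first]]; d2 <- d[all_e2[first]]
  t <- d1 / (d1 - d2)
  pts <- p1 + t * (p2 - p1)
  # per-face segment: the two edge ids
  segs <- matrix(NA_integer_, nrow(fc), 2)
  cnt <- integer(nrow(fc))
  for (ii in seq_along(all_fi)) {
    fi <- all_fi[ii]
    cnt[fi] <- cnt[fi] + 1L
    segs[fi, cnt[fi]] <- eid[ii]
  }
  if (any(cnt != 2L)) stop("cross_section: degenerate plane intersection")

  # chain segments into loops; chains that dead-end cross a mesh opening
  # (the plane cuts through a vessel end) and are discarded
  adj <- split(c(segs[, 2], segs[, 1]), c(segs[, 1], segs[, 2]))
  loops <- list()
  seen <- logical(nrow(pts))
  for (start in seq_len(nrow(pts))) {
    if (seen[start] || is.null(adj[[as.character(start)]])) next
    loop <- integer(0)
    prev <- NA_integer_; cur <- start
    closed <- TRUE
    repeat {
      loop <- c(loop, cur); seen[cur] <- TRUE
      nb <- adj[[as.character(cur)]]
      nxt <- if (is.na(prev)) nb[1] else {
        cand <- nb[nb != prev]
        if (length(cand)) cand[1] else NA_integer_
      }
      if (is.na(nxt) || length(nb) < 2) { closed <- FALSE; break }
      prev <- cur; cur <- nxt
      if (cur == start) break
    }
    if (closed && length(loop) >= 3) loops[[length(loops) + 1]] <- loop
    else seen[loop] <- TRUE
  }
  if (length(loops) == 0)
    stop("cross_section: no closed intersection loop ",
         "(plane may cross a vessel opening)")

  mk_poly <- function(idx) {
    P <- pts[idx, , drop = FALSE]
    xy <- cbind((P[, 1] - origin[1]) * B$u[1] + (P[, 2] - origin[2]) * B$u[2] +
                  (P[, 3] - origin[3]) * B$u[3],
                (P[, 1] - origin[1]) * B$v[1] + (P[, 2] - origin[2]) * B$v[2] +
                  (P[, 3] - origin[3]) * B$v[3])
    # enforce counter-clockwise orientation
    x <- xy[, 1]; y <- xy[, 2]
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    if (sum(x * y2 - x2 * y) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
    structure(list(origin = origin, normal = B$n, u = B$u, v = B$v, xy = xy),
              class = "section_polygon")
  }
  polys <- lapply(loops, mk_poly)
  near <- vapply(polys, function(p) min(sqrt(rowSums(p$xy^2))), 0)
  polys <- polys[near <= max_loop_dist]
  if (length(polys) == 0)
    stop("cross_section: no intersection loop within max_loop_dist")
  if (all_loops) return(polys)
  if (length(polys) > 1)
    stop(errorCondition(
      sprintf("cross_section: plane cuts %d lumen loops (crosses the carina?)",
              length(polys)),
      class = c("pabifurc_multiloop", "error", "condition")))
  polys[[1]]
}

#' @export
print.section_polygon <- function(x, ...) {
  cat(sprintf("<section_polygon: %d vertices, area %.2f mm^2>\n",
              nrow(x$xy), .poly_area(x$xy)))
  invisible(x)
}

# simplicity check: no two non-adjacent edges intersect (O(n^2) sweep-free)
.is_simple_loop <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  p <- xy; q <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (!length(js)) next
    d1 <- cross2(q[i, 1] - p[i, 1], q[i, 2] - p[i, 2],
                 p[js, 1] - p[i, 1], p[js, 2] - p[i, 2])
    d2 <- cross2(q[i, 1] - p[i, 1], q[i, 2] - p[i, 2],
                 q[js, 1] - p[i, 1], q[js, 2] - p[i, 2])
    d3 <- cross2(q[js, 1] - p[js, 1], q[js, 2] - p[js, 2],
                 p[i, 1] - p[js, 1], p[i, 2] - p[js, 2])
    d4 <- cross2(q[js, 1] - p[js, 1], q[js, 2] - p[js, 2],
                 q[i, 1] - p[js, 1], q[i, 2] - p[js, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

.as_loop_xy <- function(polygon) {
  if (inherits(polygon, "section_polygon")) polygon$xy
  else as.matrix(polygon)
}

#' Cross-sectional area of a section polygon
#'
#' Planar shoelace area of the ordered loop, orientation-insensitive.
#' Reported in the scaled clinical unit (100 mm^2) by default.
#'
#' @param polygon a `section_polygon` or an n x 2 coordinate matrix (mm).
#' @param scale report in 100 mm^2 (default) rather than mm^2.
#' @param check_simple reject self-intersecting loops (default `TRUE`).
#' @return area.
#' @export
csa <- function(polygon, scale = TRUE, check_simple = TRUE) {
  xy <- .as_loop_xy(polygon)
  if (nrow(xy) < 3) stop("csa: polygon needs at least 3 vertices")
  if (check_simple && !.is_simple_loop(xy))
    stop("csa: self-intersecting loop")
  a <- .poly_area(xy)
  if (scale) scale_area(a) else a
}

#' Perimeter of a section polygon
#'
#' Sum of edge lengths of the closed loop, in 10 mm units by default.
#'
#' @inheritParams csa
#' @param scale report in 10 mm (default) rather than mm.
#' @return perimeter.
#' @export
section_perimeter <- function(polygon, scale = TRUE, check_simple = TRUE) {
  xy <- .as_loop_xy(polygon)
  if (nrow(xy) < 3) stop("section_perimeter: polygon needs >= 3 vertices")
  if (check_simple && !.is_simple_loop(xy))
    stop("section_perimeter: self-intersecting loop")
  p <- .poly_perimeter(xy)
  if (scale) scale_length(p) else p
}

#' Hydraulic diameter of a cross-section
#'
#' `4 * CSA / perimeter`: equals the true diameter for a circle and shrinks
#' with non-circular deformation. Inputs are in base units (mm^2, mm);
#' the result is reported in 10 mm units by default.
#'
#' @param area cross-sectional area, mm^2 (> 0).
#' @param perimeter section perimeter, mm (> 0).
#' @param scale report in 10 mm (default) rather than mm.
#' @return hydraulic diameter.
#' @export
hydraulic_diameter <- function(area, perimeter, scale = TRUE) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("hydraulic_diameter: area and perimeter must be > 0")
  dh <- 4 * area / perimeter
  if (scale) scale_length(dh) else dh
}

#' Maximal (Feret) diameter of a section polygon
#'
#' Largest point-to-point distance across the section, computed on the
#' convex hull, in 10 mm units by default.
#'
#' @inheritParams csa
#' @param scale report in 10 mm (default) rather than mm.
#' @return maximal diameter.
#' @export
maximal_diameter <- function(polygon, scale = TRUE) {
  xy <- .as_loop_xy(polygon)
  if (nrow(xy) < 3) stop("maximal_diameter: polygon needs >= 3 vertices")
  d <- .poly_feret(xy)
  if (scale) scale_length(d) else d
}

#' Section centroid in 3-D
#' @param polygon a `section_polygon`.
#' @return length-3 point, mm.
#' @export
section_center <- function(polygon) {
  ctr <- .poly_centroid(polygon$xy)
  polygon$origin + ctr[1] * polygon$u + ctr[2] * polygon$v
}
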
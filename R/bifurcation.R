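#' Bifurcation triangle area
#'
#' Area of the 3-D triangle spanned by the section centers of the MPA
#' outlet, RPA inlet and LPA inlet planes (half the magnitude of the edge
#' cross product), reported in 100 mm^2.
#'
#' @param c_outlet,c_rpa,c_lpa length-3 center points, mm.
#' @param scale report in 100 mm^2 (default) rather than mm^2.
#' @return area; 0 for collinear points.
#' @export
bifurcation_area <- function(c_outlet, c_rpa, c_lpa, scale = TRUE) {
  v1 <- c_rpa - c_outlet
  v2 <- c_lpa - c_outlet
  cx <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  a <- sqrt(sum(cx^2)) / 2
  if (scale) scale_area(a) else a
}

#' Bifurcation angle
#'
#' Interior angle of the bifurcation triangle at the MPA-outlet vertex:
#' the angle between the vectors from the outlet center to the RPA and LPA
#' inlet centers, in degrees.
#'
#' @inheritParams bifurcation_area
#' @return angle in degrees, in (0, 180].
#' @export
bifurcation_angle <- function(c_outlet, c_rpa, c_lpa) {
  v1 <- c_rpa - c_outlet
  v2 <- c_lpa - c_outlet
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    stop("bifurcation_angle: coincident points")
  acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
}

# ---- mesh clipping ---------------------------------------------------------

#' Clip a surface by a halfspace, capping the cut
#'
#' Keeps the part of the surface with `normal . (p - origin) <= 0`.
#' Triangles crossing the plane are split; the cut boundary loops are
#' closed with triangle fans so the result stays watertight when the input
#' was (caps face along `+normal`).
#'
#' @param surface a [vessel_surface()] (any number of openings).
#' @param origin point on the clip plane, mm.
#' @param normal outward normal of the discarded halfspace.
#' @param cap close the cut with planar caps (default `TRUE`).
#' @return clipped [vessel_surface()].
#' @export
clip_surface <- function(surface, origin, normal, cap = TRUE) {
  n <- normal / sqrt(sum(normal^2))
  v <- surface$vertices
  d <- (v[, 1] - origin[1]) * n[1] + (v[, 2] - origin[2]) * n[2] +
       (v[, 3] - origin[3]) * n[3]
  d[abs(d) < 1e-9] <- 1e-9
  keepv <- d < 0
  f <- surface$faces
  k1 <- keepv[f[, 1]]; k2 <- keepv[f[, 2]]; k3 <- keepv[f[, 3]]
  nk <- k1 + k2 + k3

  verts <- v
  newv <- list()
  edge_cache <- new.env(parent = emptyenv())
  cut_pt <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- mget(key, envir = edge_cache, ifnotfound = list(NULL))[[1]]
    if (!is.null(hit)) return(hit)
    t <- d[a] / (d[a] - d[b])
    p <- v[a, ] + t * (v[b, ] - v[a, ])
    id <- nrow(verts) + length(newv) + 1L
    newv[[length(newv) + 1L]] <<- p
    assign(key, id, envir = edge_cache)
    id
  }

  out_faces <- f[nk == 3L, , drop = FALSE]
  tris <- list()
  seg_a <- integer(0); seg_b <- integer(0)
  for (fi in which(nk == 1L | nk == 2L)) {
    tri <- f[fi, ]
    kk <- keepv[tri]
    # rotate so the "odd one out" is first
    rot <- if (sum(kk) == 1L) which(kk) else which(!kk)
    ord <- ((rot - 1L + 0:2) %% 3L) + 1L
    a <- tri[ord[1]]; b <- tri[ord[2]]; c_ <- tri[ord[3]]
    iab <- cut_pt(a, b); ica <- cut_pt(c_, a)
    if (sum(kk) == 1L) {            # keep corner a
      tris[[length(tris) + 1L]] <- c(a, iab, ica)
      seg_a <- c(seg_a, iab); seg_b <- c(seg_b, ica)
    } else {                        # drop corner a, keep b and c
      tris[[length(tris) + 1L]] <- c(b, c_, ica)
      tris[[length(tris) + 1L]] <- c(b, ica, iab)
      seg_a <- c(seg_a, ica); seg_b <- c(seg_b, iab)
    }
  }
  if (length(newv))
    verts <- rbind(verts, do.call(rbind, newv))
  faces <- rbind(out_faces,
                 if (length(tris)) do.call(rbind, tris))

  if (cap && length(seg_a)) {
    # chain cut segments into loops and fan-cap each
    adj <- split(c(seg_b, seg_a), c(seg_a, seg_b))
    seen <- new.env(parent = emptyenv())
    starts <- unique(seg_a)
    B <- .plane_basis(n)
    for (st in starts) {
      if (isTRUE(mget(as.character(st), envir = seen,
                      ifnotfound = FALSE)[[1]])) next
      loop <- integer(0); prev <- NA_integer_; cur <- st
      ok <- TRUE
      repeat {
        loop <- c(loop, cur)
        assign(as.character(cur), TRUE, envir = seen)
        nb <- adj[[as.character(cur)]]
        nxt <- if (is.na(prev)) nb[1] else nb[nb != prev][1]
        if (is.na(nxt) || is.null(nxt)) { ok <- FALSE; break }
        prev <- cur; cur <- nxt
        if (cur == st) break
      }
      if (!ok || length(loop) < 3) next
      ctr <- colMeans(verts[loop, , drop = FALSE])
      cid <- nrow(verts) + 1L
      verts <- rbind(verts, ctr)
      # wind caps so their normal is +n (outward of the kept halfspace)
      P <- verts[loop, , drop = FALSE]
      xy <- cbind((P[, 1] - ctr[1]) * B$u[1] + (P[, 2] - ctr[2]) * B$u[2] +
                    (P[, 3] - ctr[3]) * B$u[3],
                  (P[, 1] - ctr[1]) * B$v[1] + (P[, 2] - ctr[2]) * B$v[2] +
                    (P[, 3] - ctr[3]) * B$v[3])
      x <- xy[, 1]; y <- xy[, 2]
      ccw <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) > 0
      if (!ccw) loop <- rev(loop)
      m <- length(loop)
      faces <- rbind(faces, cbind(cid, loop, loop[c(2:m, 1)]))
    }
  }

  used <- sort(unique(as.vector(faces)))
  remap <- match(seq_len(nrow(verts)), used)
  vessel_surface(verts[used, , drop = FALSE],
                 matrix(remap[faces], ncol = 3))
}

#' Bifurcation volume
#'
#' Lumen volume of the carina region: the part of the vessel bounded
#' proximally by the MPA outlet plane and distally by the RPA and LPA inlet
#' planes. The surface is clipped by the three halfspaces, the cuts are
#' capped, and the volume follows from the divergence theorem. Reported in
#' 1000 mm^3.
#'
#' @param surface a [vessel_surface()].
#' @param planes result of [select_measurement_planes()] (or a compatible
#'   list with `MPA_outlet`, `RPA_inlet`, `LPA_inlet`, each having `origin`
#'   and `normal` with the normal pointing away from the carina for the
#'   branches and towards it for the outlet).
#' @param scale report in 1000 mm^3 (default) rather than mm^3.
#' @return enclosed volume.
#' @export
bifurcation_volume <- function(surface, planes, scale = TRUE) {
  # orient each clip so the kept halfspace contains the carina (the
  # centroid of the three plane origins); plane normals may point either
  # way depending on how the planes were produced
  pl <- planes[c("MPA_outlet", "RPA_inlet", "LPA_inlet")]
  ccar <- (pl[[1]]$origin + pl[[2]]$origin + pl[[3]]$origin) / 3
  s <- surface
  for (p in pl) {
    n <- p$normal
    if (sum(n * (ccar - p$origin)) > 0) n <- -n
    s <- clip_surface(s, p$origin, n)
  }
  if (length(boundary_loops(s)) != 0)
    stop("bifurcation_volume: clipped region is not watertight")
  vol <- mesh_volume(s)
  if (vol <= 0) stop("bifurcation_volume: non-positive enclosed volume")
  if (scale) scale_volume(vol) else vol
}

#' MPA dilation flag
#'
#' Dichotomizes the trunk transverse diameter at 29 mm: dilated means
#' strictly greater than 29 mm.
#'
#' @param transverse_diameter trunk diameter at the transverse section
#'   plane, mm (> 0).
#' @return list with `transverse_diameter` (mm) and logical `dilated`.
#' @export
dilation_flag <- function(transverse_diameter) {
  if (any(transverse_diameter <= 0))
    stop("dilation_flag: diameter must be > 0")
  list(transverse_diameter = transverse_diameter,
       dilated = transverse_diameter > 29)
}
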
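#' Parametric bifurcation specification
#'
#' Describes an idealized main-pulmonary-artery bifurcation: a (possibly
#' tapered, elliptical) trunk along +z splitting into two straight circular
#' branches in the xz-plane. Defaults approximate an adult MPA with the
#' calibre of the reference cohort's adverse-event-free group (trunk CSA
#' about 7.7-8.4 x 100 mm^2, branch CSA about 4.7-5.0 x 100 mm^2).
#'
#' @param trunk_length trunk length, mm.
#' @param trunk_radius_inlet,trunk_radius_outlet trunk major semi-axis at
#'   inlet/outlet, mm.
#' @param ellipticity_trunk minor/major axis ratio of the trunk section,
#'   in (0, 1].
#' @param branch_radii radii (right, left), mm.
#' @param branch_lengths lengths (right, left), mm.
#' @param branch_angles angles from the trunk axis (right, left), degrees,
#'   each in (0, 90); `c(0, 0)` is accepted as the degenerate straight-tube
#'   case used for calibration.
#' @param carina_offset lateral displacement of each branch origin from the
#'   trunk axis, mm.
#' @param fillet smooth-union fillet radius at the carina, mm.
#' @param mesh_resolution segments per ring (>= 16); sets the iso-surface
#'   grid spacing to `2*pi*r_min / mesh_resolution`.
#' @param seed integer recorded with the mesh (generation is deterministic).
#' @return object of class `bifurcation_spec`.
#' @export
bifurcation_spec <- function(trunk_length = 50,
                             trunk_radius_inlet = 15.6,
                             trunk_radius_outlet = 16.3,
                             ellipticity_trunk = 0.9,
                             branch_radii = c(12.6, 12.2),
                             branch_lengths = c(35, 35),
                             branch_angles = c(50, 45),
                             carina_offset = 0,
                             fillet = 1,
                             mesh_resolution = 64,
                             seed = 1L) {
  spec <- list(trunk_length = trunk_length,
               trunk_radius_inlet = trunk_radius_inlet,
               trunk_radius_outlet = trunk_radius_outlet,
               ellipticity_trunk = ellipticity_trunk,
               branch_radii = branch_radii,
               branch_lengths = branch_lengths,
               branch_angles = branch_angles,
               carina_offset = carina_offset,
               fillet = fillet,
               mesh_resolution = mesh_resolution,
               seed = as.integer(seed))
  class(spec) <- "bifurcation_spec"
  validate_bifurcation_spec(spec)
  spec
}

#' @rdname bifurcation_spec
#' @param spec a `bifurcation_spec`.
#' @export
validate_bifurcation_spec <- function(spec) {
  with(spec, {
    if (!(trunk_length > 0 && trunk_radius_inlet > 0 &&
          trunk_radius_outlet > 0 && all(branch_radii > 0) &&
          all(branch_lengths > 0)))
      stop("bifurcation_spec: all lengths and radii must be > 0")
    if (!(ellipticity_trunk > 0 && ellipticity_trunk <= 1))
      stop("bifurcation_spec: ellipticity must be in (0, 1]")
    if (any(branch_angles < 0) || any(branch_angles >= 90))
      stop("bifurcation_spec: branch angles must be in [0, 90) degrees")
    if (any(branch_angles == 0) && !all(branch_angles == 0))
      stop("bifurcation_spec: a zero branch angle is only valid for the ",
           "degenerate straight-tube case (both angles 0)")
    if (mesh_resolution < 16)
      stop("bifurcation_spec: mesh_resolution must be >= 16 segments/ring")
    if (carina_offset < 0) stop("bifurcation_spec: carina_offset must be >= 0")
  })
  if (!all(spec$branch_angles == 0)) .check_branch_separation(spec)
  invisible(TRUE)
}

# branch tubes must separate before the branch openings, otherwise the two
# outlets merge and no single-loop branch-inlet station exists
.check_branch_separation <- function(spec) {
  rF <- .branch_frame(spec$trunk_length, spec$branch_angles[1], +1,
                      spec$carina_offset)
  lF <- .branch_frame(spec$trunk_length, spec$branch_angles[2], -1,
                      spec$carina_offset)
  need <- sum(spec$branch_radii) + spec$fillet
  sep_at <- function(t) {
    p <- (rF$origin + t * rF$dir) - (lF$origin + t * lF$dir)
    sqrt(sum(p^2)) - need
  }
  t_end <- min(spec$branch_lengths)
  if (sep_at(t_end) < 2)
    stop("geometric conflict: branch tubes self-intersect up to the branch ",
         "openings (separation ", round(sep_at(t_end), 2), " mm at the ends; ",
         "increase branch angles or lengths, or reduce radii)")
  invisible(TRUE)
}

# grid spacing implied by the ring resolution
.grid_spacing <- function(spec) {
  degenerate <- all(spec$branch_angles == 0)
  r_min <- if (degenerate) {
    spec$ellipticity_trunk * min(spec$trunk_radius_inlet,
                                 spec$trunk_radius_outlet)
  } else {
    min(spec$ellipticity_trunk * min(spec$trunk_radius_inlet,
                                     spec$trunk_radius_outlet),
        spec$branch_radii)
  }
  2 * pi * r_min / spec$mesh_resolution
}

#' Generate a bifurcation surface mesh with ground truth
#'
#' Builds the implicit solid of the specified bifurcation (smooth union of a
#' trunk and two branch tubes, opened at the three vessel ends), extracts
#' its surface by marching tetrahedra and computes the generator's ground
#' truth: the analytic centerline, per-plane section metrics at the four
#' measurement stations, the bifurcation triangle metrics and the
#' inter-plane volume. Ground-truth quantities inside the carina blend are
#' computed from the exact implicit field (radial contouring and fine voxel
#' counting) rather than the mesh, so they are independent of the
#' triangulation.
#'
#' @param spec a [bifurcation_spec()].
#' @param ground_truth compute the ground-truth block (default `TRUE`).
#' @return list with elements `surface` (a [vessel_surface()]) and `truth`
#'   (a `bifurcation_truth` list; `NULL` if not requested).
#' @export
generate_bifurcation_mesh <- function(spec, ground_truth = TRUE) {
  validate_bifurcation_spec(spec)
  fb <- .bifurcation_field(spec)
  h <- .grid_spacing(spec)

  # bounding box from capsule extents
  ends <- rbind(c(0, 0, 0), c(0, 0, spec$trunk_length))
  rad <- c(max(spec$trunk_radius_inlet, spec$trunk_radius_outlet),
           max(spec$trunk_radius_inlet, spec$trunk_radius_outlet))
  if (!fb$degenerate) {
    ends <- rbind(ends, fb$right$origin,
                  fb$right$origin + spec$branch_lengths[1] * fb$right$dir,
                  fb$left$origin,
                  fb$left$origin + spec$branch_lengths[2] * fb$left$dir)
    rad <- c(rad, spec$branch_radii[1], spec$branch_radii[1],
             spec$branch_radii[2], spec$branch_radii[2])
  }
  pad <- max(rad) + spec$fillet + 3 * h
  lo <- apply(ends, 2, min) - pad
  hi <- apply(ends, 2, max) + pad
  # offset the grid so no plane coincides with a cut plane
  x <- seq(lo[1] - 0.37 * h, hi[1], by = h)
  y <- seq(lo[2] - 0.37 * h, hi[2], by = h)
  z <- seq(lo[3] - 0.37 * h, hi[3], by = h)
  if (length(x) * length(y) * as.double(length(z)) > 8e6)
    stop("mesh grid too large; reduce mesh_resolution")
  g <- expand.grid(x = x, y = y, z = z, KEEP.OUT.ATTRS = FALSE)
  vals <- array(fb$field_raw(as.matrix(g)),
                dim = c(length(x), length(y), length(z)))
  mt <- march_tetrahedra(vals, x, y, z)

  # open the vessel ends by exact mesh clipping at the end planes: this
  # leaves exactly planar rims (the analytic circle/ellipse), which the
  # centerline tracker seeds on
  surface <- vessel_surface(mt$vertices, mt$faces)
  for (pl in fb$planes)
    surface <- clip_surface(surface, pl$origin, pl$normal, cap = FALSE)

  # label openings by nearest cut plane
  bl <- boundary_loops(surface)
  if (length(bl) != length(fb$planes))
    stop("mesh generation failed: expected ", length(fb$planes),
         " openings, found ", length(bl))
  lab <- character(length(bl))
  for (ii in seq_along(bl)) {
    ctr <- colMeans(surface$vertices[bl[[ii]], , drop = FALSE])
    dd <- vapply(fb$planes, function(pl) sum((ctr - pl$origin)^2), 0)
    lab[ii] <- fb$planes[[which.min(dd)]]$label
  }
  surface$opening_labels <- lab
  validate_surface(surface, n_openings = length(fb$planes))

  truth <- if (ground_truth) .bifurcation_truth(spec, fb) else NULL
  list(surface = surface, truth = truth)
}

# ---- ground truth ----------------------------------------------------------

#' Perimeter of an ellipse
#'
#' Arc length by numerical quadrature (used as the closed-form oracle for
#' elliptical trunk sections).
#' @param a,b semi-axes, mm.
#' @return perimeter, mm.
#' @export
ellipse_perimeter <- function(a, b) {
  integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
            0, 2 * pi, rel.tol = 1e-10)$value
}

# in-plane orthonormal basis for a unit normal
.plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(n = n, u = u, v = v)
}

# raster of {field < 0} in a plane slice with connected-component labels
# (min-label propagation, 4-connectivity)
.slice_raster <- function(field, origin, normal, half_extent, h = 0.8) {
  B <- .plane_basis(normal)
  s <- seq(-half_extent, half_extent, by = h)
  gr <- expand.grid(a = s, b = s, KEEP.OUT.ATTRS = FALSE)
  p <- cbind(origin[1] + gr$a * B$u[1] + gr$b * B$v[1],
             origin[2] + gr$a * B$u[2] + gr$b * B$v[2],
             origin[3] + gr$a * B$u[3] + gr$b * B$v[3])
  ins <- matrix(field(p) < 0, length(s), length(s))
  lab <- matrix(Inf, nrow(ins), ncol(ins))
  if (any(ins)) {
    lab[ins] <- seq_len(sum(ins))
    repeat {
      new <- lab
      new[-1, ] <- pmin(new[-1, ], lab[-nrow(lab), ])
      new[-nrow(lab), ] <- pmin(new[-nrow(lab), ], lab[-1, ])
      new[, -1] <- pmin(new[, -1], lab[, -ncol(lab)])
      new[, -ncol(lab)] <- pmin(new[, -ncol(lab)], lab[, -1])
      new[!ins] <- Inf
      if (identical(new, lab)) break
      lab <- new
    }
  }
  list(ins = ins, lab = lab, s = s, h = h)
}

.slice_components <- function(field, origin, normal, half_extent, h = 0.8) {
  r <- .slice_raster(field, origin, normal, half_extent, h)
  if (!any(r$ins)) return(0L)
  length(unique(r$lab[r$ins]))
}

# radial extent (min, max) about the centroid of the in-plane component
# containing the plane origin; NULL if the origin is not inside the lumen
.slice_origin_component <- function(field, origin, normal, half_extent,
                                    h = 0.8) {
  r <- .slice_raster(field, origin, normal, half_extent, h)
  i0 <- which.min(abs(r$s)); j0 <- i0
  if (!r$ins[i0, j0]) return(NULL)
  l0 <- r$lab[i0, j0]
  inc <- r$lab == l0 & r$ins
  ij <- which(inc, arr.ind = TRUE)
  ca <- mean(r$s[ij[, 1]]); cb <- mean(r$s[ij[, 2]])
  da <- r$s[ij[, 1]] - ca; db <- r$s[ij[, 2]] - cb
  out <- which(!inc, arr.ind = TRUE)
  oa <- r$s[out[, 1]] - ca; ob <- r$s[out[, 2]] - cb
  list(r_max = sqrt(max(da * da + db * db)),
       r_min = if (nrow(out)) sqrt(min(oa * oa + ob * ob)) else Inf)
}

# section outline of the implicit solid on a plane, by vectorized radial
# bisection about `origin` (section assumed star-shaped about it)
.field_section_polygon <- function(field, origin, normal, r_max,
                                   n_dir = 720L) {
  B <- .plane_basis(normal)
  phi <- seq(0, 2 * pi, length.out = n_dir + 1L)[-(n_dir + 1L)]
  dirs <- outer(cos(phi), B$u) + outer(sin(phi), B$v)
  if (field(matrix(origin, 1))[1] >= 0)
    stop("section center is not inside the lumen")
  lo <- rep(0, n_dir); hi <- rep(r_max, n_dir)
  ok <- field(sweep(dirs * r_max, 2, origin, "+")) > 0
  if (!all(ok)) stop("r_max too small for section polygon")
  for (it in 1:48) {
    mid <- (lo + hi) / 2
    f <- field(sweep(dirs * mid, 2, origin, "+"))
    inside <- f < 0
    lo[inside] <- mid[inside]
    hi[!inside] <- mid[!inside]
  }
  r <- (lo + hi) / 2
  cbind(r * cos(phi), r * sin(phi))  # plane coordinates, counter-clockwise
}

# polygon helpers in plane coordinates (shared with the morphometry module)
.poly_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}
.poly_perimeter <- function(xy) {
  dx <- diff(rbind(xy, xy[1, , drop = FALSE]))
  sum(sqrt(rowSums(dx^2)))
}
.poly_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(colMeans(xy))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * A)
}
.poly_feret <- function(xy) {
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  d2 <- outer(hull[, 1], hull[, 1], "-")^2 + outer(hull[, 2], hull[, 2], "-")^2
  sqrt(max(d2))
}

.section_metrics_from_poly <- function(xy) {
  A <- .poly_area(xy); P <- .poly_perimeter(xy)
  list(csa = A, perimeter = P, hydraulic_diameter = 4 * A / P,
       maximal_diameter = .poly_feret(xy))
}

# ground truth for a generated bifurcation (base units: mm, mm^2, mm^3)
.bifurcation_truth <- function(spec, fb = .bifurcation_field(spec)) {
  Lt <- spec$trunk_length
  step <- 1
  tr_s <- unique(c(seq(0, Lt, by = step), Lt))
  centerline <- list(MPA = cbind(0, 0, tr_s))
  r_at <- function(t) spec$trunk_radius_inlet +
    (spec$trunk_radius_outlet - spec$trunk_radius_inlet) * pmin(pmax(t, 0), Lt) / Lt
  e <- spec$ellipticity_trunk

  trunk_section <- function(z) {
    a <- r_at(z); b <- e * a
    P <- ellipse_perimeter(a, b)
    list(csa = pi * a * b, perimeter = P,
         hydraulic_diameter = 4 * pi * a * b / P, maximal_diameter = 2 * a)
  }

  inlet <- c(trunk_section(0), list(arc = 0, origin = c(0, 0, 0),
                                    normal = c(0, 0, 1)))

  if (fb$degenerate) {
    out <- trunk_section(Lt)
    stations <- list(
      MPA_inlet = inlet,
      MPA_outlet = c(out, list(arc = Lt, origin = c(0, 0, Lt),
                               normal = c(0, 0, 1))))
    return(structure(list(spec = spec, centerline = centerline,
                          bifurcation_point = c(0, 0, Lt),
                          stations = stations, bifurcation = NULL),
                     class = "bifurcation_truth"))
  }

  br_sR <- unique(c(seq(0, spec$branch_lengths[1], by = step),
                    spec$branch_lengths[1]))
  br_sL <- unique(c(seq(0, spec$branch_lengths[2], by = step),
                    spec$branch_lengths[2]))
  centerline$RPA <- t(fb$right$origin + outer(fb$right$dir, br_sR))
  centerline$LPA <- t(fb$left$origin + outer(fb$left$dir, br_sL))

  half_ext <- max(spec$trunk_radius_inlet, spec$trunk_radius_outlet,
                  spec$branch_radii) * 2.2 + spec$fillet

  # Carina detection. The MPA outlet is the most distal trunk-perpendicular
  # station whose section is still a clean single tube cut, and each branch
  # inlet the most proximal such station along its branch. "Clean" means
  # the in-plane component containing the axis point stays local and round:
  # r_max <= .station_roundness * r_min about it. A plain loop-count transition cannot
  # serve here: along a branch the plane cuts the neighbouring lumen
  # longitudinally (one merged loop, never two), and along the trunk the
  # two-loop transition only happens distal of the branch-inlet stations.
  # The same rule drives the mesh measurement path.
  trunk_ok <- function(zz) {
    oc <- .slice_origin_component(fb$field, c(0, 0, zz), c(0, 0, 1),
                                  half_ext)
    !is.null(oc) && oc$r_max <= .station_roundness * oc$r_min
  }
  good <- Lt * 0.5
  if (!trunk_ok(good)) stop("trunk mid-station is not a clean section")
  bad <- NA_real_
  for (zz in seq(Lt * 0.5 + 1, Lt + max(spec$branch_lengths), by = 1)) {
    if (trunk_ok(zz)) good <- zz else { bad <- zz; break }
  }
  for (it in 1:14) {
    mid <- (good + bad) / 2
    if (trunk_ok(mid)) good <- mid else bad <- mid
  }
  z_outlet <- good

  # branch inlet: most proximal branch-perpendicular station whose section
  # is a single clean tube cut. Near the carina the plane slices the other
  # lumen almost longitudinally, so the section containing the axis point
  # balloons; the criterion is locality/roundness of that component
  # (r_max <= .station_roundness * r_min about the axis point), shared with the mesh
  # measurement path.
  branch_station <- function(frame, L) {
    ok <- function(t) {
      oc <- .slice_origin_component(fb$field, frame$origin + t * frame$dir,
                                    frame$dir, half_ext)
      !is.null(oc) && oc$r_max <= .station_roundness * oc$r_min
    }
    good <- L
    bad <- NA_real_
    for (t in seq(L - 1, 0, by = -1)) {
      if (ok(t)) good <- t else { bad <- t; break }
    }
    if (is.na(bad)) return(0)
    for (it in 1:14) {
      mid <- (bad + good) / 2
      if (ok(mid)) good <- mid else bad <- mid
    }
    good
  }
  t_rpa <- branch_station(fb$right, spec$branch_lengths[1])
  t_lpa <- branch_station(fb$left, spec$branch_lengths[2])

  r_big <- half_ext * 1.6
  sec_at <- function(origin, normal) {
    xy <- .field_section_polygon(fb$field, origin, normal, r_max = r_big)
    m <- .section_metrics_from_poly(xy)
    B <- .plane_basis(normal)
    ctr2 <- .poly_centroid(xy)
    m$origin <- origin + ctr2[1] * B$u + ctr2[2] * B$v
    m$normal <- B$n
    m
  }
  outlet <- c(sec_at(c(0, 0, z_outlet), c(0, 0, 1)), list(arc = z_outlet))
  rpa <- c(sec_at(fb$right$origin + t_rpa * fb$right$dir, fb$right$dir),
           list(arc = t_rpa))
  lpa <- c(sec_at(fb$left$origin + t_lpa * fb$left$dir, fb$left$dir),
           list(arc = t_lpa))

  # bifurcation triangle from the three section centers
  co <- outlet$origin; cr <- rpa$origin; cl <- lpa$origin
  v1 <- cr - co; v2 <- cl - co
  cx <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  tri_area <- sqrt(sum(cx^2)) / 2
  ang <- acos(pmin(pmax(sum(v1 * v2) /
                          sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi

  # inter-plane volume by fine voxel counting of the exact field
  hv <- 0.4
  pts <- rbind(co, cr, cl)
  vlo <- apply(pts, 2, min) - max(spec$branch_radii,
                                  spec$trunk_radius_outlet) - 2
  vhi <- apply(pts, 2, max) + max(spec$branch_radii,
                                  spec$trunk_radius_outlet) + 2
  gx <- seq(vlo[1], vhi[1], by = hv); gy <- seq(vlo[2], vhi[2], by = hv)
  gz <- seq(vlo[3], vhi[3], by = hv)
  gg <- as.matrix(expand.grid(gx, gy, gz, KEEP.OUT.ATTRS = FALSE))
  inside <- fb$field(gg) < 0
  between <- ((gg[, 3] - z_outlet) > 0) &
    ((gg - matrix(cr, nrow(gg), 3, byrow = TRUE)) %*% fb$right$dir < 0) &
    ((gg - matrix(cl, nrow(gg), 3, byrow = TRUE)) %*% fb$left$dir < 0)
  vol <- sum(inside & between) * hv^3

  structure(list(
    spec = spec, centerline = centerline,
    bifurcation_point = c(0, 0, Lt),
    stations = list(MPA_inlet = inlet, MPA_outlet = outlet,
                    RPA_inlet = rpa, LPA_inlet = lpa),
    bifurcation = list(area = tri_area, angle = ang, volume = vol)),
    class = "bifurcation_truth")
}

#' Serialize ground truth as a JSON sidecar
#' @param truth a `bifurcation_truth`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- truth
  obj$centerline <- lapply(obj$centerline, function(m) unclass(m))
  obj$spec <- unclass(obj$spec)
  class(obj) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
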
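# Implicit (signed-distance style) fields for the parametric bifurcation.
# Negative inside the lumen wall surface, zero on it. Fields are exact
# distances for circular tubes; elliptical trunks use an exact level set
# whose gradient magnitude stays within [ellipticity, 1], which is ample
# for linear interpolation on the marching grid.

# smooth minimum (polynomial, C1): blends two fields with fillet radius k
.smin <- function(a, b, k) {
  if (k <= 0) return(pmin(a, b))
  h <- pmax(k - abs(a - b), 0) / k
  pmin(a, b) - h * h * k * 0.25
}

# capsule: segment from `a` along unit `d`, length L, radius r, rounded
# at t = 0 and extended by `ext` beyond t = L so the distal wall runs
# cleanly past its cut plane. p: n x 3 matrix
.sdf_capsule <- function(p, a, d, L, r, ext = 0) {
  q <- sweep(p, 2, a)
  t <- pmin(pmax(q %*% d, 0), L + ext)
  dx <- q[, 1] - t * d[1]
  dy <- q[, 2] - t * d[2]
  dz <- q[, 3] - t * d[3]
  sqrt(dx * dx + dy * dy + dz * dz) - r
}

# tapered elliptical trunk along +z from z=0 to z=L; linearly varying
# major semi-axis r(t) from r0 to r1, major axis along x, minor = e * major.
# The wall continues `ext_lo` below z = 0 (and `ext_hi` beyond z = L) at
# the end radius, so the inlet cut plane slices a clean tube rather than
# an end cap; beyond those extensions the tube closes axially.
.sdf_trunk <- function(p, L, r0, r1, e, ext_lo = 0, ext_hi = 0) {
  t <- pmin(pmax(p[, 3], -ext_lo), L + ext_hi)
  tr <- pmin(pmax(t, 0), L)
  r <- r0 + (r1 - r0) * tr / L
  rho <- sqrt((e * p[, 1])^2 + p[, 2]^2) - e * r   # in-plane signed
  dz <- p[, 3] - t
  out <- rho
  ax <- dz != 0
  out[ax] <- sqrt(pmax(rho[ax], 0)^2 + dz[ax]^2)
  out
}

# branch axis geometry: origin on (possibly offset) trunk end, direction in
# the xz-plane at `angle_deg` from the trunk (+z) axis, side = +1 (right,
# +x) or -1 (left, -x)
.branch_frame <- function(trunk_length, angle_deg, side, offset) {
  th <- angle_deg * pi / 180
  list(origin = c(side * offset, 0, trunk_length),
       dir = c(side * sin(th), 0, cos(th)))
}

# full clipped solid: smooth union of trunk and branches, cut by the inlet
# plane (z >= 0) and the two branch end planes. Returns the field function
# and the cut-plane list used for cap removal.
.bifurcation_field <- function(spec) {
  rF <- .branch_frame(spec$trunk_length, spec$branch_angles[1], +1,
                      spec$carina_offset)
  lF <- .branch_frame(spec$trunk_length, spec$branch_angles[2], -1,
                      spec$carina_offset)
  degenerate <- all(spec$branch_angles == 0) && spec$carina_offset == 0
  planes <- list(
    list(origin = c(0, 0, 0), normal = c(0, 0, -1), label = "MPA"))
  if (!degenerate) {
    planes <- c(planes, list(
      list(origin = rF$origin + spec$branch_lengths[1] * rF$dir,
           normal = rF$dir, label = "RPA"),
      list(origin = lF$origin + spec$branch_lengths[2] * lF$dir,
           normal = lF$dir, label = "LPA")))
  } else {
    planes <- c(planes, list(
      list(origin = c(0, 0, spec$trunk_length), normal = c(0, 0, 1),
           label = "distal")))
  }
  # raw field: the smooth tube union, with every wall extended past its
  # end plane (the vessel ends are opened afterwards by exact mesh
  # clipping, which then slices clean tube walls, not end caps)
  ext <- max(spec$trunk_radius_inlet, spec$trunk_radius_outlet,
             spec$branch_radii) + spec$fillet + 6
  field_raw <- function(p) {
    p <- matrix(p, ncol = 3)
    f <- .sdf_trunk(p, spec$trunk_length, spec$trunk_radius_inlet,
                    spec$trunk_radius_outlet, spec$ellipticity_trunk,
                    ext_lo = ext,
                    ext_hi = if (degenerate) ext else 0)
    if (!degenerate) {
      f <- .smin(f, .sdf_capsule(p, rF$origin, rF$dir,
                                 spec$branch_lengths[1],
                                 spec$branch_radii[1], ext = ext),
                 spec$fillet)
      f <- .smin(f, .sdf_capsule(p, lF$origin, lF$dir,
                                 spec$branch_lengths[2],
                                 spec$branch_radii[2], ext = ext),
                 spec$fillet)
    }
    f
  }
  # clipped field: intersected with the end halfspaces (used by ground
  # truth and voxel oracles, where the solid must match the opened mesh)
  field <- function(p) {
    p <- matrix(p, ncol = 3)
    f <- field_raw(p)
    for (pl in planes) {
      g <- (p[, 1] - pl$origin[1]) * pl$normal[1] +
           (p[, 2] - pl$origin[2]) * pl$normal[2] +
           (p[, 3] - pl$origin[3]) * pl$normal[3]
      # `normal` points out of the vessel at that opening
      f <- pmax(f, g)
    }
    f
  }
  list(field = field, field_raw = field_raw, planes = planes,
       degenerate = degenerate, right = rF, left = lF)
}

# numerical gradient of a field at points p (n x 3), central differences
.field_grad <- function(field, p, h = 1e-4) {
  g <- matrix(0, nrow(p), 3)
  for (k in 1:3) {
    dp <- matrix(0, nrow(p), 3)
    dp[, k] <- h
    g[, k] <- (field(p + dp) - field(p - dp)) / (2 * h)
  }
  g
}

# measurement-station roundness bound: a station is a clean tube cut when
# the in-plane lumen component containing the axis point has
# r_max <= .station_roundness * r_min about it. Must exceed the inverse of
# the lowest supported trunk ellipticity (1/0.72) with headroom for mesh
# discretization, and stay low enough to exclude the carina blend.
.station_roundness <- 1.4

# stricter bound used to stop the centerline marcher: section centroids
# inside the early blend can drift off-axis by over a millimetre before
# the station rule trips, so the tracker stops sooner; plane placement
# then scans forward to the .station_roundness transition
.march_roundness <- 1.25
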
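# Shared fixtures, built once per test run. Mesh generation is the slow
# part (~5-25 s each), so every test pulls from this cache.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# straight circular cylinder, radius 14 mm (the degenerate two-collinear-
# branch spec), resolution 64
fx_cylinder <- function() fx_get("cyl", function()
  generate_bifurcation_mesh(bifurcation_spec(
    branch_angles = c(0, 0), trunk_radius_inlet = 14,
    trunk_radius_outlet = 14, ellipticity_trunk = 1, trunk_length = 60,
    mesh_resolution = 64)))

# elliptical straight tube, major 20 / minor 10 mm
fx_elliptic <- function() fx_get("ell", function()
  generate_bifurcation_mesh(bifurcation_spec(
    branch_angles = c(0, 0), trunk_radius_inlet = 20,
    trunk_radius_outlet = 20, ellipticity_trunk = 0.5, trunk_length = 50,
    mesh_resolution = 64)))

# the default Y bifurcation with ground truth
fx_y <- function() fx_get("y", function()
  generate_bifurcation_mesh(bifurcation_spec()))

fx_y_centerline <- function() fx_get("y_cl", function()
  extract_centerline(fx_y()$surface))

fx_y_metrics <- function() fx_get("y_m", function()
  measure_vessel(fx_y()$surface, fx_y_centerline()))

# smaller, coarser Y for invariance tests
fx_y_small_spec <- function() bifurcation_spec(
  trunk_length = 35, trunk_radius_inlet = 12, trunk_radius_outlet = 12.5,
  branch_radii = c(9, 8.5), branch_lengths = c(26, 26),
  branch_angles = c(52, 48), mesh_resolution = 40)

fx_y_small <- function() fx_get("ys", function()
  generate_bifurcation_mesh(fx_y_small_spec(), ground_truth = FALSE))

# long shallow-angle Y: the branch tubes stay clear of their (tilted)
# end-plane rims over a wide band above the carina split, so a horizontal
# plane there cuts two clean closed loops
fx_y_long <- function() fx_get("yl", function()
  generate_bifurcation_mesh(bifurcation_spec(
    branch_angles = c(35, 35), branch_lengths = c(60, 60),
    branch_radii = c(9, 9), mesh_resolution = 40),
    ground_truth = FALSE))

# lofted tube along a circular arc (in the xz-plane) with an analytic
# centerline: an independent mesh construction, not the implicit generator
torus_tube_mesh <- function(R = 60, r = 10, arc = pi / 2, n_u = 72,
                            n_v = 48) {
  uu <- seq(0, arc, length.out = n_u)
  vv <- seq(0, 2 * pi, length.out = n_v + 1)[-(n_v + 1)]
  verts <- matrix(0, n_u * n_v, 3)
  for (i in seq_len(n_u)) {
    cx <- R * sin(uu[i]); cz <- R * (1 - cos(uu[i]))
    # radial direction from the arc center (0, 0, R) to the ring center
    rad <- c(sin(uu[i]), 0, -cos(uu[i]))
    for (j in seq_len(n_v)) {
      p <- c(cx, 0, cz) + r * cos(vv[j]) * rad + r * sin(vv[j]) * c(0, 1, 0)
      verts[(i - 1) * n_v + j, ] <- p
    }
  }
  faces <- NULL
  idx <- function(i, j) (i - 1) * n_v + ((j - 1) %% n_v) + 1
  fl <- vector("list", (n_u - 1) * n_v * 2)
  k <- 0
  for (i in seq_len(n_u - 1)) for (j in seq_len(n_v)) {
    a <- idx(i, j); b <- idx(i, j + 1); c_ <- idx(i + 1, j + 1)
    d <- idx(i + 1, j)
    fl[[k + 1]] <- c(a, b, c_); fl[[k + 2]] <- c(a, c_, d)
    k <- k + 2
  }
  vessel_surface(verts, do.call(rbind, fl),
                 opening_labels = c("MPA", "distal"))
}

# cap all boundary loops of an open surface with centroid fans, orienting
# caps outward via the resulting signed volume
cap_openings <- function(surface) {
  s <- surface
  repeat {
    bl <- boundary_loops(s)
    if (!length(bl)) break
    loop <- bl[[1]]
    v <- s$vertices
    ctr <- colMeans(v[loop, , drop = FALSE])
    v2 <- rbind(v, ctr)
    cid <- nrow(v2)
    m <- length(loop)
    # wind the fan against the existing boundary edge direction so the
    # directed-edge orientation stays consistent
    fan <- cbind(cid, loop[c(2:m, 1)], loop)
    f2 <- rbind(s$faces, fan)
    dir_e <- rbind(f2[, c(1, 2)], f2[, c(2, 3)], f2[, c(3, 1)])
    if (anyDuplicated(paste(dir_e[, 1], dir_e[, 2]))) {
      fan <- cbind(cid, loop, loop[c(2:m, 1)])
      f2 <- rbind(s$faces, fan)
    }
    s <- vessel_surface(v2, f2, s$opening_labels)
  }
  s
}

# voxel-counting volume oracle on the implicit field of a spec; evaluated
# in z-slabs to bound memory, optionally over a tight bounding box
voxel_volume <- function(spec, h = 0.5, region = NULL, bbox = NULL) {
  fb <- pabifurc:::.bifurcation_field(spec)
  if (is.null(bbox)) {
    ends <- rbind(c(0, 0, 0), c(0, 0, spec$trunk_length))
    if (!all(spec$branch_angles == 0)) {
      ends <- rbind(ends,
                    fb$right$origin + spec$branch_lengths[1] * fb$right$dir,
                    fb$left$origin + spec$branch_lengths[2] * fb$left$dir)
    }
    pad <- max(spec$trunk_radius_inlet, spec$trunk_radius_outlet,
               spec$branch_radii) + spec$fillet + 1
    bbox <- list(lo = apply(ends, 2, min) - pad,
                 hi = apply(ends, 2, max) + pad)
  }
  gx <- seq(bbox$lo[1], bbox$hi[1], by = h)
  gy <- seq(bbox$lo[2], bbox$hi[2], by = h)
  gz <- seq(bbox$lo[3], bbox$hi[3], by = h)
  slab <- max(1L, floor(5e5 / (length(gx) * length(gy))))
  total <- 0
  for (z0 in seq(1, length(gz), by = slab)) {
    zz <- gz[z0:min(z0 + slab - 1L, length(gz))]
    gg <- as.matrix(expand.grid(gx, gy, zz, KEEP.OUT.ATTRS = FALSE))
    keep <- fb$field(gg) < 0
    if (!is.null(region)) keep <- keep & region(gg)
    total <- total + sum(keep)
  }
  total * h^3
}

# regular n-gon loop (counter-clockwise), radius r
regular_ngon <- function(n, r) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3,
              byrow = TRUE)
  diag(3) * ca + sa * K + (1 - ca) * outer(a, a)
}
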
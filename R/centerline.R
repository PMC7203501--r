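#' Extract the centerline of a vessel surface
#'
#' Centroid-marching centerline: from each opening, the tracker seeds at
#' the centroid of the boundary ring, then repeatedly steps along the
#' current tangent, re-slices the vessel perpendicular to it and re-centers
#' on the section centroid. Marching stops when the section stops being a
#' clean single tube cut (the carina) or when another opening is reached.
#'
#' For a three-opening surface the path from the MPA inlet is the trunk and
#' the paths from the two branch openings are reversed to run from the
#' carina outward; the bifurcation point is the last clean trunk station.
#' Two-opening tubes (no bifurcation) yield a single path.
#'
#' @param surface a [vessel_surface()] with 2 or 3 openings.
#' @param step marching step, mm.
#' @param max_steps safety bound per branch.
#' @return object of class `vessel_centerline`: list with `points` (matrix),
#'   `branch` (factor MPA/RPA/LPA or MPA/distal), `arc` (per-branch arc
#'   length), `bifurcation_point` (or `NULL`).
#' @export
extract_centerline <- function(surface, step = 1, max_steps = 500) {
  bl <- boundary_loops(surface)
  if (!length(bl) %in% c(2L, 3L))
    stop("extract_centerline: surface must have 2 or 3 openings, found ",
         length(bl))
  labels <- surface$opening_labels
  if (is.null(labels)) {
    # largest opening is taken as the MPA inlet; branches by x of centroid
    areas <- vapply(bl, function(ix) {
      ring <- surface$vertices[ix, , drop = FALSE]
      ctr <- colMeans(ring)
      sum(sqrt(rowSums(sweep(ring, 2, ctr)^2)))  # circumference proxy
    }, 0)
    labels <- rep("", length(bl))
    labels[which.max(areas)] <- "MPA"
    rest <- which(labels == "")
    if (length(rest) == 2) {
      cx <- vapply(rest, function(i)
        mean(surface$vertices[bl[[i]], 1]), 0)
      labels[rest[which.max(cx)]] <- "RPA"
      labels[rest[which.min(cx)]] <- "LPA"
    } else labels[rest] <- "distal"
  }
  if (!"MPA" %in% labels)
    stop("extract_centerline: no opening labelled MPA")

  mesh_ctr <- colMeans(surface$vertices)
  march_from <- function(loop_idx) {
    ring <- surface$vertices[bl[[loop_idx]], , drop = FALSE]
    p <- colMeans(ring)
    # inward normal of the opening ring by plane fit, oriented into the mesh
    rc <- sweep(ring, 2, p)
    sv <- svd(rc)
    tangent <- sv$v[, 3]
    if (sum(tangent * (mesh_ctr - p)) < 0) tangent <- -tangent
    # seed at the area centroid of the rim loop: the raw vertex mean is
    # biased by uneven rim sampling and would tilt the first tangent
    B <- .plane_basis(tangent)
    xy <- cbind(rc %*% B$u, rc %*% B$v)
    c2 <- .poly_centroid(xy)
    p <- p + c2[1] * B$u + c2[2] * B$v
    normal0 <- tangent
    pts <- matrix(p, 1)
    tgs <- matrix(tangent, 1)
    for (k in seq_len(max_steps)) {
      cand <- p + step * tangent
      sec <- tryCatch(
        cross_section(surface, cand, tangent,
                      max_loop_dist = .station_roundness * 2 *
                        max(sqrt(rowSums(rc^2)))),
        pabifurc_multiloop = function(e) NULL,
        error = function(e) NULL)
      if (is.null(sec)) break
      cc <- .poly_centroid(sec$xy)
      rr <- sqrt(rowSums(sweep(sec$xy, 2, cc)^2))
      if (max(rr) > .march_roundness * min(rr)) break  # entering carina
      ctr <- section_center(sec)
      newt <- ctr - p
      nn <- sqrt(sum(newt^2))
      if (nn < 1e-9) break
      p <- ctr
      pts <- rbind(pts, p)
      tgs <- rbind(tgs, tangent)  # the tangent that sliced this station
      # exponentially smoothed tangent, frozen for the first steps: near a
      # wide rim even a small tilt makes the slicing plane cross the
      # opening, and the rim-fit normal is the best estimate there
      if (k > 3) {
        tangent <- 0.6 * tangent + 0.4 * newt / nn
        tangent <- tangent / sqrt(sum(tangent^2))
      }
      # reached another opening?
      ends <- vapply(seq_along(bl)[-loop_idx], function(i)
        min(sqrt(rowSums(sweep(surface$vertices[bl[[i]], , drop = FALSE],
                               2, p)^2))), 0)
      if (min(ends) < 1.5 * step) break
    }
    attr(pts, "normal0") <- normal0
    attr(pts, "tangents") <- tgs
    pts
  }

  paths <- lapply(seq_along(bl), march_from)
  names(paths) <- labels
  trunk <- paths[["MPA"]]
  branch_names <- setdiff(labels, "MPA")
  out_pts <- trunk
  out_branch <- rep("MPA", nrow(trunk))
  arcs <- list(MPA = c(0, cumsum(sqrt(rowSums(diff(trunk)^2)))))
  bif <- if (length(bl) == 3) trunk[nrow(trunk), ] else NULL
  for (bn in branch_names) {
    rev_ix <- rev(seq_len(nrow(paths[[bn]])))
    tg_rev <- attr(paths[[bn]], "tangents")[rev_ix, , drop = FALSE]
    pp <- paths[[bn]][rev_ix, , drop = FALSE]
    attr(pp, "tangents") <- tg_rev
    paths[[bn]] <- pp
    out_pts <- rbind(out_pts, pp)
    out_branch <- c(out_branch, rep(bn, nrow(pp)))
    arcs[[bn]] <- c(0, cumsum(sqrt(rowSums(diff(pp)^2))))
  }
  inlet_normals <- lapply(paths, attr, "normal0")
  structure(list(points = out_pts, branch = out_branch,
                 arc = unlist(arcs, use.names = FALSE),
                 arcs = arcs, inlet_normals = inlet_normals,
                 paths = c(list(MPA = trunk), paths[branch_names]),
                 bifurcation_point = bif),
            class = "vessel_centerline")
}

#' @export
print.vessel_centerline <- function(x, ...) {
  cat("<vessel_centerline:",
      paste(sprintf("%s (%d pts, %.1f mm)", names(x$paths),
                    vapply(x$paths, nrow, 0L),
                    vapply(x$arcs, max, 0)), collapse = ", "),
      ">\n")
  invisible(x)
}

# local tangent of a polyline path at row i
.path_tangent <- function(path, i) {
  n <- nrow(path)
  a <- max(1, i - 1); b <- min(n, i + 1)
  t <- path[b, ] - path[a, ]
  t / sqrt(sum(t^2))
}
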
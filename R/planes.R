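#' Select the four measurement planes
#'
#' Places the clinical measurement planes on a bifurcation surface, all
#' perpendicular to the local centerline tangent:
#' * `MPA_inlet` -- at the proximal end of the trunk centerline;
#' * `MPA_outlet` -- the most distal trunk station whose cross-section is
#'   still a clean single tube cut;
#' * `RPA_inlet`, `LPA_inlet` -- the most proximal such stations along each
#'   branch.
#'
#' "Clean" uses the carina-detection rule shared with the generator's
#' ground truth: the section loop must be single (a multi-loop signal from
#' [cross_section()] marks the carina) and stay local and round about the
#' centerline point (max radius at most `1.4 x` min radius). Station
#' refinement bisects the transition to `refine` mm.
#'
#' @param surface a [vessel_surface()] with three openings.
#' @param centerline a [extract_centerline()] result (computed if missing).
#' @param refine bisection resolution along the centerline, mm.
#' @return named list of planes (`MPA_inlet`, `MPA_outlet`, `RPA_inlet`,
#'   `LPA_inlet`), each with `origin`, `normal`, `arc`, `polygon` (the
#'   section) and `center` (3-D section centroid).
#' @export
select_measurement_planes <- function(surface, centerline = NULL,
                                      refine = 0.1) {
  if (length(boundary_loops(surface)) != 3)
    stop("select_measurement_planes: no carina found (surface does not ",
         "have three openings)")
  if (is.null(centerline)) centerline <- extract_centerline(surface)
  paths <- centerline$paths
  if (!all(c("RPA", "LPA") %in% names(paths)))
    stop("select_measurement_planes: centerline lacks RPA/LPA branches")

  loc_radius <- function(sec) max(sqrt(rowSums(sec$xy^2)))
  clean_section <- function(origin, normal, maxd) {
    sec <- tryCatch(
      cross_section(surface, origin, normal, max_loop_dist = maxd),
      pabifurc_multiloop = function(e) NULL, error = function(e) NULL)
    if (is.null(sec)) return(NULL)
    # roundness about the section centroid, matching the generator's
    # ground-truth station rule (also centroid-referenced)
    cc <- .poly_centroid(sec$xy)
    rr <- sqrt(rowSums(sweep(sec$xy, 2, cc)^2))
    if (max(rr) > .station_roundness * min(rr)) return(NULL)
    sec
  }

  plane_at <- function(path, i, dir_sign, branch) {
    # walk from station i towards the carina (dir_sign = +1 along the path
    # end, -1 from the path start) and bisect the clean->dirty transition
    p <- path[i, ]
    n <- nrow(path)
    # plane normal from the principal direction of a clean mid-path
    # window: marching tangents at the carina end are tilted by centroid
    # drift inside the blend, which would place the station obliquely
    w <- if (dir_sign > 0) max(1, n - 12):max(1, n - 3) else
      min(n, 4):min(n, 13)
    seg <- path[unique(w), , drop = FALSE]
    tg <- if (nrow(seg) >= 3) {
      svd(sweep(seg, 2, colMeans(seg)))$v[, 1]
    } else .path_tangent(path, i)
    # orient towards the carina
    toward <- if (dir_sign > 0) p - path[max(1, i - 6), ] else
      p - path[min(n, i + 6), ]
    if (sum(tg * toward) < 0) tg <- -tg
    tg <- tg / sqrt(sum(tg^2))
    # local lumen radius from a mid-path station, where the section is a
    # clean tube cut; sections at the break point itself may be unusable
    m0 <- max(1, min(n, round(n / 2)))
    jm <- if (m0 + 6 <= n) m0 + 6 else max(1, m0 - 6)
    tgm <- path[m0, ] - path[jm, ]
    tgm <- tgm / sqrt(sum(tgm^2))
    sec_mid <- cross_section(surface, path[m0, ], tgm, all_loops = TRUE,
                             max_loop_dist = Inf)
    near <- vapply(sec_mid, function(s) min(sqrt(rowSums(s$xy^2))), 0)
    maxd <- 2.5 * loc_radius(sec_mid[[which.min(near)]])
    # the re-averaged tangent can make the exact path endpoint marginally
    # dirty; back off until a clean start is found
    lo <- NA_real_
    for (s in seq(0, -4, by = -0.5)) {
      if (!is.null(clean_section(p + s * tg, tg, maxd))) { lo <- s; break }
    }
    if (is.na(lo))
      stop("select_measurement_planes: no clean section on branch ", branch)
    # the marcher stops at a stricter roundness than the station rule, so
    # scan forward for the dirty side before bisecting the transition
    hi <- NA_real_
    for (s in seq(lo + 1, lo + 12, by = 1)) {
      if (is.null(clean_section(p + s * tg, tg, maxd))) { hi <- s; break }
      lo <- s
    }
    if (is.na(hi))
      stop("select_measurement_planes: no carina transition on branch ",
           branch)
    while (hi - lo > refine) {
      mid <- (lo + hi) / 2
      if (!is.null(clean_section(p + mid * tg, tg, maxd))) lo <- mid
      else hi <- mid
    }
    origin <- p + lo * tg
    sec <- clean_section(origin, tg, maxd)
    list(origin = origin, normal = tg, polygon = sec,
         center = section_center(sec))
  }

  trunk <- paths$MPA
  # the rim-fit normal is used at the inlet: the marching tangent can be
  # tilted by a fraction of a degree, enough for a plane half a millimetre
  # above a wide rim to cross the opening
  inlet_t <- centerline$inlet_normals$MPA
  if (is.null(inlet_t)) inlet_t <- .path_tangent(trunk, 1)
  inlet_sec <- cross_section(surface, trunk[1, ] + 1.0 * inlet_t, inlet_t,
                             max_loop_dist = Inf)
  inlet <- list(origin = trunk[1, ], normal = inlet_t, polygon = inlet_sec,
                center = section_center(inlet_sec), arc = 0)

  outlet <- plane_at(trunk, nrow(trunk), +1, "MPA")
  outlet$arc <- max(centerline$arcs$MPA) +
    sqrt(sum((outlet$origin - trunk[nrow(trunk), ])^2))
  rpa <- plane_at(paths$RPA, 1, -1, "RPA")
  rpa$arc <- -sqrt(sum((rpa$origin - paths$RPA[1, ])^2))
  lpa <- plane_at(paths$LPA, 1, -1, "LPA")
  lpa$arc <- -sqrt(sum((lpa$origin - paths$LPA[1, ])^2))

  list(MPA_inlet = inlet, MPA_outlet = outlet, RPA_inlet = rpa,
       LPA_inlet = lpa)
}
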
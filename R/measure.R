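#' Measure all bifurcation morphometrics of a vessel surface
#'
#' Runs the full measurement protocol: centerline extraction, placement of
#' the four perpendicular measurement planes, per-plane cross-sectional
#' area, perimeter, hydraulic and maximal diameter, the bifurcation
#' triangle area and angle, the inter-plane bifurcation volume, and the
#' trunk transverse diameter with its 29 mm dilation flag.
#'
#' @param surface a [vessel_surface()] with three openings.
#' @param centerline optional precomputed [extract_centerline()] result.
#' @return object of class `vessel_metrics`: list with `planes` (a
#'   data.frame of per-plane metrics in scaled units), `bifurcation`
#'   (area 100 mm^2, angle degrees, volume 1000 mm^3), `dilation`
#'   (transverse diameter in mm and flag) and `features` (named vector in
#'   the canonical feature order, scaled units).
#' @export
measure_vessel <- function(surface, centerline = NULL) {
  if (is.null(centerline)) centerline <- extract_centerline(surface)
  planes <- select_measurement_planes(surface, centerline)

  plane_row <- function(id) {
    pl <- planes[[id]]
    A <- csa(pl$polygon, scale = FALSE, check_simple = FALSE)
    P <- section_perimeter(pl$polygon, scale = FALSE, check_simple = FALSE)
    data.frame(plane = id,
               csa = scale_area(A),
               perimeter = scale_length(P),
               hydraulic_diameter = hydraulic_diameter(A, P),
               maximal_diameter = maximal_diameter(pl$polygon),
               stringsAsFactors = FALSE)
  }
  ptab <- do.call(rbind, lapply(names(planes), plane_row))

  area <- bifurcation_area(planes$MPA_outlet$center,
                           planes$RPA_inlet$center,
                           planes$LPA_inlet$center)
  angle <- bifurcation_angle(planes$MPA_outlet$center,
                             planes$RPA_inlet$center,
                             planes$LPA_inlet$center)
  volume <- bifurcation_volume(surface, planes)

  dil <- dilation_flag(transverse_trunk_diameter(surface, centerline))

  g <- function(pl, col) ptab[ptab$plane == pl, col]
  features <- setNames(c(
    g("MPA_inlet", "csa"), g("MPA_outlet", "csa"),
    g("RPA_inlet", "csa"), g("LPA_inlet", "csa"),
    g("MPA_inlet", "hydraulic_diameter"), g("MPA_outlet", "hydraulic_diameter"),
    g("RPA_inlet", "hydraulic_diameter"), g("LPA_inlet", "hydraulic_diameter"),
    g("MPA_inlet", "maximal_diameter"), g("MPA_outlet", "maximal_diameter"),
    g("RPA_inlet", "maximal_diameter"), g("LPA_inlet", "maximal_diameter"),
    area, angle, volume), morphometric_features())

  structure(list(planes = ptab,
                 bifurcation = list(area = area, angle = angle,
                                    volume = volume),
                 dilation = dil,
                 features = features,
                 plane_defs = planes),
            class = "vessel_metrics")
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat("<vessel_metrics>\n")
  print(x$planes, row.names = FALSE)
  cat(sprintf("bifurcation: area %.3f (100 mm^2), angle %.1f deg, volume %.3f (1000 mm^3)\n",
              x$bifurcation$area, x$bifurcation$angle, x$bifurcation$volume))
  cat(sprintf("transverse diameter %.1f mm, dilation %s\n",
              x$dilation$transverse_diameter,
              if (x$dilation$dilated) "(+)" else "(-)"))
  invisible(x)
}

#' Trunk transverse diameter
#'
#' Maximal diameter of the trunk cross-section on an axial (z-normal)
#' plane at the trunk centerline midpoint -- the synthetic analogue of the
#' CT transverse-section measurement used for the 29 mm dilation cut-off.
#'
#' @param surface a [vessel_surface()].
#' @param centerline optional precomputed centerline.
#' @return diameter in mm.
#' @export
transverse_trunk_diameter <- function(surface, centerline = NULL) {
  if (is.null(centerline)) centerline <- extract_centerline(surface)
  trunk <- centerline$paths$MPA
  mid <- trunk[ceiling(nrow(trunk) / 2), ]
  sec <- cross_section(surface, mid, c(0, 0, 1), all_loops = TRUE,
                       max_loop_dist = Inf)
  near <- vapply(sec, function(p)
    min(sqrt(rowSums(p$xy^2))), 0)
  maximal_diameter(sec[[which.min(near)]], scale = FALSE)
}

#' Export a measurement report
#'
#' Writes the metrics as JSON, or as a one-row CSV whose columns use the
#' standard parameter labels (see [cohort_csv_labels()]).
#'
#' @param metrics a `vessel_metrics`.
#' @param path output path, `.json` or `.csv`.
#' @return invisibly `path`.
#' @export
write_metrics <- function(metrics, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- list(planes = metrics$planes,
                bifurcation = metrics$bifurcation,
                dilation = metrics$dilation,
                features = as.list(metrics$features))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else if (ext == "csv") {
    lab <- cohort_csv_labels()
    row <- as.data.frame(as.list(metrics$features), check.names = FALSE)
    names(row) <- unname(lab[morphometric_features()])
    row[[unname(lab["dilation"])]] <-
      if (metrics$dilation$dilated) "(+)" else "(-)"
    write.csv(row, path, row.names = FALSE)
  } else stop("write_metrics: unsupported extension '", ext, "'")
  invisible(path)
}
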
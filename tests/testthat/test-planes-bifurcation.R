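test_that("the four measurement planes land on the ground-truth stations", {
  m <- fx_y_metrics()
  tr <- fx_y()$truth
  for (nm in c("MPA_outlet", "RPA_inlet", "LPA_inlet")) {
    d <- sqrt(sum((m$plane_defs[[nm]]$origin - tr$stations[[nm]]$origin)^2))
    expect_lt(d, 2)   # within 2 mm of the generator's station
  }
  expect_equal(m$plane_defs$MPA_inlet$arc, 0)
})

test_that("measured plane metrics agree with the generator's ground truth", {
  m <- fx_y_metrics()
  st <- fx_y()$truth$stations
  for (nm in names(st)) {
    row <- m$planes[m$planes$plane == nm, ]
    expect_equal(row$csa, st[[nm]]$csa / 100, tolerance = 0.05)
    expect_equal(row$hydraulic_diameter, st[[nm]]$hydraulic_diameter / 10,
                 tolerance = 0.05)
    expect_equal(row$maximal_diameter, st[[nm]]$maximal_diameter / 10,
                 tolerance = 0.05)
  }
})

test_that("a cylinder has no carina to select planes on", {
  expect_error(select_measurement_planes(fx_cylinder()$surface),
               "no carina")
})

test_that("bifurcation triangle area matches the Heron oracle", {
  expect_equal(bifurcation_area(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)), 0.5)
  expect_equal(bifurcation_area(c(0, 0, 0), c(5, 5, 5), c(10, 10, 10)), 0)
  set.seed(11)
  for (k in 1:100) {
    p <- matrix(rnorm(9, sd = 20), 3)
    a <- sqrt(sum((p[2, ] - p[1, ])^2))
    b <- sqrt(sum((p[3, ] - p[1, ])^2))
    cc <- sqrt(sum((p[3, ] - p[2, ])^2))
    s <- (a + b + cc) / 2
    heron <- sqrt(max(s * (s - a) * (s - b) * (s - cc), 0))
    expect_equal(bifurcation_area(p[1, ], p[2, ], p[3, ], scale = FALSE),
                 heron, tolerance = 1e-9)
  }
})

test_that("bifurcation angle matches the law-of-cosines oracle", {
  # equilateral triangle
  eq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(bifurcation_angle(eq[1, ], eq[2, ], eq[3, ]), 60)
  # near-collinear limit -> 180 degrees
  expect_equal(bifurcation_angle(c(0, 1e-9, 0), c(-1, 0, 0), c(1, 0, 0)),
               180, tolerance = 1e-3)
  expect_error(bifurcation_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincident")
  set.seed(12)
  for (k in 1:100) {
    p <- matrix(rnorm(9, sd = 10), 3)
    a2 <- sum((p[2, ] - p[3, ])^2)
    b2 <- sum((p[3, ] - p[1, ])^2)
    c2 <- sum((p[2, ] - p[1, ])^2)
    oracle <- acos((b2 + c2 - a2) / (2 * sqrt(b2 * c2))) * 180 / pi
    expect_equal(bifurcation_angle(p[1, ], p[2, ], p[3, ]), oracle,
                 tolerance = 1e-9)
  }
})

test_that("clipped cylinder volume matches the analytic slab", {
  s <- fx_cylinder()$surface   # radius 14, length 60
  planes <- list(
    MPA_outlet = list(origin = c(0, 0, 15), normal = c(0, 0, 1)),
    RPA_inlet = list(origin = c(4, 0, 45), normal = c(0, 0, 1)),
    LPA_inlet = list(origin = c(-4, 0, 45), normal = c(0, 0, 1)))
  v <- bifurcation_volume(s, planes, scale = FALSE)
  expect_equal(v, pi * 196 * 30, tolerance = 0.02)
  # scaled reporting in 1000 mm^3
  expect_equal(bifurcation_volume(s, planes), v / 1000)
})

test_that("Y-mesh bifurcation volume agrees with voxel counting of the same region", {
  m <- fx_y_metrics()
  pd <- m$plane_defs
  ccar <- (pd$MPA_outlet$center + pd$RPA_inlet$center +
             pd$LPA_inlet$center) / 3
  halfspace <- function(gg, o, n) {
    side <- (gg[, 1] - o[1]) * n[1] + (gg[, 2] - o[2]) * n[2] +
      (gg[, 3] - o[3]) * n[3]
    if (sum(n * (ccar - o)) > 0) side > 0 else side < 0
  }
  region <- function(gg)
    halfspace(gg, pd$MPA_outlet$origin, pd$MPA_outlet$normal) &
    halfspace(gg, pd$RPA_inlet$origin, pd$RPA_inlet$normal) &
    halfspace(gg, pd$LPA_inlet$origin, pd$LPA_inlet$normal)
  orig <- rbind(pd$MPA_outlet$origin, pd$RPA_inlet$origin,
                pd$LPA_inlet$origin)
  pad <- 20
  v_vox <- voxel_volume(bifurcation_spec(), h = 0.25, region = region,
                        bbox = list(lo = apply(orig, 2, min) - pad,
                                    hi = apply(orig, 2, max) + pad))
  expect_equal(m$bifurcation$volume * 1000, v_vox, tolerance = 0.02)
})

test_that("zero-thickness clip region collapses to zero volume", {
  s <- fx_cylinder()$surface
  planes <- list(
    MPA_outlet = list(origin = c(0, 0, 30), normal = c(0, 0, 1)),
    RPA_inlet = list(origin = c(0, 0, 30.05), normal = c(0, 0, 1)),
    LPA_inlet = list(origin = c(0, 0, 30.05), normal = c(0, 0, 1)))
  v <- bifurcation_volume(s, planes, scale = FALSE)
  expect_lt(v, pi * 196 * 0.1)
})

test_that("dilation dichotomizes strictly at 29 mm", {
  expect_true(dilation_flag(30)$dilated)
  expect_false(dilation_flag(29)$dilated)
  expect_false(dilation_flag(28.999)$dilated)
  expect_error(dilation_flag(0), "> 0")
  # the default Y (trunk major diameter > 31 mm) is dilated
  expect_true(fx_y_metrics()$dilation$dilated)
})
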
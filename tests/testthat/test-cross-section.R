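test_that("perpendicular and oblique cylinder cuts match closed forms", {
  s <- fx_cylinder()$surface   # radius 14
  sec <- cross_section(s, c(0, 0, 30), c(0, 0, 1))
  expect_equal(csa(sec, scale = FALSE), pi * 196, tolerance = 0.01)
  # 45-degree oblique cut: ellipse, area / cos(45)
  n45 <- c(1, 0, 1) / sqrt(2)
  sec45 <- cross_section(s, c(0, 0, 30), n45)
  expect_equal(csa(sec45, scale = FALSE), pi * 196 / cos(pi / 4),
               tolerance = 0.01)
})

test_that("a plane distal of the carina raises the multi-loop signal", {
  gm <- fx_y_long()
  # branches split around z = 66; their end rims start above z = 90
  expect_error(cross_section(gm$surface, c(0, 0, 78), c(0, 0, 1)),
               class = "pabifurc_multiloop")
  loops <- cross_section(gm$surface, c(0, 0, 78), c(0, 0, 1),
                         all_loops = TRUE)
  expect_length(loops, 2)
})

test_that("no intersection and empty sections error", {
  s <- fx_cylinder()$surface
  expect_error(cross_section(s, c(0, 0, 500), c(0, 0, 1)),
               "does not intersect")
})

test_that("shoelace area and perimeter use the stated scaled units", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))  # unit square, mm
  expect_equal(csa(sq), 0.01)                       # 100 mm^2 units
  expect_equal(csa(sq, scale = FALSE), 1)
  expect_equal(section_perimeter(sq), 0.4)          # 10 mm units
  expect_equal(section_perimeter(sq, scale = FALSE), 4)
  # orientation-insensitive
  expect_equal(csa(sq[4:1, ]), csa(sq))
  expect_equal(section_perimeter(sq[4:1, ]), section_perimeter(sq))
})

test_that("regular 256-gon area matches the closed n-gon form", {
  ng <- regular_ngon(256, 15)
  expect_equal(csa(ng, scale = FALSE),
               0.5 * 256 * 15^2 * sin(2 * pi / 256), tolerance = 1e-12)
  expect_equal(csa(ng, scale = FALSE), pi * 225, tolerance = 1e-3)
})

test_that("self-intersecting loops are rejected", {
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(csa(bow), "self-intersecting")
  expect_error(section_perimeter(bow), "self-intersecting")
  expect_error(csa(rbind(c(0, 0), c(1, 1))), "3 vertices")
})

test_that("hydraulic diameter follows 4A/P in consistent units", {
  # circle: Dh equals the true diameter
  r <- 14
  expect_equal(hydraulic_diameter(pi * r^2, 2 * pi * r), 2.8)  # 10 mm units
  expect_equal(hydraulic_diameter(pi * r^2, 2 * pi * r, scale = FALSE), 28)
  # square of side 20: Dh = side
  expect_equal(hydraulic_diameter(400, 80, scale = FALSE), 20)
  # ellipse 20/10: quadrature-oracle perimeter
  P <- ellipse_perimeter(20, 10)
  expect_equal(hydraulic_diameter(pi * 200, P, scale = FALSE),
               4 * pi * 200 / P)
  expect_equal(4 * pi * 200 / P, 25.93, tolerance = 1e-3)
  expect_error(hydraulic_diameter(-1, 10), "> 0")
  expect_error(hydraulic_diameter(10, 0), "> 0")
})

test_that("maximal diameter equals the brute-force pairwise maximum", {
  # circle
  ng <- regular_ngon(128, 10)
  expect_equal(maximal_diameter(ng, scale = FALSE), 20, tolerance = 1e-3)
  # 20 x 10 rectangle: the diagonal
  rect <- rbind(c(0, 0), c(20, 0), c(20, 10), c(0, 10))
  expect_equal(maximal_diameter(rect, scale = FALSE), sqrt(500))
  # random polygons vs O(n^2) oracle
  set.seed(42)
  for (k in 1:20) {
    pts <- matrix(rnorm(2 * 40), ncol = 2)
    hull <- pts[chull(pts), ]
    oracle <- sqrt(max(dist(pts)^2))
    expect_equal(maximal_diameter(pts, scale = FALSE), oracle,
                 tolerance = 1e-12)
    expect_equal(maximal_diameter(hull, scale = FALSE), oracle,
                 tolerance = 1e-12)
  }
  expect_error(maximal_diameter(rbind(c(0, 0), c(1, 1))), ">= 3")
})

test_that("hydraulic diameter never exceeds the equivalent-circle diameter", {
  # property over generated circles and ellipses; equality iff circular
  set.seed(7)
  for (k in 1:25) {
    a <- runif(1, 5, 25)
    b <- a * runif(1, 0.3, 1)
    A <- pi * a * b
    P <- ellipse_perimeter(a, b)
    dh <- hydraulic_diameter(A, P, scale = FALSE)
    deq <- sqrt(4 * A / pi)
    expect_lte(dh, deq + 1e-9)
    if (abs(a - b) < 1e-12) expect_equal(dh, deq, tolerance = 1e-9)
  }
})
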
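test_that("girth matches known perimeters and scales linearly", {
  circ <- circle_section(1, n = 360)
  expect_equal(girth(circ), 2 * pi, tolerance = 1e-4)
  ell <- ellipse_section(0.06, 0.04, n = 720)
  expect_equal(girth(ell), ellipse_perimeter_quadrature(0.06, 0.04),
               tolerance = 1e-4)
  doubled <- cross_section(2 * ell$x, 2 * ell$y)
  expect_equal(girth(doubled), 2 * girth(ell), tolerance = 1e-12)
})

test_that("cross-section constructor enforces orientation and simplicity", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  cw <- cross_section(0.05 * cos(rev(th)), 0.05 * sin(rev(th)))
  expect_gt(ctpress:::polygon_area(cw$x, cw$y), 0)  # reoriented CCW
  expect_error(cross_section(cos(th[1:10]), sin(th[1:10])), "16 points")
  # a figure-eight is rejected
  t8 <- seq(0, 2 * pi, length.out = 41)[-41]
  expect_error(cross_section(sin(2 * t8), sin(t8)), "self-intersecting")
})

test_that("local radius recovers circle and ellipse curvature, clips flats", {
  circ <- circle_section(0.04, n = 360)
  expect_equal(local_radius(circ, c(0, 0.25, 0.6)), rep(0.04, 3),
               tolerance = 1e-6)
  ell <- ellipse_section(0.06, 0.04, n = 720)
  expect_equal(local_radius(ell, 0), 0.04^2 / 0.06, tolerance = 1e-4)
  sq <- square_section(0.05)
  # mid-side triples are collinear: clipped to the maximum radius
  expect_equal(local_radius(sq, 0.05), 10)
  expect_error(local_radius(circ, 1), "arc_position")
})

test_that("radial displacement shortens the girth by 2 pi w", {
  circ <- circle_section(0.05, n = 720)
  expect_identical(apply_radial_displacement(circ, 0), circ)
  # printed displacement/circumference pairs: 3.61 mm -> 2.27 cm, 11.06 mm -> 6.95 cm
  d1 <- apply_radial_displacement(circ, 0.00361)
  expect_equal(round((girth(circ) - girth(d1)) * 100, 2), 2.27)
  d2 <- apply_radial_displacement(circ, 0.01106)
  expect_equal(round((girth(circ) - girth(d2)) * 100, 2), 6.95)
  # exact identity for circles (finely sampled), parallel-curve oracle below
  fine <- circle_section(0.05, n = 1440)
  for (w in c(0.001, 0.005, 0.02)) {
    dd <- apply_radial_displacement(fine, w)
    expect_equal(girth(dd), girth(fine) - 2 * pi * w,
                 tolerance = 1e-6)
  }
  ell <- ellipse_section(0.06, 0.04, n = 720)
  de <- apply_radial_displacement(ell, 0.003)
  expect_equal(girth(de), girth(ell) - 2 * pi * 0.003, tolerance = 1e-3)
  expect_error(apply_radial_displacement(circ, 0.06), "self-intersect")
})

test_that("displacements compose additively", {
  circ <- circle_section(0.05, n = 360)
  one <- apply_radial_displacement(circ, 0.006)
  two <- apply_radial_displacement(apply_radial_displacement(circ, 0.004), 0.002)
  expect_equal(girth(two), girth(one), tolerance = 1e-12)
  expect_equal(two$x, one$x, tolerance = 1e-9)
  ell <- ellipse_section(0.06, 0.04, n = 720)
  eone <- apply_radial_displacement(ell, 0.003)
  etwo <- apply_radial_displacement(apply_radial_displacement(ell, 0.002), 0.001)
  expect_equal(girth(etwo), girth(eone), tolerance = 1e-4)
})

test_that("girth change identity maps printed displacements to printed deltas", {
  expect_equal(round(girth_change_from_displacement(0.00361) * 100, 2), 2.27)
  expect_equal(round(girth_change_from_displacement(0.01106) * 100, 2), 6.95)
  expect_equal(girth_change_from_displacement(0), 0)
  expect_error(girth_change_from_displacement(-1e-3), ">= 0")
})

test_that("leg CSV round-trips and validates", {
  leg <- frustum_leg(n = 64)
  path <- withr::local_tempfile(fileext = ".csv")
  write_leg_csv(leg, path)
  back <- read_leg_csv(path)
  expect_equal(leg_girths(back), leg_girths(leg), tolerance = 1e-9)
  for (i in seq_along(leg$sections))
    expect_equal(back$sections[[i]]$x, leg$sections[[i]]$x, tolerance = 1e-9)

  # missing label column: labels unset with a warning
  df <- utils::read.csv(path)
  df$label <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_warning(expect_warning(read_leg_csv(path2), "label"), "B")

  # malformed row is reported by number
  df2 <- utils::read.csv(path, colClasses = "character")
  df2$x_m[3] <- "oops"
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, path3, row.names = FALSE)
  expect_error(read_leg_csv(path3), "row 4")

  # open ring is rejected
  df3 <- utils::read.csv(path)
  df3 <- df3[-1, ]  # drop the first vertex of the first ring
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df3, path4, row.names = FALSE)
  expect_error(read_leg_csv(path4), "first and last vertex differ")
})

test_that("leg model validates ordering and labels", {
  s1 <- circle_section(0.04, n = 32, z = 0, label = "B")
  s2 <- circle_section(0.05, n = 32, z = 0.2, label = "D")
  expect_s3_class(leg_model(list(s1, s2), rigidity = "rigid"), "leg_model")
  expect_error(leg_model(list(s2, s1), rigidity = "rigid"),
               "strictly increasing")
  expect_warning(leg_model(list(circle_section(0.04, n = 32)), "rigid"),
                 "labelled")
  expect_error(leg_model(list(s1, s2), rigidity = "soft"), "tissue")
})

test_that("OBJ export writes a watertight side wall", {
  leg <- frustum_leg(n = 32)
  path <- withr::local_tempfile(fileext = ".obj")
  write_leg_obj(leg, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "v ")), 4 * 32)
  expect_equal(sum(startsWith(lines, "f ")), 3 * 2 * 32)
})
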
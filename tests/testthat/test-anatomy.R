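# Synthetic geometry, measurement planes, wall regions, arch angle and
# level diameters.

test_that("generator is deterministic and rejects invalid parameters", {
  p <- phenotype_defaults("C_normal")
  g1 <- build_synthetic_aorta(p, seed = 3)
  g2 <- build_synthetic_aorta(p, seed = 3)
  expect_identical(g1$surface$vertices, g2$surface$vertices)
  expect_identical(g1$centerline$points, g2$centerline$points)

  expect_error(phenotype_params("C_normal", 185, 22, 30, 26, 24),
               "arch_angle")
  expect_error(phenotype_params("C_normal", 97, -22, 30, 26, 24),
               "positive")
  expect_error(phenotype_params("C_normal", 97, 22, 30, 26, 24,
                                recirculation_strength = 0.5),
               "C_normal")
})

test_that("equal level diameters give a constant-radius tube", {
  p <- phenotype_params("C_normal", 97.3, 24, 24, 24, 24)
  g <- build_synthetic_aorta(p)
  pr <- project_to_centerline(g$centerline, g$surface$vertices)
  interior <- pr$s > 0.5 & pr$s < max(g$centerline$arclength) - 0.5
  radial_dev <- abs(pr$radius[interior] - 1.2) / 1.2
  expect_lt(max(radial_dev), 0.01)
})

test_that("generator round-trip recovers level diameters and arch angle", {
  for (grp in c("A_severe", "B_mild", "C_normal")) {
    p <- phenotype_defaults(grp)
    g <- build_synthetic_aorta(p)
    lv <- measure_levels(g$surface, g$centerline)
    targets <- c(p$annulus_d, p$sinus_d, p$stj_d, p$midAA_d)
    expect_rel_equal(lv, targets, 0.01)
    ang <- measure_arch_angle(g$centerline)
    expect_lt(abs(ang - p$arch_angle_deg), 3)
  }
})

test_that("arch angle matches the circle-chord closed form on arcs", {
  d <- 1
  for (ratio in c(2, 3, 5, 10, 20, 50)) {
    rc <- ratio * d
    half <- min(2.0, acos(max(-1, 1 - 3 * d / rc)))  # deep enough arcs
    cl <- arc_centerline(rc, half_angle = half, diameter = 1.5)
    exact <- 2 * atan(sqrt(2 * rc * d - d^2) / d) * 180 / pi
    expect_lt(abs(measure_arch_angle(cl, offset_diameter = d) - exact), 1)
  }
})

test_that("arch angle approaches 180 degrees monotonically for shallow arcs", {
  d <- 1
  angs <- vapply(c(5, 20, 80, 300), function(rc) {
    half <- acos(1 - 2.5 * d / rc)
    measure_arch_angle(arc_centerline(rc, half_angle = half),
                       offset_diameter = d)
  }, numeric(1))
  expect_true(all(diff(angs) > 0))
  expect_gt(angs[length(angs)], 170)
  expect_lt(angs[length(angs)], 180)
})

test_that("arch angle errors on degenerate or too-short centerlines", {
  # straight line: flat height profile
  cl <- straight_centerline()
  expect_error(measure_arch_angle(cl), "ambiguous|flat")
  # arc too shallow for the offset to cross
  cl2 <- arc_centerline(20, half_angle = 0.2, diameter = 1.5)
  expect_error(measure_arch_angle(cl2, offset_diameter = 1), "cross|apex")
})

test_that("plane positions follow the arclength rules on a straight tube", {
  tube <- straight_tube(length_cm = 25, diameter = 2,
                        landmarks = c(annulus = 2, sinus = 2.5, stj = 3,
                                      mid_AA = 5, brachiocephalic = 10,
                                      left_carotid = 11,
                                      left_subclavian = 12))
  planes <- extract_planes(tube$centerline, tube$surface)
  s <- vapply(planes, function(p) p$arclength, numeric(1))
  # hand-computed from the rules with D = 2 cm, just-offset fraction 0.1
  expect_equal(unname(s),
               c(2 + 2, 10 - 2, 10 - 0.2, 12 + 0.2, 12.2 + 4),
               tolerance = 25 / 400)
  expect_true(all(diff(s) > 0))
})

test_that("plane extraction validates landmarks", {
  tube <- straight_tube(landmarks = c(annulus = 2, stj = 3,
                                      brachiocephalic = 10,
                                      left_carotid = 11))
  expect_error(extract_planes(tube$centerline, tube$surface),
               "left_subclavian")
  tube2 <- straight_tube(landmarks = c(annulus = 2, stj = 3,
                                       brachiocephalic = 11,
                                       left_carotid = 10,
                                       left_subclavian = 12))
  expect_error(extract_planes(tube2$centerline, tube2$surface),
               "out of order")
})

test_that("wall region bands have cylinder-band areas and stay disjoint", {
  tube <- straight_tube(length_cm = 25, diameter = 2, n_axial = 300,
                        landmarks = c(annulus = 2, sinus = 2.5, stj = 3,
                                      mid_AA = 5, brachiocephalic = 10,
                                      left_carotid = 11,
                                      left_subclavian = 12))
  planes <- extract_planes(tube$centerline, tube$surface)
  regions <- define_wall_regions(tube$surface, tube$centerline, planes)
  area <- attr(regions, "area")
  # band of width one diameter on a radius-1 cylinder: 2*pi*1*2; checked
  # on the bands whose neighbors do not overlap them (planes 1 and 2 are
  # 0.9 D apart by the extraction rules, so their bands always share a
  # 0.1 D strip that the nearest-plane rule splits)
  for (rg in c("arch", "descending")) {
    expect_rel_equal(sum(area[regions[[rg]]]), 4 * pi, 0.05)
  }
  ids <- unlist(regions)
  expect_equal(anyDuplicated(ids), 0L)

  # overlapping bands (arch and distal_AA planes 2.4 cm apart here) still
  # partition triangles by nearest plane
  for (grp in c("A_severe", "B_mild", "C_normal")) {
    g <- build_synthetic_aorta(phenotype_defaults(grp))
    pls <- extract_planes(g$centerline, g$surface)
    rgs <- define_wall_regions(g$surface, g$centerline, pls)
    expect_equal(anyDuplicated(unlist(rgs)), 0L)
    expect_true(all(vapply(rgs, length, integer(1)) > 0))
  }
})

test_that("level measurement matches circle and ellipse oracles", {
  tube <- straight_tube(length_cm = 10, diameter = 2.4, n_axial = 100,
                        n_theta = 48,
                        landmarks = c(annulus = 2, sinus = 4, stj = 6,
                                      mid_AA = 8))
  lv <- measure_levels(tube$surface, tube$centerline)
  expect_rel_equal(lv, rep(24, 4), 0.005)

  # elliptical tube, semi-axes 10 and 14.4 mm: caliper mean (20+28.8)/2
  nth <- 48
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  verts <- NULL
  zs <- seq(0, 10, length.out = 100)
  for (zi in zs) verts <- rbind(verts, cbind(zi, 1.0 * cos(th),
                                             1.44 * sin(th)))
  tris <- NULL
  for (i in 1:99) {
    b <- (i - 1) * nth
    for (j in 1:nth) {
      jn <- if (j == nth) 1 else j + 1
      tris <- rbind(tris, c(b + j, b + nth + j, b + jn),
                    c(b + jn, b + nth + j, b + nth + jn))
    }
  }
  esurf <- aorta_surface(verts, tris, landmarks = c(mid_AA = 5))
  ecl <- straight_centerline(10, diameter = 2.44, n = 200)
  sec <- measure_section(esurf, ecl, 5)
  expect_equal((sec$min_caliper + sec$max_caliper) / 2 * 10, 24.4,
               tolerance = 0.15)
})

test_that("centerline constructor enforces its invariants", {
  expect_error(aorta_centerline(cbind(1:10, 0, 0), 1), "at least 50")
  pts <- cbind(c(seq(0, 5, length.out = 60), 5), 0, 0)
  expect_error(aorta_centerline(pts, 1), "strictly increasing")
  cl <- straight_centerline()
  expect_true(all(abs(sqrt(rowSums(cl$tangent^2)) - 1) < 1e-12))
  expect_error(aorta_centerline(straight_centerline()$points, -1),
               "positive")
})
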
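# WSS/TAWSS estimators, Poiseuille reference, slice vorticity,
# recirculation detection and pattern labels.

poiseuille_setup <- function(q = 83.33, diameter = 2, length_cm = 20) {
  cl <- straight_centerline(length_cm, diameter)
  tube <- straight_tube(length_cm, diameter)
  f <- generate_field(cl, steady_waveform(q = q))
  pr <- project_to_centerline(cl, neoaorta:::triangle_geometry(
    tube$surface)$centroid)
  region <- which(pr$s > 0.3 * length_cm & pr$s < 0.6 * length_cm)
  list(cl = cl, surf = tube$surface, field = f, region = region)
}

test_that("regional WSS matches the Poiseuille oracle within 2%", {
  px <- poiseuille_setup()
  wss <- wss_instant(px$field, px$surf, px$region)
  expect_equal(attr(wss, "skipped"), 0)
  expect_rel_equal(mean(wss), poiseuille_wss(0.04, 83.33, 2), 0.02)
})

test_that("WSS is zero for a still fluid and linear in viscosity", {
  px <- poiseuille_setup()
  f0 <- wrap_tube_field(function(p, t) matrix(0, nrow(p), 3))
  wss0 <- wss_instant(f0, px$surf, px$region, eps = 0.02)
  expect_true(all(wss0 == 0))
  w1 <- wss_instant(px$field, px$surf, px$region,
                    fluid = fluid_properties(mu = 0.04))
  w2 <- wss_instant(px$field, px$surf, px$region,
                    fluid = fluid_properties(mu = 0.08))
  expect_equal(as.numeric(w2), as.numeric(2 * w1), tolerance = 1e-12)
})

test_that("TAWSS reduces to the steady value and scales linearly", {
  px <- poiseuille_setup()
  tw <- tawss(px$field, px$surf, px$region, n_frames = 6)
  inst <- wss_instant(px$field, px$surf, px$region)
  area <- attr(inst, "area")
  expect_equal(tw, sum(inst * area) / sum(area), tolerance = 1e-9)
  # doubling the flow doubles TAWSS
  px2 <- poiseuille_setup(q = 2 * 83.33)
  expect_rel_equal(tawss(px2$field, px2$surf, px2$region, n_frames = 6),
                   2 * tw, 1e-6)
})

test_that("pulsatile TAWSS matches the quasi-steady cycle-mean |Q| value", {
  cl <- straight_centerline(20, 2)
  tube <- straight_tube(20, 2)
  w <- scale_waveform(default_inflow_waveform(), 5)
  f <- generate_field(cl, w, n_frames = 24)
  pr <- project_to_centerline(cl, neoaorta:::triangle_geometry(
    tube$surface)$centroid)
  region <- which(pr$s > 6 & pr$s < 12)
  tw <- tawss(f, tube$surface, region, n_frames = 24)
  frames <- (0:23) / 24 * w$period
  q_absmean <- mean(abs(waveform_at(w, frames)))
  expect_rel_equal(tw, poiseuille_wss(0.04, q_absmean, 2), 0.03)
})

test_that("TAWSS follows the inverse-cube diameter law", {
  px1 <- poiseuille_setup(q = 83.33, diameter = 2)
  px2 <- poiseuille_setup(q = 83.33, diameter = 2 * 1.3)
  t1 <- tawss(px1$field, px1$surf, px1$region, n_frames = 4)
  t2 <- tawss(px2$field, px2$surf, px2$region, n_frames = 4)
  expect_rel_equal(t1 / t2, 1.3^3, 0.05)
})

test_that("Poiseuille WSS formula is exact", {
  # hand-evaluated 32*0.04*83.33/(pi*8) before the build
  expect_equal(poiseuille_wss(0.04, 83.33, 2.0), 4.243962,
               tolerance = 1e-6)
  expect_equal(poiseuille_wss(0.04, 83.33, 4.0),
               poiseuille_wss(0.04, 83.33, 2.0) / 8, tolerance = 1e-12)
  expect_equal(poiseuille_wss(0.04, 0, 2.0), 0)
})

test_that("slice vorticity reproduces its analytic oracles", {
  pl <- tube_plane(10)
  # solid-body rotation about the plane normal: |curl| = 2*Omega
  fr <- wrap_tube_field(function(p, t) cbind(0, -5 * p[, 3], 5 * p[, 2]))
  expect_rel_equal(vorticity_slice(fr, pl, n_grid = 48, delta = 0.005),
                   10, 0.01)
  # uniform translation: zero to discretization noise
  fu <- wrap_tube_field(function(p, t) cbind(3 + 0 * p[, 1], 0, 0))
  expect_lt(vorticity_slice(fu, pl, n_grid = 48, delta = 0.005),
            1e-6 * 3 / 2)
  # Poiseuille: slice mean = 8U/(3R)
  cl <- straight_centerline(20, 2)
  f <- generate_field(cl, steady_waveform(q = 83.33))
  U <- 83.33 / pi
  expect_rel_equal(vorticity_slice(f, pl, n_grid = 48), 8 * U / 3, 0.03)
  # a grid mostly outside the lumen leaves too few interior cells
  expect_error(vorticity_slice(f, tube_plane(10, diameter = 8),
                               n_grid = 8), "16")
})

test_that("cycle-averaged vorticity is steady-consistent and linear", {
  pl <- tube_plane(10)
  cl <- straight_centerline(20, 2)
  f <- generate_field(cl, steady_waveform(q = 60))
  single <- vorticity_slice(f, pl, n_grid = 40)
  expect_equal(vorticity_metric(f, pl, n_grid = 40, n_frames = 3), single,
               tolerance = 1e-9)
  f2 <- generate_field(cl, steady_waveform(q = 120))
  expect_rel_equal(vorticity_metric(f2, pl, n_grid = 40, n_frames = 3),
                   2 * single, 1e-6)
  # streamwise component of a pure axial shear flow equals zero
  expect_lt(vorticity_slice(f, pl, n_grid = 40,
                            component = "streamwise"), 1e-6)
})

test_that("recirculation fraction separates phenotypes and caps at one", {
  g <- build_synthetic_aorta(phenotype_defaults("A_severe"))
  cl <- g$centerline
  planes <- extract_planes(cl, g$surface)
  w <- scale_waveform(default_inflow_waveform(), 5)
  iv <- c(planes$plane2$arclength, planes$plane3$arclength)
  fA <- generate_field(cl, w, recirculation_spec(iv, 0.5))
  recA <- recirculation_fraction(fA, iv)
  expect_true(recA$present)
  expect_gt(recA$fraction, 0.02)
  f0 <- generate_field(cl, w)
  rec0 <- recirculation_fraction(f0, iv)
  expect_lt(rec0$fraction, 0.01)
  expect_false(rec0$present)
  # fully reversed plug flow
  frev <- velocity_field(
    function(p, t) {
      at <- centerline_at(cl, project_to_centerline(cl, p)$s)
      -10 * at$tangent
    },
    period = 0.8, lumen = fA$lumen, peak_systole_time = 0)
  expect_equal(recirculation_fraction(frev, iv, t = 0, cl = cl)$fraction, 1)
})

test_that("WSS pattern labels follow the argmax region with distal ties", {
  regions <- c("root", "proximal_AA", "distal_AA", "arch", "descending")
  prof <- function(v) stats::setNames(v, regions)
  expect_equal(wss_pattern(prof(c(2, 4, 6, 5, 3))), "distal_AA_peak")
  expect_equal(wss_pattern(prof(c(2, 3, 4, 6, 3))), "arch_peak")
  expect_equal(wss_pattern(prof(c(6, 3, 4, 5, 3))), "other")
  expect_equal(wss_pattern(prof(c(2, 3, 5, 5, 3))), "arch_peak")  # tie
  expect_error(wss_pattern(c(root = 1, arch = 2)), "five")
})
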
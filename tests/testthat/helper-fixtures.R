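# Shared fixtures: analytic tubes, centerlines and wrapped velocity fields
# built in code at test time.

# straight tube centerline along +x, constant diameter (cm)
straight_centerline <- function(length_cm = 20, diameter = 2,
                                n = 400) {
  x <- seq(0, length_cm, length.out = n)
  aorta_centerline(cbind(x, 0, 0), rep(diameter, n))
}

straight_tube <- function(length_cm = 20, diameter = 2, n_axial = 160,
                          n_theta = 32, landmarks = numeric()) {
  cl <- straight_centerline(length_cm, diameter)
  list(centerline = cl,
       surface = loft_tube(cl, n_axial = n_axial, n_theta = n_theta,
                           landmarks = landmarks))
}

# planar circular-arc centerline of radius rc spanning +-half_angle
arc_centerline <- function(rc, half_angle = 2.0, diameter = 1.5,
                           n = 2001) {
  psi <- seq(-half_angle, half_angle, length.out = n)
  aorta_centerline(cbind(rc * sin(psi), 0, -rc * (1 - cos(psi))),
                   rep(diameter, n))
}

# slice plane on a straight +x tube at arclength s
tube_plane <- function(s, diameter = 2, label = "plane0") {
  structure(list(label = label, arclength = s, origin = c(s, 0, 0),
                 normal = c(1, 0, 0), diameter = diameter),
            class = "slice_plane")
}

# constant-flow waveform
steady_waveform <- function(q = 83.33, period = 0.8) {
  inflow_waveform(seq(0, period, length.out = 101), rep(q, 101))
}

# wrap an analytic evaluator on a straight +x tube of radius R
wrap_tube_field <- function(evaluate, radius = 1, length_cm = 20,
                            period = 1, n_frames = 4) {
  velocity_field(
    evaluate, period = period, n_frames = n_frames,
    lumen = function(p) {
      sqrt(p[, 2]^2 + p[, 3]^2) < radius & p[, 1] > 0 & p[, 1] < length_cm
    },
    local_radius = function(p) rep(radius, nrow(p)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
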
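# Hemodynamic metrics: instantaneous and time-averaged wall shear stress
# per region, slice-averaged vorticity per plane, the Poiseuille WSS
# reference, recirculation-zone detection, and WSS-pattern classification.

REGION_ORDER <- c("root", "proximal_AA", "distal_AA", "arch", "descending")

# resolve per-triangle wall offsets: explicit eps, or local radius / 50
resolve_eps <- function(field, surf, triangles, eps) {
  if (!is.null(eps)) return(rep_len(eps, length(triangles)))
  stop_if(is.null(field$local_radius),
          "field has no local radius map; pass 'eps' explicitly")
  geo <- triangle_geometry(surf)
  field$local_radius(geo$centroid[triangles, , drop = FALSE]) / 50
}

#' Instantaneous wall shear stress over a region
#'
#' One-sided finite difference anchored at the no-slip wall:
#' WSS = mu * |tangential velocity at wall offset eps| / eps, per triangle.
#'
#' @param field A `velocity_field`.
#' @param surf An `aorta_surface`.
#' @param region Integer triangle indices (one element of
#'   [define_wall_regions()]).
#' @param fluid A [fluid_properties()] list.
#' @param eps Wall offset (cm); default is local radius / 50.
#' @param t Time (s).
#' @return Numeric vector of WSS (dyn/cm^2) per triangle; NA where the
#'   offset point left the lumen (count in `attr(,"skipped")`).
#' @export
wss_instant <- function(field, surf, region, fluid = fluid_properties(),
                        eps = NULL, t = 0) {
  stop_if(length(region) == 0, "empty region")
  eps <- resolve_eps(field, surf, region, eps)
  nw <- sample_near_wall(field, surf, eps = eps, triangles = region, t = t)
  out <- fluid$mu * nw$speed / pmax(eps, .Machine$double.eps)
  out[eps == 0] <- 0
  attr(out, "skipped") <- sum(nw$skipped)
  attr(out, "area") <- nw$area
  out
}

#' Time-averaged wall shear stress of a region
#'
#' Time-average of the instantaneous WSS over one cardiac cycle (uniform
#' frame quadrature), then area-weighted average over the region triangles.
#'
#' @inheritParams wss_instant
#' @param n_frames Frames per cycle (default: the field's).
#' @return Regional TAWSS in dyn/cm^2.
#' @export
tawss <- function(field, surf, region, fluid = fluid_properties(),
                  eps = NULL, n_frames = NULL) {
  stop_if(length(region) == 0, "empty region")
  if (is.null(n_frames)) n_frames <- field$n_frames
  eps <- resolve_eps(field, surf, region, eps)
  times <- (seq_len(n_frames) - 1) / n_frames * field$period
  acc <- matrix(0, length(region), n_frames)
  area <- NULL
  for (k in seq_along(times)) {
    wk <- wss_instant(field, surf, region, fluid, eps = eps, t = times[k])
    if (is.null(area)) area <- attr(wk, "area")
    acc[, k] <- wk
  }
  t_avg <- rowMeans(acc, na.rm = TRUE)
  ok <- is.finite(t_avg)
  stop_if(!any(ok), "all region samples left the lumen")
  sum(t_avg[ok] * area[ok]) / sum(area[ok])
}

#' Poiseuille wall shear stress
#'
#' WSS = 32 mu Q / (pi D^3): the analytic wall shear of steady laminar flow
#' in a circular pipe; at fixed flow it falls with the cube of the
#' diameter.
#'
#' @param mu Dynamic viscosity (poise).
#' @param Q Flow rate (cm^3/s).
#' @param D Diameter (cm).
#' @return WSS in dyn/cm^2.
#' @export
poiseuille_wss <- function(mu, Q, D) {
  check_positive(mu, "mu"); check_positive(D, "D")
  stop_if(!is.numeric(Q) || any(!is.finite(Q)), "'Q' must be finite")
  32 * mu * Q / (pi * D^3)
}

#' Slice-averaged vorticity at one instant
#'
#' Samples the field on a masked in-plane grid, forms the full 3-D curl at
#' every interior grid point by central differences (offset `delta` along
#' the two in-plane axes and the plane normal), and averages the vorticity
#' magnitude (or its streamwise component) over the masked cells. Points
#' whose difference stencil leaves the lumen are excluded.
#'
#' @param field A `velocity_field`.
#' @param plane A `slice_plane`.
#' @param t Time (s).
#' @param n_grid Grid resolution per side.
#' @param delta Finite-difference offset (cm); default diameter / 400.
#' @param component `"magnitude"` (|curl|) or `"streamwise"` (|curl . n|).
#' @return Slice-averaged vorticity (1/s).
#' @export
vorticity_slice <- function(field, plane, t = 0, n_grid = 40,
                            delta = NULL,
                            component = c("magnitude", "streamwise")) {
  component <- match.arg(component)
  if (is.null(delta)) delta <- plane$diameter / 400
  sp <- sample_on_plane(field, plane, n_grid = n_grid, t = t)
  pts <- sp$points[sp$mask, , drop = FALSE]
  b <- sp$basis
  dirs <- rbind(b$e1, b$e2, plane$normal)
  # keep points whose full 6-point stencil stays inside the lumen
  ok <- rep(TRUE, nrow(pts))
  for (j in 1:3) for (sgn in c(-1, 1)) {
    shifted <- pts + sgn * delta * matrix(dirs[j, ], nrow(pts), 3,
                                          byrow = TRUE)
    ok <- ok & field$lumen(shifted)
  }
  pts <- pts[ok, , drop = FALSE]
  stop_if(nrow(pts) < 16,
          "grid too coarse: fewer than 16 interior cells in the mask")
  D <- vector("list", 3)
  for (j in 1:3) {
    dvec <- matrix(dirs[j, ], nrow(pts), 3, byrow = TRUE)
    D[[j]] <- (field$evaluate(pts + delta * dvec, t) -
                 field$evaluate(pts - delta * dvec, t)) / (2 * delta)
  }
  # gradient tensor G_ij = dv_i/dx_j = sum_k D_k,i e_k,j (orthonormal dirs)
  G <- array(0, c(nrow(pts), 3, 3))
  for (k in 1:3) for (j in 1:3)
    G[, , j] <- G[, , j] + D[[k]] * dirs[k, j]
  curl <- cbind(G[, 3, 2] - G[, 2, 3],
                G[, 1, 3] - G[, 3, 1],
                G[, 2, 1] - G[, 1, 2])
  if (component == "magnitude") {
    mean(row_norms(curl))
  } else {
    mean(abs(as.vector(curl %*% plane$normal)))
  }
}

#' Cycle-averaged slice vorticity metric
#'
#' Average of [vorticity_slice()] over uniformly spaced frames of one
#' cardiac cycle.
#'
#' @inheritParams vorticity_slice
#' @param n_frames Frames per cycle (default: the field's).
#' @return Cycle- and slice-averaged vorticity (1/s).
#' @export
vorticity_metric <- function(field, plane, n_grid = 40, n_frames = NULL,
                             delta = NULL,
                             component = c("magnitude", "streamwise")) {
  component <- match.arg(component)
  if (is.null(n_frames)) n_frames <- field$n_frames
  times <- (seq_len(n_frames) - 1) / n_frames * field$period
  mean(vapply(times, function(tt)
    vorticity_slice(field, plane, t = tt, n_grid = n_grid, delta = delta,
                    component = component), numeric(1)))
}

#' Recirculation fraction between two stations
#'
#' Samples the lumen volume between two arclengths on a deterministic
#' (s, radius, angle) grid, uniform in volume, and returns the fraction of
#' sample points whose tangent-projected axial velocity is negative at the
#' chosen instant (default: peak systole, the frame of maximum inflow). A
#' recirculation-present flag is raised when the fraction exceeds
#' `threshold`.
#'
#' @param field A `velocity_field` carrying a centerline (as produced by
#'   [generate_field()]), or any field if `cl` is supplied.
#' @param interval Arclength interval (cm), typically planes 2-3.
#' @param t Sample instant (s); default the field's peak-systole time.
#' @param threshold Fraction above which the flag is raised.
#' @param n_s,n_r,n_chi Grid resolution in arclength, radius, angle.
#' @param cl Optional `aorta_centerline` overriding the field's.
#' @return List with `fraction`, `present`, `n_points`.
#' @export
recirculation_fraction <- function(field, interval, t = NULL,
                                   threshold = 0.02,
                                   n_s = 24, n_r = 12, n_chi = 24,
                                   cl = NULL) {
  if (is.null(cl)) cl <- field$centerline
  stop_if(is.null(cl), "no centerline available; pass 'cl'")
  stop_if(length(interval) != 2 || diff(interval) <= 0,
          "'interval' must be an increasing (start, end) pair")
  stop_if(interval[1] < 0 || interval[2] > max(cl$arclength),
          "interval outside the geometry")
  if (is.null(t)) t <- field$peak_systole_time
  stop_if(is.null(t), "no peak-systole time on the field; pass 't'")

  s_grid <- seq(interval[1], interval[2], length.out = n_s + 2)[2:(n_s + 1)]
  at <- centerline_at(cl, s_grid)
  radii <- 0.98 * centerline_diameter(cl, s_grid) / 2
  vfrac <- (seq_len(n_r) - 0.5) / n_r
  chi <- (seq_len(n_chi) - 1) / n_chi * 2 * pi

  pts <- matrix(0, n_s * n_r * n_chi, 3)
  tg_rep <- matrix(0, n_s * n_r * n_chi, 3)
  row <- 1L
  for (i in seq_len(n_s)) {
    bb <- plane_basis(at$tangent[i, ])
    for (j in seq_len(n_r)) {
      rho <- radii[i] * sqrt(vfrac[j])
      ring <- matrix(at$point[i, ], n_chi, 3, byrow = TRUE) +
        rho * (outer(cos(chi), bb$e1) + outer(sin(chi), bb$e2))
      pts[row:(row + n_chi - 1L), ] <- ring
      tg_rep[row:(row + n_chi - 1L), ] <-
        matrix(at$tangent[i, ], n_chi, 3, byrow = TRUE)
      row <- row + n_chi
    }
  }
  vel <- field$evaluate(pts, t)
  axial <- rowSums(vel * tg_rep)
  stop_if(length(axial) == 0, "empty sample set")
  scale <- max(abs(axial), 1e-12)
  frac <- mean(axial < -1e-9 * scale)
  list(fraction = frac, present = frac > threshold,
       n_points = length(axial))
}

#' Classify the regional WSS pattern
#'
#' Labels a subject by the region of maximum TAWSS: `distal_AA` gives
#' `distal_AA_peak`, `arch` gives `arch_peak`, anything else `other`.
#' Exact ties are broken toward the more distal region.
#'
#' @param tawss_by_region Named numeric vector over the five regions.
#' @return One of `"distal_AA_peak"`, `"arch_peak"`, `"other"`.
#' @export
wss_pattern <- function(tawss_by_region) {
  stop_if(!all(REGION_ORDER %in% names(tawss_by_region)),
          "all five regions are required: ",
          paste(REGION_ORDER, collapse = ", "))
  v <- tawss_by_region[REGION_ORDER]
  mx <- max(v)
  winners <- which(v >= mx - 1e-12 * max(abs(mx), 1))
  peak <- REGION_ORDER[max(winners)]   # ties toward the more distal region
  switch(peak, distal_AA = "distal_AA_peak", arch = "arch_peak", "other")
}
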
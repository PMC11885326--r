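# Synthetic time-periodic velocity fields on tube geometries: a
# flux-consistent axial profile with an optional near-wall shear envelope
# and a phenotype-controlled recirculation bubble, replacing a 3-D CFD
# solve for metric computation.

#' Recirculation bubble specification
#'
#' @param interval Arclength interval (cm), typically planes 2-3.
#' @param strength Peak reverse axial velocity as a fraction of the local
#'   mean forward velocity (>= 0).
#' @param swirl Tangential velocity amplitude fraction.
#' @return An object of class `recirculation_spec`.
#' @export
recirculation_spec <- function(interval, strength, swirl = 0.5 * strength) {
  stop_if(length(interval) != 2 || diff(interval) <= 0,
          "'interval' must be an increasing (start, end) pair")
  stop_if(strength < 0, "'strength' must be >= 0")
  structure(list(interval = as.numeric(interval), strength = strength,
                 swirl = swirl),
            class = "recirculation_spec")
}

#' Construct a velocity-field container
#'
#' Wraps an arbitrary evaluator so analytic fields (uniform, solid-body
#' rotation, Poiseuille) can flow through the same metric code as the
#' synthetic aortic fields.
#'
#' @param evaluate Function `(points, t)` returning an n x 3 velocity
#'   matrix (cm/s) for an n x 3 point matrix.
#' @param period Cardiac period (s).
#' @param lumen Function `(points)` returning a logical inside-lumen mask.
#' @param n_frames Default frames per cycle for time quadrature.
#' @param local_radius Optional function `(points)` returning the local
#'   lumen radius (cm) at each point (used for default wall offsets).
#' @param peak_systole_time Optional instant of maximum inflow (s).
#' @param meta Optional list of extra fields.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(evaluate, period, lumen, n_frames = 40,
                           local_radius = NULL, peak_systole_time = NULL,
                           meta = list()) {
  structure(c(list(evaluate = evaluate, period = period, lumen = lumen,
                   n_frames = n_frames, local_radius = local_radius,
                   peak_systole_time = peak_systole_time), meta),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: T = %.3f s, %d frames/cycle\n",
              x$period, x$n_frames))
  invisible(x)
}

# outer-curvature unit direction per centerline point (zero where straight)
centerline_outer_direction <- function(cl) {
  tg <- cl$tangent
  n <- nrow(tg)
  dT <- rbind(tg[2, ] - tg[1, ], tg[3:n, ] - tg[1:(n - 2), ],
              tg[n, ] - tg[n - 1, ])
  dT <- dT - tg * rowSums(dT * tg)
  nrm <- row_norms(dT)
  out <- -dT / pmax(nrm, .Machine$double.eps)
  out[nrm < 1e-8, ] <- 0
  out
}

#' Generate a synthetic velocity field on a tube geometry
#'
#' The axial component follows a generalized Poiseuille profile
#' `u = U (m+2)/m (1 - (rho/r)^m)` along the local centerline tangent, with
#' the local radius taken from the centerline diameter profile and the
#' amplitude scaled at every instant so the cross-sectional flux equals
#' Q(t) at every station. The profile exponent map `shear_envelope(s)`
#' (default 2 everywhere, the exact parabolic profile) lets the wall shear
#' vary axially at fixed flux, emulating the impingement-driven shear peak
#' of developed aortic flow; with the default the field reduces to exact
#' quasi-steady Poiseuille flow.
#'
#' A recirculation bubble can be superposed on an arclength interval: an
#' axial deficit reversing the flow near the outer-curvature wall (peak
#' reverse velocity = `strength` times the local mean velocity) plus a
#' tangential swirl, with a compensating forward component biased toward
#' the inner wall so every cross-section still integrates to Q(t) exactly.
#' The bubble envelope rises and falls smoothly over the interval
#' (`sin^2` in normalized arclength).
#'
#' @param cl An `aorta_centerline`.
#' @param w An `inflow_waveform` (already scaled to the cardiac output).
#' @param recirc A `recirculation_spec`, or NULL for none.
#' @param shear_envelope Function of arclength returning the local profile
#'   exponent (>= 2), or NULL for the parabolic default.
#' @param n_frames Frames per cycle for downstream time quadrature.
#' @param seed Recorded for provenance; the construction is deterministic.
#' @return A `velocity_field`.
#' @export
generate_field <- function(cl, w, recirc = NULL, shear_envelope = NULL,
                           n_frames = 40, seed = 1L) {
  s_max <- max(cl$arclength)
  if (!is.null(recirc)) {
    stop_if(recirc$interval[1] < 0 || recirc$interval[2] > s_max,
            "recirculation interval outside the geometry")
  }
  outer_dir <- centerline_outer_direction(cl)
  peak_t <- w$time[which.max(w$flow)]

  eval_fun <- function(points, t) {
    points <- matrix(as.numeric(points), ncol = 3)
    pr <- project_to_centerline(cl, points)
    r <- centerline_diameter(cl, pr$s) / 2
    x <- pr$radius / r
    inside <- x < 1
    at <- centerline_at(cl, pr$s)
    qt <- waveform_at(w, t)
    ubar <- qt / (pi * r^2)
    m <- if (is.null(shear_envelope)) rep(2, length(r)) else
      pmax(2, shear_envelope(pr$s))
    u_ax <- ubar * (m + 2) / m * (1 - pmin(x, 1)^m)
    vel <- at$tangent * u_ax

    if (!is.null(recirc) && recirc$strength > 0) {
      sa <- recirc$interval[1]; sb <- recirc$interval[2]
      u01 <- (pr$s - sa) / (sb - sa)
      act <- inside & u01 > 0 & u01 < 1
      if (any(act)) {
        B <- numeric(length(u01))
        B[act] <- sin(pi * pmin(u01[act], 1))^2
        # angular weight relative to the outer-curvature wall
        odir <- cbind(
          interp_arclength(cl$arclength, outer_dir[, 1], pr$s),
          interp_arclength(cl$arclength, outer_dir[, 2], pr$s),
          interp_arclength(cl$arclength, outer_dir[, 3], pr$s))
        onorm <- row_norms(odir)
        odir <- odir / pmax(onorm, .Machine$double.eps)
        # straight sections: fall back to a fixed transverse direction
        fallback <- onorm < 0.5
        if (any(fallback)) {
          tg <- at$tangent[fallback, , drop = FALSE]
          ref <- matrix(rep(c(0, 1, 0), each = sum(fallback)), ncol = 3)
          swap <- abs(rowSums(ref * tg)) > 0.9
          ref[swap, ] <- matrix(rep(c(1, 0, 0), each = sum(swap)),
                                ncol = 3)
          v <- ref - tg * rowSums(ref * tg)
          odir[fallback, ] <- normalize_rows(v)
        }
        radial <- points - at$point
        rad_n <- normalize_rows(radial)
        cos_chi <- rowSums(rad_n * odir)
        g <- (1 + cos_chi) / 2
        h <- 4 * x^2 * (1 - pmin(x, 1)^2)
        s_ <- recirc$strength
        u_para <- 2 * ubar * (1 - pmin(x, 1)^2)
        deficit <- (u_para + s_ * ubar) * sqrt(B * pmax(g, 0)) * h
        # flux removed by the deficit at this station, restored by a
        # forward parabolic component confined to the inner-curvature half
        # (weight 1 - g vanishes at the bubble center, so the compensation
        # does not cancel the reversal)
        dQ <- qt * sqrt(B) * 4 * (1 + s_) / (3 * pi)
        comp <- (4 * dQ / (pi * r^2)) * (1 - g) * (1 - pmin(x, 1)^2)
        vel <- vel + at$tangent * (comp - deficit)
        if (recirc$swirl > 0) {
          e_theta <- cbind(
            at$tangent[, 2] * rad_n[, 3] - at$tangent[, 3] * rad_n[, 2],
            at$tangent[, 3] * rad_n[, 1] - at$tangent[, 1] * rad_n[, 3],
            at$tangent[, 1] * rad_n[, 2] - at$tangent[, 2] * rad_n[, 1])
          u_theta <- recirc$swirl * ubar * sqrt(B * pmax(g, 0)) *
            (x * (1 - pmin(x, 1)^2)) / 0.3849
          vel <- vel + e_theta * u_theta
        }
      }
    }
    vel[!inside, ] <- 0
    vel
  }

  lumen_fun <- function(points) {
    points <- matrix(as.numeric(points), ncol = 3)
    pr <- project_to_centerline(cl, points)
    r <- centerline_diameter(cl, pr$s) / 2
    pr$radius < r & pr$s > 0 & pr$s < s_max
  }
  radius_fun <- function(points) {
    pr <- project_to_centerline(cl, matrix(as.numeric(points), ncol = 3))
    centerline_diameter(cl, pr$s) / 2
  }

  velocity_field(eval_fun, period = w$period, lumen = lumen_fun,
                 n_frames = n_frames, local_radius = radius_fun,
                 peak_systole_time = peak_t,
                 meta = list(centerline = cl, waveform = w,
                             recirc = recirc, seed = seed))
}

# orthonormal in-plane basis for a unit normal
plane_basis <- function(normal) {
  ref <- c(0, 1, 0)
  if (abs(sum(ref * normal)) > 0.9) ref <- c(1, 0, 0)
  e1 <- ref - sum(ref * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Sample a velocity field on a slice plane
#'
#' Regular `n_grid` x `n_grid` grid spanning the plane's local diameter
#' (with a 5% margin), masked to the lumen cross-section.
#'
#' @param field A `velocity_field`.
#' @param plane A `slice_plane`.
#' @param n_grid Grid resolution per side (>= 8).
#' @param t Time (s) of the sample.
#' @return List with `points` (n x 3), `mask`, `velocity` (n x 3, zero
#'   outside the mask), `u`, `v` grid coordinates and the plane basis.
#' @export
sample_on_plane <- function(field, plane, n_grid = 40, t = 0) {
  stop_if(n_grid < 8, "'n_grid' too small for a resolved section")
  b <- plane_basis(plane$normal)
  half <- 0.525 * plane$diameter
  uu <- seq(-half, half, length.out = n_grid)
  grid <- expand.grid(u = uu, v = uu)
  pts <- matrix(plane$origin, nrow(grid), 3, byrow = TRUE) +
    outer(grid$u, b$e1) + outer(grid$v, b$e2)
  mask <- field$lumen(pts)
  stop_if(!any(mask), "plane lies outside the lumen")
  vel <- matrix(0, nrow(grid), 3)
  vel[mask, ] <- field$evaluate(pts[mask, , drop = FALSE], t)
  list(points = pts, mask = mask, velocity = vel,
       u = grid$u, v = grid$v, basis = b, cell = uu[2] - uu[1])
}

#' Sample near-wall tangential velocity
#'
#' For each requested wall triangle, evaluates the velocity at the centroid
#' offset inward by `eps` along the inward normal, subtracts the velocity
#' at the wall anchor (the centroid itself) and projects the difference
#' onto the wall tangent plane. With `eps = 0` the result is exactly zero,
#' consistent with no-slip.
#'
#' @param field A `velocity_field`.
#' @param surf An `aorta_surface`.
#' @param eps Wall offset(s) in cm (scalar or per-triangle).
#' @param triangles Integer triangle indices (default all).
#' @param t Time (s).
#' @return List with `tangential` (n x 3 relative tangential velocity),
#'   `speed`, `eps`, `area`, and `skipped` (offset point left the lumen).
#' @export
sample_near_wall <- function(field, surf, eps, triangles = NULL, t = 0) {
  geo <- triangle_geometry(surf)
  if (is.null(triangles)) triangles <- seq_len(nrow(surf$triangles))
  cen <- geo$centroid[triangles, , drop = FALSE]
  nrm <- geo$normal[triangles, , drop = FALSE]
  eps <- rep_len(eps, length(triangles))
  stop_if(any(eps < 0), "'eps' must be >= 0")
  off <- cen - nrm * eps
  inside <- field$lumen(off)
  v_off <- matrix(0, length(triangles), 3)
  if (any(inside))
    v_off[inside, ] <- field$evaluate(off[inside, , drop = FALSE], t)
  v_wall <- field$evaluate(cen, t)
  rel <- v_off - v_wall
  rel <- rel - nrm * rowSums(rel * nrm)
  rel[!inside, ] <- NA_real_
  list(tangential = rel, speed = row_norms(rel), eps = eps,
       area = geo$area[triangles], skipped = !inside)
}
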
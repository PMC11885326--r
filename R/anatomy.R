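# Synthetic aortic anatomy: phenotype parameters, centerline + lofted tube
# surface, measurement planes, wall regions, arch angle and level diameters.

#' Phenotype parameters for the synthetic aorta generator
#'
#' Bundles the anatomical knobs that distinguish the three dilation
#' phenotypes: the aortic arch angle, the four root/ascending level diameters
#' (annulus, sinus of Valsalva, sino-tubular junction, mid-ascending aorta)
#' and the recirculation strength used by the synthetic flow-field generator.
#'
#' @param group One of `"A_severe"`, `"B_mild"`, `"C_normal"`.
#' @param arch_angle_deg Aortic arch angle in degrees, in (0, 180).
#' @param annulus_d,sinus_d,stj_d,midAA_d Level diameters in mm.
#' @param recirculation_strength Peak reverse axial velocity in the arch
#'   recirculation bubble, as a fraction of the local mean forward velocity.
#'   Must be 0 for the normal phenotype.
#' @return An object of class `phenotype_params`.
#' @export
phenotype_params <- function(group,
                             arch_angle_deg,
                             annulus_d, sinus_d, stj_d, midAA_d,
                             recirculation_strength = 0) {
  group <- match.arg(group, c("A_severe", "B_mild", "C_normal"))
  d <- c(annulus_d = annulus_d, sinus_d = sinus_d,
         stj_d = stj_d, midAA_d = midAA_d)
  check_positive(d, "level diameters")
  stop_if(!is.finite(arch_angle_deg) || arch_angle_deg <= 0 ||
            arch_angle_deg >= 180,
          "'arch_angle_deg' must lie strictly between 0 and 180 degrees")
  stop_if(recirculation_strength < 0,
          "'recirculation_strength' must be >= 0")
  stop_if(group == "C_normal" && recirculation_strength != 0,
          "recirculation_strength must be 0 for the C_normal phenotype")
  structure(list(group = group,
                 arch_angle_deg = arch_angle_deg,
                 annulus_d = annulus_d, sinus_d = sinus_d,
                 stj_d = stj_d, midAA_d = midAA_d,
                 recirculation_strength = recirculation_strength),
            class = "phenotype_params")
}

#' Default phenotype parameters per dilation group
#'
#' Group medians: arch angles and the four level diameters follow the study
#' cohort medians for each group; the recirculation strength encodes the
#' qualitative flow finding that a recirculation pocket is present and
#' pronounced in the severe group, weak in the mild group and absent in
#' controls.
#'
#' @param group One of `"A_severe"`, `"B_mild"`, `"C_normal"`.
#' @return A `phenotype_params` object.
#' @export
phenotype_defaults <- function(group = c("A_severe", "B_mild", "C_normal")) {
  group <- match.arg(group)
  switch(group,
    A_severe = phenotype_params("A_severe", 72.3, 29.6, 38.7, 29.8, 25.0,
                                recirculation_strength = 1.2),
    B_mild   = phenotype_params("B_mild", 76.6, 24.5, 28.4, 23.3, 23.9,
                                recirculation_strength = 0.3),
    C_normal = phenotype_params("C_normal", 97.3, 22.1, 30.2, 26.0, 24.2,
                                recirculation_strength = 0))
}

#' Construct a centerline object
#'
#' @param points n x 3 matrix of ordered coordinates (cm).
#' @param local_diameter Local lumen diameter (cm) per point.
#' @return An object of class `aorta_centerline` with fields `points`,
#'   `arclength`, `tangent`, `local_diameter`.
#' @export
aorta_centerline <- function(points, local_diameter) {
  points <- as.matrix(points)
  stop_if(ncol(points) != 3, "'points' must be an n x 3 matrix")
  n <- nrow(points)
  stop_if(n < 50, "a centerline needs at least 50 points")
  seg <- diff(points)
  ds <- row_norms(seg)
  stop_if(any(ds <= 0), "centerline arclength must be strictly increasing")
  arclength <- c(0, cumsum(ds))
  # central-difference tangents, one-sided at the ends
  tangent <- rbind(points[2, ] - points[1, ],
                   points[3:n, ] - points[1:(n - 2), ],
                   points[n, ] - points[n - 1, ])
  tangent <- normalize_rows(tangent)
  local_diameter <- rep_len(local_diameter, n)
  check_positive(local_diameter, "local_diameter")
  structure(list(points = points, arclength = arclength,
                 tangent = tangent, local_diameter = local_diameter),
            class = "aorta_centerline")
}

#' @export
print.aorta_centerline <- function(x, ...) {
  cat(sprintf("aorta_centerline: %d points, length %.2f cm, diameter %.2f-%.2f cm\n",
              nrow(x$points), max(x$arclength),
              min(x$local_diameter), max(x$local_diameter)))
  invisible(x)
}

# Local diameter (cm) at arbitrary arclength
centerline_diameter <- function(cl, s) {
  interp_arclength(cl$arclength, cl$local_diameter, s)
}

# Point and unit tangent at arbitrary arclength
centerline_at <- function(cl, s) {
  p <- cbind(interp_arclength(cl$arclength, cl$points[, 1], s),
             interp_arclength(cl$arclength, cl$points[, 2], s),
             interp_arclength(cl$arclength, cl$points[, 3], s))
  tg <- cbind(interp_arclength(cl$arclength, cl$tangent[, 1], s),
              interp_arclength(cl$arclength, cl$tangent[, 2], s),
              interp_arclength(cl$arclength, cl$tangent[, 3], s))
  list(point = p, tangent = normalize_rows(tg))
}

#' Project points onto a centerline
#'
#' Nearest-segment projection, vectorized. Used for region assignment and
#' for the tube coordinates (arclength, radius) of the velocity field.
#'
#' @param cl An `aorta_centerline`.
#' @param pts n x 3 matrix of points (cm).
#' @return List with `s` (projected arclength), `radius` (distance to the
#'   projected axis point) and `index` (nearest centerline vertex).
#' @export
project_to_centerline <- function(cl, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  P <- cl$points
  n <- nrow(P)
  npts <- nrow(pts)
  # coarse nearest vertex on a strided subsample, then a vectorized local
  # refinement window
  stride <- max(1L, as.integer(floor(n / 80)))
  coarse_idx <- seq(1L, n, by = stride)
  Pc <- P[coarse_idx, , drop = FALSE]
  pc2 <- rowSums(Pc * Pc)
  idx <- integer(npts)
  chunk <- 50000L
  win <- stride + 2L
  offs <- -win:win
  for (lo in seq(1L, npts, by = chunk)) {
    hi <- min(lo + chunk - 1L, npts)
    pp <- pts[lo:hi, , drop = FALSE]
    d2 <- outer(rowSums(pp * pp), pc2, "+") - 2 * pp %*% t(Pc)
    ci <- coarse_idx[max.col(-d2, ties.method = "first")]
    # refinement: all window candidates at once via index matrices
    cand <- pmin(pmax(outer(ci, offs, "+"), 1L), n)
    dd <- (matrix(P[cand, 1], length(ci)) - pp[, 1])^2 +
          (matrix(P[cand, 2], length(ci)) - pp[, 2])^2 +
          (matrix(P[cand, 3], length(ci)) - pp[, 3])^2
    idx[lo:hi] <- cand[cbind(seq_along(ci), max.col(-dd,
                                                    ties.method = "first"))]
  }
  # project onto the two segments adjacent to the nearest vertex
  i0 <- pmax(idx - 1L, 1L)
  i1 <- pmin(idx + 1L, n)
  seg_proj <- function(ia, ib) {
    a <- P[ia, , drop = FALSE]
    ab <- P[ib, , drop = FALSE] - a
    len2 <- pmax(rowSums(ab * ab), .Machine$double.eps)
    tt <- pmin(1, pmax(0, rowSums((pts - a) * ab) / len2))
    q <- a + ab * tt
    list(t = tt, d = row_norms(pts - q),
         s = cl$arclength[ia] + tt * (cl$arclength[ib] - cl$arclength[ia]))
  }
  prA <- seg_proj(i0, idx)
  prB <- seg_proj(idx, i1)
  d_vert <- row_norms(pts - P[idx, , drop = FALSE])
  r_out <- pmin(d_vert, prA$d, prB$d)
  s_out <- ifelse(prA$d <= prB$d,
                  ifelse(prA$d <= d_vert, prA$s, cl$arclength[idx]),
                  ifelse(prB$d <= d_vert, prB$s, cl$arclength[idx]))
  list(s = s_out, radius = r_out, index = idx)
}

#' Construct a triangulated tube surface
#'
#' @param vertices n x 3 matrix (cm).
#' @param triangles m x 3 integer matrix of vertex indices (1-based),
#'   oriented with outward normals.
#' @param landmarks Named numeric vector of arclength positions (cm).
#' @return An object of class `aorta_surface`.
#' @export
aorta_surface <- function(vertices, triangles, landmarks = numeric()) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stop_if(ncol(vertices) != 3, "'vertices' must be n x 3")
  stop_if(min(triangles) < 1 || max(triangles) > nrow(vertices),
          "triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 landmarks = landmarks),
            class = "aorta_surface")
}

#' @export
print.aorta_surface <- function(x, ...) {
  cat(sprintf("aorta_surface: %d vertices, %d triangles, %d landmarks\n",
              nrow(x$vertices), nrow(x$triangles), length(x$landmarks)))
  if (length(x$landmarks))
    cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  invisible(x)
}

# Triangle centroids, areas and outward normals
triangle_geometry <- function(surf) {
  v1 <- surf$vertices[surf$triangles[, 1], , drop = FALSE]
  v2 <- surf$vertices[surf$triangles[, 2], , drop = FALSE]
  v3 <- surf$vertices[surf$triangles[, 3], , drop = FALSE]
  centroid <- (v1 + v2 + v3) / 3
  e1 <- v2 - v1; e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- row_norms(cr) / 2
  normal <- normalize_rows(cr)
  list(centroid = centroid, area = area, normal = normal)
}

# -------------------------------------------------------------------------
# Arch construction. The apex is a circular arc of radius
#   R_c = d / (2 cos^2(theta/2)),
# for which the tangent-offset angle measurement returns exactly theta:
# the offset line at depth d (one apex diameter) crosses the arc at
# half-width w = sqrt(2 R_c d - d^2) = d tan(theta/2). The arc spans just
# past the crossing depth (angular extent pi - theta plus a margin; acute
# "gothic" angles overhang slightly), and each end is blended by a small
# circular fillet onto a vertical limb. Everything is planar (x-z).
build_arch_centerline <- function(theta_deg, d_apex, tilt_asc = 12 * pi / 180) {
  theta <- theta_deg * pi / 180
  rc <- d_apex / (2 * cos(theta / 2)^2)
  phi_arc <- (pi - theta) + 0.05
  stop_if(phi_arc >= 2.1, "arch angle too acute for the apex construction")
  gammaE <- pi / 2 - phi_arc        # tangent tilt from vertical at arc end
  rb <- 0.5 * d_apex                # fillet radius

  # one half in (x, z), apex at origin; gamma = tangent angle from
  # straight-down, tangent t(gamma) = (sin g, -cos g); the limb below the
  # fillet runs at a fixed tilt gamma_t (0 = vertical)
  arc_pt <- function(psi) c(rc * sin(psi), -rc * (1 - cos(psi)))
  make_half <- function(gamma_t) {
    lb <- rb * abs(gamma_t - gammaE)
    E <- arc_pt(phi_arc)
    tE <- c(sin(gammaE), -cos(gammaE))
    if (gammaE >= gamma_t) {        # turn clockwise onto the limb
      center <- E + rb * c(tE[2], -tE[1])
      blend_pt <- function(g) center - rb * c(-cos(g), -sin(g))
    } else {                        # turn counter-clockwise
      center <- E + rb * c(-tE[2], tE[1])
      blend_pt <- function(g) center - rb * c(cos(g), sin(g))
    }
    V <- blend_pt(gamma_t)          # start of the straight limb
    t_limb <- c(sin(gamma_t), -cos(gamma_t))
    arc_len <- rc * phi_arc
    list(len_to_limb = arc_len + lb, xz = function(s) {
      if (s <= arc_len) return(arc_pt(s / rc))
      if (s <= arc_len + lb) {
        g <- gammaE + (gamma_t - gammaE) * (s - arc_len) / lb
        return(blend_pt(g))
      }
      V + (s - arc_len - lb) * t_limb
    })
  }
  desc <- make_half(0)
  # ascending limb leans away from the descending limb (in half
  # coordinates +x, mirrored to -x globally) so a dilated sinus clears the
  # descending aorta even for acute hairpin arches
  asc <- make_half(tilt_asc)
  list(half_desc = desc$xz, half_asc = asc$xz, rc = rc, phi_arc = phi_arc,
       arc_half_len = rc * phi_arc,
       blend_desc = desc$len_to_limb - rc * phi_arc,
       blend_asc = asc$len_to_limb - rc * phi_arc)
}

#' Build a synthetic aorta for a phenotype
#'
#' Constructs a planar candy-cane centerline (straight ascending limb,
#' circular-apex arch with straight tangent limbs, straight descending limb)
#' whose measured arch angle equals the requested one by construction, and
#' lofts a circular-section tube along it. The diameter profile passes
#' exactly through the four level diameters (with a smooth sinus bulge) and
#' continues at the mid-ascending value distally. Branch ostia
#' (brachiocephalic, left carotid, left subclavian) are marked as arclength
#' landmarks on the arch; branch tubes are not modeled, as downstream flow
#' split is handled by the 0-D network.
#'
#' The construction is fully parametric: a fixed `seed` trivially yields
#' identical output.
#'
#' @param params A `phenotype_params` object.
#' @param seed Integer, recorded for provenance (the loft is deterministic).
#' @param n_points Number of centerline points.
#' @param n_axial,n_theta Surface loft resolution (rings, points per ring).
#' @return List with elements `centerline` (`aorta_centerline`) and
#'   `surface` (`aorta_surface`).
#' @export
build_synthetic_aorta <- function(params, seed = 1L,
                                  n_points = 600, n_axial = 160,
                                  n_theta = 32) {
  stop_if(!inherits(params, "phenotype_params"),
          "'params' must be a phenotype_params object")
  # mm -> cm
  D_a <- params$annulus_d / MM_PER_CM
  D_sin <- params$sinus_d / MM_PER_CM
  D_stj <- params$stj_d / MM_PER_CM
  D_mid <- params$midAA_d / MM_PER_CM

  # landmark stations along the ascending limb; a short constant-diameter
  # stub precedes the annulus so its cross-section is cleanly measurable
  s_ann <- 0.4 * D_a
  s_sin <- s_ann + 0.8 * D_a
  s_stj <- s_ann + 1.5 * D_a
  L_asc <- s_ann + max(3.2 * D_a, 1.5 * D_a + 1.2 * D_mid)
  s_mid <- (s_stj + L_asc) / 2

  # arch: apex arc sized for the exact target angle, blended onto
  # vertical ascending/descending limbs
  d_apex <- D_mid
  arch <- build_arch_centerline(params$arch_angle_deg, d_apex)
  half_asc <- arch$arc_half_len + arch$blend_asc
  half_desc <- arch$arc_half_len + arch$blend_desc
  L_desc <- 4.5 * D_mid
  s_apex <- L_asc + half_asc          # annulus -> apex arclength
  s_total <- s_apex + half_desc + L_desc
  stop_if(L_asc < half_asc + 0.5,
          "ascending limb too short for this arch geometry")

  s_grid <- seq(0, s_total, length.out = n_points)
  point_at <- function(s) {
    u <- s - s_apex                   # signed arclength from the apex
    if (u >= 0) {
      xz <- arch$half_desc(u)         # descending half
      c(xz[1], 0, xz[2])
    } else {
      xz <- arch$half_asc(-u)         # ascending half, mirrored in x
      c(-xz[1], 0, xz[2])
    }
  }
  pts <- t(vapply(s_grid, point_at, numeric(3)))
  arc_start <- s_apex - arch$arc_half_len
  arc_len <- 2 * arch$arc_half_len

  # diameter profile: natural spline through the four levels, constant
  # at the mid-ascending value beyond (so equal level inputs give an
  # exactly constant-radius tube)
  knots_s <- c(0, s_ann, s_sin, s_stj, s_mid, s_mid + 0.6 * D_mid, s_total)
  knots_d <- c(D_a, D_a, D_sin, D_stj, D_mid, D_mid, D_mid)
  prof <- stats::splinefun(knots_s, knots_d, method = "natural")
  dia <- prof(s_grid)
  dia[s_grid >= s_mid + 0.6 * D_mid] <- D_mid
  stop_if(any(dia <= 0), "degenerate diameter profile (non-positive)")

  cl <- aorta_centerline(pts, dia)

  landmarks <- c(annulus = s_ann, sinus = s_sin, stj = s_stj, mid_AA = s_mid,
                 brachiocephalic = arc_start + 0.30 * arc_len,
                 left_carotid = arc_start + 0.50 * arc_len,
                 left_subclavian = arc_start + 0.70 * arc_len)

  surf <- loft_tube(cl, n_axial = n_axial, n_theta = n_theta,
                    landmarks = landmarks)
  list(centerline = cl, surface = surf, params = params, seed = seed)
}

#' Loft a circular-section tube surface along a centerline
#'
#' Rotation-minimizing frames are propagated by parallel transport so the
#' loft is twist-free for non-planar centerlines too.
#'
#' @param cl An `aorta_centerline`.
#' @param n_axial Number of rings.
#' @param n_theta Points per ring.
#' @param landmarks Named arclength positions attached to the surface.
#' @return An `aorta_surface` with outward-oriented triangles.
#' @export
loft_tube <- function(cl, n_axial = 160, n_theta = 32,
                      landmarks = numeric()) {
  stop_if(n_axial < 2 || n_theta < 3, "loft resolution too coarse")
  s_rings <- seq(0, max(cl$arclength), length.out = n_axial)
  # snap a ring onto every landmark station so level sections are exact
  if (length(landmarks) > 0) {
    s_rings <- sort(unique(c(s_rings, landmarks)))
    s_rings <- s_rings[s_rings >= 0 & s_rings <= max(cl$arclength)]
    n_axial <- length(s_rings)
  }
  at <- centerline_at(cl, s_rings)
  radii <- centerline_diameter(cl, s_rings) / 2
  tg <- at$tangent

  # parallel-transport frame
  nrm <- matrix(0, n_axial, 3)
  ref <- c(0, 1, 0)
  if (abs(sum(ref * tg[1, ])) > 0.9) ref <- c(1, 0, 0)
  n0 <- ref - sum(ref * tg[1, ]) * tg[1, ]
  nrm[1, ] <- n0 / sqrt(sum(n0 * n0))
  for (i in 2:n_axial) {
    v <- nrm[i - 1, ] - sum(nrm[i - 1, ] * tg[i, ]) * tg[i, ]
    nrm[i, ] <- v / sqrt(sum(v * v))
  }
  binrm <- cbind(tg[, 2] * nrm[, 3] - tg[, 3] * nrm[, 2],
                 tg[, 3] * nrm[, 1] - tg[, 1] * nrm[, 3],
                 tg[, 1] * nrm[, 2] - tg[, 2] * nrm[, 1])

  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  verts <- matrix(0, n_axial * n_theta, 3)
  for (i in seq_len(n_axial)) {
    ring <- matrix(at$point[i, ], n_theta, 3, byrow = TRUE) +
      radii[i] * (outer(cos(theta), nrm[i, ]) + outer(sin(theta), binrm[i, ]))
    verts[((i - 1) * n_theta + 1):(i * n_theta), ] <- ring
  }

  # quad strips -> triangles; orientation fixed below by an outwardness test
  tris <- matrix(0L, 2 * (n_axial - 1) * n_theta, 3)
  k <- 1L
  for (i in seq_len(n_axial - 1)) {
    base <- (i - 1L) * n_theta
    for (j in seq_len(n_theta)) {
      jn <- if (j == n_theta) 1L else j + 1L
      a <- base + j; b <- base + jn
      c_ <- base + n_theta + j; d_ <- base + n_theta + jn
      tris[k, ] <- c(a, c_, b); k <- k + 1L
      tris[k, ] <- c(b, c_, d_); k <- k + 1L
    }
  }
  surf <- aorta_surface(verts, tris, landmarks)
  # flip orientation if normals point inward on average
  geo <- triangle_geometry(surf)
  pr <- project_to_centerline(cl, geo$centroid[seq(1, nrow(geo$centroid),
                                                   by = 37), , drop = FALSE])
  axis_pt <- centerline_at(cl, pr$s)$point
  radial <- geo$centroid[seq(1, nrow(geo$centroid), by = 37), , drop = FALSE] -
    axis_pt
  if (mean(rowSums(radial * geo$normal[seq(1, nrow(geo$normal), by = 37),
                                       , drop = FALSE])) < 0) {
    surf$triangles <- surf$triangles[, c(1, 3, 2)]
  }
  surf
}

#' Extract the five measurement planes
#'
#' Plane 0 sits one local diameter above the annulus slice; plane 1 one
#' local diameter proximal to the brachiocephalic ostium; plane 2 just
#' before the brachiocephalic ostium; plane 3 just after the left
#' subclavian ostium; plane 4 two local diameters beyond plane 3. "One
#' diameter" always means the local equivalent diameter at the reference
#' slice; "just before/after" is a fixed fraction (`just_offset`) of that
#' diameter.
#'
#' @param cl An `aorta_centerline`.
#' @param surf An `aorta_surface` carrying the landmark annotations.
#' @param just_offset Offset fraction for the "just before/after" rules.
#' @return A list of five `slice_plane` objects named `plane0`..`plane4`.
#' @export
extract_planes <- function(cl, surf, just_offset = 0.1) {
  lm <- surf$landmarks
  need <- c("annulus", "brachiocephalic", "left_carotid", "left_subclavian")
  missing <- setdiff(need, names(lm))
  stop_if(length(missing) > 0,
          "missing landmarks: ", paste(missing, collapse = ", "))
  ost <- lm[c("brachiocephalic", "left_carotid", "left_subclavian")]
  stop_if(any(diff(ost) <= 0),
          "branch ostia landmarks out of order along arclength")
  s_max <- max(cl$arclength)
  stop_if(any(lm < 0) || any(lm > s_max),
          "landmark arclength outside centerline range")

  D <- function(s) centerline_diameter(cl, s)
  s0 <- lm[["annulus"]] + D(lm[["annulus"]])
  s1 <- lm[["brachiocephalic"]] - D(lm[["brachiocephalic"]])
  s2 <- lm[["brachiocephalic"]] - just_offset * D(lm[["brachiocephalic"]])
  s3 <- lm[["left_subclavian"]] + just_offset * D(lm[["left_subclavian"]])
  s4 <- s3 + 2 * D(s3)
  s_planes <- c(plane0 = s0, plane1 = s1, plane2 = s2, plane3 = s3,
                plane4 = s4)
  stop_if(any(diff(s_planes) <= 0),
          "plane arclengths not strictly increasing; landmarks out of order")
  stop_if(any(s_planes < 0) || any(s_planes > s_max),
          "plane positions fall outside the centerline")

  at <- centerline_at(cl, s_planes)
  planes <- lapply(seq_along(s_planes), function(i) {
    structure(list(label = names(s_planes)[i],
                   arclength = unname(s_planes[i]),
                   origin = at$point[i, ],
                   normal = at$tangent[i, ],
                   diameter = D(s_planes[[i]])),
              class = "slice_plane")
  })
  names(planes) <- names(s_planes)
  planes
}

#' @export
print.slice_plane <- function(x, ...) {
  cat(sprintf("slice_plane %s: s = %.2f cm, D = %.2f cm\n",
              x$label, x$arclength, x$diameter))
  invisible(x)
}

#' Define the five wall regions
#'
#' The root region covers wall triangles whose centerline-projected
#' arclength lies between one local diameter proximal of the sino-tubular
#' junction and the STJ itself. The proximal/distal ascending, arch and
#' descending regions are arclength bands of half-width 0.5 local diameter
#' around planes 1-4. Where bands overlap, a triangle goes to the nearest
#' plane, keeping the regions pairwise disjoint.
#'
#' @param surf An `aorta_surface` (with an `stj` landmark).
#' @param cl An `aorta_centerline`.
#' @param planes Output of [extract_planes()].
#' @return An object of class `wall_regions`: a named list (`root`,
#'   `proximal_AA`, `distal_AA`, `arch`, `descending`) of integer triangle
#'   index vectors, with triangle areas in `attr(,"area")`.
#' @export
define_wall_regions <- function(surf, cl, planes) {
  stop_if(!"stj" %in% names(surf$landmarks), "missing landmark: stj")
  geo <- triangle_geometry(surf)
  pr <- project_to_centerline(cl, geo$centroid)
  s <- pr$s

  s_stj <- surf$landmarks[["stj"]]
  d_stj <- centerline_diameter(cl, s_stj)
  in_root <- s >= (s_stj - d_stj) & s <= s_stj

  band_planes <- c("plane1", "plane2", "plane3", "plane4")
  s_p <- vapply(planes[band_planes], function(p) p$arclength, numeric(1))
  d_p <- vapply(planes[band_planes], function(p) p$diameter, numeric(1))
  dist_mat <- abs(outer(s, s_p, "-"))
  in_band <- sweep(dist_mat, 2, 0.5 * d_p, "<=")
  nearest <- max.col(-dist_mat, ties.method = "first")
  band_of <- ifelse(rowSums(in_band) > 0, nearest, NA_integer_)
  # only keep the nearest-plane assignment if that band actually contains it
  keep <- !is.na(band_of) &
    in_band[cbind(seq_along(s), ifelse(is.na(band_of), 1L, band_of))]
  band_of[!keep] <- NA_integer_

  region_names <- c("root", "proximal_AA", "distal_AA", "arch", "descending")
  assign <- rep(NA_integer_, length(s))
  assign[!is.na(band_of)] <- band_of[!is.na(band_of)] + 1L
  assign[in_root] <- 1L   # root takes precedence over a stray band overlap

  regions <- lapply(seq_along(region_names), function(i) which(assign == i))
  names(regions) <- region_names
  empty <- region_names[vapply(regions, length, integer(1)) == 0]
  stop_if(length(empty) > 0,
          "empty wall region(s): ", paste(empty, collapse = ", "))
  structure(regions, area = geo$area, class = "wall_regions")
}

#' @export
print.wall_regions <- function(x, ...) {
  n <- vapply(x, length, integer(1))
  a <- vapply(seq_along(x), function(i) sum(attr(x, "area")[x[[i]]]),
              numeric(1))
  cat("wall_regions:\n")
  for (i in seq_along(x))
    cat(sprintf("  %-12s %5d triangles, area %.2f cm^2\n", names(x)[i],
                n[i], a[i]))
  invisible(x)
}

#' Measure the aortic arch angle
#'
#' Finds the centerline apex (the point farthest from the end-to-end chord),
#' draws the tangent line there, displaces it by one diameter toward the
#' centerline interior, and returns the angle subtended at the apex by the
#' first crossings of the displaced line with the centerline on each side.
#'
#' @param cl An `aorta_centerline`.
#' @param offset_diameter Displacement (cm); defaults to the local diameter
#'   at the apex.
#' @param up Height axis defining "highest"; geometries from
#'   [build_synthetic_aorta()] (and imported anatomies following the same
#'   convention) are oriented with the arch apex up along +z.
#' @return Arch angle in degrees.
#' @export
measure_arch_angle <- function(cl, offset_diameter = NULL,
                               up = c(0, 0, 1)) {
  P <- cl$points
  n <- nrow(P)
  up <- up / sqrt(sum(up * up))
  h <- as.vector(P %*% up)
  i_apex <- which.max(h)
  span <- max(h) - min(h)
  stop_if(span < 1e-8, "ambiguous height maximum: centerline is flat")
  near_max <- which(h > max(h) - 1e-6 * span)
  stop_if(any(abs(diff(sort(near_max))) > 2),
          "ambiguous height maximum: multiple separated apex candidates")
  stop_if(i_apex <= 2 || i_apex >= n - 1,
          "apex too close to a centerline end")
  A <- P[i_apex, ]
  tangent <- P[i_apex + 1, ] - P[i_apex - 1, ]
  t_hat <- tangent / sqrt(sum(tangent * tangent))
  # offset direction: downward (toward the centerline interior),
  # orthogonal to the apex tangent
  nvec <- -(up - sum(up * t_hat) * t_hat)
  stop_if(sqrt(sum(nvec * nvec)) < 1e-9,
          "apex tangent parallel to the height axis")
  n_hat <- nvec / sqrt(sum(nvec * nvec))

  d <- if (is.null(offset_diameter)) cl$local_diameter[i_apex] else
    offset_diameter
  check_positive(d, "offset_diameter")

  # in-plane coordinates relative to the apex
  xi <- as.vector(sweep(P, 2, A) %*% t_hat)
  eta <- as.vector(sweep(P, 2, A) %*% n_hat)
  # crossings of eta = d, nearest to the apex on each side
  cross_xi <- function(side) {
    idx <- which(diff(sign(eta - d)) != 0)
    if (length(idx) == 0) return(NA_real_)
    xs <- vapply(idx, function(i) {
      w <- (d - eta[i]) / (eta[i + 1] - eta[i])
      xi[i] + w * (xi[i + 1] - xi[i])
    }, numeric(1))
    xs <- if (side < 0) xs[xs < 0] else xs[xs > 0]
    if (length(xs) == 0) return(NA_real_)
    xs[which.min(abs(xs))]
  }
  xb <- cross_xi(-1); xc <- cross_xi(+1)
  stop_if(is.na(xb) || is.na(xc),
          "offset line does not cross the centerline on both sides ",
          "(centerline too short for this offset)")
  vb <- c(xb, d); vc <- c(xc, d)
  ang <- acos(sum(vb * vc) / (sqrt(sum(vb^2)) * sqrt(sum(vc^2))))
  ang * 180 / pi
}

#' Measure a lumen cross-section from the surface mesh
#'
#' Cuts the triangulated wall with the plane perpendicular to the centerline
#' at arclength `s`, chains the intersection into a closed contour and
#' returns the equivalent-circle diameter (from the enclosed area) plus the
#' minimum and maximum caliper diameters.
#'
#' @param surf An `aorta_surface`.
#' @param cl An `aorta_centerline`.
#' @param s Arclength of the cut (cm).
#' @return List with `equiv_d`, `min_caliper`, `max_caliper` (cm).
#' @export
measure_section <- function(surf, cl, s) {
  at <- centerline_at(cl, s)
  o <- at$point[1, ]; nrm <- at$tangent[1, ]
  d_loc <- centerline_diameter(cl, s)

  geo <- triangle_geometry(surf)
  pr <- project_to_centerline(cl, geo$centroid)
  cand <- which(abs(pr$s - s) <= max(0.75 * d_loc, 0.1) &
                  row_norms(sweep(geo$centroid, 2, o)) <= 1.5 * d_loc)
  stop_if(length(cand) == 0, "no wall triangles near the section plane")

  # unique edges of the candidate triangles
  tri <- surf$triangles[cand, , drop = FALSE]
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  edges <- unique(t(apply(edges, 1, sort)))
  vids <- sort(unique(as.vector(edges)))
  hv <- as.vector(sweep(surf$vertices[vids, , drop = FALSE], 2, o) %*% nrm)
  hmap <- stats::setNames(hv, vids)
  tol <- 1e-9 * max(1, d_loc)
  # on-plane vertices contribute directly; strictly crossing edges are
  # interpolated (robust when the cut lands exactly on a vertex ring)
  on_plane <- vids[abs(hmap[as.character(vids)]) <= tol]
  h1 <- hmap[as.character(edges[, 1])]
  h2 <- hmap[as.character(edges[, 2])]
  crossing <- (h1 > tol & h2 < -tol) | (h1 < -tol & h2 > tol)
  pts3 <- surf$vertices[on_plane, , drop = FALSE]
  if (any(crossing)) {
    e <- edges[crossing, , drop = FALSE]
    w <- h1[crossing] / (h1[crossing] - h2[crossing])
    pcross <- surf$vertices[e[, 1], , drop = FALSE] * (1 - w) +
      surf$vertices[e[, 2], , drop = FALSE] * w
    pts3 <- rbind(pts3, pcross)
  }
  stop_if(nrow(pts3) < 8, "non-closed cross-section contour")
  e1 <- c(nrm[2], -nrm[1], 0)
  if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(1, 0, 0)
  e1 <- e1 - sum(e1 * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  u <- as.vector(sweep(pts3, 2, o) %*% e1)
  v2 <- as.vector(sweep(pts3, 2, o) %*% e2)
  uc <- u - mean(u); vc <- v2 - mean(v2)
  ang <- atan2(vc, uc)
  ord <- order(ang)
  ua <- uc[ord]; va <- vc[ord]
  gaps <- diff(c(ang[ord], ang[ord][1] + 2 * pi))
  stop_if(max(gaps) > 1.0, "non-closed cross-section contour")

  # shoelace area
  nn <- length(ua)
  jj <- c(2:nn, 1)
  area <- abs(sum(ua * va[jj] - ua[jj] * va)) / 2
  equiv_d <- 2 * sqrt(area / pi)

  # caliper widths over rotating directions
  alphas <- seq(0, pi, length.out = 181)[-181]
  widths <- vapply(alphas, function(a) {
    proj <- ua * cos(a) + va * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  list(equiv_d = equiv_d, min_caliper = min(widths),
       max_caliper = max(widths))
}

#' Measure the four root/ascending level diameters
#'
#' Annulus, sinus of Valsalva and sino-tubular junction report the
#' equivalent-circle diameter of the lumen cross-section; the mid-ascending
#' aorta reports the mean of the minimum and maximum caliper diameters.
#'
#' @param surf An `aorta_surface` with `annulus`, `sinus`, `stj`, `mid_AA`
#'   landmarks.
#' @param cl An `aorta_centerline`.
#' @return Named numeric vector of diameters in mm.
#' @export
measure_levels <- function(surf, cl) {
  need <- c("annulus", "sinus", "stj", "mid_AA")
  missing <- setdiff(need, names(surf$landmarks))
  stop_if(length(missing) > 0,
          "missing landmarks: ", paste(missing, collapse = ", "))
  s_max <- max(cl$arclength)
  out <- vapply(need, function(lv) {
    s <- surf$landmarks[[lv]]
    # end slices cannot be cut by the mesh; nudge inside by one ring
    s <- min(max(s, 0.01 * s_max), 0.99 * s_max)
    sec <- measure_section(surf, cl, s)
    if (lv == "mid_AA") (sec$min_caliper + sec$max_caliper) / 2 else
      sec$equiv_d
  }, numeric(1))
  out * MM_PER_CM
}
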
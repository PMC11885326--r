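# Body-size normalization and dilation classification: Haycock BSA,
# level-wise Z-scores against a pluggable normative reference, and the
# Z-score group thresholds; synthetic cohort generation.

AORTIC_LEVELS <- c("annulus", "sinus", "stj", "mid_AA")

#' Haycock body surface area
#'
#' BSA (m^2) = 0.024265 * weight^0.5378 * height^0.3964, with weight in kg
#' and height in cm.
#'
#' @param weight_kg Body weight in kg.
#' @param height_cm Height in cm.
#' @return BSA in m^2.
#' @export
haycock_bsa <- function(weight_kg, height_cm) {
  check_positive(weight_kg, "weight_kg")
  check_positive(height_cm, "height_cm")
  0.024265 * weight_kg^0.5378 * height_cm^0.3964
}

#' Build a normative diameter reference model
#'
#' A reference model maps body surface area to the expected mean and
#' standard deviation of each aortic level diameter (mm). Means and SDs
#' must be positive and non-decreasing over the supported BSA domain.
#'
#' @param levels Character vector of level names.
#' @param mean_fun,sd_fun Named lists of functions of BSA (m^2) returning mm.
#' @param bsa_range Supported BSA domain (m^2).
#' @return An object of class `reference_model`.
#' @export
reference_model <- function(levels, mean_fun, sd_fun,
                            bsa_range = c(0.5, 2.5)) {
  stop_if(!all(levels %in% names(mean_fun)) ||
            !all(levels %in% names(sd_fun)),
          "mean_fun and sd_fun must provide every level")
  grid <- seq(bsa_range[1], bsa_range[2], length.out = 41)
  for (lv in levels) {
    m <- mean_fun[[lv]](grid); s <- sd_fun[[lv]](grid)
    stop_if(any(m <= 0) || any(s <= 0),
            "reference mean/sd must be strictly positive (level ", lv, ")")
    stop_if(any(diff(m) < -1e-9) || any(diff(s) < -1e-9),
            "reference mean/sd must be non-decreasing in BSA (level ",
            lv, ")")
  }
  structure(list(levels = levels, mean_fun = mean_fun, sd_fun = sd_fun,
                 bsa_range = bsa_range),
            class = "reference_model")
}

#' Bundled synthetic normative reference
#'
#' An affine-in-BSA reference (constant SD per level) calibrated so that
#' adolescent control diameters score near zero and the dilation-group
#' thresholds land at clinically plausible absolute diameters. It is a
#' synthetic stand-in for a published pediatric reference and is not valid
#' for clinical use; user-supplied references can be loaded with
#' [read_reference_csv()].
#'
#' @return A `reference_model`.
#' @export
synthetic_reference <- function() {
  coefs <- list(
    annulus = c(a = 8.0, b = 8.0, sd = 1.2),
    sinus   = c(a = 12.0, b = 9.0, sd = 2.2),
    stj     = c(a = 10.0, b = 8.0, sd = 2.0),
    mid_AA  = c(a = 10.0, b = 8.5, sd = 2.0))
  mk_mean <- function(p) { force(p); function(bsa) p[["a"]] + p[["b"]] * bsa }
  mk_sd <- function(p) { force(p); function(bsa) rep_len(p[["sd"]],
                                                         length(bsa)) }
  reference_model(AORTIC_LEVELS,
                  mean_fun = lapply(coefs, mk_mean),
                  sd_fun = lapply(coefs, mk_sd))
}

#' Read a reference model from CSV
#'
#' Expects columns `level`, `bsa`, `mean_mm`, `sd_mm`; values are linearly
#' interpolated in BSA within the tabulated range.
#'
#' @param path CSV file path.
#' @return A `reference_model`.
#' @export
read_reference_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "bsa", "mean_mm", "sd_mm")
  stop_if(!all(need %in% names(tab)),
          "reference CSV must have columns: ", paste(need, collapse = ", "))
  levels <- unique(tab$level)
  mk <- function(lv, col) {
    sub <- tab[tab$level == lv, ]
    sub <- sub[order(sub$bsa), ]
    stats::approxfun(sub$bsa, sub[[col]], rule = 1)
  }
  mean_fun <- stats::setNames(lapply(levels, mk, col = "mean_mm"), levels)
  sd_fun <- stats::setNames(lapply(levels, mk, col = "sd_mm"), levels)
  reference_model(levels, mean_fun, sd_fun,
                  bsa_range = range(tab$bsa))
}

#' Z-score of a measured diameter
#'
#' (diameter - mean(BSA)) / sd(BSA) for the given level.
#'
#' @param diameter_mm Measured diameter (mm).
#' @param level Level name present in the reference.
#' @param bsa Body surface area (m^2).
#' @param ref A `reference_model` (default: the bundled synthetic one).
#' @return Dimensionless Z-score.
#' @export
zscore <- function(diameter_mm, level, bsa, ref = synthetic_reference()) {
  stop_if(!level %in% ref$levels, "unknown level: ", level)
  stop_if(bsa < ref$bsa_range[1] || bsa > ref$bsa_range[2],
          sprintf("BSA %.2f outside reference domain [%.2f, %.2f]",
                  bsa, ref$bsa_range[1], ref$bsa_range[2]))
  (diameter_mm - ref$mean_fun[[level]](bsa)) / ref$sd_fun[[level]](bsa)
}

#' Classify dilation severity from level Z-scores
#'
#' Uses the maximum Z across levels ("any component of the aortic root"):
#' severe if max Z >= 4, mild if 2 < max Z < 4, normal if max Z <= 2.
#'
#' @param zscores Named numeric vector of per-level Z-scores.
#' @return List with `value` (`"severe"`, `"mild"` or `"normal"`), `max_z`
#'   and `level_of_max`.
#' @export
classify_dilation <- function(zscores) {
  stop_if(length(zscores) == 0 || all(is.na(zscores)),
          "at least one level Z-score is required")
  zscores <- zscores[!is.na(zscores)]
  i <- which.max(zscores)
  mz <- zscores[[i]]
  value <- if (mz >= 4) "severe" else if (mz > 2) "mild" else "normal"
  list(value = value, max_z = mz,
       level_of_max = if (is.null(names(zscores))) NA_character_ else
         names(zscores)[i])
}

# Anchor-level Z windows that pin each subject's class, plus the group's
# median level-diameter profile (mm); the non-anchor levels scale with the
# anchor so the anatomical shape (sinus bulge included) is preserved.
.group_sampling <- list(
  A_severe = list(anchor = "sinus", window = c(4.2, 6.5), z_cap = Inf,
                  profile = c(annulus = 29.6, sinus = 38.7,
                              stj = 29.8, mid_AA = 25.0)),
  B_mild   = list(anchor = "annulus", window = c(2.6, 3.6), z_cap = 3.8,
                  profile = c(annulus = 24.5, sinus = 28.4,
                              stj = 23.3, mid_AA = 23.9)),
  C_normal = list(anchor = "sinus", window = c(0.5, 1.8), z_cap = 1.9,
                  profile = c(annulus = 22.1, sinus = 30.2,
                              stj = 26.0, mid_AA = 24.2)))

.group_angle_ranges <- list(A_severe = c(68.5, 77.2),
                            B_mild = c(71.1, 85.2),
                            C_normal = c(87.4, 99.0))

#' Generate a synthetic three-group cohort
#'
#' Samples `n_per_group` subjects per dilation group. Ages are uniform on
#' 8-18 years with age-increasing height and weight, cardiac output uniform
#' on 3.8-6 L/min, systolic targets uniform on 100-130 mmHg and diastolic on
#' 60-80 mmHg. Level diameters are drawn by anchoring the group's
#' class-determining level in Z-space inside its class window and scaling
#' the group's median level profile to that anchor (mild jitter, remaining
#' levels capped below the class boundary), so every subject classifies
#' into its intended group by construction while keeping the anatomical
#' shape - sinus bulge included - of its phenotype. Arch angles are drawn
#' uniformly within each group's observed range; recirculation strength is
#' the group default.
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param seed Integer seed; the cohort is a pure function of it.
#' @param ref A `reference_model` used for the Z-to-mm mapping.
#' @return A data frame of class `neoaorta_cohort`, one row per subject.
#' @export
generate_cohort <- function(n_per_group, seed = 1L,
                            ref = synthetic_reference()) {
  stop_if(!is.numeric(n_per_group) || n_per_group < 1,
          "'n_per_group' must be >= 1")
  n_per_group <- as.integer(n_per_group)
  groups <- c("A_severe", "B_mild", "C_normal")
  rows <- list()
  set.seed(as.integer(seed))
  for (g in groups) {
    samp <- .group_sampling[[g]]
    arange <- .group_angle_ranges[[g]]
    strength <- phenotype_defaults(g)$recirculation_strength
    for (i in seq_len(n_per_group)) {
      age <- stats::runif(1, 8, 18)
      height <- 125 + 4.5 * (age - 8) + stats::runif(1, -8, 8)
      weight <- 28 + 3.2 * (age - 8) + stats::runif(1, -6, 10)
      bsa <- haycock_bsa(weight, height)
      co <- stats::runif(1, 3.8, 6.0)
      sys <- stats::runif(1, 100, 130)
      dia <- stats::runif(1, 60, 80)
      # anchor the class-determining level in Z-space, scale the group's
      # median level profile to it (with mild jitter), and cap the
      # non-anchor Z-scores so the intended class is preserved
      z_anchor <- stats::runif(1, samp$window[1], samp$window[2])
      anchor_d <- ref$mean_fun[[samp$anchor]](bsa) +
        z_anchor * ref$sd_fun[[samp$anchor]](bsa)
      f <- anchor_d / samp$profile[[samp$anchor]]
      jit <- stats::runif(length(AORTIC_LEVELS), 0.98, 1.02)
      dmm <- samp$profile[AORTIC_LEVELS] * f * jit
      names(dmm) <- AORTIC_LEVELS
      dmm[samp$anchor] <- anchor_d
      for (lv in setdiff(AORTIC_LEVELS, samp$anchor)) {
        cap <- ref$mean_fun[[lv]](bsa) +
          samp$z_cap * ref$sd_fun[[lv]](bsa)
        dmm[lv] <- min(dmm[[lv]], cap)
      }
      angle <- stats::runif(1, arange[1], arange[2])
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_%02d", sub("_.*", "", g), i),
        group = g, age = age, sex = sample(c("M", "F"), 1),
        weight_kg = weight, height_cm = height, bsa = bsa,
        cardiac_output = co, systolic = sys, diastolic = dia,
        annulus_d = dmm[["annulus"]], sinus_d = dmm[["sinus"]],
        stj_d = dmm[["stj"]], midAA_d = dmm[["mid_AA"]],
        arch_angle_deg = angle, recirculation_strength = strength,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("neoaorta_cohort", "data.frame")
  out
}

#' Phenotype parameters for one cohort row
#'
#' @param subject One row of a [generate_cohort()] data frame.
#' @return A `phenotype_params` object.
#' @export
subject_params <- function(subject) {
  phenotype_params(subject$group, subject$arch_angle_deg,
                   subject$annulus_d, subject$sinus_d, subject$stj_d,
                   subject$midAA_d,
                   recirculation_strength = subject$recirculation_strength)
}
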
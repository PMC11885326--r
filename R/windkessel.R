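# 0-D open-loop lumped-parameter hemodynamics: inflow waveform scaling,
# Murray-law flow distribution, per-outlet 3-element Windkessel (RCR)
# dynamics with cycle-convergence control, and the tuning loop that matches
# target systolic/diastolic pressures.

#' Blood fluid properties
#'
#' Defaults: dynamic viscosity 0.04 poise (dyn s/cm^2) and density
#' 1.06 g/cm^3, the Newtonian blood model of large-vessel CFD; kinematic
#' viscosity is their ratio.
#'
#' @param mu Dynamic viscosity (poise).
#' @param rho Density (g/cm^3).
#' @return List with `mu`, `rho`, `nu` (cm^2/s).
#' @export
fluid_properties <- function(mu = 0.04, rho = 1.06) {
  check_positive(mu, "mu"); check_positive(rho, "rho")
  list(mu = mu, rho = rho, nu = mu / rho)
}

#' Analytic default inflow waveform
#'
#' A two-phase pulse over one cardiac cycle: a systolic half-sine ejection
#' of duration T/3 followed by a small reverse lobe (5% of the systolic
#' amplitude, duration T/10) emulating valve-closure backflow, then zero
#' diastolic flow. Amplitude is normalized to a unit cycle mean; scale to a
#' cardiac output with [scale_waveform()]. A measured waveform can be
#' loaded from CSV with [read_waveform_csv()].
#'
#' @param period Cardiac period T in seconds.
#' @param n Number of samples over one period (first sample repeated last).
#' @return An object of class `inflow_waveform` with fields `period`,
#'   `time`, `flow` (cm^3/s).
#' @export
default_inflow_waveform <- function(period = 0.8, n = 200) {
  check_positive(period, "period")
  t <- seq(0, period, length.out = n + 1)
  ts <- period / 3; td <- period / 10
  q <- ifelse(t <= ts, sin(pi * t / ts),
              ifelse(t <= ts + td, -0.05 * sin(pi * (t - ts) / td), 0))
  q[n + 1] <- q[1]
  w <- inflow_waveform(t, q)
  scale_factor <- 1 / waveform_mean(w)
  w$flow <- w$flow * scale_factor
  w
}

#' Construct an inflow waveform
#'
#' @param time Sample times (s) from 0 to the period, inclusive.
#' @param flow Flow samples (cm^3/s); first and last must agree (periodic).
#' @return An `inflow_waveform`.
#' @export
inflow_waveform <- function(time, flow) {
  stop_if(length(time) != length(flow) || length(time) < 8,
          "'time' and 'flow' must be equal-length vectors (>= 8 samples)")
  stop_if(any(diff(time) <= 0), "'time' must be strictly increasing")
  stop_if(abs(flow[1] - flow[length(flow)]) >
            1e-6 * (max(abs(flow)) + 1e-12),
          "waveform must be periodic (first and last flow equal)")
  structure(list(period = time[length(time)] - time[1],
                 time = time - time[1], flow = flow),
            class = "inflow_waveform")
}

#' @export
print.inflow_waveform <- function(x, ...) {
  cat(sprintf(
    "inflow_waveform: T = %.3f s, mean %.1f cm^3/s (%.2f L/min), peak %.1f cm^3/s\n",
    x$period, waveform_mean(x), waveform_mean(x) / CM3S_PER_LMIN,
    max(x$flow)))
  invisible(x)
}

#' Cycle-mean flow of a waveform (cm^3/s)
#' @param w An `inflow_waveform`.
#' @export
waveform_mean <- function(w) {
  trapz(w$time, w$flow) / w$period
}

#' Read an inflow waveform from CSV
#'
#' Expects columns `time_s` and `flow_cm3_s` spanning one period.
#'
#' @param path CSV file path.
#' @return An `inflow_waveform`.
#' @export
read_waveform_csv <- function(path) {
  tab <- utils::read.csv(path)
  stop_if(!all(c("time_s", "flow_cm3_s") %in% names(tab)),
          "waveform CSV needs columns time_s, flow_cm3_s")
  inflow_waveform(tab$time_s, tab$flow_cm3_s)
}

#' Evaluate a waveform at arbitrary (periodic) times
#' @param w An `inflow_waveform`.
#' @param t Times in seconds.
#' @return Flow in cm^3/s.
#' @export
waveform_at <- function(w, t) {
  stats::approx(w$time, w$flow, xout = t %% w$period, rule = 2)$y
}

#' Scale a waveform to a target cardiac output
#'
#' Multiplies all flows by a single factor so the cycle mean equals the
#' cardiac output; shape and period are unchanged.
#'
#' @param w An `inflow_waveform`.
#' @param cardiac_output Target cardiac output in L/min.
#' @return The scaled `inflow_waveform`.
#' @export
scale_waveform <- function(w, cardiac_output) {
  check_positive(cardiac_output, "cardiac_output")
  m <- waveform_mean(w)
  stop_if(abs(m) < 1e-12 * max(abs(w$flow), 1e-12),
          "cannot scale a zero-mean waveform")
  w$flow <- w$flow * (cardiac_output * CM3S_PER_LMIN / m)
  w
}

#' Murray-law flow split
#'
#' fraction_i = d_i^exponent / sum(d_j^exponent). The modified law with
#' exponent 2 distributes flow proportionally to lumen area.
#'
#' @param outlet_diameters Outlet diameters (cm).
#' @param exponent Murray exponent (default 2).
#' @return Flow fractions summing to one.
#' @export
murray_split <- function(outlet_diameters, exponent = 2.0) {
  stop_if(length(outlet_diameters) == 0, "at least one outlet is required")
  check_positive(outlet_diameters, "outlet_diameters")
  p <- outlet_diameters^exponent
  p / sum(p)
}

#' Three-element Windkessel parameters for one outlet
#'
#' @param Rp Proximal resistance (dyn s/cm^5).
#' @param C Capacitance (cm^5/dyn).
#' @param Rd Distal resistance (dyn s/cm^5).
#' @return An object of class `rcr`.
#' @export
rcr <- function(Rp, C, Rd) {
  check_positive(c(Rp, C, Rd), "RCR parameters")
  structure(list(Rp = Rp, C = C, Rd = Rd), class = "rcr")
}

#' @export
print.rcr <- function(x, ...) {
  cat(sprintf("rcr: Rp = %.1f, C = %.3e, Rd = %.1f (CGS)\n",
              x$Rp, x$C, x$Rd))
  invisible(x)
}

#' Simulate the 0-D outlet network
#'
#' The inlet flow is divided among outlets by the Murray fractions at every
#' instant; each outlet evolves the standard 3-element Windkessel dynamics
#' (proximal pressure P = Q Rp + Pc, with C dPc/dt = Q - Pc/Rd and zero
#' distal reference pressure), integrated with the exact exponential update
#' of the single-state capacitor equation, unconditionally stable at any
#' time step. Whole cycles are integrated until the relative change of both
#' systolic and diastolic root pressure versus the previous cycle is within
#' `cycle_tol`, with a minimum of 8 cycles; only the final cycle is
#' reported. The root pressure is the flow-weighted mean of the outlet
#' proximal pressures.
#'
#' @param w An `inflow_waveform` (cm^3/s).
#' @param outlets List of outlets, each `list(diameter = cm, rcr = rcr)`.
#' @param dt Time step (s).
#' @param max_cycles Maximum cycles to integrate (>= 8).
#' @param cycle_tol Relative cycle-convergence tolerance.
#' @param murray_exponent Exponent of the flow split.
#' @return An object of class `windkessel_sim`: time grid and root/outlet
#'   pressure and flow traces (mmHg, cm^3/s) for the final cycle,
#'   systolic/diastolic root pressures, cycle count, the per-cycle
#'   variability history, and a `converged` flag.
#' @export
simulate_network <- function(w, outlets, dt = 0.001, max_cycles = 30,
                             cycle_tol = 0.01, murray_exponent = 2.0) {
  stop_if(length(outlets) == 0, "at least one outlet is required")
  check_positive(dt, "dt")
  # fewer than 8 cycles can run, but can never satisfy the minimum-cycle
  # rule, so such results are always flagged unconverged
  n_steps <- round(w$period / dt)
  stop_if(abs(n_steps * dt - w$period) > dt,
          "'dt' must divide the period to within one sample")
  tt <- seq_len(n_steps) * dt
  q_in <- waveform_at(w, tt)

  dia_out <- vapply(outlets, function(o) o$diameter, numeric(1))
  frac <- murray_split(dia_out, murray_exponent)
  Rp <- vapply(outlets, function(o) o$rcr$Rp, numeric(1))
  Cc <- vapply(outlets, function(o) o$rcr$C, numeric(1))
  Rd <- vapply(outlets, function(o) o$rcr$Rd, numeric(1))

  n_out <- length(outlets)
  # steady-state initialization of the capacitor pressures
  pc <- waveform_mean(w) * frac * Rd
  a <- exp(-dt / (Rd * Cc))
  sys_prev <- NA_real_; dia_prev <- NA_real_
  history <- numeric(0)
  converged <- FALSE
  n_cycles <- 0L
  p_root <- NULL; p_out <- NULL; q_out <- NULL

  for (cyc in seq_len(max_cycles)) {
    p_out <- matrix(0, n_steps, n_out)
    q_out <- outer(q_in, frac)
    for (i in seq_len(n_out)) {
      drive <- q_out[, i] * Rd[i] * (1 - a[i])
      pc_trace <- stats::filter(drive, a[i], method = "recursive",
                                init = pc[i])
      pc_trace <- as.numeric(pc_trace)
      p_out[, i] <- q_out[, i] * Rp[i] + pc_trace
      pc[i] <- pc_trace[n_steps]
    }
    p_root <- as.vector(p_out %*% frac) / DYN_PER_MMHG
    sys <- max(p_root); dia <- min(p_root)
    n_cycles <- cyc
    if (!is.na(sys_prev)) {
      var_cyc <- max(abs(sys - sys_prev) / abs(sys_prev),
                     abs(dia - dia_prev) / abs(dia_prev))
      history <- c(history, var_cyc)
      if (cyc >= 8 && var_cyc <= cycle_tol) {
        converged <- TRUE
        sys_prev <- sys; dia_prev <- dia
        break
      }
    }
    sys_prev <- sys; dia_prev <- dia
  }

  structure(list(time = tt, dt = dt,
                 root_pressure = p_root,
                 outlet_pressure = p_out / DYN_PER_MMHG,
                 outlet_flow = q_out,
                 inlet_flow = q_in,
                 flow_fractions = frac,
                 systolic = max(p_root), diastolic = min(p_root),
                 mean_pressure = mean(p_root),
                 n_cycles = n_cycles,
                 cycle_variability = history,
                 converged = converged),
            class = "windkessel_sim")
}

#' @export
print.windkessel_sim <- function(x, ...) {
  cat(sprintf(
    "windkessel_sim: %d cycles (%s), root pressure %.1f/%.1f mmHg (mean %.1f)\n",
    x$n_cycles, if (x$converged) "converged" else "NOT converged",
    x$systolic, x$diastolic, x$mean_pressure))
  invisible(x)
}

# Distribute network totals to outlets: resistances inversely proportional
# and capacitances proportional to the Murray fraction, fixed Rp:Rd ratio.
distribute_rcr <- function(R_total, C_total, fractions, rp_rd_ratio) {
  lapply(seq_along(fractions), function(i) {
    Ri <- R_total / fractions[i]
    rcr(Rp = Ri * rp_rd_ratio / (1 + rp_rd_ratio),
        C = C_total * fractions[i],
        Rd = Ri / (1 + rp_rd_ratio))
  })
}

#' Tune outlet RCR parameters to pressure targets
#'
#' Two-knob fixed-point iteration: the total network resistance is scaled
#' by the ratio of target to simulated mean pressure (mean taken as the
#' systolic/diastolic average on both sides, so the fixed point matches
#' both targets), and the total capacitance by the ratio of simulated to
#' target pulse pressure. Totals are redistributed to outlets with
#' resistance inversely proportional and capacitance proportional to the
#' Murray fraction; the Rp:Rd ratio is held fixed. Iteration stops when
#' both the systolic and diastolic relative errors are within `tol`.
#'
#' @param w An `inflow_waveform` scaled to the subject's cardiac output.
#' @param outlet_diameters Outlet diameters (cm).
#' @param systolic,diastolic Target pressures (mmHg).
#' @param tol Relative pressure tolerance.
#' @param max_iter Maximum tuning iterations.
#' @param rp_rd_ratio Fixed proximal:distal resistance ratio.
#' @param dt,max_cycles,cycle_tol Passed to [simulate_network()].
#' @param init Optional `list(R_total=, C_total=)` starting guess; defaults
#'   to mean-pressure / mean-flow and a 1.5 s distal time constant.
#' @return An object of class `windkessel_fit`: tuned outlet `rcr` list,
#'   achieved pressures, per-iteration error trace, the final
#'   `windkessel_sim`, and a `converged` flag.
#' @export
tune_rcr <- function(w, outlet_diameters, systolic, diastolic,
                     tol = 0.01, max_iter = 50, rp_rd_ratio = 0.04,
                     dt = 0.001, max_cycles = 30, cycle_tol = 0.01,
                     init = NULL) {
  stop_if(!(systolic > diastolic && diastolic > 0),
          "targets must satisfy systolic > diastolic > 0")
  frac <- murray_split(outlet_diameters)
  q_mean <- waveform_mean(w)
  check_positive(q_mean, "mean inflow")
  target_mean <- (systolic + diastolic) / 2
  target_pp <- systolic - diastolic

  if (is.null(init)) {
    R_total <- target_mean * DYN_PER_MMHG / q_mean
    C_total <- 1.5 / (R_total / (1 + rp_rd_ratio))
  } else {
    R_total <- init$R_total; C_total <- init$C_total
  }

  best <- NULL; best_err <- Inf
  trace <- data.frame(iter = integer(), systolic = numeric(),
                      diastolic = numeric(), err = numeric())
  converged <- FALSE
  sim <- NULL
  for (it in seq_len(max_iter)) {
    rcrs <- distribute_rcr(R_total, C_total, frac, rp_rd_ratio)
    outlets <- lapply(seq_along(frac), function(i)
      list(diameter = outlet_diameters[i], rcr = rcrs[[i]]))
    sim <- simulate_network(w, outlets, dt = dt, max_cycles = max_cycles,
                            cycle_tol = cycle_tol)
    err_sys <- abs(sim$systolic - systolic) / systolic
    err_dia <- abs(sim$diastolic - diastolic) / diastolic
    err <- max(err_sys, err_dia)
    trace <- rbind(trace, data.frame(iter = it, systolic = sim$systolic,
                                     diastolic = sim$diastolic, err = err))
    if (err < best_err) {
      best_err <- err
      best <- list(rcrs = rcrs, outlets = outlets, sim = sim)
    }
    if (err_sys <= tol && err_dia <= tol) {
      converged <- TRUE
      break
    }
    sim_mean <- (sim$systolic + sim$diastolic) / 2
    sim_pp <- max(sim$systolic - sim$diastolic, 1e-6)
    R_total <- R_total * (target_mean / sim_mean)
    C_total <- C_total * (sim_pp / target_pp)
  }
  structure(list(rcrs = best$rcrs, outlets = best$outlets,
                 outlet_diameters = outlet_diameters,
                 fractions = frac,
                 achieved = c(systolic = best$sim$systolic,
                              diastolic = best$sim$diastolic),
                 targets = c(systolic = systolic, diastolic = diastolic),
                 rel_error = c(
                   systolic = abs(best$sim$systolic - systolic) / systolic,
                   diastolic = abs(best$sim$diastolic - diastolic) /
                     diastolic),
                 n_iter = nrow(trace), trace = trace,
                 sim = best$sim, converged = converged,
                 rp_rd_ratio = rp_rd_ratio),
            class = "windkessel_fit")
}

#' @export
print.windkessel_fit <- function(x, ...) {
  cat(sprintf(
    "windkessel_fit: %d iterations (%s)\n  target %.1f/%.1f mmHg, achieved %.1f/%.1f (rel. err %.2f%% / %.2f%%)\n",
    x$n_iter, if (x$converged) "converged" else "NOT converged",
    x$targets["systolic"], x$targets["diastolic"],
    x$achieved["systolic"], x$achieved["diastolic"],
    100 * x$rel_error["systolic"], 100 * x$rel_error["diastolic"]))
  invisible(x)
}

#' @export
coef.windkessel_fit <- function(object, ...) {
  out <- t(vapply(object$rcrs, function(r) c(Rp = r$Rp, C = r$C, Rd = r$Rd),
                  numeric(3)))
  rownames(out) <- paste0("outlet", seq_len(nrow(out)))
  out
}

#' Reynolds number of the aortic inflow
#'
#' U d / nu with U the mean inlet velocity (cycle-mean flow over the inlet
#' cross-sectional area).
#'
#' @param cardiac_output Cardiac output (L/min).
#' @param inlet_diameter Inlet diameter (cm).
#' @param fluid A [fluid_properties()] list.
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(cardiac_output, inlet_diameter,
                     fluid = fluid_properties()) {
  check_positive(cardiac_output, "cardiac_output")
  check_positive(inlet_diameter, "inlet_diameter")
  q <- cardiac_output * CM3S_PER_LMIN
  u <- q / (pi * inlet_diameter^2 / 4)
  u * inlet_diameter / fluid$nu
}
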
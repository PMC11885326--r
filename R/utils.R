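# Unit conversions and small shared helpers. All geometry is in cm internally;
# diameters cross the user interface in mm, pressures in mmHg, flows in cm^3/s
# (cardiac output in L/min at the interface).

#' @keywords internal
DYN_PER_MMHG <- 1333.22

#' @keywords internal
CM3S_PER_LMIN <- 1000 / 60

MM_PER_CM <- 10

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

check_positive <- function(x, name) {
  stop_if(!is.numeric(x) || any(!is.finite(x)) || any(x <= 0),
          sprintf("'%s' must be positive and finite", name))
  invisible(x)
}

# Row-wise euclidean norm of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))

# Normalize rows of an n x 3 matrix
normalize_rows <- function(m) {
  n <- row_norms(m)
  m / pmax(n, .Machine$double.eps)
}

# Linear interpolation of a quantity defined on centerline arclength
interp_arclength <- function(s_grid, values, s) {
  stats::approx(s_grid, values, xout = s, rule = 2)$y
}

# Trapezoidal integral of y(x)
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
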
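# Voltage <-> mobility <-> diameter physics for a cylindrical differential
# mobility analyzer (DMA). All inputs are SI (m, s, V, Pa, K); only
# scan_diameter_range() reports nm, as that is the instrument-facing unit.

ELEMENTARY_CHARGE <- 1.602176634e-19 # C, exact (SI 2019)

#' Cylindrical DMA geometry
#'
#' Electrode radii and effective classification length of a coaxial-cylinder
#' differential mobility analyzer. Defaults are the published constants of the
#' TSI nano-DMA (model 3085-class column) used with electrostatic classifier
#' platforms; they are instrument constants, overridable for other columns.
#'
#' @param r_inner inner electrode radius in m (default 0.937 cm)
#' @param r_outer outer electrode radius in m (default 1.905 cm)
#' @param effective_length effective classification length in m (default 4.987 cm)
#' @return An object of class `dma_geometry`.
#' @examples
#' dma_geometry()
#' @export
dma_geometry <- function(r_inner = 0.937e-2, r_outer = 1.905e-2,
                         effective_length = 4.987e-2) {
  check_scalar_pos(r_inner, "r_inner")
  check_scalar_pos(r_outer, "r_outer")
  check_scalar_pos(effective_length, "effective_length")
  if (r_inner >= r_outer) {
    stop_domain("`r_inner` must be strictly smaller than `r_outer`")
  }
  structure(list(r_inner = r_inner, r_outer = r_outer,
                 effective_length = effective_length),
            class = "dma_geometry")
}

#' Carrier-gas conditions and slip-correction parameterization
#'
#' Holds the gas viscosity, mean free path and the Cunningham slip-correction
#' coefficients of the Stokes-Millikan mobility relation. Defaults are air at
#' 296.15 K and 101.325 kPa with the modern slip parameterization
#' (A1, A2, A3) = (1.165, 0.483, 0.997) and mean free path 67.3 nm, the
#' reference conditions used by aerosol mobility instrumentation.
#'
#' @param temperature gas temperature in K
#' @param pressure gas pressure in Pa
#' @param viscosity dynamic viscosity in Pa s
#' @param mean_free_path gas mean free path in m at the stated T and p
#' @param slip_coefficients numeric triple (A1, A2, A3), dimensionless
#' @return An object of class `gas_conditions`.
#' @export
gas_conditions <- function(temperature = 296.15, pressure = 101325,
                           viscosity = 1.83245e-5, mean_free_path = 67.3e-9,
                           slip_coefficients = c(1.165, 0.483, 0.997)) {
  check_scalar_pos(temperature, "temperature")
  check_scalar_pos(pressure, "pressure")
  check_scalar_pos(viscosity, "viscosity")
  check_scalar_pos(mean_free_path, "mean_free_path")
  if (length(slip_coefficients) != 3L || any(!is.finite(slip_coefficients)) ||
      any(slip_coefficients <= 0)) {
    stop_domain("`slip_coefficients` must be three positive numbers (A1, A2, A3)")
  }
  structure(list(temperature = temperature, pressure = pressure,
                 viscosity = viscosity, mean_free_path = mean_free_path,
                 slip_coefficients = as.numeric(slip_coefficients)),
            class = "gas_conditions")
}

#' Classifier scan settings
#'
#' Sheath and aerosol volumetric flows plus the voltage endpoints and timing of
#' an automatic up-scan. The default sheath flow is 2.5e-4 m^3/s (15 Lpm); the
#' default 10 V - 10 kV endpoints span the measurable singly-charged
#' EM-diameter range of roughly 1.95-64.9 nm for the nano-DMA geometry.
#'
#' @param sheath_flow sheath volumetric flow in m^3/s
#' @param aerosol_flow aerosol (sample) volumetric flow in m^3/s
#' @param v_min,v_max scan voltage endpoints in V, `0 < v_min < v_max`
#' @param up_scan_time,retrace_time scan timing in s
#' @return An object of class `scan_settings`.
#' @export
scan_settings <- function(sheath_flow = 2.5e-4, aerosol_flow = 1.6e-5,
                          v_min = 10, v_max = 1e4,
                          up_scan_time = 120, retrace_time = 30) {
  check_scalar_pos(sheath_flow, "sheath_flow")
  check_scalar_pos(aerosol_flow, "aerosol_flow")
  check_scalar_pos(v_min, "v_min")
  check_scalar_pos(v_max, "v_max")
  check_scalar_pos(up_scan_time, "up_scan_time")
  check_scalar_pos(retrace_time, "retrace_time")
  if (v_min >= v_max) stop_domain("`v_min` must be strictly smaller than `v_max`")
  if (aerosol_flow >= sheath_flow) {
    stop_domain("`sheath_flow` must exceed `aerosol_flow`")
  }
  structure(list(sheath_flow = sheath_flow, aerosol_flow = aerosol_flow,
                 v_min = v_min, v_max = v_max,
                 up_scan_time = up_scan_time, retrace_time = retrace_time),
            class = "scan_settings")
}

#' Transfer-function centroid mobility of a cylindrical DMA
#'
#' The electrical mobility classified at the centroid of the DMA transfer
#' function for an applied voltage:
#' `Z* = Q_sh * ln(r_outer / r_inner) / (2 * pi * L * V)`.
#'
#' @param voltage applied classifier voltage in V (vectorized, all > 0)
#' @param geom a [dma_geometry()]
#' @param scan a [scan_settings()] (only the sheath flow is used)
#' @return Electrical mobility in m^2 V^-1 s^-1.
#' @export
centroid_mobility <- function(voltage, geom = dma_geometry(),
                              scan = scan_settings()) {
  stopifnot(inherits(geom, "dma_geometry"), inherits(scan, "scan_settings"))
  if (any(!is.finite(voltage)) || any(voltage <= 0)) {
    stop_domain("`voltage` must be positive and finite")
  }
  scan$sheath_flow * log(geom$r_outer / geom$r_inner) /
    (2 * pi * geom$effective_length * voltage)
}

#' Cunningham slip correction factor
#'
#' `C(d) = 1 + Kn * (A1 + A2 * exp(-A3 / Kn))` with Knudsen number
#' `Kn = 2 * lambda / d`. Corrects Stokes drag for non-continuum gas effects;
#' approaches 1 in the continuum limit (large particles).
#'
#' @param diameter particle diameter in m (vectorized, all > 0)
#' @param gas a [gas_conditions()]
#' @return Dimensionless factor, always > 1.
#' @export
slip_correction <- function(diameter, gas = gas_conditions()) {
  stopifnot(inherits(gas, "gas_conditions"))
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop_domain("`diameter` must be positive and finite")
  }
  kn <- 2 * gas$mean_free_path / diameter
  a <- gas$slip_coefficients
  1 + kn * (a[1] + a[2] * exp(-a[3] / kn))
}

#' Electrical mobility of a charged sphere (Stokes-Millikan)
#'
#' `Z = n * e * C(d) / (3 * pi * mu * d)`. The default single charge matches
#' the charge-equilibrated, predominantly singly-charged aerosol produced by a
#' bipolar neutralizer.
#'
#' @param diameter sphere diameter in m (vectorized)
#' @param charges number of elementary charges (>= 1)
#' @param gas a [gas_conditions()]
#' @return Electrical mobility in m^2 V^-1 s^-1.
#' @export
mobility_from_diameter <- function(diameter, charges = 1,
                                   gas = gas_conditions()) {
  if (!is.numeric(charges) || length(charges) != 1L || charges < 1) {
    stop_domain("`charges` must be a single count >= 1")
  }
  charges * ELEMENTARY_CHARGE * slip_correction(diameter, gas) /
    (3 * pi * gas$viscosity * diameter)
}

#' Invert the Stokes-Millikan relation: diameter from mobility
#'
#' Finds the unique diameter with the given electrical mobility by bisection on
#' the bracket 0.1 nm - 10 um (mobility is strictly decreasing in diameter, so
#' the root is unique). Relative tolerance 1e-12; deterministic and
#' derivative-free.
#'
#' @param mobility electrical mobility in m^2 V^-1 s^-1 (vectorized)
#' @param charges number of elementary charges (>= 1)
#' @param gas a [gas_conditions()]
#' @param bracket search bracket in m, default `c(1e-10, 1e-5)`
#' @return Diameter in m.
#' @export
diameter_from_mobility <- function(mobility, charges = 1,
                                   gas = gas_conditions(),
                                   bracket = c(1e-10, 1e-5)) {
  if (any(!is.finite(mobility)) || any(mobility <= 0)) {
    stop_domain("`mobility` must be positive and finite")
  }
  z_hi <- mobility_from_diameter(bracket[1], charges, gas)
  z_lo <- mobility_from_diameter(bracket[2], charges, gas)
  out_of_range <- mobility > z_hi | mobility < z_lo
  if (any(out_of_range)) {
    stop_domain(sprintf(
      "mobility outside the invertible image of the bracket [%g m, %g m]: [%g, %g] m^2/(V s)",
      bracket[1], bracket[2], z_lo, z_hi))
  }
  # vectorized bisection: Z(d) is strictly decreasing in d
  lo <- rep(bracket[1], length(mobility))
  hi <- rep(bracket[2], length(mobility))
  for (i in seq_len(200)) {
    mid <- 0.5 * (lo + hi)
    too_small <- mobility_from_diameter(mid, charges, gas) > mobility
    lo <- ifelse(too_small, mid, lo)
    hi <- ifelse(too_small, hi, mid)
    if (max((hi - lo) / lo) < 1e-12) break
  }
  0.5 * (lo + hi)
}

#' Measurable EM-diameter range of a voltage scan
#'
#' Maps the scan voltage endpoints through the transfer-function centroid and
#' the Stokes-Millikan inversion to the range of singly-charged
#' electrophoretic-mobility diameters the scan can classify. With the default
#' nano-DMA geometry, a 2.5e-4 m^3/s sheath flow and 10 V - 10 kV endpoints
#' this reproduces the instrument's printed 1.95-64.9 nm range to within a few
#' percent.
#'
#' @param geom a [dma_geometry()]
#' @param scan a [scan_settings()]
#' @param gas a [gas_conditions()]
#' @return Named numeric vector `c(d_min, d_max)` in nm.
#' @examples
#' scan_diameter_range()
#' @export
scan_diameter_range <- function(geom = dma_geometry(), scan = scan_settings(),
                                gas = gas_conditions()) {
  z <- centroid_mobility(c(scan$v_min, scan$v_max), geom, scan)
  d <- diameter_from_mobility(z, charges = 1, gas = gas)
  c(d_min = d[1] * 1e9, d_max = d[2] * 1e9)
}
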
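#' Probe-to-power dosimetry chain
#'
#' Converts a spectrum-analyzer reading `P_MES` (dBm) into the incident
#' plane-wave power flux at the sample position:
#' \deqn{P_{ELEC} = P_{MES}[\mathrm{W}] / A_{CABLE}, \quad
#'       U_{ELEC} = \sqrt{P_{ELEC} Z_0}, \quad
#'       E = AF \cdot U_{ELEC}, \quad
#'       P_{EMG} = E^2 / \eta_0.}
#' The last step assumes a locally plane wave; see [plane_wave_ratio()] for
#' the validity check. Readings below the analyzer's sensitivity floor
#' (`NA` or below `cal$sensitivity_floor_dbm`) propagate as a typed
#' below-floor flag; no numeric estimate is fabricated for them.
#'
#' @param p_mes_dbm Numeric vector of analyzer readings in dBm; `NA` marks a
#'   below-floor reading.
#' @param cal An [rf_calibration()] object.
#' @return A data.frame of class `rf_field_estimate` with one row per
#'   reading and columns `p_mes_dbm`, `below_floor`, `p_elec_w`, `u_elec_v`,
#'   `e_field_v_per_m`, `p_emg_w_per_m2`. Below-floor rows carry `NA` in all
#'   numeric estimate columns.
#' @examples
#' cal <- rf_calibration()
#' probe_chain(-35.5, cal)  # E about 1.06 V/m
#' @export
probe_chain <- function(p_mes_dbm, cal = rf_calibration()) {
  stopifnot(inherits(cal, "rf_calibration"), is.numeric(p_mes_dbm))
  below <- is.na(p_mes_dbm) | p_mes_dbm < cal$sensitivity_floor_dbm
  p_elec <- u_elec <- e <- p_emg <- rep(NA_real_, length(p_mes_dbm))
  if (any(!below)) {
    pw <- dbm_to_watt(p_mes_dbm[!below])
    p_elec[!below] <- pw / cal$a_cable
    u_elec[!below] <- sqrt(p_elec[!below] * cal$port_impedance_ohm)
    e[!below]      <- cal$antenna_factor_per_m * u_elec[!below]
    p_emg[!below]  <- e[!below]^2 / cal$wave_impedance_ohm
  }
  structure(
    data.frame(
      p_mes_dbm = p_mes_dbm,
      below_floor = below,
      p_elec_w = p_elec,
      u_elec_v = u_elec,
      e_field_v_per_m = e,
      p_emg_w_per_m2 = p_emg
    ),
    class = c("rf_field_estimate", "data.frame")
  )
}

#' Build the generator-power / measured-power exposure table
#'
#' Takes a measurement ladder (one row per generator power rung and probe
#' axis) and appends the chain outputs E and P_EMG. Below-floor rungs stay
#' flagged and render as missing when written to CSV.
#'
#' @param ladder A data.frame with columns `p_gene_dbm`, `axis`
#'   (one of "x", "y", "z"), `p_mes_dbm` (`NA` = below floor) and optionally
#'   `frequency_hz`.
#' @param cal An [rf_calibration()] object.
#' @return The ladder sorted by decreasing generator power with chain columns
#'   `p_elec_w`, `e_field_v_per_m`, `p_emg_w_per_m2`, `below_floor` appended.
#' @export
build_exposure_table <- function(ladder, cal = rf_calibration()) {
  errs <- validate_measurements(ladder)
  if (length(errs)) {
    stop("invalid measurement ladder:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  ladder <- ladder[order(-ladder$p_gene_dbm, ladder$axis), , drop = FALSE]
  est <- probe_chain(ladder$p_mes_dbm, cal)
  ladder$p_elec_w        <- est$p_elec_w
  ladder$e_field_v_per_m <- est$e_field_v_per_m
  ladder$p_emg_w_per_m2  <- est$p_emg_w_per_m2
  ladder$below_floor     <- est$below_floor
  rownames(ladder) <- NULL
  ladder
}

#' Published x-axis measurement ladder of the exposure system
#'
#' The ten-rung generator-power ladder (+20 dBm down to -40 dBm) with the
#' corresponding x-axis analyzer readings at 1.77 GHz; the -40 dBm rung fell
#' below the analyzer's sensitivity floor and is `NA`. The printed E-field
#' and power-flux cells are attached as `e_printed_v_per_m` and
#' `p_emg_printed_w_per_m2` for comparison at printed (2 significant figure)
#' precision.
#'
#' @return A data.frame with one row per rung.
#' @export
reference_ladder <- function() {
  data.frame(
    p_gene_dbm = c(20, 10, 5, 0, -5, -10, -15, -20, -30, -40),
    axis = "x",
    p_mes_dbm = c(-29.8, -35.5, -40, -45.5, -50, -55.5, -60.3, -65.5, -72, NA),
    frequency_hz = 1.77e9,
    e_printed_v_per_m = c(2.05, 1.06, 0.63, 0.33, 0.2, 0.11, 0.061, 0.033,
                          0.016, NA),
    p_emg_printed_w_per_m2 = c(1.1e-2, 2.9e-3, 1.1e-3, 2.9e-4, 1.1e-4,
                               2.9e-5, 9.8e-6, 2.9e-6, 6.6e-7, NA)
  )
}

#' Minimum far-field distance of a radiating source
#'
#' The locally-plane-wave (far-field) region starts at
#' \eqn{d \ge 2 D^2 / \lambda} from a source of largest dimension D. For the
#' 5.5 cm patch-antenna diagonal and the 16.5 cm wavelength at 1.8 GHz this
#' gives d > 3.6 cm, well under the 16.8 cm antenna-to-sample distance.
#'
#' @param source_diagonal_m Largest dimension D of the source, in m.
#' @param wavelength_m Wavelength of the propagating wave, in m. Supply
#'   either this or `frequency_hz`.
#' @param frequency_hz Frequency in Hz, converted with c = 2.998e8 m/s.
#' @return Minimum far-field distance in m.
#' @export
min_farfield_distance <- function(source_diagonal_m, wavelength_m = NULL,
                                  frequency_hz = NULL) {
  if (is.null(wavelength_m)) {
    if (is.null(frequency_hz)) {
      stop("supply `wavelength_m` or `frequency_hz`", call. = FALSE)
    }
    if (!is.numeric(frequency_hz) || any(frequency_hz <= 0)) {
      stop("`frequency_hz` must be > 0", call. = FALSE)
    }
    wavelength_m <- 2.998e8 / frequency_hz
  }
  if (!is.numeric(source_diagonal_m) || any(source_diagonal_m < 0)) {
    stop("`source_diagonal_m` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(wavelength_m) || any(wavelength_m <= 0)) {
    stop("`wavelength_m` must be > 0", call. = FALSE)
  }
  2 * source_diagonal_m^2 / wavelength_m
}

#' ICNIRP (2020) general-public reference levels
#'
#' Whole-body reference levels for 30-min-averaged exposure in the
#' >400-2000 MHz band:
#' \eqn{E_{max} = 1.375 f_{MHz}^{0.5}} V/m,
#' \eqn{H_{max} = 0.0037 f_{MHz}^{0.5}} A/m,
#' \eqn{S_{max} = f_{MHz}/200} W/m^2.
#' Outside the stated band the formulas do not apply and the function
#' refuses to extrapolate.
#'
#' @param f_mhz Frequency in MHz, in (400, 2000].
#' @return An object of class `icnirp_limits`: list with `f_mhz`,
#'   `e_max_v_per_m`, `h_max_a_per_m`, `p_emg_max_w_per_m2`.
#' @examples
#' icnirp_limits(1800)  # E 58.336 V/m, H 0.15698 A/m, S 9 W/m^2
#' @export
icnirp_limits <- function(f_mhz) {
  stopifnot(is.numeric(f_mhz), length(f_mhz) == 1L, is.finite(f_mhz))
  if (f_mhz < 400 || f_mhz > 2000) {
    stop("reference-level formulas are valid for 400-2000 MHz only; got ",
         f_mhz, " MHz", call. = FALSE)
  }
  structure(
    list(
      f_mhz = f_mhz,
      e_max_v_per_m = 1.375 * f_mhz^0.5,
      h_max_a_per_m = 0.0037 * f_mhz^0.5,
      p_emg_max_w_per_m2 = f_mhz / 200
    ),
    class = "icnirp_limits"
  )
}

#' @export
print.icnirp_limits <- function(x, ...) {
  cat(sprintf("ICNIRP general-public reference levels at %g MHz\n", x$f_mhz))
  cat(sprintf("  E_max : %.5g V/m\n", x$e_max_v_per_m))
  cat(sprintf("  H_max : %.5g A/m\n", x$h_max_a_per_m))
  cat(sprintf("  S_max : %.5g W/m^2\n", x$p_emg_max_w_per_m2))
  invisible(x)
}

#' Exposure margin relative to the power-flux reference level
#'
#' @param p_emg_w_per_m2 Incident power flux in W/m^2 (>= 0).
#' @param limits An [icnirp_limits()] object.
#' @return Dimensionless ratio `p_emg / S_max`; 1 means at the limit.
#' @export
exposure_margin <- function(p_emg_w_per_m2, limits) {
  stopifnot(inherits(limits, "icnirp_limits"),
            is.numeric(p_emg_w_per_m2), all(p_emg_w_per_m2 >= 0, na.rm = TRUE))
  p_emg_w_per_m2 / limits$p_emg_max_w_per_m2
}
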
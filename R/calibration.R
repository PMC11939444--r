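#' Probe/analyzer calibration constants
#'
#' Bundles the constants that define the dosimetry chain from spectrum-analyzer
#' reading to incident plane-wave power flux: cable attenuation, antenna
#' factor, port impedance, wave impedance of the propagation medium, and the
#' analyzer's sensitivity floor.
#'
#' @param cable_attenuation_db Cable attenuation in dB (negative for a
#'   passive cable). Default -3.896 dB, the SMA cable's S21 at 1.77 GHz.
#' @param antenna_factor_per_m Antenna factor AF in 1/m converting the probe
#'   RMS voltage to the incident E-field magnitude, E = AF * U.
#'   Default 179.89 (manufacturer calibration at 1.77 GHz).
#' @param port_impedance_ohm SMA port impedance Z0 in ohm. Default 50.
#' @param wave_impedance_ohm Wave impedance of the medium in ohm.
#'   Default 377 (air).
#' @param sensitivity_floor_dbm Lowest measurable analyzer power in dBm;
#'   readings below it are below-floor flags, never numbers. Default -75.
#' @return An object of class `rf_calibration` (a named list with the fields
#'   above plus `a_cable`, the linear cable coefficient).
#' @examples
#' cal <- rf_calibration()
#' cal$a_cable  # 0.40776
#' @export
rf_calibration <- function(cable_attenuation_db = -3.896,
                           antenna_factor_per_m = 179.89,
                           port_impedance_ohm = 50,
                           wave_impedance_ohm = 377,
                           sensitivity_floor_dbm = -75) {
  stopifnot(
    is.numeric(cable_attenuation_db), length(cable_attenuation_db) == 1L,
    is.finite(cable_attenuation_db),
    is.numeric(antenna_factor_per_m), antenna_factor_per_m > 0,
    is.numeric(port_impedance_ohm), port_impedance_ohm > 0,
    is.numeric(wave_impedance_ohm), wave_impedance_ohm > 0,
    is.numeric(sensitivity_floor_dbm), is.finite(sensitivity_floor_dbm)
  )
  if (cable_attenuation_db > 0) {
    stop("`cable_attenuation_db` must be <= 0 for a passive cable",
         call. = FALSE)
  }
  a_cable <- attenuation_db_to_coeff(cable_attenuation_db)
  structure(
    list(
      cable_attenuation_db  = cable_attenuation_db,
      a_cable               = a_cable,
      antenna_factor_per_m  = antenna_factor_per_m,
      port_impedance_ohm    = port_impedance_ohm,
      wave_impedance_ohm    = wave_impedance_ohm,
      sensitivity_floor_dbm = sensitivity_floor_dbm
    ),
    class = "rf_calibration"
  )
}

#' @export
print.rf_calibration <- function(x, ...) {
  cat("RF probe calibration\n")
  cat(sprintf("  cable attenuation : %.4g dB (A_CABLE = %.5g)\n",
              x$cable_attenuation_db, x$a_cable))
  cat(sprintf("  antenna factor    : %.5g 1/m\n", x$antenna_factor_per_m))
  cat(sprintf("  port impedance    : %.4g ohm\n", x$port_impedance_ohm))
  cat(sprintf("  wave impedance    : %.4g ohm\n", x$wave_impedance_ohm))
  cat(sprintf("  sensitivity floor : %.4g dBm\n", x$sensitivity_floor_dbm))
  invisible(x)
}

#' Read / write calibration constants as YAML
#'
#' The on-disk schema uses explicit unit-suffixed keys:
#' `cable_attenuation_db, antenna_factor_per_m, port_impedance_ohm,
#' wave_impedance_ohm, sensitivity_floor_dbm`.
#'
#' @param path File path.
#' @return `read_calibration()` returns an `rf_calibration`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  need <- c("cable_attenuation_db", "antenna_factor_per_m",
            "port_impedance_ohm", "wave_impedance_ohm",
            "sensitivity_floor_dbm")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    stop("calibration file ", path, " is missing key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- need[!vapply(y[need], function(v) is.numeric(v) && length(v) == 1L,
                      logical(1))]
  if (length(bad)) {
    stop("calibration file ", path, " has non-numeric value(s) for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(rf_calibration, y[need])
}

#' @rdname read_calibration
#' @param cal An `rf_calibration` object.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "rf_calibration"))
  yaml::write_yaml(cal[c("cable_attenuation_db", "antenna_factor_per_m",
                         "port_impedance_ohm", "wave_impedance_ohm",
                         "sensitivity_floor_dbm")], path)
  invisible(path)
}
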
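#' Convert absolute power from dBm to watt
#'
#' dBm is absolute power on a logarithmic scale referenced to 1 mW, so
#' \eqn{P[\mathrm{W}] = 10^{P[\mathrm{dBm}]/10} / 1000}.
#'
#' @param p_dbm Numeric vector of powers in dBm. Must be finite.
#' @return Numeric vector of powers in watt (strictly positive).
#' @seealso [watt_to_dbm()] for the inverse.
#' @examples
#' dbm_to_watt(0)    # 1 mW
#' dbm_to_watt(-75)  # spectrum-analyzer sensitivity floor
#' @export
dbm_to_watt <- function(p_dbm) {
  if (!is.numeric(p_dbm) || any(!is.finite(p_dbm))) {
    stop("`p_dbm` must be finite numeric", call. = FALSE)
  }
  10^(p_dbm / 10) / 1000
}

#' Convert absolute power from watt to dBm
#'
#' @param p_w Numeric vector of powers in watt, strictly positive.
#' @return Numeric vector of powers in dBm.
#' @export
watt_to_dbm <- function(p_w) {
  if (!is.numeric(p_w) || any(!is.finite(p_w)) || any(p_w <= 0)) {
    stop("`p_w` must be finite and > 0 (dBm is undefined at or below 0 W)",
         call. = FALSE)
  }
  10 * log10(p_w * 1000)
}

#' Convert a cable attenuation in dB to a linear power coefficient
#'
#' A passive cable attenuates: its S21 magnitude in dB is non-positive and
#' the linear coefficient \eqn{A = 10^{\mathrm{dB}/10}} lies in (0, 1].
#' The exposure-system SMA cable measures -3.896 dB at 1.77 GHz, i.e.
#' A = 0.40776.
#'
#' @param att_db Attenuation in dB (<= 0 for a passive cable; a warning is
#'   emitted for positive values, which describe gain).
#' @return Linear power coefficient, `10^(att_db/10)`.
#' @export
attenuation_db_to_coeff <- function(att_db) {
  if (!is.numeric(att_db) || any(!is.finite(att_db))) {
    stop("`att_db` must be finite numeric", call. = FALSE)
  }
  if (any(att_db > 0)) {
    warning("positive `att_db` describes gain, not a passive cable")
  }
  10^(att_db / 10)
}
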
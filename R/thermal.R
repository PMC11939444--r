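#' Volumetric heat capacities used in the thermal budget
#'
#' Water: 1160 Wh/(m^3 K). Kidney tissue: 3644 J/(L K) = 1012 Wh/(m^3 K).
#' @name heat-capacities
#' @export
C_WATER_WH_PER_M3K <- 1160

#' @rdname heat-capacities
#' @export
C_KIDNEY_WH_PER_M3K <- 1012

#' Worst-case lossless radiative heating budget
#'
#' Upper bound on sample heating if every incident watt were stored as heat:
#' \deqn{\Delta T = P_{EMG} \cdot \mathrm{Surf}_{PETRI} \cdot \Delta t /
#'       (C \cdot V)}
#' with the dish surface \eqn{\pi \phi^2 / 4}. Units are part of the
#' contract: power flux in W/m^2, duration in hours, capacity in
#' Wh/(m^3 K), volume in m^3. At the highest amplitude used
#' (1.1e-2 W/m^2, 15 min, 53 mm dish, 2 mm of water) the bound is about
#' 1.2e-3 degC - no "microwave-oven" effect.
#'
#' @param incident_w_per_m2 Incident plane-wave power flux, W/m^2 (>= 0).
#' @param dish_diameter_m Petri dish diameter, m.
#' @param duration_h Exposure duration, hours.
#' @param heat_capacity_wh_per_m3k Volumetric heat capacity, Wh/(m^3 K).
#' @param volume_m3 Heated volume, m^3.
#' @return Temperature rise in kelvin.
#' @export
delta_t_budget <- function(incident_w_per_m2, dish_diameter_m = 0.053,
                           duration_h = 0.25,
                           heat_capacity_wh_per_m3k = C_WATER_WH_PER_M3K,
                           volume_m3 = 4.5e-6) {
  stopifnot(is.numeric(incident_w_per_m2), all(incident_w_per_m2 >= 0),
            dish_diameter_m > 0, duration_h > 0,
            heat_capacity_wh_per_m3k > 0, volume_m3 > 0)
  surf <- pi * dish_diameter_m^2 / 4
  incident_w_per_m2 * surf * duration_h /
    (heat_capacity_wh_per_m3k * volume_m3)
}

#' First-order-plus-dead-time thermal plant
#'
#' Lumped model of the heated exposure box:
#' \eqn{\tau \, dT/dt = -(T - T_{amb}) + K u(t - \theta)}, where u is the
#' PWM duty of the hot-water pump. The shipped default parameters are
#' synthetic (no plant constants are published for the physical box), chosen
#' to reproduce the regulation behaviour qualitatively: slow ~10 min wall
#' dynamics, short transport delay, sub-1-degC dips on hood opening.
#'
#' @param static_gain_c_per_duty Steady-state gain K, degC per unit duty.
#' @param time_constant_s Plant time constant tau, s.
#' @param dead_time_s Transport dead time theta, s (>= 0).
#' @param ambient_temp_c Ambient temperature, degC.
#' @param hood_open_disturbance_c Step added to the sensed air temperature
#'   while the hood is open (negative: cold room air), degC.
#' @return Object of class `rf_plant`.
#' @export
plant_model <- function(static_gain_c_per_duty = 30,
                        time_constant_s = 600,
                        dead_time_s = 20,
                        ambient_temp_c = 22,
                        hood_open_disturbance_c = -0.9) {
  stopifnot(time_constant_s > 0, dead_time_s >= 0,
            is.finite(static_gain_c_per_duty))
  structure(
    list(static_gain_c_per_duty = static_gain_c_per_duty,
         time_constant_s = time_constant_s,
         dead_time_s = dead_time_s,
         ambient_temp_c = ambient_temp_c,
         hood_open_disturbance_c = hood_open_disturbance_c),
    class = "rf_plant"
  )
}

#' PID gains from Internal Model Control tuning
#'
#' Standard IMC rules for a first-order-plus-dead-time plant with one
#' closed-loop speed parameter lambda_c:
#' \eqn{k_p = \tau / (K (\lambda_c + \theta))}, integral time \eqn{T_i = \tau}
#' (so \eqn{k_i = k_p / \tau}), derivative time 0 - a PI controller, the
#' usual IMC choice for slow thermal plants; `kd` is carried but zero.
#'
#' @param plant An [plant_model()].
#' @param closed_loop_tau_s Desired closed-loop time constant lambda_c, s.
#' @param setpoint_c Regulation setpoint, degC (default 37).
#' @return Object of class `rf_pid_gains`: list `kp`, `ki` (1/s), `kd` (s),
#'   `setpoint_c`.
#' @export
imc_pid_gains <- function(plant, closed_loop_tau_s = 120, setpoint_c = 37) {
  stopifnot(inherits(plant, "rf_plant"), closed_loop_tau_s > 0)
  K <- plant$static_gain_c_per_duty
  if (K == 0) stop("plant static gain is zero: IMC tuning undefined",
                   call. = FALSE)
  kp <- plant$time_constant_s /
    (K * (closed_loop_tau_s + plant$dead_time_s))
  structure(
    list(kp = kp, ki = kp / plant$time_constant_s, kd = 0,
         setpoint_c = setpoint_c),
    class = "rf_pid_gains"
  )
}

#' Simulate PID/PWM hot-water temperature regulation
#'
#' Fixed-step explicit simulation of the closed loop. The PID output,
#' clamped to [0, 1] with conditional anti-windup, sets the duty cycle of a
#' 5 s PWM period; within each period the pump is modelled at its mean value
#' (duty), accurate because the plant time constant is two orders of
#' magnitude above the period. Hood-open intervals add the plant's
#' disturbance step to the sensed air temperature; the slow wall/water state
#' integrates the first-order-plus-dead-time dynamics. The controller
#' integrator is initialised to hold the starting temperature (bumpless
#' start), so a run starting at the setpoint with no disturbance stays
#' there.
#'
#' @param plant An [plant_model()].
#' @param gains An [imc_pid_gains()] result (or compatible list).
#' @param schedule Data.frame of hood events with columns `t_open_s`,
#'   `t_close_s` (may have zero rows); see [gen_hood_schedule()].
#' @param duration_s Total simulated time, s.
#' @param pwm_period_s PWM period, s (default 5).
#' @param dt_s Integration step, s; must be <= `pwm_period_s / 10`.
#' @param start_temp_c Initial box temperature, degC; defaults to ambient.
#' @param load_disturbance_c Constant load disturbance added to the plant
#'   input (degC), for steady-state-error checks. Default 0.
#' @param noise_sd_c Gaussian measurement noise on the sensed temperature,
#'   degC. Default 0.
#' @param seed RNG seed used when `noise_sd_c > 0`; runs are reproducible
#'   given the seed.
#' @return Object of class `rf_temp_trace`: data.frame `time_s`, `temp_c`
#'   (sensed temperature, including hood disturbance), `duty`, `hood_open`,
#'   with the event schedule attached as attribute `"events"`.
#' @export
simulate_regulation <- function(plant, gains,
                                schedule = gen_hood_schedule(0),
                                duration_s = 3600,
                                pwm_period_s = 5, dt_s = 0.5,
                                start_temp_c = plant$ambient_temp_c,
                                load_disturbance_c = 0,
                                noise_sd_c = 0, seed = NULL) {
  stopifnot(inherits(plant, "rf_plant"), is.list(gains),
            duration_s > 0, pwm_period_s > 0)
  if (dt_s > pwm_period_s / 10) {
    stop("`dt_s` must be <= pwm_period_s / 10", call. = FALSE)
  }
  if (nrow(schedule) && any(schedule$t_close_s > duration_s)) {
    stop("hood schedule extends beyond `duration_s`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n <- floor(duration_s / dt_s)
  time_s <- (seq_len(n) - 1) * dt_s
  hood_open <- rep(FALSE, n)
  if (nrow(schedule)) {
    for (k in seq_len(nrow(schedule))) {
      hood_open <- hood_open |
        (time_s >= schedule$t_open_s[k] & time_s < schedule$t_close_s[k])
    }
  }

  K <- plant$static_gain_c_per_duty
  tau <- plant$time_constant_s
  n_delay <- round(plant$dead_time_s / dt_s)
  steps_per_period <- round(pwm_period_s / dt_s)

  temp <- duty_out <- numeric(n)
  state <- start_temp_c
  # bumpless start: integrator holds the initial temperature (only when
  # integral action exists; a gainless controller must leave the plant free)
  integ <- if (K != 0 && gains$ki > 0) {
    max(0, min(1, (start_temp_c - plant$ambient_temp_c) / K))
  } else 0
  u_hist <- rep(integ, n_delay + 1L)  # delayed duty buffer
  duty <- integ
  prev_err <- 0

  for (i in seq_len(n)) {
    sensed <- state + if (hood_open[i]) plant$hood_open_disturbance_c else 0
    meas <- sensed + if (noise_sd_c > 0) stats::rnorm(1, 0, noise_sd_c) else 0
    if ((i - 1L) %% steps_per_period == 0L) {
      err <- gains$setpoint_c - meas
      cand <- integ + gains$ki * err * pwm_period_s
      u_raw <- gains$kp * err + cand +
        gains$kd * (err - prev_err) / pwm_period_s
      # conditional anti-windup: only integrate when not pushing into a limit
      if ((u_raw < 1 || err < 0) && (u_raw > 0 || err > 0)) integ <- cand
      duty <- max(0, min(1, gains$kp * err + integ +
                              gains$kd * (err - prev_err) / pwm_period_s))
      prev_err <- err
    }
    u_hist <- c(u_hist[-1L], duty)
    u_del <- u_hist[1L]
    state <- state + dt_s / tau *
      (-(state - plant$ambient_temp_c) + K * u_del + load_disturbance_c)
    temp[i] <- sensed
    duty_out[i] <- duty
  }

  structure(
    data.frame(time_s = time_s, temp_c = temp, duty = duty_out,
               hood_open = hood_open),
    events = schedule,
    class = c("rf_temp_trace", "data.frame")
  )
}

#' Open-loop step response of the plant (for identification tests)
#'
#' Simulates the plant alone under a duty step at t = 0, starting from
#' steady state at the pre-step duty.
#'
#' @param plant An [plant_model()].
#' @param duty_from,duty_to Duty before / after the step.
#' @param duration_s,dt_s Simulated time and step, s.
#' @param noise_sd_c Gaussian measurement noise, degC.
#' @param seed RNG seed for the noise.
#' @return An `rf_temp_trace` data.frame (`duty` column holds the input).
#' @export
step_response <- function(plant, duty_from = 0, duty_to = 0.5,
                          duration_s = 4000, dt_s = 0.5,
                          noise_sd_c = 0, seed = NULL) {
  stopifnot(inherits(plant, "rf_plant"))
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration_s / dt_s)
  time_s <- (seq_len(n) - 1) * dt_s
  K <- plant$static_gain_c_per_duty
  tau <- plant$time_constant_s
  n_delay <- round(plant$dead_time_s / dt_s)
  state <- plant$ambient_temp_c + K * duty_from
  u_hist <- rep(duty_from, n_delay + 1L)
  temp <- numeric(n)
  for (i in seq_len(n)) {
    temp[i] <- state + if (noise_sd_c > 0) stats::rnorm(1, 0, noise_sd_c) else 0
    u_hist <- c(u_hist[-1L], duty_to)
    state <- state + dt_s / tau *
      (-(state - plant$ambient_temp_c) + K * u_hist[1L])
  }
  structure(
    data.frame(time_s = time_s, temp_c = temp, duty = duty_to,
               hood_open = FALSE),
    events = gen_hood_schedule(0),
    class = c("rf_temp_trace", "data.frame")
  )
}

#' Identify a first-order-plus-dead-time plant from a step response
#'
#' Two-point graphical method: the steady-state gain is
#' \eqn{\Delta T_{ss} / \Delta u} with the final value taken from the trace
#' tail; the 28.3% and 63.2% rise times give
#' \eqn{\tau = 1.5 (t_{63.2} - t_{28.3})} and
#' \eqn{\theta = t_{63.2} - \tau} (exact for a true first-order-plus-dead-time
#' response). Crossings are located by linear interpolation.
#'
#' @param trace An `rf_temp_trace` from an open-loop step experiment; the
#'   step is applied at `time_s = 0`.
#' @param step_magnitude Duty change that produced the response (non-zero).
#' @param settle_tol Relative tail drift above which the trace is declared
#'   non-settled (default 0.02).
#' @return An [plant_model()] with the identified gain, time constant and
#'   dead time (ambient taken from the trace start).
#' @export
identify_fopdt <- function(trace, step_magnitude, settle_tol = 0.02) {
  stopifnot(inherits(trace, "rf_temp_trace") || is.data.frame(trace))
  if (!is.numeric(step_magnitude) || step_magnitude == 0) {
    stop("`step_magnitude` must be non-zero: a zero step is unidentifiable",
         call. = FALSE)
  }
  t <- trace$time_s
  y <- trace$temp_c
  n <- length(y)
  if (n < 20) stop("trace too short for identification", call. = FALSE)
  # measurement noise biases first-crossing detection early; when the tail
  # is rough, smooth with a centered running mean (~1% of the trace, narrow
  # enough that curvature bias stays well below the noise floor)
  tail_rough <- stats::sd(diff(y[seq.int(floor(0.95 * n), n)])) / sqrt(2)
  if (is.finite(tail_rough) && tail_rough > 1e-9) {
    w <- max(5L, 2L * floor(0.005 * n) + 1L)
    ys <- stats::filter(y, rep(1 / w, w), sides = 2)
    keep <- !is.na(ys)
    y[keep] <- ys[keep]
  }
  y0 <- mean(y[1:3])  # pre-step level (trace starts at steady state)
  tail_idx <- seq.int(floor(0.95 * n), n)
  y_ss <- mean(y[tail_idx])
  mid_idx <- seq.int(floor(0.85 * n), floor(0.9 * n))
  dy <- y_ss - y0
  if (abs(dy) < 1e-12) {
    stop("no response detected: unidentifiable", call. = FALSE)
  }
  if (abs(mean(y[mid_idx]) - y_ss) > settle_tol * abs(dy)) {
    stop("step response has not settled: identification failed",
         call. = FALSE)
  }
  cross <- function(frac) {
    lev <- y0 + frac * dy
    up <- dy > 0
    idx <- if (up) which(y >= lev) else which(y <= lev)
    if (!length(idx)) stop("response never reaches ", frac * 100,
                           "% of its final value", call. = FALSE)
    i <- idx[1]
    if (i == 1L) return(t[1])
    t[i - 1] + (lev - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  t632 <- cross(1 - exp(-1))
  t283 <- cross(1 - exp(-1 / 3))
  tau <- 1.5 * (t632 - t283)
  theta <- max(0, t632 - tau)
  plant_model(
    static_gain_c_per_duty = dy / step_magnitude,
    time_constant_s = tau,
    dead_time_s = theta,
    ambient_temp_c = y0
  )
}

#' Summary metrics of a regulation trace
#'
#' @param trace An `rf_temp_trace`.
#' @param setpoint_c Setpoint, degC.
#' @param band_c Half-width of the regulation band, degC (default 0.2).
#' @param event_exclusion_s Seconds after each hood closing excluded from the
#'   steady-state band statistic (open intervals are always excluded).
#'   Default 60.
#' @return List: `max_deviation_c` (over the whole trace),
#'   `max_event_deviation_c` (within event windows),
#'   `band_occupancy` (fraction of non-event samples inside the band),
#'   `n_events`.
#' @export
trace_metrics <- function(trace, setpoint_c = 37, band_c = 0.2,
                          event_exclusion_s = 60) {
  stopifnot(nrow(trace) > 0)
  dev <- abs(trace$temp_c - setpoint_c)
  events <- attr(trace, "events")
  in_event <- rep(FALSE, nrow(trace))
  if (!is.null(events) && nrow(events)) {
    for (k in seq_len(nrow(events))) {
      in_event <- in_event |
        (trace$time_s >= events$t_open_s[k] &
         trace$time_s < events$t_close_s[k] + event_exclusion_s)
    }
  }
  list(
    max_deviation_c = max(dev),
    max_event_deviation_c = if (any(in_event)) max(dev[in_event]) else NA_real_,
    band_occupancy = if (any(!in_event)) mean(dev[!in_event] <= band_c)
                     else NA_real_,
    n_events = if (is.null(events)) 0L else nrow(events)
  )
}

#' Read / write temperature traces as CSV
#'
#' Columns `time_s, temp_c, duty, hood_open`.
#' @param path File path.
#' @return `read_trace()` returns an `rf_temp_trace`; `write_trace()`
#'   returns `path` invisibly.
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "temp_c")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("trace CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.unsorted(d$time_s, strictly = TRUE)) {
    stop("trace `time_s` must be strictly increasing", call. = FALSE)
  }
  structure(d, events = gen_hood_schedule(0),
            class = c("rf_temp_trace", "data.frame"))
}

#' @rdname read_trace
#' @param trace An `rf_temp_trace`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
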
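#' Effect profiles for the Ct-table generator
#'
#' Named per-condition true fold changes with baseline Ct values and
#' replicate noise, used to generate qPCR tables with a known ground truth.
#' The shipped profiles encode the verbally reported effect sizes of the
#' amplitude-ladder experiments - they are paper-derived parameters, not
#' deposited data (the raw figure data are not public):
#' \itemize{
#'   \item `"kiaa_biphasic"`: 2.5-fold stimulation at +10 dBm, unresponsive at
#'     0/-10/-20 dBm, 5-fold at -30 and -40 dBm (the U-shaped profile);
#'   \item `"krt79_peak"`: 10-fold stimulation at -10 dBm, 0.5-fold
#'     (two-fold decrease) at 0 dBm, otherwise unresponsive;
#'   \item `"null"`: every condition at fold 1.
#' }
#'
#' @param name One of `"kiaa_biphasic"`, `"krt79_peak"`, `"null"`, or `"custom"`.
#' @param folds For `name = "custom"`: named numeric vector of true fold
#'   changes per condition, which must include the control at fold 1.
#' @param gene Target gene label.
#' @param control_condition Control label (fold fixed at 1).
#' @param ref_baseline_ct,target_baseline_ct Baseline Ct of the reference /
#'   target gene at fold 1, in cycles.
#' @param noise_sd Replicate noise standard deviation on the cycle scale,
#'   in cycles (default 0.15, typical qPCR replicate variation).
#' @return Object of class `rf_effect_profile`.
#' @export
effect_profile <- function(name = c("kiaa_biphasic", "krt79_peak", "null",
                                    "custom"),
                           folds = NULL, gene = NULL,
                           control_condition = "sham",
                           ref_baseline_ct = 18, target_baseline_ct = 24,
                           noise_sd = 0.15) {
  name <- match.arg(name)
  ladder1 <- function(vals) {
    f <- c(1, vals)
    names(f) <- c(control_condition,
                  "+10dBm", "0dBm", "-10dBm", "-20dBm", "-30dBm", "-40dBm")
    f
  }
  if (name == "kiaa_biphasic") {
    folds <- ladder1(c(2.5, 1, 1, 1, 5, 5))
    if (is.null(gene)) gene <- "KIAA1211"
  } else if (name == "krt79_peak") {
    folds <- ladder1(c(1, 0.5, 10, 1, 1, 1))
    if (is.null(gene)) gene <- "KRT79"
  } else if (name == "null") {
    folds <- ladder1(c(1, 1, 1, 1, 1, 1))
    if (is.null(gene)) gene <- "NULLGENE"
  } else {
    if (is.null(folds) || is.null(names(folds))) {
      stop("custom profile needs a named `folds` vector", call. = FALSE)
    }
    if (is.null(gene)) gene <- "GENE1"
    if (!control_condition %in% names(folds)) {
      folds <- c(stats::setNames(1, control_condition), folds)
    }
  }
  if (any(folds <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (folds[[control_condition]] != 1) {
    stop("control condition fold must be 1", call. = FALSE)
  }
  stopifnot(noise_sd >= 0)
  structure(
    list(name = name, gene = gene, folds = folds,
         control_condition = control_condition,
         ref_baseline_ct = ref_baseline_ct,
         target_baseline_ct = target_baseline_ct,
         noise_sd = noise_sd),
    class = "rf_effect_profile"
  )
}

#' Generate a synthetic qPCR Ct table
#'
#' For every condition and replicate the reference-gene Ct is drawn as
#' Normal(ref baseline, sd) and the target-gene Ct as
#' Normal(target baseline - log2(true fold), sd): noise is Normal on the
#' cycle scale, hence lognormal on the quantity scale. With `noise_sd = 0`
#' the downstream pipeline recovers every fold exactly. Output is
#' reproducible per seed.
#'
#' @param profile An [effect_profile()] (or list of them sharing one
#'   reference gene, for multi-gene tables).
#' @param replicates Biological replicates per condition (default 3).
#' @param noise_sd Override the profile's cycle-scale noise sd.
#' @param seed RNG seed.
#' @param ref_gene Reference gene label (default "GAPDH").
#' @return Data.frame `gene, condition, replicate, ct` containing the
#'   reference gene and every target gene, with the true folds attached as
#'   attribute `"truth"`.
#' @export
gen_ct_table <- function(profile, replicates = 3, noise_sd = NULL,
                         seed = NULL, ref_gene = "GAPDH") {
  if (inherits(profile, "rf_effect_profile")) profile <- list(profile)
  stopifnot(length(profile) >= 1,
            all(vapply(profile, inherits, logical(1), "rf_effect_profile")),
            replicates >= 1)
  conds <- names(profile[[1]]$folds)
  for (p in profile) stopifnot(identical(names(p$folds), conds))
  if (!is.null(seed)) set.seed(seed)

  grid <- expand.grid(replicate = seq_len(replicates), condition = conds,
                      stringsAsFactors = FALSE)
  sd0 <- if (is.null(noise_sd)) profile[[1]]$noise_sd else noise_sd
  rows <- data.frame(
    gene = ref_gene, condition = grid$condition, replicate = grid$replicate,
    ct = profile[[1]]$ref_baseline_ct + rnorm_or_zero(nrow(grid), sd0)
  )
  for (p in profile) {
    sdp <- if (is.null(noise_sd)) p$noise_sd else noise_sd
    mu <- p$target_baseline_ct - log2(p$folds[grid$condition])
    rows <- rbind(rows, data.frame(
      gene = p$gene, condition = grid$condition, replicate = grid$replicate,
      ct = mu + rnorm_or_zero(nrow(grid), sdp)
    ))
  }
  truth <- do.call(rbind, lapply(profile, function(p) {
    data.frame(gene = p$gene, condition = names(p$folds),
               true_fold = unname(p$folds))
  }))
  rownames(rows) <- rownames(truth) <- NULL
  structure(rows, truth = truth)
}

rnorm_or_zero <- function(n, sd) {
  if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
}

#' Generate a probe measurement ladder from true power fluxes
#'
#' Inverts the dosimetry chain to the noiseless analyzer reading
#' (\eqn{E = \sqrt{P_{EMG}\,\eta_0}}, \eqn{U = E/AF},
#' \eqn{P_{ELEC} = U^2/Z_0}, \eqn{P_{MES} = P_{ELEC} A_{CABLE}}), adds
#' Gaussian noise on the dB scale (multiplicative in power, matching
#' instrument behaviour), and applies the sensitivity floor: readings below
#' it become `NA` (below-floor flags).
#'
#' @param true_pemg_w_per_m2 True incident power fluxes, W/m^2 (> 0).
#' @param cal An [rf_calibration()].
#' @param noise_db_sd Reading noise sd in dB (default 0).
#' @param seed RNG seed.
#' @param p_gene_dbm Optional generator-power labels for the rungs.
#' @param axis Probe axis label (default "x").
#' @param frequency_hz Carrier frequency (default 1.77e9).
#' @return Measurement data.frame `p_gene_dbm, axis, p_mes_dbm, frequency_hz`
#'   with the truth attached as attribute `"truth"`.
#' @export
gen_probe_ladder <- function(true_pemg_w_per_m2, cal = rf_calibration(),
                             noise_db_sd = 0, seed = NULL,
                             p_gene_dbm = NULL, axis = "x",
                             frequency_hz = 1.77e9) {
  stopifnot(is.numeric(true_pemg_w_per_m2), all(true_pemg_w_per_m2 > 0),
            inherits(cal, "rf_calibration"), noise_db_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  e <- sqrt(true_pemg_w_per_m2 * cal$wave_impedance_ohm)
  u <- e / cal$antenna_factor_per_m
  p_elec <- u^2 / cal$port_impedance_ohm
  p_mes <- watt_to_dbm(p_elec * cal$a_cable) +
    rnorm_or_zero(length(true_pemg_w_per_m2), noise_db_sd)
  p_mes[p_mes < cal$sensitivity_floor_dbm] <- NA_real_
  if (is.null(p_gene_dbm)) {
    p_gene_dbm <- seq_along(true_pemg_w_per_m2)  # rung index placeholder
  }
  structure(
    data.frame(p_gene_dbm = p_gene_dbm, axis = axis, p_mes_dbm = p_mes,
               frequency_hz = frequency_hz),
    truth = data.frame(p_gene_dbm = p_gene_dbm,
                       true_pemg_w_per_m2 = true_pemg_w_per_m2)
  )
}

#' Generate a field map with target inhomogeneity and polarization
#'
#' Constructs a lognormal power field and rescales it affinely over the
#' Petri mask so the mask mean and the population coefficient of variation
#' hit the targets exactly. E components are x-dominant with
#' \eqn{|E_x| = \sqrt{2 \eta P}} (peak amplitude of a plane wave carrying
#' flux P) and \eqn{|E_y|, |E_z|} set to the requested mean-magnitude
#' ratios; H is the ideal plane-wave companion
#' \eqn{\hat z \times \vec E / \eta}, optionally scaled to detune the
#' plane-wave ratio.
#'
#' @param mean_power_w_per_m2 Target mask-mean power flux (> 0).
#' @param target_inhom_percent Target inhomogeneity (>= 0); 0 gives a
#'   uniform map.
#' @param polarization Length-2 numeric `c(ez_ex, ey_ex)` mean-magnitude
#'   ratios (default `c(0, 0)`, pure x polarization).
#' @param grid_size Grid side in pixels (default 61 at 1 mm pitch, covering
#'   the 52 mm dish).
#' @param seed RNG seed.
#' @param h_scale Scale factor applied to H (default 1; `1/1.01` makes the
#'   plane-wave ratio 1.01).
#' @param ... Passed to [field_map()].
#' @return An [field_map()] with power, E and H grids; generation targets
#'   attached as attribute `"truth"`.
#' @export
gen_field_map <- function(mean_power_w_per_m2, target_inhom_percent = 7,
                          polarization = c(0, 0), grid_size = 61,
                          seed = NULL, h_scale = 1, ...) {
  stopifnot(mean_power_w_per_m2 > 0, target_inhom_percent >= 0,
            length(polarization) == 2, all(polarization >= 0),
            grid_size >= 3, h_scale > 0)
  if (!is.null(seed)) set.seed(seed)
  skeleton <- field_map(power = matrix(1, grid_size, grid_size), ...)
  msk <- petri_mask(skeleton)
  power <- matrix(mean_power_w_per_m2, grid_size, grid_size)
  if (target_inhom_percent > 0) {
    raw <- matrix(stats::rlnorm(grid_size^2, 0, 0.25), grid_size, grid_size)
    v <- raw[msk]
    npix <- length(v)
    sd_pop <- stats::sd(v) * sqrt((npix - 1) / npix)
    z <- (raw - mean(v)) / sd_pop            # mask pop-mean 0, pop-sd 1
    power <- mean_power_w_per_m2 *
      (1 + target_inhom_percent / 100 * z)
    if (any(power < 0)) {
      stop("target inhomogeneity too large for the lognormal draw ",
           "(negative power); lower the target", call. = FALSE)
    }
  }
  eta <- skeleton$wave_impedance_ohm
  ex <- sqrt(2 * eta * power)
  e <- list(x = matrix(as.complex(ex), grid_size),
            z = matrix(as.complex(polarization[1] * ex), grid_size),
            y = matrix(as.complex(polarization[2] * ex), grid_size))
  # ideal plane-wave companion: H = z_hat x E / eta (Ez carries no H here)
  h <- list(x = -e$y / eta * h_scale,
            y = e$x / eta * h_scale,
            z = matrix(as.complex(0), grid_size, grid_size))
  structure(
    field_map(power = power, e = e[c("x", "y", "z")], h = h, ...),
    truth = list(mean_power_w_per_m2 = mean_power_w_per_m2,
                 target_inhom_percent = target_inhom_percent,
                 polarization = polarization, h_scale = h_scale)
  )
}

#' Generate a hood-opening schedule
#'
#' Deterministic list of disjoint hood-open intervals, defaulting to the two
#' openings of a regulation cycle (sample insertion and removal).
#'
#' @param n_events Number of openings (default 2).
#' @param open_duration_s Duration of each opening, s (default 30).
#' @param spacing_s Time between consecutive openings (start to start), s.
#' @param start_s Time of the first opening, s.
#' @return Data.frame `t_open_s, t_close_s` (zero rows when `n_events = 0`).
#' @export
gen_hood_schedule <- function(n_events = 2, open_duration_s = 30,
                              spacing_s = 900, start_s = 600) {
  stopifnot(n_events >= 0, open_duration_s > 0, spacing_s > 0, start_s >= 0)
  if (n_events == 0) {
    return(data.frame(t_open_s = numeric(0), t_close_s = numeric(0)))
  }
  t_open <- start_s + (seq_len(n_events) - 1) * spacing_s
  sched <- data.frame(t_open_s = t_open, t_close_s = t_open + open_duration_s)
  if (n_events > 1 && any(sched$t_close_s[-n_events] > sched$t_open_s[-1])) {
    stop("hood events overlap: spacing_s must exceed open_duration_s",
         call. = FALSE)
  }
  sched
}
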
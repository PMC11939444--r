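#' Validate a Ct table
#'
#' Checks the schema (columns `gene, condition, replicate, ct`), finiteness
#' of Ct values, presence of the reference gene for every (condition,
#' replicate), presence of the control condition, and replicate counts.
#'
#' @param ct Data.frame to check.
#' @param ref_gene Reference gene label.
#' @param control_condition Control condition label.
#' @param min_replicates Minimum replicates per (gene, condition) for
#'   statistics (default 2).
#' @return Character vector of error messages (empty when valid).
#' @export
validate_ct_table <- function(ct, ref_gene = "GAPDH",
                              control_condition = "sham",
                              min_replicates = 2) {
  errs <- character(0)
  need <- c("gene", "condition", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) {
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(ct$ct))
  if (length(bad)) {
    errs <- c(errs, paste0("non-finite ct at row(s): ",
                           paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (!ref_gene %in% ct$gene) {
    errs <- c(errs, paste0("reference gene '", ref_gene, "' absent"))
  } else {
    samples <- unique(ct[ct$gene != ref_gene, c("condition", "replicate")])
    refs <- ct[ct$gene == ref_gene, c("condition", "replicate")]
    key <- function(d) paste(d$condition, d$replicate)
    gap <- samples[!key(samples) %in% key(refs), , drop = FALSE]
    if (nrow(gap)) {
      errs <- c(errs, paste0(
        "reference gene '", ref_gene, "' missing for (condition, replicate): ",
        paste(paste0(gap$condition, "/", gap$replicate), collapse = ", ")))
    }
    dup <- refs[duplicated(key(refs)), , drop = FALSE]
    if (nrow(dup)) {
      errs <- c(errs, paste0("duplicate reference-gene rows for: ",
                             paste(paste0(dup$condition, "/", dup$replicate),
                                   collapse = ", ")))
    }
  }
  if (!control_condition %in% ct$condition) {
    errs <- c(errs, paste0("control condition '", control_condition,
                           "' absent"))
  }
  tgt <- ct[ct$gene != ref_gene, ]
  if (nrow(tgt)) {
    cnt <- stats::aggregate(replicate ~ gene + condition, tgt, length)
    short <- cnt[cnt$replicate < min_replicates, , drop = FALSE]
    if (nrow(short)) {
      errs <- c(errs, paste0(
        "fewer than ", min_replicates, " replicates for: ",
        paste(paste0(short$gene, "/", short$condition), collapse = ", ")))
    }
  }
  errs
}

#' Validate a probe measurement ladder
#'
#' @param ladder Data.frame with columns `p_gene_dbm, axis, p_mes_dbm`.
#' @return Character vector of error messages (empty when valid).
#' @export
validate_measurements <- function(ladder) {
  errs <- character(0)
  need <- c("p_gene_dbm", "axis", "p_mes_dbm")
  miss <- setdiff(need, names(ladder))
  if (length(miss)) {
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!nrow(ladder)) return("ladder is empty")
  if (!all(ladder$axis %in% c("x", "y", "z"))) {
    errs <- c(errs, "axis must be one of 'x', 'y', 'z'")
  }
  key <- paste(ladder$p_gene_dbm, ladder$axis)
  if (anyDuplicated(key)) {
    errs <- c(errs, paste0("duplicate (p_gene_dbm, axis) rung(s): ",
                           paste(unique(key[duplicated(key)]),
                                 collapse = ", ")))
  }
  if (any(!is.finite(ladder$p_gene_dbm))) {
    errs <- c(errs, "non-finite p_gene_dbm")
  }
  errs
}

#' Validate a set of input files against their schemas
#'
#' @param ct_path,measurements_path,calibration_path Optional file paths;
#'   `NULL` entries are skipped.
#' @param ... Passed to [validate_ct_table()].
#' @return Data.frame `file, error` with one row per problem (zero rows when
#'   everything is valid).
#' @export
validate_inputs <- function(ct_path = NULL, measurements_path = NULL,
                            calibration_path = NULL, ...) {
  out <- data.frame(file = character(0), error = character(0))
  add <- function(file, errs) {
    if (length(errs)) {
      out <<- rbind(out, data.frame(file = file, error = errs))
    }
  }
  try_read <- function(path, reader, validator) {
    if (!file.exists(path)) return(add(path, "file not found"))
    d <- tryCatch(reader(path), error = function(e) conditionMessage(e))
    if (is.character(d)) add(path, d) else add(path, validator(d))
  }
  if (!is.null(ct_path)) {
    try_read(ct_path, utils::read.csv, function(d)
      validate_ct_table(d, ...))
  }
  if (!is.null(measurements_path)) {
    try_read(measurements_path, read_measurements, validate_measurements)
  }
  if (!is.null(calibration_path)) {
    c_err <- tryCatch({ read_calibration(calibration_path); character(0) },
                      error = function(e) conditionMessage(e))
    add(calibration_path, c_err)
  }
  rownames(out) <- NULL
  out
}

#' Read / write measurement ladders as CSV
#'
#' Columns `p_gene_dbm, axis, p_mes_dbm, frequency_hz`; an empty `p_mes_dbm`
#' cell marks a below-floor reading.
#'
#' @param path File path.
#' @return `read_measurements()` returns a data.frame; the writer returns
#'   `path` invisibly.
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path)
  if ("p_mes_dbm" %in% names(d)) d$p_mes_dbm <- as.numeric(d$p_mes_dbm)
  d
}

#' @rdname read_measurements
#' @param ladder Measurement data.frame.
#' @export
write_measurements <- function(ladder, path) {
  utils::write.csv(ladder, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an exposure table as CSV
#'
#' Below-floor rungs render their estimate cells as `---`, mirroring how the
#' published table marks the rung the analyzer could not measure.
#'
#' @param tab Output of [build_exposure_table()].
#' @param path File path.
#' @export
write_exposure_table <- function(tab, path) {
  out <- tab
  for (col in c("p_mes_dbm", "p_elec_w", "e_field_v_per_m",
                "p_emg_w_per_m2")) {
    if (col %in% names(out)) {
      v <- formatC(out[[col]], digits = 6, format = "g")
      v[out$below_floor] <- "---"
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run the full exposure-characterisation and readout pipeline
#'
#' Executes, in order: the dosimetry exposure table, ICNIRP safety margins,
#' the worst-case thermal budget, the qPCR relative-expression analysis, and
#' the dose-response profile classification; writes every stage's CSV plus a
#' human-readable Markdown report into `out_dir`. Every calibration constant
#' and the seed appear in the report header, and identical configurations
#' produce identical output bundles.
#'
#' @param measurements Measurement ladder data.frame (or path to its CSV).
#' @param ct Ct table data.frame (or path), or `NULL` to skip the qPCR stage.
#' @param cal An [rf_calibration()] (or path to a calibration YAML).
#' @param out_dir Output directory (created if needed).
#' @param f_mhz Carrier frequency in MHz for the safety stage (default 1770).
#' @param ladder Amplitude-ordered exposure conditions for profiling
#'   (increasing amplitude, control excluded).
#' @param ref_gene,control_condition,alpha qPCR analysis parameters.
#' @param exposure_h,dish_diameter_m,volume_m3 Thermal-budget inputs.
#' @return Invisibly, a list with the computed tables and the report path.
#' @export
run_pipeline <- function(measurements, ct = NULL, cal = rf_calibration(),
                         out_dir = tempfile("rfdosim_run_"),
                         f_mhz = 1770,
                         ladder = c("-40dBm", "-30dBm", "-20dBm", "-10dBm",
                                    "0dBm", "+10dBm"),
                         ref_gene = "GAPDH", control_condition = "sham",
                         alpha = 0.05, exposure_h = 0.25,
                         dish_diameter_m = 0.053, volume_m3 = 4.5e-6) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(ct)) ct <- utils::read.csv(ct)
  if (is.character(cal)) cal <- read_calibration(cal)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tab <- build_exposure_table(measurements, cal)
  write_exposure_table(tab, file.path(out_dir, "exposure_table.csv"))

  lim <- icnirp_limits(f_mhz)
  margins <- exposure_margin(tab$p_emg_w_per_m2, lim)
  budget <- delta_t_budget(max(tab$p_emg_w_per_m2, na.rm = TRUE),
                           dish_diameter_m = dish_diameter_m,
                           duration_h = exposure_h, volume_m3 = volume_m3)

  results <- profiles <- NULL
  if (!is.null(ct)) {
    results <- relative_expression(ct, ref_gene, control_condition)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    profiles <- profile_dose_response(results, ladder, alpha = alpha)
    utils::write.csv(profiles, file.path(out_dir, "profiles.csv"),
                     row.names = FALSE)
  }

  report <- file.path(out_dir, "report.md")
  lines <- c(
    "# RF exposure run report",
    "",
    "## Calibration constants",
    sprintf("- A_CABLE = %.5g (%.4g dB)", cal$a_cable,
            cal$cable_attenuation_db),
    sprintf("- AF = %.5g 1/m", cal$antenna_factor_per_m),
    sprintf("- Z0 = %.4g ohm", cal$port_impedance_ohm),
    sprintf("- eta0 = %.4g ohm", cal$wave_impedance_ohm),
    sprintf("- sensitivity floor = %.4g dBm", cal$sensitivity_floor_dbm),
    "",
    "## Exposure table",
    sprintf("- %d rungs (%d below floor); P_EMG from %.3g to %.3g W/m^2",
            nrow(tab), sum(tab$below_floor),
            min(tab$p_emg_w_per_m2, na.rm = TRUE),
            max(tab$p_emg_w_per_m2, na.rm = TRUE)),
    "",
    sprintf("## ICNIRP reference levels at %g MHz", f_mhz),
    sprintf("- E_max = %.5g V/m; H_max = %.5g A/m; S_max = %.5g W/m^2",
            lim$e_max_v_per_m, lim$h_max_a_per_m, lim$p_emg_max_w_per_m2),
    sprintf("- largest exposure margin = %.3g (fraction of S_max)",
            max(margins, na.rm = TRUE)),
    "",
    "## Worst-case thermal budget",
    sprintf(paste0("- lossless heating bound at max amplitude, %.3g h, ",
                   "%.3g m dish, %.3g m^3 water: %.3g degC"),
            exposure_h, dish_diameter_m, volume_m3, budget)
  )
  if (!is.null(profiles)) {
    lines <- c(lines, "", "## Dose-response profiles",
               sprintf("- %s: %s", profiles$gene, profiles$shape))
  }
  writeLines(lines, report)

  invisible(list(exposure_table = tab, limits = lim, margins = margins,
                 delta_t_c = budget, results = results, profiles = profiles,
                 report = report, out_dir = out_dir))
}
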
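#' Per-replicate relative quantities from a Ct table
#'
#' Single-reference-gene relative quantification. For each (condition,
#' replicate) sample, \eqn{\Delta Ct = Ct_{target} - Ct_{ref}}; the
#' per-replicate relative quantity is \eqn{2^{-\Delta Ct}} normalised to the
#' control condition. Two normalisations are offered: `"arithmetic"`
#' (default) divides by the arithmetic mean of the control-replicate
#' quantities, so the control mean fold is exactly 1; `"geometric"`
#' subtracts the mean control \eqn{\Delta Ct} on the cycle scale (the
#' classic \eqn{2^{-\Delta\Delta Ct}} form), equivalent to dividing by the
#' geometric mean. They coincide when control replicates are noiseless.
#'
#' @param ct A Ct table: data.frame with columns `gene`, `condition`,
#'   `replicate`, `ct` (and optionally `batch`). The reference gene must be
#'   present for every (condition, replicate).
#' @param ref_gene Reference (housekeeping) gene identifier, default "GAPDH".
#' @param control_condition Label of the sham/control condition,
#'   default "sham".
#' @param norm `"arithmetic"` or `"geometric"` control normalisation.
#' @return Data.frame `gene, condition, replicate, delta_ct, fold` with one
#'   row per target-gene replicate.
#' @export
relative_quantities <- function(ct, ref_gene = "GAPDH",
                                control_condition = "sham",
                                norm = c("arithmetic", "geometric")) {
  norm <- match.arg(norm)
  errs <- validate_ct_table(ct, ref_gene = ref_gene,
                            control_condition = control_condition)
  if (length(errs)) {
    stop("invalid Ct table:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  ref <- ct[ct$gene == ref_gene, ]
  tgt <- ct[ct$gene != ref_gene, ]
  key <- function(d) paste(d$condition, d$replicate, sep = "\r")
  ref_ct <- ref$ct[match(key(tgt), key(ref))]
  tgt$delta_ct <- tgt$ct - ref_ct
  out <- do.call(rbind, lapply(split(tgt, tgt$gene), function(g) {
    ctrl_dct <- g$delta_ct[g$condition == control_condition]
    rq <- 2^(-g$delta_ct)
    fold <- switch(norm,
      arithmetic = rq / mean(2^(-ctrl_dct)),
      geometric  = 2^(-(g$delta_ct - mean(ctrl_dct)))
    )
    data.frame(gene = g$gene, condition = g$condition,
               replicate = g$replicate, delta_ct = g$delta_ct, fold = fold)
  }))
  rownames(out) <- NULL
  out
}

#' Relative expression with ANOVA/Tukey significance
#'
#' Summarises [relative_quantities()] per gene and condition (mean fold
#' change, SEM, n) and attaches Tukey-adjusted p-values from a per-gene
#' one-way ANOVA across conditions, each exposure condition compared to the
#' control only ([anova_tukey()]), plus significance stars
#' ([significance_stars()]).
#'
#' @inheritParams relative_quantities
#' @param log2_scale If `TRUE`, run the ANOVA on log2 fold changes instead of
#'   linear ones. Default `FALSE`.
#' @return Data.frame `gene, condition, n, fold_change, sem, p_adj, stars`;
#'   the control rows carry `p_adj = NA` and `stars = ""`.
#' @examples
#' ct <- gen_ct_table(effect_profile("kiaa_biphasic"), replicates = 3,
#'                    noise_sd = 0.15, seed = 42)
#' relative_expression(ct)
#' @export
relative_expression <- function(ct, ref_gene = "GAPDH",
                                control_condition = "sham",
                                norm = c("arithmetic", "geometric"),
                                log2_scale = FALSE) {
  rq <- relative_quantities(ct, ref_gene, control_condition, norm)
  out <- do.call(rbind, lapply(split(rq, rq$gene), function(g) {
    agg <- do.call(rbind, lapply(split(g, g$condition), function(cc) {
      data.frame(gene = cc$gene[1], condition = cc$condition[1],
                 n = nrow(cc), fold_change = mean(cc$fold),
                 sem = stats::sd(cc$fold) / sqrt(nrow(cc)))
    }))
    padj <- anova_tukey(g, control_condition = control_condition,
                        log2_scale = log2_scale)
    agg$p_adj <- padj$p_adj[match(agg$condition, padj$condition)]
    agg
  }))
  out$stars <- ifelse(is.na(out$p_adj), "", significance_stars(out$p_adj))
  # control first, then decreasing amplitude label order as given
  out <- out[order(out$gene, out$condition != control_condition,
                   out$condition), ]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey contrasts against the control
#'
#' Fits `fold ~ condition` for one gene's replicate-level quantities with
#' [stats::aov()], then extracts the Tukey HSD adjusted p-value of each
#' exposure condition versus the control from [stats::TukeyHSD()]. If every
#' observation is identical (no between- and no within-group variation) the
#' family of p-values is 1 by convention.
#'
#' @param rq Replicate-level data.frame with columns `condition`, `fold`
#'   (one gene).
#' @param control_condition Control label.
#' @param log2_scale Run the ANOVA on log2(fold).
#' @return Data.frame `condition, p_adj` for the non-control conditions.
#' @export
anova_tukey <- function(rq, control_condition = "sham", log2_scale = FALSE) {
  stopifnot(all(c("condition", "fold") %in% names(rq)))
  conds <- unique(rq$condition)
  if (!control_condition %in% conds) {
    stop("control condition '", control_condition, "' not present",
         call. = FALSE)
  }
  if (length(conds) < 2) {
    stop("need at least 2 conditions for ANOVA", call. = FALSE)
  }
  tab <- table(rq$condition)
  if (any(tab < 2)) {
    stop("every condition needs >= 2 replicates for ANOVA; short: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  y <- if (log2_scale) log2(rq$fold) else rq$fold
  grp <- factor(rq$condition)
  others <- setdiff(conds, control_condition)
  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    return(data.frame(condition = others, p_adj = 1))
  }
  fit <- stats::aov(y ~ grp)
  tk <- stats::TukeyHSD(fit)$grp
  cmp <- rownames(tk)
  p_adj <- vapply(others, function(cc) {
    i <- match(TRUE, cmp == paste0(cc, "-", control_condition) |
                     cmp == paste0(control_condition, "-", cc))
    unname(tk[i, "p adj"])
  }, numeric(1))
  data.frame(condition = others, p_adj = unname(p_adj), row.names = NULL)
}

#' Shapiro-Wilk normality check of a replicate set
#'
#' Advisory only: the analysis pipeline reports the p-value but does not
#' switch to a non-parametric test on failure.
#'
#' @param values Numeric replicate values.
#' @return List `p_value` (NA when not computable), `computable`, `note`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    return(list(p_value = NA_real_, computable = FALSE,
                note = "fewer than 3 finite values"))
  }
  if (length(values) > 5000) {
    return(list(p_value = NA_real_, computable = FALSE,
                note = "more than 5000 values"))
  }
  if (stats::sd(values) == 0) {
    return(list(p_value = NA_real_, computable = FALSE,
                note = "zero variance"))
  }
  list(p_value = stats::shapiro.test(values)$p.value, computable = TRUE,
       note = "")
}

#' Significance star labels
#'
#' Strict-inequality thresholds: p < 0.0001 "****", < 0.001 "***",
#' < 0.01 "**", < 0.05 "*", otherwise "ns". Boundary values take the weaker
#' label.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p < 0.05]   <- "*"
  out[p < 0.01]   <- "**"
  out[p < 0.001]  <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' Classify a gene's amplitude-response profile
#'
#' Deterministic shape rule over an amplitude-ordered ladder of fold changes
#' with Tukey-adjusted p-values (control excluded from the ladder):
#' \itemize{
#'   \item no significant condition: `"flat"`;
#'   \item the significant conditions form exactly two same-direction runs
#'     anchored at the two ladder ends, separated by a non-significant
#'     interior gap: `"biphasic-U"` when the responses are up,
#'     `"biphasic-inverted"` when down - the hormetic signature of high
#'     response at both amplitude extremes and none in between;
#'   \item otherwise, if the significant fold changes are monotone in
#'     amplitude (Spearman |rho| >= `spearman_threshold` over the
#'     significant rungs): `"monotonic-up"` / `"monotonic-down"`;
#'   \item anything else: `"mixed"`.
#' }
#' This operationalisation of the verbal U-shape description is a package
#' design choice; both `alpha` and the Spearman threshold are exposed.
#'
#' @param results One gene's rows of [relative_expression()] output
#'   (columns `condition`, `fold_change`, `p_adj`).
#' @param ladder Character vector of condition labels in increasing
#'   amplitude order, control excluded.
#' @param alpha Significance level on `p_adj` (default 0.05).
#' @param spearman_threshold Monotonicity threshold on |rho| (default 0.8).
#' @return List `shape`, `significant` (named logical along the ladder),
#'   `direction` (named character), `ladder`.
#' @export
classify_dose_response <- function(results, ladder, alpha = 0.05,
                                   spearman_threshold = 0.8) {
  stopifnot(all(c("condition", "fold_change", "p_adj") %in% names(results)))
  if (length(ladder) < 3) {
    return(list(shape = "not-classifiable", significant = NULL,
                direction = NULL, ladder = ladder))
  }
  miss <- setdiff(ladder, results$condition)
  if (length(miss)) {
    stop("ladder condition(s) absent from results: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  i <- match(ladder, results$condition)
  fold <- results$fold_change[i]
  sig <- !is.na(results$p_adj[i]) & results$p_adj[i] < alpha
  dir <- ifelse(fold > 1, "up", "down")
  names(sig) <- names(dir) <- ladder
  m <- length(ladder)

  shape <- if (!any(sig)) {
    "flat"
  } else {
    runs <- rle(sig)
    two_anchored <- length(runs$values) >= 3 &&
      runs$values[1] && runs$values[length(runs$values)] &&
      sum(runs$values) == 2
    if (two_anchored && length(unique(dir[sig])) == 1) {
      if (dir[sig][1] == "up") "biphasic-U" else "biphasic-inverted"
    } else if (sum(sig) >= 2) {
      rho <- stats::cor(which(sig), fold[sig], method = "spearman")
      if (!is.na(rho) && abs(rho) >= spearman_threshold) {
        if (rho > 0) "monotonic-up" else "monotonic-down"
      } else "mixed"
    } else "mixed"
  }
  list(shape = shape, significant = sig, direction = dir, ladder = ladder)
}

#' Profile every gene in a results table
#'
#' @param results Output of [relative_expression()].
#' @param ladder Conditions in increasing amplitude order (control excluded).
#' @inheritParams classify_dose_response
#' @return Data.frame with one row per gene: `gene`, `shape`, and the
#'   per-rung fold changes as `fold_<condition>` columns.
#' @export
profile_dose_response <- function(results, ladder, alpha = 0.05,
                                  spearman_threshold = 0.8) {
  out <- do.call(rbind, lapply(split(results, results$gene), function(g) {
    cl <- classify_dose_response(g, ladder, alpha, spearman_threshold)
    row <- data.frame(gene = g$gene[1], shape = cl$shape)
    for (cc in ladder) {
      row[[paste0("fold_", cc)]] <- g$fold_change[match(cc, g$condition)]
    }
    row
  }))
  rownames(out) <- NULL
  out
}
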
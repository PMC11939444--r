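make_ct <- function(delta_ct_by_cond, reps = 3, ref_ct = 18, gene = "G1") {
  # builds a table where the target's delta-Ct is exactly as given
  rows <- list()
  for (cond in names(delta_ct_by_cond)) {
    for (r in seq_len(reps)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = c("GAPDH", gene), condition = cond, replicate = r,
        ct = c(ref_ct, ref_ct + delta_ct_by_cond[[cond]][r]))
    }
  }
  do.call(rbind, rows)
}

test_that("equal delta-Ct gives fold 1; one cycle less doubles expression", {
  ct <- make_ct(list(sham = c(6, 6, 6), "+10dBm" = c(6, 6, 6)))
  res <- relative_expression(ct)
  expect_equal(res$fold_change, c(1, 1))

  ct2 <- make_ct(list(sham = c(6, 6, 6), "+10dBm" = c(5, 5, 5)))
  res2 <- relative_expression(ct2)
  expect_equal(res2$fold_change[res2$condition == "+10dBm"], 2)
})

test_that("control mean fold is exactly 1 and sample shifts cancel", {
  ct <- gen_ct_table(effect_profile("kiaa_biphasic"), seed = 21)
  rq <- relative_quantities(ct)
  ctrl <- rq[rq$condition == "sham", ]
  expect_equal(mean(ctrl$fold), 1)

  # adding any constant to all Cts of one (condition, replicate) sample
  # leaves every fold unchanged (reference-gene normalization)
  shifted <- ct
  pick <- shifted$condition == "-30dBm" & shifted$replicate == 2
  shifted$ct[pick] <- shifted$ct[pick] + 3.7
  expect_equal(relative_quantities(shifted)$fold, rq$fold)
})

test_that("geometric normalisation matches the classic 2^-ddCt form", {
  ct <- gen_ct_table(effect_profile("kiaa_biphasic"), seed = 33)
  rq <- relative_quantities(ct, norm = "geometric")
  tgt <- ct[ct$gene != "GAPDH", ]
  ref <- ct[ct$gene == "GAPDH", ]
  dct <- tgt$ct - ref$ct[match(paste(tgt$condition, tgt$replicate),
                               paste(ref$condition, ref$replicate))]
  ddct <- dct - mean(dct[tgt$condition == "sham"])
  expect_equal(rq$fold, unname(2^(-ddct)))
})

test_that("missing reference gene rows are named in the error", {
  ct <- make_ct(list(sham = c(6, 6, 6), "+10dBm" = c(5, 5, 5)))
  ct <- ct[!(ct$gene == "GAPDH" & ct$condition == "+10dBm" &
             ct$replicate == 2), ]
  expect_error(relative_expression(ct), "\\+10dBm/2")
})

test_that("fold-change estimator recovers a 2.5-fold effect", {
  prof <- effect_profile("custom",
                         folds = c("+10dBm" = 2.5),
                         gene = "G1")
  ct <- gen_ct_table(prof, replicates = 3, noise_sd = 0.15, seed = 42)
  res <- relative_expression(ct)
  est <- res$fold_change[res$condition == "+10dBm"]
  expect_lt(abs(est - 2.5) / 2.5, 0.15)
})

test_that("normality check is advisory and guards degenerate input", {
  expect_false(normality_check(c(1, 2))$computable)
  expect_false(normality_check(rep(3, 10))$computable)
  set.seed(1)
  hits <- vapply(1:100, function(i) {
    normality_check(rnorm(50))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  set.seed(2)
  bimodal <- c(rnorm(25, -3, 0.2), rnorm(25, 3, 0.2))
  expect_lt(normality_check(bimodal)$p_value, 0.05)
})

test_that("Tukey with two groups reduces to the pairwise t-test", {
  set.seed(14)
  rq <- data.frame(condition = rep(c("sham", "+10dBm"), each = 4),
                   fold = c(rnorm(4, 1, 0.1), rnorm(4, 1.6, 0.1)))
  tk <- anova_tukey(rq)
  tt <- t.test(fold ~ condition, rq, var.equal = TRUE)$p.value
  expect_equal(tk$p_adj, tt, tolerance = 1e-3)
})

test_that("degenerate ANOVA inputs are handled by convention", {
  rq <- data.frame(condition = rep(c("sham", "a", "b"), each = 3), fold = 1)
  expect_equal(anova_tukey(rq)$p_adj, c(1, 1))
  # one zero-variance group among varying ones computes normally
  rq2 <- data.frame(condition = rep(c("sham", "a"), each = 3),
                    fold = c(1, 1, 1, 1.5, 1.6, 1.7))
  expect_true(is.finite(anova_tukey(rq2)$p_adj))
  expect_error(anova_tukey(data.frame(condition = "sham", fold = 1)),
               "2 conditions")
  expect_error(
    anova_tukey(data.frame(condition = c("sham", "sham", "a"),
                           fold = c(1, 1.1, 2))),
    ">= 2 replicates")
})

test_that("star labels use strict thresholds and are monotone", {
  expect_equal(significance_stars(c(0.03, 0.05, 5e-5, 0.2, 1e-3, 1e-2)),
               c("*", "ns", "****", "ns", "**", "*"))
  p <- sort(c(0, 10^seq(-6, 0, by = 0.25), 1e-4, 1e-3, 1e-2, 0.05, 1))
  lab <- significance_stars(p)
  rank <- c("****" = 4, "***" = 3, "**" = 2, "*" = 1, ns = 0)[lab]
  expect_true(all(diff(rank) <= 0))  # weaker labels as p grows
})

test_that("dose-response shapes follow the documented rule", {
  res <- function(folds, padj) {
    data.frame(condition = amplitude_ladder, fold_change = folds,
               p_adj = padj)
  }
  ns <- 0.5; sig <- 0.001
  # up at both ends, flat interior -> hormetic U
  kiaa <- res(c(5, 5, 1, 1, 1, 2.5), c(sig, sig, ns, ns, ns, sig))
  expect_equal(classify_dose_response(kiaa, amplitude_ladder)$shape,
               "biphasic-U")
  # down at both ends -> inverted
  inv <- res(c(0.3, 0.4, 1, 1, 1, 0.2), c(sig, sig, ns, ns, ns, sig))
  expect_equal(classify_dose_response(inv, amplitude_ladder)$shape,
               "biphasic-inverted")
  # nothing significant -> flat
  flat <- res(c(1.2, 0.9, 1, 1.1, 1, 1.3), rep(ns, 6))
  expect_equal(classify_dose_response(flat, amplitude_ladder)$shape, "flat")
  # strictly increasing significant folds -> monotonic-up
  mono <- res(c(1.2, 1.5, 2, 3, 4, 6), rep(sig, 6))
  expect_equal(classify_dose_response(mono, amplitude_ladder)$shape,
               "monotonic-up")
  mono_d <- res(c(0.8, 0.6, 0.5, 0.4, 0.3, 0.2), rep(sig, 6))
  expect_equal(classify_dose_response(mono_d, amplitude_ladder)$shape,
               "monotonic-down")
  # single interior response -> mixed
  mid <- res(c(1, 1, 3, 1, 1, 1), c(ns, ns, sig, ns, ns, ns))
  expect_equal(classify_dose_response(mid, amplitude_ladder)$shape, "mixed")
  # opposite directions at the two ends -> not biphasic
  opp <- res(c(3, 1, 1, 1, 1, 0.3), c(sig, ns, ns, ns, ns, sig))
  expect_false(classify_dose_response(opp, amplitude_ladder)$shape %in%
               c("biphasic-U", "biphasic-inverted"))
  # short ladders are not classifiable
  expect_equal(
    classify_dose_response(kiaa[1:2, ], amplitude_ladder[1:2])$shape,
    "not-classifiable")
})

test_that("profiles table classifies the seeded hormetic gene end to end", {
  ct <- gen_ct_table(list(effect_profile("kiaa_biphasic"),
                          effect_profile("null")), seed = 42)
  res <- relative_expression(ct)
  prof <- profile_dose_response(res, amplitude_ladder)
  expect_equal(prof$shape[prof$gene == "KIAA1211"], "biphasic-U")
  expect_equal(prof$shape[prof$gene == "NULLGENE"], "flat")
  expect_equal(prof[["fold_-30dBm"]][prof$gene == "KIAA1211"],
               res$fold_change[res$gene == "KIAA1211" &
                               res$condition == "-30dBm"])
})
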
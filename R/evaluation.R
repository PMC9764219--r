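#' Diagnostic classification and agreement statistics
#'
#' Scores predicted FFR against a reference at the clinical threshold
#' (positive = ischemic = FFR at or below the threshold): confusion
#' counts, sensitivity/specificity/PPV/NPV/accuracy in percent with exact
#' Clopper-Pearson 95% confidence intervals, Pearson correlation, and
#' Bland-Altman agreement (mean difference predicted - reference, SD, and
#' mean +/- 1.96 SD limits).
#'
#' @param predicted,reference equal-length numeric vectors of FFR values
#'   in `(0, 1.5)`.
#' @param threshold ischemic threshold (default 0.80; ties classify
#'   ischemic).
#' @param conf CI level.
#' @return a `diagnostic_report` list.
#' @examples
#' set.seed(1)
#' ref <- runif(40, 0.5, 1)
#' classify_and_score(ref + rnorm(40, 0, 0.03), ref)
#' @export
classify_and_score <- function(predicted, reference, threshold = 0.80,
                               conf = 0.95) {
  if (length(predicted) != length(reference))
    stop("input error: predicted and reference lengths differ")
  if (any(!is.finite(predicted)) || any(!is.finite(reference)))
    stop("input error: non-finite FFR values")
  if (any(predicted <= 0 | predicted >= 1.5) ||
      any(reference <= 0 | reference >= 1.5))
    stop("input error: FFR values must lie in (0, 1.5)")
  pos <- reference <= threshold
  pred_pos <- predicted <= threshold
  TP <- sum(pred_pos & pos); FP <- sum(pred_pos & !pos)
  TN <- sum(!pred_pos & !pos); FN <- sum(!pred_pos & pos)
  rate <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- as.numeric(binom.test(x, n, conf.level = conf)$conf.int)
    100 * c(x / n, ci[1], ci[2])
  }
  metrics <- rbind(sensitivity = rate(TP, TP + FN),
                   specificity = rate(TN, TN + FP),
                   PPV = rate(TP, TP + FP),
                   NPV = rate(TN, TN + FN),
                   accuracy = rate(TP + TN, length(pos)))
  colnames(metrics) <- c("pct", "ci_lo", "ci_hi")
  d <- predicted - reference
  ba <- list(mean_difference = mean(d), sd = sd(d),
             limits = mean(d) + c(-1, 1) * 1.96 * sd(d))
  r <- if (sd(predicted) > 0 && sd(reference) > 0)
    cor(predicted, reference) else NA_real_
  structure(list(counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
                 n = length(pos), metrics = metrics, pearson_r = r,
                 bland_altman = ba, threshold = threshold, conf = conf),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Diagnostic performance at FFR <= %.2f (n = %d; TP %d, FP %d, TN %d, FN %d)\n",
              x$threshold, x$n, x$counts["TP"], x$counts["FP"],
              x$counts["TN"], x$counts["FN"]))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %5.1f%% (%.1f-%.1f)\n", rownames(m)[i], m[i, 1],
                m[i, 2], m[i, 3]))
  cat(sprintf("  Pearson r %.3f; Bland-Altman %.3f +/- %.3f (limits %.3f, %.3f)\n",
              x$pearson_r, x$bland_altman$mean_difference, x$bland_altman$sd,
              x$bland_altman$limits[1], x$bland_altman$limits[2]))
  invisible(x)
}

#' ROC analysis with ischemic-threshold recovery
#'
#' Empirical ROC over all cutpoints of the predicted values (a case is
#' called positive when its predicted FFR is at or below the cutpoint,
#' positives defined by `reference <= threshold`), trapezoid AUC, and the
#' optimal operating cutpoint maximizing Youden's J = sensitivity -
#' (1 - specificity). Because every threshold between two adjacent
#' predicted values yields the same classification, the optimum is
#' reported as the interval from the optimal cutpoint to the next
#' distinct predicted value.
#'
#' @inheritParams classify_and_score
#' @return list with `AUC`, `optimal_threshold` (`c(lo, hi)`), `roc`
#'   (data frame of cutpoint, TPR, FPR), `threshold`.
#' @export
roc_threshold_recovery <- function(predicted, reference, threshold = 0.80) {
  if (length(predicted) != length(reference))
    stop("input error: predicted and reference lengths differ")
  pos <- reference <= threshold
  if (!any(pos) || all(pos))
    stop("ROC undefined error: reference labels contain a single class")
  cuts <- sort(unique(predicted))
  tpr <- vapply(cuts, function(ct) mean(predicted[pos] <= ct), numeric(1))
  fpr <- vapply(cuts, function(ct) mean(predicted[!pos] <= ct), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
  j <- tpr - fpr
  best <- which.max(j[-1]) # skip the empty-classifier point
  lo <- cuts[best]
  hi <- if (best < length(cuts)) cuts[best + 1] else lo
  list(AUC = auc, optimal_threshold = c(lo = lo, hi = hi),
       roc = data.frame(cutpoint = c(-Inf, cuts), TPR = tpr, FPR = fpr),
       threshold = threshold)
}

#' Patient-generalized clinical input values
#'
#' Cohort-average values used wherever a model configuration marks an
#' input as patient-generalized: MAP 87.3 mmHg, HR 70.8 bpm, CO 4.5
#' L/min, hematocrit 39.2%, ostial diameter 3.9 mm, distal location
#' 30 mm.
#'
#' @return named list of generalized values.
#' @export
generalized_inputs <- function() {
  list(MAP_mmHg = 87.3, HR_bpm = 70.8, CO_Lmin = 4.5,
       hematocrit_pct = 39.2, ostial_diameter_mm = 3.9,
       distal_location_mm = 30)
}

#' Build a streamlined model configuration
#'
#' Three model variants differing in which inputs are patient-specific:
#' * `baseline` — every input patient-specific.
#' * `semi-streamlined` — generalized MAP, heart rate, hematocrit, inlet
#'   cardiac output, waveform shape and ostial diameter; patient-specific
#'   cardiac output for the resistance distribution, stenosis, tree and
#'   distal location.
#' * `streamlined` — semi-streamlined with the distal location also
#'   generalized (30 mm).
#'
#' @param variant `"baseline"`, `"semi-streamlined"` or `"streamlined"`.
#' @param generalized generalized values (default [generalized_inputs()];
#'   pass cohort means to re-derive them from data).
#' @return a `model_config`: per-input source flags and the generalized
#'   values.
#' @export
build_model_config <- function(variant = c("baseline", "semi-streamlined",
                                           "streamlined"),
                               generalized = generalized_inputs()) {
  variant <- match.arg(variant)
  inputs <- c("MAP", "HR", "hematocrit", "inlet_CO", "resistance_CO",
              "distal_location", "waveform", "ostial_diameter")
  flags <- stats::setNames(rep("patient_specific", length(inputs)), inputs)
  if (variant != "baseline") {
    flags[c("MAP", "HR", "hematocrit", "inlet_CO", "waveform",
            "ostial_diameter")] <- "generalized"
  }
  if (variant == "streamlined") flags["distal_location"] <- "generalized"
  structure(list(variant = variant, flags = flags, generalized = generalized),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Model variant '%s':\n", x$variant))
  for (nm in names(x$flags)) cat(sprintf("  %-16s %s\n", nm, x$flags[nm]))
  invisible(x)
}

#' Apply a model configuration to a patient case
#'
#' Produces the effective patient record and [ffr_config()] for one model
#' variant: generalized flags replace the corresponding patient fields
#' with cohort-average values (the inlet cardiac output and waveform are
#' routed through the config so the resistance distribution can stay
#' patient-specific).
#'
#' @param case a cohort case (`list(tree, patient)`).
#' @param model a [build_model_config()] result.
#' @param config base [ffr_config()].
#' @return list `(patient, config)` ready for [simulate_ffr()].
#' @export
apply_model_config <- function(case, model, config = ffr_config()) {
  stopifnot(inherits(model, "model_config"))
  p <- case$patient
  g <- model$generalized
  f <- model$flags
  if (f["MAP"] == "generalized") p$MAP_mmHg <- g$MAP_mmHg
  if (f["HR"] == "generalized") p$HR_bpm <- g$HR_bpm
  if (f["hematocrit"] == "generalized") p$hematocrit_pct <- g$hematocrit_pct
  if (f["distal_location"] == "generalized")
    p$distal_location_mm <- min(g$distal_location_mm,
                                max_reachable_distal(case$tree,
                                                     case$tree$stenoses[[1]]) - 0.5)
  cfg <- config
  cfg$inlet_CO_Lmin <- if (f["inlet_CO"] == "generalized") g$CO_Lmin
  else config$inlet_CO_Lmin
  cfg$resistance_CO_Lmin <- if (f["resistance_CO"] == "generalized") g$CO_Lmin
  else config$resistance_CO_Lmin
  if (f["waveform"] == "generalized")
    cfg$waveform <- canonical_waveform(p$side)
  list(patient = p, config = cfg)
}

#' Compute FFR for a cohort under a model variant
#'
#' @param cases cohort cases.
#' @param variant model variant name, see [build_model_config()].
#' @param controls solver controls.
#' @param config base [ffr_config()].
#' @param generalized generalized input values.
#' @return numeric vector of FFR values, one per case.
#' @export
cohort_ffr <- function(cases, variant = "baseline",
                       controls = demo_controls(), config = ffr_config(),
                       generalized = generalized_inputs()) {
  model <- build_model_config(variant, generalized)
  vapply(cases, function(cs) {
    eff <- apply_model_config(cs, model, config)
    simulate_ffr(cs$tree, eff$patient, eff$config, controls)$FFR
  }, numeric(1))
}
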
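#' Uncertain clinical input
#'
#' One uncertain model input: its marginal distribution and how a sampled
#' value is applied to the baseline — `"value"` replaces the baseline,
#' `"factor"` multiplies it, `"addition"` adds to it (in the input's own
#' units, e.g. percentage points of stenosis degree).
#'
#' @param name input name.
#' @param kind `"value"`, `"factor"`, or `"addition"`.
#' @param dist `"normal"` or `"uniform"`.
#' @param mean,sd normal parameters.
#' @param min,max uniform parameters.
#' @return an `uncertain_input` list.
#' @export
uncertain_input <- function(name, kind = c("value", "factor", "addition"),
                            dist = c("normal", "uniform"),
                            mean = NULL, sd = NULL, min = NULL, max = NULL) {
  kind <- match.arg(kind); dist <- match.arg(dist)
  if (dist == "normal") {
    if (is.null(mean) || is.null(sd) || sd <= 0)
      stop("normal input needs mean and sd > 0")
  } else if (is.null(min) || is.null(max) || max <= min)
    stop("uniform input needs min < max")
  structure(list(name = name, kind = kind, dist = dist, mean = mean, sd = sd,
                 min = min, max = max), class = "uncertain_input")
}

#' Clinical input uncertainty distributions
#'
#' The four uncertain clinical inputs of the FFR uncertainty study and
#' their distributions: distal location replaced by N(30.0, 3.5) mm,
#' cardiac output multiplied by N(1, 0.153), stenosis degree shifted by
#' N(0, 16.9) percentage points, mean arterial pressure multiplied by
#' N(1, 0.056).
#'
#' @return named list of [uncertain_input()]s in the canonical order
#'   `distal_location, cardiac_output, stenosis_degree,
#'   mean_arterial_pressure`.
#' @export
clinical_uncertainty_inputs <- function() {
  list(distal_location = uncertain_input("distal_location", "value",
                                         mean = 30.0, sd = 3.5),
       cardiac_output = uncertain_input("cardiac_output", "factor",
                                        mean = 1, sd = 0.153),
       stenosis_degree = uncertain_input("stenosis_degree", "addition",
                                         mean = 0, sd = 16.9),
       mean_arterial_pressure = uncertain_input("mean_arterial_pressure",
                                                "factor", mean = 1,
                                                sd = 0.056))
}

q_input <- function(u, inp) {
  if (inp$dist == "normal") qnorm(u, inp$mean, inp$sd)
  else qunif(u, inp$min, inp$max)
}

#' Saltelli design for second-order Sobol estimation
#'
#' Builds the `n (2k + 2)` sample design supporting first-, second- and
#' total-order index estimation: base matrices A and B (Latin-hypercube
#' samples mapped through each input's inverse CDF) followed by the
#' radial blocks `AB_i` (A with column i from B) and `BA_i` (B with
#' column i from A). Deterministic for a fixed seed.
#'
#' @param inputs list of [uncertain_input()]s (k >= 2).
#' @param n base sample size (powers of 2 recommended).
#' @param seed integer seed.
#' @return numeric matrix with `n*(2k+2)` rows, one column per input, and
#'   attributes `k`, `n`, `input_names`, `blocks`.
#' @examples
#' d <- saltelli_sample(clinical_uncertainty_inputs(), n = 8, seed = 1)
#' nrow(d)  # 8 * (2*4 + 2) = 80
#' @export
saltelli_sample <- function(inputs, n, seed = 1) {
  k <- length(inputs)
  if (k < 2) stop("design error: at least 2 inputs are required")
  if (n < 2) stop("design error: base sample size must be >= 2")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  U <- lhs::randomLHS(n, 2L * k)
  Au <- U[, 1:k, drop = FALSE]
  Bu <- U[, (k + 1):(2 * k), drop = FALSE]
  blocks <- vector("list", 2 * k + 2)
  blocks[[1]] <- Au; blocks[[2]] <- Bu
  for (i in seq_len(k)) {
    ABi <- Au; ABi[, i] <- Bu[, i]
    blocks[[2 + i]] <- ABi
    BAi <- Bu; BAi[, i] <- Au[, i]
    blocks[[2 + k + i]] <- BAi
  }
  Um <- do.call(rbind, blocks)
  X <- vapply(seq_len(k), function(j) q_input(Um[, j], inputs[[j]]),
              numeric(nrow(Um)))
  colnames(X) <- unname(vapply(inputs, function(i) i$name, character(1)))
  structure(X, k = k, n = n, input_names = colnames(X),
            blocks = c("A", "B", paste0("AB", 1:k), paste0("BA", 1:k)),
            class = c("saltelli_design", "matrix", "array"))
}

split_design_outputs <- function(Y, k, n) {
  if (length(Y) != n * (2 * k + 2))
    stop(sprintf("output length %d does not match n(2k+2) = %d",
                 length(Y), n * (2 * k + 2)))
  YA <- Y[1:n]; YB <- Y[(n + 1):(2 * n)]
  YAB <- lapply(seq_len(k), function(i) Y[((1 + i) * n + 1):((2 + i) * n)])
  YBA <- lapply(seq_len(k), function(i)
    Y[((1 + k + i) * n + 1):((2 + k + i) * n)])
  list(YA = YA, YB = YB, YAB = YAB, YBA = YBA)
}

# estimators on one (possibly resampled, possibly multi-case) split.
# Each element may be a matrix (rows = base samples, cols = cases): the
# numerators are then pooled over cases and the variance is taken over the
# aggregate of all outputs.
sobol_point_estimates <- function(sp, k) {
  YA <- as.matrix(sp$YA); YB <- as.matrix(sp$YB)
  mu <- mean(cbind(YA, YB))
  YA <- YA - mu; YB <- YB - mu
  V <- var(c(YA, YB))
  if (!is.finite(V) || V <= 0) return(NULL)
  Si <- STi <- numeric(k)
  Vij <- matrix(NA_real_, k, k)
  YABc <- lapply(sp$YAB, function(m) as.matrix(m) - mu)
  YBAc <- lapply(sp$YBA, function(m) as.matrix(m) - mu)
  for (i in seq_len(k)) {
    Si[i] <- mean(YB * (YABc[[i]] - YA)) / V
    STi[i] <- mean((YA - YABc[[i]])^2) / (2 * V)
  }
  for (i in seq_len(k)) for (j in seq_len(k)) if (j > i) {
    Vc <- mean(YBAc[[i]] * YABc[[j]] - YA * YB) / V
    Vij[i, j] <- Vc - Si[i] - Si[j]
  }
  list(Si = Si, STi = STi, Sij = Vij, V = V)
}

#' Sobol sensitivity indices from Saltelli-design outputs
#'
#' First-order (main-effect) indices `Si` by the Saltelli-2010 estimator,
#' total-effect indices `STi` by the Jansen estimator, and second-order
#' interaction indices `Sij` from the `BA_i x AB_j` blocks. Percentile
#' bootstrap confidence intervals are computed by resampling the `n` base
#' rows; the convergence flag requires every CI width to be below 10% of
#' the largest index, and inputs whose total index exceeds
#' `significance_threshold` (default 0.05) are marked significant.
#'
#' @param Y model outputs in design row order (vector), or a matrix with
#'   one column per aggregated case (rows in design order).
#' @param design the [saltelli_sample()] used, or supply `k` and `n`.
#' @param k,n design dimensions if `design` is not given.
#' @param B bootstrap resamples (default 1000).
#' @param conf CI level (default 0.95).
#' @param significance_threshold index size considered significant.
#' @param seed seed for the bootstrap resampling.
#' @return a `sobol_result`: data frame `indices` (input, Si with CI, STi
#'   with CI), matrix `Sij`, total variance `V`, `converged`,
#'   `significant`.
#' @export
sobol_indices <- function(Y, design = NULL, k = NULL, n = NULL, B = 1000,
                          conf = 0.95, significance_threshold = 0.05,
                          seed = 1) {
  if (!is.null(design)) {
    k <- attr(design, "k"); n <- attr(design, "n")
    nms <- attr(design, "input_names")
  } else nms <- paste0("x", seq_len(k))
  if (is.null(k) || is.null(n)) stop("supply design or both k and n")
  Ym <- if (is.matrix(Y)) Y else matrix(Y, ncol = 1)
  if (any(!is.finite(Ym))) stop("outputs must be finite")
  if (nrow(Ym) != n * (2 * k + 2))
    stop(sprintf("output length %d does not match n(2k+2) = %d",
                 nrow(Ym), n * (2 * k + 2)))
  block <- function(b) Ym[((b - 1) * n + 1):(b * n), , drop = FALSE]
  sp <- list(YA = block(1), YB = block(2),
             YAB = lapply(seq_len(k), function(i) block(2 + i)),
             YBA = lapply(seq_len(k), function(i) block(2 + k + i)))
  pt <- sobol_point_estimates(sp, k)
  if (is.null(pt))
    stop("degenerate error: model output variance is zero; indices undefined")

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  bs_Si <- matrix(NA_real_, B, k); bs_STi <- matrix(NA_real_, B, k)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    spb <- list(YA = sp$YA[idx, , drop = FALSE],
                YB = sp$YB[idx, , drop = FALSE],
                YAB = lapply(sp$YAB, function(m) m[idx, , drop = FALSE]),
                YBA = lapply(sp$YBA, function(m) m[idx, , drop = FALSE]))
    pb <- sobol_point_estimates(spb, k)
    if (!is.null(pb)) { bs_Si[b, ] <- pb$Si; bs_STi[b, ] <- pb$STi }
  }
  al <- (1 - conf) / 2
  qs <- function(m) apply(m, 2, quantile, probs = c(al, 1 - al), na.rm = TRUE)
  ci_Si <- qs(bs_Si); ci_STi <- qs(bs_STi)
  widths <- c(ci_Si[2, ] - ci_Si[1, ], ci_STi[2, ] - ci_STi[1, ])
  max_index <- max(abs(c(pt$Si, pt$STi)))
  indices <- data.frame(input = nms, Si = pt$Si, Si_lo = ci_Si[1, ],
                        Si_hi = ci_Si[2, ], STi = pt$STi,
                        STi_lo = ci_STi[1, ], STi_hi = ci_STi[2, ],
                        row.names = NULL, stringsAsFactors = FALSE)
  dimnames(pt$Sij) <- list(nms, nms)
  structure(list(indices = indices, Sij = pt$Sij, V = pt$V,
                 converged = all(widths < 0.1 * max_index),
                 significant = nms[pt$STi > significance_threshold],
                 conf = conf, n = n, k = k, B = B,
                 n_cases = ncol(Ym)),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, digits = 3, ...) {
  cat(sprintf("Sobol indices (n = %d base samples, k = %d, %d case(s)); V[Y] = %.3g\n",
              x$n, x$k, x$n_cases, x$V))
  print(format(x$indices, digits = digits), row.names = FALSE)
  cat(sprintf("CI-converged: %s; significant (STi > 0.05): %s\n", x$converged,
              if (length(x$significant)) paste(x$significant, collapse = ", ")
              else "none"))
  invisible(x)
}

# apply one sampled parameter vector to a case, returning perturbed
# (patient, tree, notes). rs is held fixed; a perturbed degree re-derives
# the reference radius ru.
apply_uncertainty <- function(case, x, inputs) {
  patient <- case$patient; tree <- case$tree
  clipped <- character(0)
  for (nm in names(inputs)) {
    v <- x[[nm]]; inp <- inputs[[nm]]
    if (nm == "cardiac_output") {
      f <- v; if (f < 0.05) { f <- 0.05; clipped <- c(clipped, nm) }
      patient$CO_Lmin <- patient$CO_Lmin * f
    } else if (nm == "mean_arterial_pressure") {
      f <- v; if (f < 0.05) { f <- 0.05; clipped <- c(clipped, nm) }
      patient$MAP_mmHg <- patient$MAP_mmHg * f
    } else if (nm == "stenosis_degree") {
      st <- tree$stenoses[[1]]
      d <- st$degree_pct + v
      if (d < 0 || d > 99.5) { d <- min(max(d, 0), 99.5); clipped <- c(clipped, nm) }
      tree$stenoses[[1]] <- stenosis_spec(st$segment_id, st$position_mm,
                                          st$length_mm, degree_pct = d,
                                          rs_mm = st$rs_mm)
    } else if (nm == "distal_location") {
      reach <- max_reachable_distal(tree, tree$stenoses[[1]])
      d <- v
      if (d < 1 || d > reach - 0.5) { d <- min(max(d, 1), reach - 0.5)
        clipped <- c(clipped, nm) }
      patient$distal_location_mm <- d
    } else stop("unknown uncertain input '", nm, "'")
  }
  list(patient = patient, tree = tree, clipped = clipped)
}

#' Global uncertainty quantification of FFR over a cohort
#'
#' For each case, applies every Saltelli-sampled parameter vector (cardiac
#' output and mean arterial pressure as multiplicative factors — the
#' cardiac-output factor perturbs only the resistance distribution, with
#' the inlet waveform kept at the case baseline; stenosis degree as an
#' additive perturbation clipped to `[0, 99.5]`%; distal location as a
#' replacement value), recomputes FFR, and estimates Sobol indices on the
#' aggregate of all FFR values.
#'
#' @param cases list of cases from [generate_cohort()] (each
#'   `list(tree, patient)`).
#' @param inputs uncertain inputs (default [clinical_uncertainty_inputs()]).
#' @param n base sample size.
#' @param seed design seed.
#' @param controls solver controls (default [demo_controls()]).
#' @param config an [ffr_config()].
#' @param B bootstrap resamples.
#' @param max_failure_frac abort if more than this fraction of simulations
#'   fail (default 0.01).
#' @return a `sobol_result` with extra fields `n_failed`, `n_clipped`,
#'   `baseline_FFR`.
#' @export
uq_pipeline <- function(cases, inputs = clinical_uncertainty_inputs(),
                        n = 64, seed = 1, controls = demo_controls(),
                        config = ffr_config(), B = 500,
                        max_failure_frac = 0.01) {
  k <- length(inputs)
  design <- saltelli_sample(inputs, n, seed)
  nrows <- nrow(design)
  Y <- matrix(NA_real_, nrows, length(cases))
  n_clipped <- 0L
  baseline <- numeric(length(cases))
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    if (!length(case$tree$stenoses))
      stop("every case needs a stenosis annotation")
    baseline[ci] <- simulate_ffr(case$tree, case$patient, config, controls)$FFR
    base_CO <- case$patient$CO_Lmin
    for (r in seq_len(nrows)) {
      x <- as.list(design[r, ])
      pert <- apply_uncertainty(case, x, inputs)
      n_clipped <- n_clipped + length(pert$clipped)
      cfg <- config
      cfg$inlet_CO_Lmin <- config$inlet_CO_Lmin %||% base_CO
      cfg$resistance_CO_Lmin <- pert$patient$CO_Lmin
      Y[r, ci] <- tryCatch(
        simulate_ffr(pert$tree, pert$patient, cfg, controls)$FFR,
        error = function(e) NA_real_)
    }
  }
  n_failed <- sum(!is.finite(Y))
  if (n_failed > max_failure_frac * length(Y))
    stop(sprintf("pipeline error: %d of %d simulations failed (> %.0f%%)",
                 n_failed, length(Y), 100 * max_failure_frac))
  if (n_failed > 0) {
    # drop whole base rows containing any failure, across all blocks
    bad_base <- unique(((which(!is.finite(Y), arr.ind = TRUE)[, 1] - 1) %% n) + 1)
    keep <- setdiff(seq_len(n), bad_base)
    sel <- as.vector(outer(keep, (0:(2 * k + 1)) * n, `+`))
    Y <- Y[sort(sel), , drop = FALSE]
    n <- length(keep)
    message(sprintf("excluded %d failed simulation(s): %d base rows dropped",
                    n_failed, length(bad_base)))
  }
  res <- sobol_indices(Y, k = k, n = n, B = B, seed = seed)
  res$indices$input <- names(inputs)
  dimnames(res$Sij) <- list(names(inputs), names(inputs))
  res$significant <- names(inputs)[res$indices$STi > 0.05]
  res$n_failed <- n_failed
  res$n_clipped <- n_clipped
  res$baseline_FFR <- baseline
  res
}

#' Reclassification under inflated input uncertainty
#'
#' Re-samples the cardiac-output and stenosis-degree uncertainty
#' distributions at increasing standard-deviation multipliers (distal
#' location and MAP stay at their baselines), recomputing FFR for `m`
#' draws per case and level. Draws are nested: the same standard-normal
#' deviates are scaled by each multiplier. Reports the mean within-case
#' FFR range and the reclassification proportion (fraction of cases whose
#' classification at the 0.80 threshold differs from baseline for at
#' least one draw), overall and by coronary side.
#'
#' @param cases cohort cases.
#' @param sd_multipliers standard-deviation multipliers (include 0 for the
#'   baseline level).
#' @param m draws per case and level (>= 2).
#' @param seed seed for the deviates.
#' @param inputs uncertain inputs providing the CO and degree sds.
#' @param controls,config solver controls and pipeline config.
#' @param threshold ischemic threshold.
#' @return a `reclassification_curve` data frame: `multiplier`,
#'   `mean_range`, `RP`, `RP_left`, `RP_right`, plus attribute
#'   `baseline_FFR`.
#' @export
reclassification_study <- function(cases, sd_multipliers = seq(0, 3, by = 1),
                                   m = 8, seed = 1,
                                   inputs = clinical_uncertainty_inputs(),
                                   controls = demo_controls(),
                                   config = ffr_config(), threshold = 0.80) {
  if (m < 2) stop("design error: at least 2 draws per level are required")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  z <- array(rnorm(m * 2 * length(cases)), c(m, 2, length(cases)))
  sd_co <- inputs$cardiac_output$sd
  sd_deg <- inputs$stenosis_degree$sd
  baseline <- vapply(cases, function(cs)
    simulate_ffr(cs$tree, cs$patient, config, controls)$FFR, numeric(1))
  side <- vapply(cases, function(cs) cs$patient$side, character(1))
  rows <- lapply(sd_multipliers, function(s) {
    rng <- numeric(length(cases)); recls <- logical(length(cases))
    for (ci in seq_along(cases)) {
      if (s == 0) { rng[ci] <- 0; recls[ci] <- FALSE; next }
      case <- cases[[ci]]
      ff <- vapply(seq_len(m), function(j) {
        x <- list(cardiac_output = max(1 + s * sd_co * z[j, 1, ci], 0.05),
                  stenosis_degree = s * sd_deg * z[j, 2, ci])
        pert <- apply_uncertainty(case, x,
                                  inputs[c("cardiac_output", "stenosis_degree")])
        cfg <- config
        cfg$inlet_CO_Lmin <- config$inlet_CO_Lmin %||% case$patient$CO_Lmin
        cfg$resistance_CO_Lmin <- pert$patient$CO_Lmin
        simulate_ffr(pert$tree, pert$patient, cfg, controls)$FFR
      }, numeric(1))
      rng[ci] <- max(ff) - min(ff)
      recls[ci] <- any((ff <= threshold) != (baseline[ci] <= threshold))
    }
    data.frame(multiplier = s, mean_range = mean(rng), RP = mean(recls),
               RP_left = if (any(side == "left")) mean(recls[side == "left"]) else NA_real_,
               RP_right = if (any(side == "right")) mean(recls[side == "right"]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_FFR") <- baseline
  class(out) <- c("reclassification_curve", "data.frame")
  out
}
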
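#' Locate the distal pressure probe
#'
#' Walks `L_distal` mm of arc length downstream from the distal end of the
#' stenosis (or from the ostium if `stenosis` is `NULL`); at bifurcations
#' the walk follows the child with the larger proximal radius (the main
#' branch continuation).
#'
#' @param tree a [coronary_tree()].
#' @param stenosis a [stenosis_spec()] on that tree, or `NULL`.
#' @param L_distal_mm distal distance in mm (> 0).
#' @return list with `segment_id`, `position_mm`, and the `path` of
#'   segment ids walked.
#' @export
locate_distal_probe <- function(tree, stenosis, L_distal_mm) {
  stopifnot(inherits(tree, "coronary_tree"))
  if (L_distal_mm <= 0) stop("distal distance must be positive")
  if (is.null(stenosis)) {
    seg_id <- tree$root; pos <- 0
  } else {
    seg_id <- stenosis$segment_id
    pos <- stenosis$position_mm + stenosis$length_mm
  }
  remaining <- L_distal_mm
  path <- seg_id
  walked <- 0
  repeat {
    seg <- tree$segments[[seg_id]]
    avail <- seg$length_mm - pos
    if (remaining <= avail + 1e-9)
      return(list(segment_id = seg_id,
                  position_mm = min(pos + remaining, seg$length_mm),
                  path = path))
    remaining <- remaining - avail
    walked <- walked + avail
    ch <- tree_children(tree, seg_id)
    if (!length(ch))
      stop(sprintf("placement error: only %.1f mm reachable downstream, %.1f mm requested",
                   walked, L_distal_mm))
    r <- vapply(ch, function(id) radius_at(tree$segments[[id]], 0), numeric(1))
    seg_id <- ch[which.max(r)]
    path <- c(path, seg_id)
    pos <- 0
  }
}

# longest main-branch arc length reachable downstream of a stenosis
max_reachable_distal <- function(tree, stenosis) {
  seg_id <- stenosis$segment_id
  pos <- stenosis$position_mm + stenosis$length_mm
  total <- 0
  repeat {
    seg <- tree$segments[[seg_id]]
    total <- total + seg$length_mm - pos
    ch <- tree_children(tree, seg_id)
    if (!length(ch)) return(total)
    r <- vapply(ch, function(id) radius_at(tree$segments[[id]], 0), numeric(1))
    seg_id <- ch[which.max(r)]
    pos <- 0
  }
}

#' Compute FFR from a converged hyperemic simulation
#'
#' FFR is the ratio of the time-averaged distal pressure to the
#' time-averaged ostial pressure over the final cycle; values at or below
#' the clinical threshold (default 0.80) are flagged ischemic.
#'
#' @param sim a `coroflow_sim` from [run_simulation()].
#' @param distal_probe name of the distal probe column (default
#'   `"distal"`).
#' @param inlet_probe name of the ostial probe column.
#' @param threshold ischemic threshold on FFR.
#' @param require_converged refuse non-converged simulations (default
#'   `TRUE`).
#' @return an `ffr_result`: `FFR`, `Pd_mean_mmHg`, `Pa_mean_mmHg`,
#'   `ischemic`, `threshold`, `distal_probe`.
#' @export
compute_ffr <- function(sim, distal_probe = "distal", inlet_probe = "inlet",
                        threshold = 0.80, require_converged = TRUE) {
  stopifnot(inherits(sim, "coroflow_sim"))
  if (require_converged && !isTRUE(sim$report$converged))
    stop("simulation did not reach periodic convergence; increase max_cycles or relax l2_tol")
  for (nm in c(distal_probe, inlet_probe))
    if (!nm %in% colnames(sim$P)) stop("no probe named '", nm, "'")
  Pa <- mean(sim$P[, inlet_probe])
  Pd <- mean(sim$P[, distal_probe])
  ffr <- Pd / Pa
  structure(list(FFR = ffr, Pd_mean_mmHg = Pd / MMHG_PA,
                 Pa_mean_mmHg = Pa / MMHG_PA,
                 ischemic = ffr <= threshold, threshold = threshold,
                 distal_probe = distal_probe,
                 report = sim$report),
            class = "ffr_result")
}

#' @export
print.ffr_result <- function(x, ...) {
  cat(sprintf("FFR = %.3f (Pd %.1f / Pa %.1f mmHg) -> %s at the %.2f threshold\n",
              x$FFR, x$Pd_mean_mmHg, x$Pa_mean_mmHg,
              if (x$ischemic) "ischemic" else "non-ischemic", x$threshold))
  invisible(x)
}

#' FFR pipeline configuration
#'
#' Options of the end-to-end FFR computation that are not numerical solver
#' controls: the coronary fraction of cardiac output, dominance splits,
#' hyperemia factors, Windkessel compliance, which cardiac output feeds
#' the inlet waveform vs. the peripheral resistances, and whether the
#' aortic reference pressure Pa is the simulated ostial pressure (the
#' default, mirroring the invasive Pd/Pa measurement) or the clinical MAP.
#'
#' @param coronary_fraction resting coronary fraction of cardiac output.
#' @param splits dominance splits, see [dominance_split()].
#' @param hyperemic_flow_factor named per-side inflow factors.
#' @param hyperemic_resistance_factor factor on terminal resistances.
#' @param compliance Windkessel compliance per terminal, m^3/Pa.
#' @param inlet_CO_Lmin override for the cardiac output feeding the inlet
#'   waveform (`NULL` = patient value).
#' @param resistance_CO_Lmin override for the cardiac output feeding the
#'   resistance distribution (`NULL` = patient value).
#' @param distal_override_mm override for the distal location (`NULL` =
#'   patient value).
#' @param waveform waveform shape override (`NULL` = canonical shape for
#'   the patient's side).
#' @param Pa_source `"simulated"` or `"MAP"`.
#' @return an `ffr_config` list.
#' @export
ffr_config <- function(coronary_fraction = 0.04,
                       splits = c(right = 0.70, left = 0.80,
                                  `co-dominant` = 0.75),
                       hyperemic_flow_factor = c(left = 4, right = 3),
                       hyperemic_resistance_factor = 0.22,
                       compliance = 9e-11,
                       inlet_CO_Lmin = NULL, resistance_CO_Lmin = NULL,
                       distal_override_mm = NULL, waveform = NULL,
                       Pa_source = c("simulated", "MAP")) {
  structure(list(coronary_fraction = coronary_fraction, splits = splits,
                 hyperemic_flow_factor = hyperemic_flow_factor,
                 hyperemic_resistance_factor = hyperemic_resistance_factor,
                 compliance = compliance, inlet_CO_Lmin = inlet_CO_Lmin,
                 resistance_CO_Lmin = resistance_CO_Lmin,
                 distal_override_mm = distal_override_mm,
                 waveform = waveform, Pa_source = match.arg(Pa_source)),
            class = "ffr_config")
}

#' Simulate FFR for one patient case
#'
#' End-to-end hyperemic FFR: blood viscosity from hematocrit, inlet
#' waveform from cardiac output / heart rate / dominance scaled by the
#' hyperemic flow factor, terminal resistances from the cube-radius rule
#' at rest scaled by the hyperemic resistance factor, pulse-wave
#' simulation to periodic convergence, and Pd/Pa at the distal location.
#'
#' @param tree a [coronary_tree()] with at most one stenosis.
#' @param patient list with `MAP_mmHg, CO_Lmin, HR_bpm, hematocrit_pct,
#'   dominance, side, distal_location_mm` (see [load_patient()]).
#' @param config an [ffr_config()].
#' @param controls a [simulation_controls()].
#' @param wall a [wall_law()].
#' @return an `ffr_result`, with the full simulation attached as
#'   attribute `"sim"`.
#' @export
simulate_ffr <- function(tree, patient, config = ffr_config(),
                         controls = simulation_controls(),
                         wall = wall_law()) {
  stopifnot(inherits(tree, "coronary_tree"))
  blood <- blood_properties(hematocrit = patient$hematocrit_pct / 100)
  side <- match.arg(patient$side, c("left", "right"))
  shape <- config$waveform %||% canonical_waveform(side)
  CO_inlet <- config$inlet_CO_Lmin %||% patient$CO_Lmin
  CO_resist <- config$resistance_CO_Lmin %||% patient$CO_Lmin
  L_distal <- config$distal_override_mm %||% patient$distal_location_mm

  inflow <- build_inflow(CO_inlet, patient$HR_bpm, patient$dominance, side,
                         state = "hyperemia", shape = shape,
                         coronary_fraction = config$coronary_fraction,
                         splits = config$splits,
                         hyperemic_flow_factor = config$hyperemic_flow_factor)
  Qost_rest <- CO_resist * config$coronary_fraction *
    dominance_split(side, patient$dominance, config$splits)
  outlets <- distribute_resistances(terminal_radii(tree), patient$MAP_mmHg,
                                    Qost_rest, state = "hyperemia",
                                    hyperemic_resistance_factor =
                                      config$hyperemic_resistance_factor,
                                    C = config$compliance)
  stenosis <- if (length(tree$stenoses)) tree$stenoses[[1]] else NULL
  probe <- locate_distal_probe(tree, stenosis, L_distal)
  probes <- data.frame(name = "distal", segment_id = probe$segment_id,
                       position_mm = probe$position_mm,
                       stringsAsFactors = FALSE)
  sim <- run_simulation(tree, blood, wall, inflow, outlets, controls, probes)
  res <- compute_ffr(sim)
  if (config$Pa_source == "MAP") {
    res$Pa_mean_mmHg <- patient$MAP_mmHg
    res$FFR <- res$Pd_mean_mmHg / patient$MAP_mmHg
    res$ischemic <- res$FFR <= res$threshold
  }
  res$distal_probe <- probe
  attr(res, "sim") <- sim
  res
}
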
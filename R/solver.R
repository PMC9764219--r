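#' Simulation controls
#'
#' Numerical controls for [run_simulation()]. Defaults follow the
#' convergence-tested reference settings: 500 um grid spacing, 1e-5 s time
#' step, up to 20 cardiac cycles, per-cycle relative L2 change of the
#' distal pressure waveform below 1e-3. Set `dt_s = NULL` to choose the
#' time step automatically from the CFL condition (`cfl` times the maximum
#' stable step estimated from the initial state).
#'
#' @param dt_s time step in seconds, or `NULL` for automatic.
#' @param dx_um grid spacing in micrometers.
#' @param max_cycles maximum cardiac cycles to march.
#' @param l2_tol periodic-convergence tolerance (relative L2).
#' @param cfl CFL number in `(0, 1]`.
#' @param record_stenosis record per-step traces (flow and total pressure
#'   on both sides) at every stenosis interface.
#' @return a `simulation_controls` list.
#' @export
simulation_controls <- function(dt_s = 1e-5, dx_um = 500, max_cycles = 20,
                                l2_tol = 1e-3, cfl = 0.9,
                                record_stenosis = TRUE) {
  if (!is.null(dt_s) && dt_s <= 0) stop("dt must be positive")
  if (dx_um <= 0) stop("dx must be positive")
  if (cfl <= 0 || cfl > 1) stop("CFL number must lie in (0, 1]")
  structure(list(dt_s = dt_s, dx_um = dx_um, max_cycles = max_cycles,
                 l2_tol = l2_tol, cfl = cfl,
                 record_stenosis = record_stenosis),
            class = "simulation_controls")
}

# fast demo controls used by examples / uncertainty sweeps on small trees
#' Coarse controls for small-tree demonstration runs
#'
#' A coarser grid (2 mm) with a CFL-chosen time step. Time-averaged
#' pressures on small synthetic trees are grid-insensitive at this
#' resolution (the pressure gradient is piecewise near-linear and the
#' stenosis is an interface element), which makes large uncertainty sweeps
#' tractable.
#'
#' @param dx_um grid spacing, micrometers.
#' @param ... passed to [simulation_controls()].
#' @return a `simulation_controls` list.
#' @export
demo_controls <- function(dx_um = 2000, ...) {
  simulation_controls(dt_s = NULL, dx_um = dx_um, ...)
}

#' Run a pulse-wave simulation over a coronary tree
#'
#' Discretizes the tree, attaches the inlet waveform and Windkessel
#' outlets, and time-marches the 1D mass/momentum equations until the
#' distal pressure waveform is periodic (per-cycle relative L2 change
#' below `l2_tol`) or `max_cycles` is reached. The state is initialized at
#' the mean perfusion pressure implied by the outlets (`mean inflow x
#' parallel resistance`) to shorten the startup transient.
#'
#' @param tree a [coronary_tree()].
#' @param blood a [blood_properties()].
#' @param wall a [wall_law()].
#' @param inflow an [build_inflow()] waveform.
#' @param outlets named list of [windkessel_outlet()]s covering every
#'   terminal segment, e.g. from [distribute_resistances()].
#' @param controls a [simulation_controls()].
#' @param probes data frame with columns `name`, `segment_id`,
#'   `position_mm`; a probe named `inlet` at the ostium is always added.
#'   The first non-inlet probe (or the inlet) is the convergence probe.
#' @return a `coroflow_sim` object: `t` (s, one cycle), matrices `P` (Pa),
#'   `Q` (m^3/s), `A` (m^2) with one column per probe, `report` (a
#'   convergence report), and `stenosis_trace` (list of per-interface
#'   data frames `t, Q, Pt_up, Pt_down`).
#' @export
run_simulation <- function(tree, blood = blood_properties(),
                           wall = wall_law(), inflow, outlets,
                           controls = simulation_controls(),
                           probes = NULL) {
  stopifnot(inherits(tree, "coronary_tree"), inherits(inflow, "inflow_waveform"))
  gridded <- discretize(tree, controls$dx_um)
  run_simulation_gridded(gridded, blood, wall, inflow, outlets, controls,
                         probes)
}

run_simulation_gridded <- function(gridded, blood, wall, inflow, outlets,
                                   controls, probes = NULL) {
  tree <- gridded$tree
  terms <- tree_terminals(tree)
  miss <- setdiff(terms, names(outlets))
  if (length(miss))
    stop("terminals without Windkessel outlets: ", paste(miss, collapse = ", "))

  pieces <- lapply(gridded$pieces, function(p)
    list(n = p$n, dx = p$dx, A0 = p$A0, beta = beta_stiffness(p$A0, wall)))
  junc <- if (length(gridded$junctions))
    do.call(rbind, lapply(gridded$junctions, function(j)
      c(j$parent, j$child1, j$child2)))
  else matrix(integer(0), 0, 3)
  sten <- lapply(gridded$stenosis_ifaces, function(si) {
    sp <- si$stenosis
    cf <- stenosis_coefficients(sp)
    list(up = si$up, down = si$down, Kv = cf$Kv, Kt = cf$Kt, Ku = cf$Ku,
         ru = sp$ru_mm * MM_M, Au = sp$Au_mm2 * 1e-6, As = sp$As_mm2 * 1e-6,
         Ls = sp$length_mm * MM_M)
  })

  # resting-state mean perfusion pressure implied by the outlets
  Rpar <- 1 / sum(vapply(outlets[terms], function(o) 1 / o$Rp, numeric(1)))
  P_init <- inflow$mean_Q * Rpar
  outm <- do.call(rbind, lapply(terms, function(id)
    c(gridded$terminal_pieces[[id]], outlets[[id]]$Rp, outlets[[id]]$C,
      P_init)))

  # warm-start flows: distribute the mean inflow by outlet conductance and
  # accumulate shares up the piece graph
  npiece <- length(gridded$pieces)
  Q_init <- numeric(npiece)
  share <- vapply(terms, function(id) (1 / outlets[[id]]$Rp) * Rpar,
                  numeric(1))
  Q_init[vapply(terms, function(id) gridded$terminal_pieces[[id]],
                integer(1))] <- inflow$mean_Q * share
  parent_of <- integer(npiece)
  for (j in gridded$junctions) {
    parent_of[j$child1] <- j$parent
    parent_of[j$child2] <- j$parent
  }
  for (si in gridded$stenosis_ifaces) parent_of[si$down] <- si$up
  ord <- order(vapply(seq_len(npiece), function(p) {
    d <- 0; while (parent_of[p] > 0) { p <- parent_of[p]; d <- d + 1 }; d
  }, numeric(1)), decreasing = TRUE)
  for (p in ord) if (parent_of[p] > 0)
    Q_init[parent_of[p]] <- Q_init[parent_of[p]] + Q_init[p]
  # a stenosis-split piece pair shares one flow; junction parents summed
  # twice would double count, so recompute: flows already accumulate once
  # per child edge (junction children sum; stenosis down passes through)

  # probe table: inlet first, then user probes
  ptab <- data.frame(name = "inlet", segment_id = tree$root, position_mm = 0,
                     stringsAsFactors = FALSE)
  if (!is.null(probes)) {
    stopifnot(all(c("name", "segment_id", "position_mm") %in% names(probes)))
    ptab <- rbind(ptab, probes[, c("name", "segment_id", "position_mm")])
  }
  if (anyDuplicated(ptab$name)) stop("probe names must be unique")
  pidx <- t(vapply(seq_len(nrow(ptab)), function(i)
    grid_locate(gridded, ptab$segment_id[i], ptab$position_mm[i]),
    integer(2)))
  conv_probe <- if (nrow(ptab) > 1) 2L else 1L

  # time step: paper default or CFL-derived; rounded to an integer number
  # of steps per cycle so cycles align sample-for-sample
  dt <- controls$dt_s
  if (is.null(dt)) {
    # anticipate the peak systolic pressure (Windkessel swing plus
    # stenotic losses at peak flow) so the wave speed of the inflated
    # vessel still satisfies the CFL bound
    Qpk <- max(abs(inflow$Q))
    dPs_pk <- 0
    for (s in sten) {
      kv <- blood$mu * s$Kv / (2 * pi * s$ru^3)
      kt <- blood$rho * s$Kt / (2 * s$Au^2) * (s$Au / s$As - 1)^2
      dPs_pk <- dPs_pk + kv * Qpk + kt * Qpk^2
    }
    pk_ratio <- if (inflow$mean_Q > 0) Qpk / inflow$mean_Q else 1
    P_pk <- 1.5 * (P_init * pk_ratio + dPs_pk)
    cmax <- max(vapply(pieces, function(p) {
      A_pk <- tube_law_area(P_pk, p$A0, wall)
      max(wave_speed(A_pk, p$A0, blood$rho, wall))
    }, numeric(1)))
    umax <- Qpk / min(vapply(pieces, function(p) min(p$A0), numeric(1)))
    dxmin <- min(vapply(pieces, function(p) p$dx, numeric(1)))
    dt <- 0.9 * controls$cfl * dxmin / (cmax + umax)
  }
  auto_dt <- is.null(controls$dt_s)
  res <- NULL
  for (attempt in 1:4) {
    nsteps <- max(16L, as.integer(ceiling(inflow$period / dt)))
    dt_run <- inflow$period / nsteps
    Qin <- stats::approx(inflow$t, inflow$Q,
                         xout = (seq_len(nsteps) - 1) * dt_run, rule = 2)$y
    res <- tryCatch(
      solve_tree_cpp(pieces, junc, sten, outm, gridded$inlet_piece,
                     Qin, blood$rho, blood$mu, blood$alpha, blood$Cf,
                     wall$Pext, dt_run, nsteps, controls$max_cycles,
                     controls$l2_tol, controls$cfl, pidx, conv_probe,
                     P_init, Q_init, isTRUE(controls$record_stenosis)),
      error = function(e) {
        # under automatic stepping, a mid-run CFL violation (the state
        # stiffened beyond the startup estimate) triggers a retry with a
        # smaller step; a user-fixed dt is never second-guessed
        if (auto_dt && attempt < 4 &&
            grepl("CFL violated mid-run", conditionMessage(e))) NULL
        else stop(e)
      })
    if (!is.null(res)) { dt <- dt_run; break }
    dt <- dt * 0.6
  }

  dimnames(res$P) <- dimnames(res$Q) <- dimnames(res$A) <-
    list(NULL, ptab$name)
  sten_trace <- NULL
  if (isTRUE(controls$record_stenosis) && length(sten)) {
    sten_trace <- lapply(seq_along(sten), function(s)
      data.frame(t = res$t, Q = res$sten_Q[, s], Pt_up = res$sten_Pt_up[, s],
                 Pt_down = res$sten_Pt_down[, s]))
  }
  report <- structure(list(cycles_run = res$cycles_run,
                           l2_history = res$l2_history,
                           converged = res$converged,
                           mean_area_deformation_pct =
                             res$mean_area_deformation_pct,
                           dt_s = dt, steps_per_cycle = nsteps,
                           l2_tol = controls$l2_tol),
                      class = "convergence_report")
  structure(list(t = res$t, P = res$P, Q = res$Q, A = res$A,
                 probes = ptab, report = report,
                 stenosis_trace = sten_trace, inflow = inflow),
            class = "coroflow_sim")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Converged: %s after %d cycle(s); last L2 = %.3g (tol %.1g); mean |A-A0|/A0 = %.2f%%; dt = %.3g s (%d steps/cycle)\n",
              x$converged, x$cycles_run,
              tail(x$l2_history, 1), x$l2_tol,
              x$mean_area_deformation_pct, x$dt_s, x$steps_per_cycle))
  invisible(x)
}

#' @export
print.coroflow_sim <- function(x, ...) {
  cat(sprintf("1D pulse-wave simulation: %d probes (%s), one cycle of %d samples\n",
              ncol(x$P), paste(colnames(x$P), collapse = ", "), length(x$t)))
  print(x$report)
  invisible(x)
}

#' Cycle-averaged probe quantities
#'
#' Arithmetic mean over the returned (final) cycle for every probe.
#'
#' @param sim a `coroflow_sim`.
#' @return data frame with probe name, mean pressure (Pa and mmHg), and
#'   mean flow (m^3/s and mL/min).
#' @export
probe_means <- function(sim) {
  data.frame(probe = colnames(sim$P),
             P_Pa = colMeans(sim$P), P_mmHg = colMeans(sim$P) / MMHG_PA,
             Q_m3s = colMeans(sim$Q), Q_mLmin = colMeans(sim$Q) / MLMIN_M3S,
             row.names = NULL)
}
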
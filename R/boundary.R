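#' Dominance flow split
#'
#' Fraction of total coronary flow sent to one side of the circulation
#' given the flow dominance. Defaults: right-dominant 70:30 (left:right),
#' left-dominant 80:20, co-dominant 75:25.
#'
#' @param side `"left"` or `"right"`.
#' @param dominance `"right"`, `"left"` or `"co-dominant"`.
#' @param splits named numeric vector of left-side fractions per dominance.
#' @return fraction of coronary flow in `[0, 1]`.
#' @export
dominance_split <- function(side = c("left", "right"),
                            dominance = c("right", "left", "co-dominant"),
                            splits = c(right = 0.70, left = 0.80,
                                       `co-dominant` = 0.75)) {
  side <- match.arg(side)
  dominance <- match.arg(dominance)
  left_frac <- splits[[dominance]]
  if (side == "left") left_frac else 1 - left_frac
}

#' Build an ostial inflow waveform
#'
#' Scales a unit-mean waveform shape in time to the cardiac period
#' `T = 60/HR` and in amplitude so that its period mean equals the target
#' ostial flow: cardiac output times the coronary fraction times the
#' dominance split, multiplied under hyperemia by 4 (left) or 3 (right).
#'
#' @param CO_Lmin cardiac output, L/min.
#' @param HR_bpm heart rate, beats/min.
#' @param dominance flow dominance, see [dominance_split()].
#' @param side coronary side being simulated.
#' @param state `"rest"` or `"hyperemia"`.
#' @param shape a waveform object from [canonical_waveform()] or
#'   [constant_waveform()] (unit-mean samples over one period).
#' @param coronary_fraction fraction of cardiac output perfusing the
#'   coronaries at rest (default 0.04).
#' @param splits passed to [dominance_split()].
#' @param hyperemic_flow_factor named factors applied under hyperemia.
#' @return an `inflow_waveform` object with fields `t` (s), `Q` (m^3/s),
#'   `period`, `mean_Q`, `side`, `state`. First and last samples coincide.
#' @examples
#' w <- build_inflow(4.5, 70, "right", "left", "rest")
#' w$mean_Q * 6e7  # mL/min
#' @export
build_inflow <- function(CO_Lmin, HR_bpm,
                         dominance = c("right", "left", "co-dominant"),
                         side = c("left", "right"),
                         state = c("rest", "hyperemia"),
                         shape = canonical_waveform(side),
                         coronary_fraction = 0.04,
                         splits = c(right = 0.70, left = 0.80, `co-dominant` = 0.75),
                         hyperemic_flow_factor = c(left = 4, right = 3)) {
  side <- match.arg(side); state <- match.arg(state)
  dominance <- match.arg(dominance)
  if (CO_Lmin <= 0 || HR_bpm <= 0) stop("CO and HR must be positive")
  period <- 60 / HR_bpm
  target <- CO_Lmin * LMIN_M3S * coronary_fraction *
    dominance_split(side, dominance, splits)
  if (state == "hyperemia") target <- target * hyperemic_flow_factor[[side]]
  tau <- shape$tau
  val <- shape$value
  # renormalize so the trapezoid period-mean is exactly the target
  m <- trapz_mean(tau, val)
  Q <- target * val / m
  structure(list(t = tau * period, Q = Q, period = period, mean_Q = target,
                 side = side, state = state, HR_bpm = HR_bpm),
            class = "inflow_waveform")
}

trapz_mean <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x)) / (x[n] - x[1])
}

#' @export
print.inflow_waveform <- function(x, ...) {
  cat(sprintf("Inflow waveform (%s, %s): period %.3f s, mean %.1f mL/min\n",
              x$side, x$state, x$period, x$mean_Q / MLMIN_M3S))
  invisible(x)
}

#' Two-element Windkessel outlet
#'
#' @param terminal_id terminal segment id this outlet is attached to.
#' @param Rp peripheral resistance, Pa s/m^3.
#' @param C compliance, m^3/Pa; default 9e-11 (9 micro cm^4 s^2/g).
#' @return a `windkessel_outlet` list.
#' @export
windkessel_outlet <- function(terminal_id, Rp, C = 9e-11) {
  if (Rp <= 0 || C <= 0) stop("Rp and C must be positive")
  structure(list(terminal_id = as.character(terminal_id), Rp = Rp, C = C),
            class = "windkessel_outlet")
}

#' Distribute terminal resistances over a coronary tree
#'
#' Peripheral resistance at terminal branch i follows the cube-radius rule
#' `Ri = (Pmean/Qostial) * (sum_j rj^3) / ri^3`, so that the parallel
#' combination equals `Pmean/Qostial` exactly. `Pmean` and `Qostial` are
#' resting-state values; under hyperemia every `Ri` is multiplied by the
#' resistance factor (default 0.22).
#'
#' @param terminal_radii_mm named vector of terminal branch radii (mm);
#'   names are terminal segment ids.
#' @param Pmean_mmHg resting mean arterial pressure, mmHg.
#' @param Qostial_Lmin resting ostial flow, L/min.
#' @param state `"rest"` or `"hyperemia"`.
#' @param hyperemic_resistance_factor factor applied to every `Ri` under
#'   hyperemia (default 0.22).
#' @param C compliance per terminal, m^3/Pa.
#' @return named list of [windkessel_outlet()]s.
#' @examples
#' outs <- distribute_resistances(c(a = 2, b = 1), 90, 0.126)
#' outs$a$Rp / outs$b$Rp  # = (1/2)^3
#' @export
distribute_resistances <- function(terminal_radii_mm, Pmean_mmHg, Qostial_Lmin,
                                   state = c("rest", "hyperemia"),
                                   hyperemic_resistance_factor = 0.22,
                                   C = 9e-11) {
  state <- match.arg(state)
  if (any(terminal_radii_mm <= 0)) stop("terminal radii must be positive")
  if (Pmean_mmHg <= 0 || Qostial_Lmin <= 0) stop("Pmean and Qostial must be positive")
  Pmean <- Pmean_mmHg * MMHG_PA
  Qost <- Qostial_Lmin * LMIN_M3S
  w <- unname(terminal_radii_mm)^3
  Ri <- (Pmean / Qost) * sum(w) / w
  if (state == "hyperemia") Ri <- Ri * hyperemic_resistance_factor
  ids <- names(terminal_radii_mm)
  if (is.null(ids)) ids <- as.character(seq_along(Ri))
  stats::setNames(lapply(seq_along(Ri), function(i)
    windkessel_outlet(ids[i], Ri[i], C)), ids)
}

# terminal radii (distal end) of a tree, named by terminal segment id, mm
terminal_radii <- function(tree) {
  terms <- tree_terminals(tree)
  stats::setNames(vapply(terms, function(id) {
    seg <- tree$segments[[id]]
    radius_at(seg, seg$length_mm)
  }, numeric(1)), terms)
}

#' Implicit-Euler Windkessel pressure update
#'
#' One step of `C dP/dt = Q - P/Rp` with the inflow `Q` held over the step:
#' `P_next = (C P/dt + Q) / (C/dt + 1/Rp)`.
#'
#' @param P current pressure, Pa.
#' @param Q inflow into the Windkessel, m^3/s.
#' @param outlet a [windkessel_outlet()].
#' @param dt time step, s.
#' @return next pressure, Pa.
#' @export
windkessel_flux <- function(P, Q, outlet, dt) {
  if (dt <= 0) stop("dt must be positive")
  (outlet$C * P / dt + Q) / (outlet$C / dt + 1 / outlet$Rp)
}
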
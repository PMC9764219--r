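# shared fixtures: all inputs are generated in code at test time

# single straight vessel
make_tube <- function(L = 50, r = 1.95, id = "s1") {
  coronary_tree(list(vessel_segment(id, NA, length_mm = L, radius_mm = r,
                                    terminal = TRUE)))
}

# symmetric 7-segment binary tree with explicit radii
make_binary7 <- function(r0 = 1.95, L = 20) {
  r1 <- r0 / 2^(1/3); r2 <- r1 / 2^(1/3)
  segs <- list(
    vessel_segment("a", NA, L, r0),
    vessel_segment("b", "a", L, r1), vessel_segment("c", "a", L, r1),
    vessel_segment("d", "b", L, r2, terminal = TRUE),
    vessel_segment("e", "b", L, r2, terminal = TRUE),
    vessel_segment("f", "c", L, r2, terminal = TRUE),
    vessel_segment("g", "c", L, r2, terminal = TRUE))
  coronary_tree(segs)
}

# inflow waveform built directly from samples (e.g. exactly zero flow)
raw_inflow <- function(Q_const, period = 0.8, n = 33) {
  tau <- seq(0, 1, length.out = n)
  structure(list(t = tau * period, Q = rep(Q_const, n), period = period,
                 mean_Q = Q_const, side = "left", state = "rest",
                 HR_bpm = 60 / period),
            class = "inflow_waveform")
}

# the reference synthetic FFR case used across solver-level tests:
# depth-3 left Murray tree, focal stenosis on the root's major child
reference_case <- function(degree = 50, distal = 20, side = "left") {
  tree <- generate_tree(tree_recipe(depth = 3, length_ratio = 14,
                                    side = side), seed = 1)
  host <- tree$segments[["sL"]]
  if (degree > 0) {
    ru <- radius_at(host, 5)
    tree$stenoses <- list(stenosis_spec("sL", position_mm = 3, length_mm = 4,
                                        degree_pct = degree, ru_mm = ru))
  }
  patient <- list(MAP_mmHg = 87.3, CO_Lmin = 4.5, HR_bpm = 70.8,
                  hematocrit_pct = 39.2, dominance = "right", side = side,
                  distal_location_mm = distal)
  list(tree = tree, patient = patient)
}

# fabricated simulation object for FFR arithmetic tests
fake_sim <- function(Pa_mmHg, Pd_mmHg, n = 10) {
  P <- cbind(inlet = rep(Pa_mmHg * 133.322387415, n),
             distal = rep(Pd_mmHg * 133.322387415, n))
  structure(list(t = seq_len(n) * 1e-3, P = P,
                 Q = P * 0, A = P * 0,
                 probes = data.frame(name = c("inlet", "distal")),
                 report = structure(list(converged = TRUE, cycles_run = 2,
                                         l2_history = c(NA, 1e-5),
                                         mean_area_deformation_pct = 0.1,
                                         dt_s = 1e-3, steps_per_cycle = n,
                                         l2_tol = 1e-3),
                                    class = "convergence_report")),
            class = "coroflow_sim")
}
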
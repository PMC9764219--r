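test_that("uniform rest state is a machine-precision equilibrium", {
  tr <- make_tube(L = 30)
  sim <- run_simulation(tr, blood_properties(), wall_law(),
                        raw_inflow(0, period = 0.05, n = 9),
                        list(s1 = windkessel_outlet("s1", 1e9, 9e-11)),
                        simulation_controls(dt_s = NULL, dx_um = 1000,
                                            max_cycles = 3, l2_tol = 0),
                        data.frame(name = "distal", segment_id = "s1",
                                   position_mm = 30))
  expect_lt(max(abs(sim$Q)), 1e-18)
  expect_lt(max(abs(sim$P)), 1e-9)
  expect_equal(max(abs(sim$A / (pi * (1.95e-3)^2) - 1)), 0, tolerance = 1e-12)
})

test_that("repeated runs are bitwise identical", {
  case <- reference_case(degree = 50)
  r1 <- simulate_ffr(case$tree, case$patient, controls = demo_controls())
  r2 <- simulate_ffr(case$tree, case$patient, controls = demo_controls())
  expect_identical(attr(r1, "sim")$P, attr(r2, "sim")$P)
  expect_identical(r1$FFR, r2$FFR)
})

test_that("symmetric bifurcation splits flow exactly in half", {
  tr <- make_binary7(L = 25)
  outs <- distribute_resistances(
    stats::setNames(rep(1.95 / 2^(2/3), 4), c("d", "e", "f", "g")),
    87.3, 0.126, "hyperemia")
  inflow <- build_inflow(4.5, 70.8, "right", "left", "hyperemia")
  probes <- data.frame(name = c("b_end", "c_end"),
                       segment_id = c("b", "c"), position_mm = 25)
  sim <- run_simulation(tr, blood_properties(), wall_law(), inflow, outs,
                        demo_controls(), probes)
  expect_equal(sim$Q[, "b_end"], sim$Q[, "c_end"], tolerance = 1e-10)
})

test_that("refinement leaves the mean distal pressure nearly unchanged", {
  case <- reference_case(degree = 50)
  pd <- vapply(c(1000, 500), function(dx) {
    r <- simulate_ffr(case$tree, case$patient,
                      controls = simulation_controls(dt_s = 1e-5, dx_um = dx))
    r$Pd_mean_mmHg
  }, numeric(1))
  expect_lt(abs(pd[2] / pd[1] - 1), 0.005)
})

test_that("periodic L2 convergence is monotone once reached", {
  tr <- make_tube(L = 40)
  inflow <- build_inflow(4.5, 70.8, "right", "left", "hyperemia")
  sim <- run_simulation(tr, blood_properties(), wall_law(), inflow,
                        list(s1 = windkessel_outlet("s1", 1.2e9, 9e-11)),
                        simulation_controls(dt_s = NULL, dx_um = 1000,
                                            max_cycles = 8, l2_tol = 0),
                        data.frame(name = "distal", segment_id = "s1",
                                   position_mm = 40))
  l2 <- sim$report$l2_history[-1]
  below <- which(l2 < 1e-3)
  expect_gt(length(below), 0)
  expect_true(all(l2[below[1]:length(l2)] < 1e-3))
})

test_that("a CFL-violating time step is refused at startup", {
  tr <- make_tube(L = 30)
  expect_error(
    run_simulation(tr, blood_properties(), wall_law(),
                   build_inflow(4.5, 70.8, "right", "left", "rest"),
                   list(s1 = windkessel_outlet("s1", 1e9, 9e-11)),
                   simulation_controls(dt_s = 5e-4, dx_um = 1000),
                   data.frame(name = "distal", segment_id = "s1",
                              position_mm = 30)),
    "CFL")
})

test_that("missing outlets and bad probes are reported", {
  tr <- make_binary7()
  expect_error(
    run_simulation(tr, blood_properties(), wall_law(),
                   build_inflow(4.5, 70, "right", "left", "rest"),
                   list(d = windkessel_outlet("d", 1e9, 9e-11)),
                   demo_controls()),
    "without Windkessel")
})
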
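test_that("Saltelli design has the right size, determinism, and marginals", {
  inputs <- clinical_uncertainty_inputs()
  d <- saltelli_sample(inputs, 8, seed = 1)
  expect_equal(nrow(d), 8 * (2 * 4 + 2))
  expect_identical(colnames(d),
                   c("distal_location", "cardiac_output", "stenosis_degree",
                     "mean_arterial_pressure"))
  expect_identical(unclass(saltelli_sample(inputs, 8, seed = 1)), unclass(d))
  expect_false(identical(unclass(saltelli_sample(inputs, 8, seed = 2)),
                         unclass(d)))
  expect_error(saltelli_sample(inputs[1], 8, seed = 1), "at least 2")
  # per-column mean/sd within 3 standard errors at n = 4096
  d2 <- saltelli_sample(inputs, 4096, seed = 5)
  base <- d2[1:4096, ]   # the A block has independent marginals
  mu <- c(30, 1, 0, 1); sd_ <- c(3.5, 0.153, 16.9, 0.056)
  for (j in 1:4) {
    expect_lt(abs(mean(base[, j]) - mu[j]), 3 * sd_[j] / sqrt(4096))
    expect_lt(abs(sd(base[, j]) - sd_[j]), 3 * sd_[j] / sqrt(2 * 4096))
  }
})

test_that("block structure holds: AB_i differs from A only in column i", {
  inputs <- clinical_uncertainty_inputs()
  n <- 16; k <- 4
  d <- saltelli_sample(inputs, n, seed = 9)
  A <- d[1:n, ]; B <- d[(n + 1):(2 * n), ]
  for (i in 1:k) {
    ABi <- d[((1 + i) * n + 1):((2 + i) * n), ]
    expect_identical(ABi[, -i], A[, -i])
    expect_identical(ABi[, i], B[, i])
    BAi <- d[((1 + k + i) * n + 1):((2 + k + i) * n), ]
    expect_identical(BAi[, -i], B[, -i])
    expect_identical(BAi[, i], A[, i])
  }
})

test_that("additive Gaussian model recovers its variance decomposition", {
  ins <- list(z1 = uncertain_input("z1", "value", mean = 0, sd = 1),
              z2 = uncertain_input("z2", "value", mean = 0, sd = 1))
  d <- saltelli_sample(ins, 4096, seed = 11)
  Y <- d[, 1] + 2 * d[, 2]
  s <- sobol_indices(Y, design = d, B = 500, seed = 11)
  idx <- s$indices
  expect_true(idx$Si_lo[1] <= 0.2 && 0.2 <= idx$Si_hi[1])
  expect_true(idx$Si_lo[2] <= 0.8 && 0.8 <= idx$Si_hi[2])
  # additive: Si ~ STi, interactions ~ 0
  expect_lt(max(abs(idx$Si - idx$STi)), 0.05)
  expect_lt(abs(s$Sij[1, 2]), 0.05)
  expect_true(s$converged)
  expect_identical(s$significant, c("z1", "z2"))
})

test_that("estimators match a brute-force double-loop Monte Carlo oracle", {
  # additive quadratic model on uniform inputs
  f <- function(z1, z2) z1 + z2^2
  ins <- list(z1 = uncertain_input("z1", "value", dist = "uniform",
                                   min = -1, max = 1),
              z2 = uncertain_input("z2", "value", dist = "uniform",
                                   min = -1, max = 1))
  d <- saltelli_sample(ins, 8192, seed = 13)
  s <- sobol_indices(f(d[, 1], d[, 2]), design = d, B = 200, seed = 13)
  # independent double-loop estimate of V[E[Y|Zi]] / V[Y]
  set.seed(99)
  M_out <- 20000; M_in <- 500
  dl <- function(which) {
    outer_z <- runif(M_out, -1, 1)
    cond <- vapply(outer_z, function(z) {
      inner <- runif(M_in, -1, 1)
      if (which == 1) mean(f(z, inner)) else mean(f(inner, z))
    }, numeric(1))
    var(cond)
  }
  Vtot <- 1 / 3 + (1 / 5 - 1 / 9)
  expect_lt(abs(s$indices$Si[1] - dl(1) / Vtot), 0.02)
  expect_lt(abs(s$indices$Si[2] - dl(2) / Vtot), 0.02)
})

test_that("degenerate outputs are rejected", {
  ins <- list(z1 = uncertain_input("z1", "value", mean = 0, sd = 1),
              z2 = uncertain_input("z2", "value", mean = 0, sd = 1))
  d <- saltelli_sample(ins, 64, seed = 1)
  expect_error(sobol_indices(rep(1, nrow(d)), design = d, B = 10),
               "degenerate")
  expect_error(sobol_indices(rnorm(10), design = d), "does not match")
})

test_that("a single active input takes all of the variance", {
  ins <- list(z1 = uncertain_input("z1", "value", mean = 0, sd = 1),
              z2 = uncertain_input("z2", "value", mean = 0, sd = 1))
  d <- saltelli_sample(ins, 2048, seed = 17)
  s <- sobol_indices(3 * d[, 1], design = d, B = 200, seed = 17)
  expect_gt(s$indices$STi[1], 0.95)
  expect_lt(s$indices$STi[2], 0.05)
})

test_that("bootstrap CIs shrink roughly as 1/sqrt(n)", {
  ins <- list(z1 = uncertain_input("z1", "value", mean = 0, sd = 1),
              z2 = uncertain_input("z2", "value", mean = 0, sd = 1))
  w <- vapply(c(256, 4096), function(n) {
    d <- saltelli_sample(ins, n, seed = 23)
    s <- sobol_indices(d[, 1] + 2 * d[, 2], design = d, B = 300, seed = 23)
    mean(s$indices$Si_hi - s$indices$Si_lo)
  }, numeric(1))
  expect_lt(w[2], w[1] / 2)   # 16x n should shrink width ~4x; demand 2x
})

test_that("uncertainty transforms apply by kind", {
  cases <- generate_cohort(cohort_recipe(n_patients = 1), seed = 3)
  case <- cases[[1]]
  inputs <- clinical_uncertainty_inputs()
  x <- list(distal_location = 28, cardiac_output = 1.2,
            stenosis_degree = 10, mean_arterial_pressure = 0.9)
  pert <- coroflow:::apply_uncertainty(case, x, inputs)
  expect_equal(pert$patient$distal_location_mm, 28)       # value: replaces
  expect_equal(pert$patient$CO_Lmin, case$patient$CO_Lmin * 1.2)  # factor
  expect_equal(pert$patient$MAP_mmHg, case$patient$MAP_mmHg * 0.9)
  expect_equal(pert$tree$stenoses[[1]]$degree_pct,
               case$stenosis$degree_pct + 10)             # addition
  # rs is held fixed; ru re-derived from the perturbed degree
  expect_equal(pert$tree$stenoses[[1]]$rs_mm, case$stenosis$rs_mm)
  expect_gt(pert$tree$stenoses[[1]]$ru_mm, case$stenosis$ru_mm)
  # clipping at the degree cap
  x$stenosis_degree <- 80
  pert2 <- coroflow:::apply_uncertainty(case, x, inputs)
  expect_equal(pert2$tree$stenoses[[1]]$degree_pct, 99.5)
  expect_true("stenosis_degree" %in% pert2$clipped)
})
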
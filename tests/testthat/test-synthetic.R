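test_that("generated trees obey Murray's law at every bifurcation", {
  # symmetric split of r = 2 mm: children r = 2 / 2^(1/3)
  tr <- generate_tree(tree_recipe(depth = 2, ostial_radius_mm = 2), seed = 1)
  kids <- Filter(function(s) identical(s$parent, "s"), tr$segments)
  expect_equal(radius_at(kids[[1]], 0), 2 / 2^(1/3), tolerance = 1e-12)
  for (gamma in c(1, 0.8)) {
    tr2 <- generate_tree(tree_recipe(depth = 4, asymmetry = gamma,
                                     min_radius_mm = 0.2), seed = 2)
    for (sid in names(tr2$segments)) {
      ch <- Filter(function(s) identical(s$parent, sid), tr2$segments)
      if (length(ch) == 2) {
        # the law applies to the branch's nominal (proximal) radius; the
        # segment itself tapers smoothly into its major child
        rp <- radius_at(tr2$segments[[sid]], 0)
        rc <- sort(unname(vapply(ch, function(s) radius_at(s, 0),
                                 numeric(1))))
        expect_equal(rp^3, rc[1]^3 + rc[2]^3, tolerance = 1e-12)
        expect_equal(rc[1] / rc[2], gamma, tolerance = 1e-12)
      }
    }
  }
})

test_that("tree structure, pruning, and round-trip validity", {
  tr <- generate_tree(tree_recipe(depth = 3), seed = 1)
  expect_length(tr$segments, 7)
  expect_equal(sum(vapply(tr$segments, function(s) s$terminal, logical(1))), 4)
  # thin branches prune with a warning
  expect_warning(generate_tree(tree_recipe(depth = 8, min_radius_mm = 0.8),
                               seed = 1), "pruned")
  # save -> load round trip revalidates
  f <- tempfile(fileext = ".json")
  save_tree(tr, f)
  expect_s3_class(load_tree(f), "coronary_tree")
})

test_that("canonical waveforms are unit-mean, periodic, side-distinct", {
  for (side in c("left", "right")) {
    w <- canonical_waveform(side)
    n <- length(w$tau)
    m <- sum((w$value[-1] + w$value[-n]) / 2 * diff(w$tau))
    expect_equal(m, 1, tolerance = 1e-12)
    expect_identical(w$value[1], w$value[n])
    expect_true(all(w$value > 0))
  }
  # left: diastolic-dominant (> 60% of area after systole)
  expect_gt(diastolic_fraction(canonical_waveform("left")), 0.60)
  expect_lt(diastolic_fraction(canonical_waveform("right")),
            diastolic_fraction(canonical_waveform("left")))
})

test_that("cohort scalars match recipe moments and truncation", {
  cases <- generate_cohort(cohort_recipe(n_patients = 200), seed = 11)
  CO <- vapply(cases, function(cs) cs$patient$CO_Lmin, numeric(1))
  expect_lt(abs(mean(CO) - 4.5), 3 * 1.5 / sqrt(200))
  HR <- vapply(cases, function(cs) cs$patient$HR_bpm, numeric(1))
  expect_lt(abs(mean(HR) - 70.8), 3 * 13.7 / sqrt(200))
  deg <- vapply(cases, function(cs) cs$stenosis$degree_pct, numeric(1))
  expect_true(all(deg >= 20 & deg <= 95))
  expect_lt(abs(mean(deg) - 55.6), 4)   # truncation shifts the mean slightly
  d <- vapply(cases, function(cs) cs$patient$distal_location_mm, numeric(1))
  expect_true(all(d >= 5 & d <= 65))
  MAP <- vapply(cases, function(cs) cs$patient$MAP_mmHg, numeric(1))
  expect_lt(abs(mean(MAP) - (125.8 + 2 * 67.1) / 3), 3)
  # same seed gives an identical cohort; different seed does not
  again <- generate_cohort(cohort_recipe(n_patients = 200), seed = 11)
  expect_identical(vapply(again, function(cs) cs$patient$CO_Lmin, numeric(1)),
                   CO)
  other <- generate_cohort(cohort_recipe(n_patients = 200), seed = 12)
  expect_false(identical(vapply(other, function(cs) cs$patient$CO_Lmin,
                                numeric(1)), CO))
})

test_that("every cohort case simulates end-to-end", {
  cases <- generate_cohort(cohort_recipe(n_patients = 3), seed = 21)
  for (cs in cases) {
    res <- simulate_ffr(cs$tree, cs$patient, controls = demo_controls())
    expect_true(res$report$converged)
    expect_gt(res$FFR, 0)
    expect_lt(res$FFR, 1.2)
  }
})

test_that("patient records round-trip through JSON", {
  cases <- generate_cohort(cohort_recipe(n_patients = 1), seed = 2)
  f <- tempfile(fileext = ".json")
  save_patient(cases[[1]]$patient, f)
  back <- load_patient(f)
  expect_equal(back$CO_Lmin, cases[[1]]$patient$CO_Lmin)
  expect_identical(back$side, cases[[1]]$patient$side)
})
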
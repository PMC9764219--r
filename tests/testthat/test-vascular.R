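test_that("tree-json save/load round-trips losslessly", {
  tr <- make_binary7()
  tr$stenoses <- list(stenosis_spec("b", position_mm = 4.123456789,
                                    length_mm = 7.3, degree_pct = 55.6,
                                    ru_mm = 1.5477))
  f <- tempfile(fileext = ".json")
  save_tree(tr, f)
  tr2 <- load_tree(f)
  expect_identical(names(tr2$segments), names(tr$segments))
  for (id in names(tr$segments)) {
    expect_identical(tr2$segments[[id]]$length_mm, tr$segments[[id]]$length_mm)
    expect_identical(tr2$segments[[id]]$radius_mm, tr$segments[[id]]$radius_mm)
    expect_identical(tr2$segments[[id]]$parent, tr$segments[[id]]$parent)
    expect_identical(tr2$segments[[id]]$terminal, tr$segments[[id]]$terminal)
  }
  expect_identical(tr2$stenoses[[1]]$position_mm, tr$stenoses[[1]]$position_mm)
  expect_identical(tr2$stenoses[[1]]$rs_mm, tr$stenoses[[1]]$rs_mm)
  expect_identical(tr2$dominance, tr$dominance)
  # single-segment minimal file
  tr1 <- make_tube()
  f1 <- tempfile(fileext = ".json")
  save_tree(tr1, f1)
  back <- load_tree(f1)
  expect_length(back$segments, 1)
  expect_length(back$stenoses, 0)
})

test_that("7-segment tree has 4 terminals and one root", {
  tr <- make_binary7()
  expect_length(tr$segments, 7)
  terms <- vapply(tr$segments, function(s) s$terminal, logical(1))
  expect_equal(sum(terms), 4)
  roots <- vapply(tr$segments, function(s) is.na(s$parent), logical(1))
  expect_equal(sum(roots), 1)
})

test_that("topology errors are caught", {
  expect_error(coronary_tree(list(
    vessel_segment("a", NA, 10, 1.9),
    vessel_segment("b", "zz", 10, 1.5, terminal = TRUE),
    vessel_segment("c", "a", 10, 1.5, terminal = TRUE))),
    "missing parent")
  expect_error(coronary_tree(list(
    vessel_segment("a", NA, 10, 1.9),
    vessel_segment("b", NA, 10, 1.5, terminal = TRUE))),
    "one root")
  expect_error(coronary_tree(list(
    vessel_segment("a", NA, 10, 1.9),
    vessel_segment("b", "a", 10, 1.5, terminal = TRUE))),
    "children")
  # stenosis beyond segment end
  expect_error(coronary_tree(list(vessel_segment("a", NA, 10, 1.9,
                                                 terminal = TRUE)),
                             list(stenosis_spec("a", 8, 5, degree_pct = 50,
                                                ru_mm = 1.9))),
               "past segment end")
})

test_that("centerline CSV import builds a valid tree", {
  f <- tempfile(fileext = ".csv")
  df <- rbind(
    data.frame(segment_id = "a", parent_id = NA, arclength_mm = c(0, 25, 50),
               radius_mm = c(1.95, 1.9, 1.85)),
    data.frame(segment_id = "b", parent_id = "a", arclength_mm = c(0, 30),
               radius_mm = c(1.5, 1.4)),
    data.frame(segment_id = "c", parent_id = "a", arclength_mm = c(0, 30),
               radius_mm = c(1.2, 1.1)))
  write.csv(df, f, row.names = FALSE)
  tr <- load_tree(f)
  expect_length(tr$segments, 3)
  expect_true(tr$segments$b$terminal && tr$segments$c$terminal)
  expect_equal(radius_at(tr$segments$a, 25), 1.9)
  expect_equal(radius_at(tr$segments$a, 12.5), (1.95 + 1.9) / 2)
})

test_that("discretize node counts, spacing, and length preservation", {
  g <- discretize(make_tube(L = 50), dx_um = 500)
  expect_equal(g$pieces[[1]]$n, 101)
  expect_equal(g$pieces[[1]]$dx, 0.5e-3)
  expect_equal(g$pieces[[1]]$A0, rep(pi * (1.95e-3)^2, 101))
  # ceiling rule: L = 10.3 mm at dx = 500 um -> 22 nodes, shrunken spacing
  g2 <- discretize(make_tube(L = 10.3), dx_um = 500)
  expect_equal(g2$pieces[[1]]$n, 22)
  expect_equal(g2$pieces[[1]]$dx, 10.3e-3 / 21)
  expect_lt(g2$pieces[[1]]$dx, 0.5e-3 + 1e-15)
  # per-segment length preserved to 1e-9 relative, with and without stenosis
  tr <- make_binary7()
  tr$stenoses <- list(stenosis_spec("a", 5, 6, degree_pct = 40, ru_mm = 1.9))
  g3 <- discretize(tr, 500)
  for (sid in names(tr$segments)) {
    tot <- sum(vapply(g3$pieces, function(p)
      if (p$segment_id == sid) (p$n - 1) * p$dx else 0, numeric(1)))
    expect_equal(tot, tr$segments[[sid]]$length_mm * 1e-3, tolerance = 1e-9)
  }
  # stenosis splits its host into two pieces joined by one interface
  expect_length(g3$stenosis_ifaces, 1)
  expect_equal(length(g3$pieces), 8)
  expect_error(discretize(make_tube(L = 0.8), 500), "smaller dx")
})

test_that("stenosis geometry closes over any two of degree/rs/ru", {
  g <- stenosis_geometry(ru_mm = 2, rs_mm = 1)
  expect_equal(g$degree_pct, 50)
  g2 <- stenosis_geometry(degree_pct = 55.6, rs_mm = 0.7)
  expect_equal(g2$ru_mm, 0.7 / 0.444, tolerance = 1e-12)
  g3 <- stenosis_geometry(degree_pct = 0, ru_mm = 1.5)
  expect_equal(g3$rs_mm, 1.5)
  expect_equal(g3$As_mm2, g3$Au_mm2)
  # round trip ru -> degree -> ru to 1e-9 relative
  set.seed(7)
  for (i in 1:25) {
    ru <- runif(1, 0.8, 3); rs <- runif(1, 0.05, 0.99) * ru
    d <- stenosis_geometry(ru_mm = ru, rs_mm = rs)$degree_pct
    expect_equal(stenosis_geometry(degree_pct = d, rs_mm = rs)$ru_mm, ru,
                 tolerance = 1e-9)
  }
  expect_error(stenosis_geometry(degree_pct = 50), "at least two")
  expect_error(stenosis_geometry(degree_pct = 100, rs_mm = 1), "100")
  expect_error(stenosis_geometry(degree_pct = 50, rs_mm = 1, ru_mm = 3),
               "inconsistent")
})

test_that("stenosis loss coefficients match hand evaluation", {
  # Ls=10, Du=3, Ds=1.5 (Au/As = 4): Kv = 32*(8.3 + 2.46)*16/3
  sp <- stenosis_spec("x", 1, 10, ru_mm = 1.5, rs_mm = 0.75)
  k <- stenosis_coefficients(sp)
  expect_equal(k$Kv, 32 * (0.83 * 10 + 1.64 * 1.5) * 16 / 3)
  expect_equal(k$Kv, 1836.373, tolerance = 1e-6)
  expect_equal(k$Kt, 1.52)
  expect_equal(k$Ku, 1.2)
  # degree 0: Au/As = 1
  sp0 <- stenosis_spec("x", 1, 5, degree_pct = 0, ru_mm = 1.5)
  expect_equal(stenosis_coefficients(sp0)$Kv, 32 * (0.83 * 5 + 1.64 * 3) / 3)
  expect_equal(stenosis_coefficients(sp0)$Kv, 96.74667, tolerance = 1e-6)
})

test_that("Kv increases with stenosis length and degree", {
  for (Ls in c(4, 8, 12)) {
    kv <- vapply(c(10, 30, 50, 70, 90), function(d)
      stenosis_coefficients(stenosis_spec("x", 1, Ls, degree_pct = d,
                                          ru_mm = 1.8))$Kv, numeric(1))
    expect_true(all(diff(kv) > 0))
  }
  for (d in c(20, 50, 80)) {
    kv <- vapply(c(2, 5, 10, 15), function(Ls)
      stenosis_coefficients(stenosis_spec("x", 1, Ls, degree_pct = d,
                                          ru_mm = 1.8))$Kv, numeric(1))
    expect_true(all(diff(kv) > 0))
  }
})
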
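#' Recipe for a Murray-law bifurcating tree
#'
#' Radii obey Murray's law at every bifurcation,
#' `r_parent^3 = r_major^3 + r_minor^3`, with child asymmetry
#' `gamma = r_minor/r_major`. Segment lengths are `length_ratio` times the
#' proximal radius, optionally jittered log-normally (seeded).
#'
#' @param depth number of generations (1 = a single segment).
#' @param ostial_radius_mm root radius, mm (default 1.95, i.e. the 3.9 mm
#'   generalized ostial diameter).
#' @param asymmetry minor/major child radius ratio in `(0, 1]`.
#' @param length_ratio segment length / proximal radius.
#' @param min_radius_mm branches thinner than this are pruned (vessels
#'   below ~1 mm diameter are not reconstructed from angiography).
#' @param length_jitter_sd sd of log-normal length jitter (0 = none).
#' @param side,dominance labels carried onto the tree.
#' @param murray_exponent branching exponent (3 = Murray).
#' @return a `tree_recipe` list.
#' @export
tree_recipe <- function(depth = 3, ostial_radius_mm = 1.95, asymmetry = 1,
                        length_ratio = 10, min_radius_mm = 0.5,
                        length_jitter_sd = 0, side = "left",
                        dominance = "right", murray_exponent = 3) {
  if (depth < 1) stop("depth must be >= 1")
  if (asymmetry <= 0 || asymmetry > 1) stop("asymmetry must lie in (0, 1]")
  structure(list(depth = depth, ostial_radius_mm = ostial_radius_mm,
                 asymmetry = asymmetry, length_ratio = length_ratio,
                 min_radius_mm = min_radius_mm,
                 length_jitter_sd = length_jitter_sd, side = side,
                 dominance = dominance, murray_exponent = murray_exponent),
            class = "tree_recipe")
}

#' Generate a Murray-law coronary tree
#'
#' @param recipe a [tree_recipe()].
#' @param seed integer seed (used for length jitter; the topology and radii
#'   are deterministic given the recipe).
#' @return a validated [coronary_tree()].
#' @examples
#' tr <- generate_tree(tree_recipe(depth = 3))
#' length(tr$segments)  # 7
#' @export
generate_tree <- function(recipe = tree_recipe(), seed = 1) {
  stopifnot(inherits(recipe, "tree_recipe"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  m <- recipe$murray_exponent
  g <- recipe$asymmetry
  segs <- list()
  pruned <- 0L
  jitter <- function() {
    if (recipe$length_jitter_sd > 0)
      exp(rnorm(1, -recipe$length_jitter_sd^2 / 2, recipe$length_jitter_sd))
    else 1
  }
  grow <- function(id, parent, r_mm, level) {
    r_major <- r_mm / (1 + g^m)^(1 / m)
    r_minor <- g * r_major
    can_split <- level < recipe$depth && r_minor >= recipe$min_radius_mm
    if (level < recipe$depth && !can_split) pruned <<- pruned + 1L
    L <- recipe$length_ratio * r_mm * jitter()
    # uniform radius per branch, stepping down at junctions (the usual
    # 1D-network idealization); tapered or sampled profiles remain fully
    # supported for measured geometries
    segs[[id]] <<- vessel_segment(id, parent, length_mm = L,
                                  radius_mm = r_mm,
                                  terminal = !can_split)
    if (can_split) {
      grow(paste0(id, "L"), id, r_major, level + 1)
      grow(paste0(id, "R"), id, r_minor, level + 1)
    }
  }
  grow("s", NA_character_, recipe$ostial_radius_mm, 1)
  if (pruned > 0)
    warning(sprintf("%d bifurcation(s) pruned: child radius below %.2f mm",
                    pruned, recipe$min_radius_mm))
  coronary_tree(unname(segs),
                ostial_diameter_mm = 2 * recipe$ostial_radius_mm,
                dominance = recipe$dominance)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Canonical coronary inflow waveform shapes
#'
#' Analytic, periodic, unit-mean waveform shapes standing in for
#' population-averaged coronary flow waveforms: a baseline plus smooth
#' raised-cosine systolic and diastolic pulses. The left shape is
#' diastolic-dominant (most left-coronary perfusion occurs in diastole,
#' when intramyocardial compression relents); the right shape is balanced.
#' These are synthetic stand-ins, replaceable by any user-supplied sampled
#' waveform.
#'
#' @param side `"left"` or `"right"`.
#' @param n number of samples over one period (first = last).
#' @return a `coronary_waveform` object with `tau` (normalized time in
#'   `[0, 1]`) and unit-mean `value`.
#' @examples
#' w <- canonical_waveform("left")
#' @export
canonical_waveform <- function(side = c("left", "right"), n = 513) {
  side <- match.arg(side)
  tau <- seq(0, 1, length.out = n)
  hann <- function(t, center, width) {
    u <- (t - center) / width
    ifelse(abs(u) <= 0.5, cos(pi * u)^2, 0)
  }
  # systole occupies roughly the first third of the cycle
  if (side == "left") {
    v <- 0.35 + 0.55 * hann(tau, 0.16, 0.30) + 1.75 * hann(tau, 0.62, 0.50)
  } else {
    v <- 0.35 + 1.10 * hann(tau, 0.16, 0.30) + 1.10 * hann(tau, 0.62, 0.50)
  }
  v[n] <- v[1]
  v <- v / trapz_mean(tau, v)
  structure(list(tau = tau, value = v, side = side),
            class = "coronary_waveform")
}

#' Constant (steady) waveform shape
#'
#' @param n number of samples.
#' @return a unit-mean constant `coronary_waveform`.
#' @export
constant_waveform <- function(n = 5) {
  tau <- seq(0, 1, length.out = n)
  structure(list(tau = tau, value = rep(1, n), side = "none"),
            class = "coronary_waveform")
}

#' Diastolic area fraction of a waveform shape
#'
#' Fraction of the period-integrated flow delivered in diastole, taken as
#' the part of the cycle after `systole_end`.
#'
#' @param shape a `coronary_waveform`.
#' @param systole_end normalized time at which systole ends (default 1/3).
#' @return fraction in `[0, 1]`.
#' @export
diastolic_fraction <- function(shape, systole_end = 1/3) {
  tau <- shape$tau; v <- shape$value
  n <- length(tau)
  seg <- (tau[-1] + tau[-n]) / 2 > systole_end
  contrib <- (v[-1] + v[-n]) / 2 * diff(tau)
  sum(contrib[seg]) / sum(contrib)
}

#' Recipe for a synthetic patient cohort
#'
#' Clinical scalar distributions follow the aggregated characteristics of
#' an angiographic coronary-disease population: cardiac output
#' N(4.5, 1.5) L/min, heart rate N(70.8, 13.7) bpm, systolic/diastolic
#' pressure N(125.8, 25.8)/N(67.1, 12.7) mmHg (MAP = (SBP + 2 DBP)/3),
#' hematocrit around 39.2%, stenosis degree N(55.6, 17.2)% truncated to
#' `[20, 95]`, distal pressure-sampling location uniform on `[5, 65]` mm,
#' dominance 79.6/12.2/8.2% right/left/co-dominant.
#'
#' @param n_patients cohort size.
#' @param CO,HR,SBP,DBP,hematocrit mean/sd pairs.
#' @param degree mean/sd of stenosis degree (%), truncated to
#'   `degree_range`.
#' @param degree_range truncation bounds for sampled degrees.
#' @param distal_range_mm range of distal locations (mm).
#' @param stenosis_length_range_mm range of stenosis lengths (mm).
#' @param dominance_probs probabilities of right/left/co-dominant.
#' @return a `cohort_recipe` list.
#' @export
cohort_recipe <- function(n_patients = 10,
                          CO = c(4.5, 1.5), HR = c(70.8, 13.7),
                          SBP = c(125.8, 25.8), DBP = c(67.1, 12.7),
                          hematocrit = c(39.2, 4.5),
                          degree = c(55.6, 17.2), degree_range = c(20, 95),
                          distal_range_mm = c(5, 65),
                          stenosis_length_range_mm = c(8, 15),
                          dominance_probs = c(right = 0.796, left = 0.122,
                                              `co-dominant` = 0.082)) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  for (p in list(CO, HR, SBP, DBP, hematocrit, degree))
    if (length(p) != 2 || p[2] <= 0) stop("distribution parameters must be (mean, sd > 0)")
  structure(as.list(environment()), class = "cohort_recipe")
}

rnorm_trunc <- function(n, mean, sd, lo, hi, max_tries = 1000) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0
  while (length(bad) && tries < max_tries) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lo), hi)
  x
}

#' Generate a synthetic patient cohort
#'
#' Each case carries a Murray-law tree (left or right, per sampled
#' dominance and vessel side), a focal stenosis mid-way along the root
#' segment with sampled degree and length, a clinical record, and a distal
#' location clipped to the arc length actually reachable downstream of the
#' stenosis on the generated tree.
#'
#' @param recipe a [cohort_recipe()].
#' @param seed integer seed; the cohort is deterministic given
#'   `(recipe, seed)`.
#' @param tree_recipe base [tree_recipe()]; side is overridden per case.
#'   The default (3 generations, length/radius 22) leaves enough arc
#'   length downstream of the stenosis for clinical distal locations.
#' @param stenosis_position_frac arc-length fraction of the host branch at
#'   which the stenosis is centered.
#' @return list of cases, each `list(id, tree, patient, stenosis)` where
#'   `patient` has fields `MAP_mmHg, CO_Lmin, HR_bpm, hematocrit_pct,
#'   dominance, side, distal_location_mm`.
#' @export
generate_cohort <- function(recipe = cohort_recipe(), seed = 1,
                            tree_recipe = coroflow::tree_recipe(
                              depth = 3, length_ratio = 22,
                              length_jitter_sd = 0.08),
                            stenosis_position_frac = 0.4) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  n <- recipe$n_patients
  CO <- rnorm_trunc(n, recipe$CO[1], recipe$CO[2], 1.5, 10)
  HR <- rnorm_trunc(n, recipe$HR[1], recipe$HR[2], 40, 130)
  SBP <- rnorm_trunc(n, recipe$SBP[1], recipe$SBP[2], 80, 220)
  DBP <- pmin(rnorm_trunc(n, recipe$DBP[1], recipe$DBP[2], 40, 120), SBP - 10)
  hct <- rnorm_trunc(n, recipe$hematocrit[1], recipe$hematocrit[2], 20, 60)
  deg <- rnorm_trunc(n, recipe$degree[1], recipe$degree[2],
                     recipe$degree_range[1], recipe$degree_range[2])
  dom <- sample(names(recipe$dominance_probs), n, replace = TRUE,
                prob = recipe$dominance_probs)
  side <- sample(c("left", "right"), n, replace = TRUE, prob = c(0.735, 0.265))
  Ls <- runif(n, recipe$stenosis_length_range_mm[1],
              recipe$stenosis_length_range_mm[2])
  distal <- runif(n, recipe$distal_range_mm[1], recipe$distal_range_mm[2])
  tree_seeds <- sample.int(1e6, n)
  lapply(seq_len(n), function(i) {
    trc <- tree_recipe
    trc$side <- side[i]; trc$dominance <- dom[i]
    tree <- generate_tree(trc, seed = tree_seeds[i])
    # focal stenosis on the root's major child -- a non-terminal branch
    # whenever depth >= 3, so flow can redistribute to the sibling as it
    # does around a real branch lesion
    kids <- names(tree$segments)[vapply(tree$segments, function(s)
      identical(s$parent, tree$root), logical(1))]
    r0 <- vapply(kids, function(id) radius_at(tree$segments[[id]], 0),
                 numeric(1))
    host <- tree$segments[[kids[which.max(r0)]]]
    pos <- stenosis_position_frac * host$length_mm - Ls[i] / 2
    if (pos < 2) pos <- 2
    ru <- radius_at(host, pos + Ls[i] / 2)
    st <- stenosis_spec(host$id, position_mm = pos, length_mm = Ls[i],
                        degree_pct = deg[i], ru_mm = ru)
    tree$stenoses <- list(st)
    reach <- max_reachable_distal(tree, st)
    d <- min(distal[i], reach - 1)
    list(id = sprintf("case%03d", i), tree = tree,
         patient = list(id = sprintf("case%03d", i),
                        MAP_mmHg = (SBP[i] + 2 * DBP[i]) / 3,
                        CO_Lmin = CO[i], HR_bpm = HR[i],
                        hematocrit_pct = hct[i], dominance = dom[i],
                        side = side[i], distal_location_mm = d),
         stenosis = st)
  })
}

#' Read or write a patient record as JSON
#'
#' Patient JSON fields: `MAP_mmHg, CO_Lmin, HR_bpm, hematocrit_pct,
#' dominance, side, distal_location_mm`.
#'
#' @param patient a patient record list.
#' @param path file path.
#' @return `load_patient` returns the record; `save_patient` returns
#'   `path` invisibly.
#' @export
save_patient <- function(patient, path) {
  jsonlite::write_json(patient, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_patient
#' @export
load_patient <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("MAP_mmHg", "CO_Lmin", "HR_bpm", "hematocrit_pct", "dominance",
            "side", "distal_location_mm")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("patient record lacks fields: ",
                         paste(miss, collapse = ", "))
  rec
}
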
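#' Vessel segment
#'
#' One branch of a coronary tree. The radius profile is either a linear
#' taper between a proximal and distal radius, or sampled centerline points
#' `(s_mm, r_mm)` that are linearly interpolated.
#'
#' @param id segment identifier (character).
#' @param parent parent segment id, or `NA` for the root (ostium).
#' @param length_mm arc length in mm (> 0).
#' @param radius_mm either one radius (constant), or `c(proximal, distal)`.
#' @param centerline optional two-column matrix `(s_mm, r_mm)`; overrides
#'   `radius_mm` when given.
#' @param terminal logical; `TRUE` for a terminal (outlet) segment.
#' @return a `vessel_segment` list.
#' @export
vessel_segment <- function(id, parent = NA_character_, length_mm, radius_mm = NULL,
                           centerline = NULL, terminal = FALSE) {
  id <- as.character(id)
  length_mm <- as.numeric(length_mm)
  if (!is.null(radius_mm)) radius_mm <- as.numeric(radius_mm)
  if (!is.finite(length_mm) || length_mm <= 0)
    stop(sprintf("segment '%s': length must be positive", id))
  if (is.null(centerline)) {
    if (is.null(radius_mm)) stop(sprintf("segment '%s': radius profile missing", id))
    if (length(radius_mm) == 1) radius_mm <- rep(radius_mm, 2)
    if (length(radius_mm) != 2 || any(!is.finite(radius_mm)) || any(radius_mm <= 0))
      stop(sprintf("segment '%s': radii must be two positive numbers", id))
  } else {
    centerline <- as.matrix(centerline)
    if (ncol(centerline) != 2 || nrow(centerline) < 2)
      stop(sprintf("segment '%s': centerline needs >= 2 (s, r) rows", id))
    if (any(centerline[, 2] <= 0))
      stop(sprintf("segment '%s': centerline radii must be positive", id))
    if (is.unsorted(centerline[, 1], strictly = TRUE))
      stop(sprintf("segment '%s': centerline arc lengths must increase", id))
  }
  structure(list(id = id,
                 parent = if (is.na(parent)) NA_character_ else as.character(parent),
                 length_mm = length_mm, radius_mm = radius_mm,
                 centerline = centerline, terminal = isTRUE(terminal)),
            class = "vessel_segment")
}

#' Radius at an arc-length position along a segment
#'
#' Linear interpolation of the segment's radius profile (taper or sampled
#' centerline); positions outside `[0, L]` are clamped.
#'
#' @param seg a [vessel_segment()].
#' @param s_mm arc length from the proximal end, mm (vectorized).
#' @return radius in mm.
#' @export
radius_at <- function(seg, s_mm) {
  s_mm <- pmin(pmax(s_mm, 0), seg$length_mm)
  if (!is.null(seg$centerline)) {
    stats::approx(seg$centerline[, 1], seg$centerline[, 2], xout = s_mm,
                  rule = 2)$y
  } else {
    seg$radius_mm[1] + (seg$radius_mm[2] - seg$radius_mm[1]) * s_mm / seg$length_mm
  }
}

#' Stenosis geometry from any two of degree, rs, ru
#'
#' Stenosis degree is the percent radius reduction,
#' `degree = (1 - rs/ru) * 100`. Given any two of `{degree, rs, ru}` the
#' third is derived; when all three are supplied they must be mutually
#' consistent.
#'
#' @param degree_pct stenosis degree in percent, `[0, 100)`.
#' @param rs_mm minimal luminal radius in mm.
#' @param ru_mm reference (unstenosed) radius in mm.
#' @return list with `degree_pct`, `rs_mm`, `ru_mm`, and derived diameters
#'   `Du_mm`, `Ds_mm` and areas `Au_mm2`, `As_mm2`.
#' @examples
#' stenosis_geometry(ru_mm = 2, rs_mm = 1)   # 50% stenosis
#' @export
stenosis_geometry <- function(degree_pct = NULL, rs_mm = NULL, ru_mm = NULL) {
  if (!is.null(degree_pct)) degree_pct <- as.numeric(degree_pct)
  if (!is.null(rs_mm)) rs_mm <- as.numeric(rs_mm)
  if (!is.null(ru_mm)) ru_mm <- as.numeric(ru_mm)
  have <- c(degree = !is.null(degree_pct), rs = !is.null(rs_mm), ru = !is.null(ru_mm))
  if (sum(have) < 2) stop("at least two of {degree, rs, ru} are required")
  if (!is.null(degree_pct) && (degree_pct < 0 || degree_pct >= 100))
    stop("stenosis degree must lie in [0, 100)")
  if (!is.null(rs_mm) && rs_mm <= 0) stop("rs must be positive")
  if (!is.null(ru_mm) && ru_mm <= 0) stop("ru must be positive")
  if (all(have)) {
    implied <- (1 - rs_mm / ru_mm) * 100
    if (abs(implied - degree_pct) > 1e-6 * max(1, abs(degree_pct)))
      stop(sprintf("inconsistent stenosis triple: degree %.6g%% vs implied %.6g%%",
                   degree_pct, implied))
  } else if (!have["degree"]) {
    degree_pct <- (1 - rs_mm / ru_mm) * 100
    if (degree_pct < 0) stop("rs exceeds ru: negative stenosis degree")
  } else if (!have["ru"]) {
    ru_mm <- rs_mm / (1 - degree_pct / 100)
  } else {
    rs_mm <- ru_mm * (1 - degree_pct / 100)
  }
  list(degree_pct = degree_pct, rs_mm = rs_mm, ru_mm = ru_mm,
       Du_mm = 2 * ru_mm, Ds_mm = 2 * rs_mm,
       Au_mm2 = pi * ru_mm^2, As_mm2 = pi * rs_mm^2)
}

#' Stenosis specification
#'
#' A focal stenosis on a host segment, located by the arc length of its
#' proximal end. Supply any two of `degree_pct`, `rs_mm`, `ru_mm`.
#'
#' @param segment_id host segment id.
#' @param position_mm arc length of the proximal end of the stenosis, mm.
#' @param length_mm stenosis length `Ls`, mm.
#' @inheritParams stenosis_geometry
#' @return a `stenosis_spec` list, including the derived geometry fields.
#' @export
stenosis_spec <- function(segment_id, position_mm, length_mm,
                          degree_pct = NULL, rs_mm = NULL, ru_mm = NULL) {
  position_mm <- as.numeric(position_mm)
  length_mm <- as.numeric(length_mm)
  if (position_mm < 0) stop("stenosis position must be >= 0")
  if (length_mm <= 0) stop("stenosis length must be positive")
  g <- stenosis_geometry(degree_pct, rs_mm, ru_mm)
  structure(c(list(segment_id = as.character(segment_id),
                   position_mm = position_mm, length_mm = length_mm), g),
            class = "stenosis_spec")
}

#' Stenosis pressure-loss coefficients
#'
#' Viscous, "turbulent" and inertial coefficients of the integral stenosis
#' pressure-loss element:
#' `Kv = 32 * (0.83*Ls + 1.64*Ds) * (Au/As)^2 / Du` (lengths in identical
#' units), `Kt = 1.52`, `Ku = 1.2`.
#'
#' @param spec a [stenosis_spec()].
#' @param Kt,Ku override the default constants if needed.
#' @return list with `Kv`, `Kt`, `Ku`.
#' @export
stenosis_coefficients <- function(spec, Kt = 1.52, Ku = 1.2) {
  stopifnot(inherits(spec, "stenosis_spec"))
  Kv <- 32 * (0.83 * spec$length_mm + 1.64 * spec$Ds_mm) *
    (spec$Au_mm2 / spec$As_mm2)^2 / spec$Du_mm
  list(Kv = Kv, Kt = Kt, Ku = Ku)
}

#' Coronary tree
#'
#' A rooted, strictly bifurcating network of [vessel_segment()]s with
#' optional [stenosis_spec()] annotations. Validated on construction:
#' exactly one root, every non-terminal has exactly two children, no
#' cycles, stenoses reference existing segments and lie within their arc
#' length.
#'
#' @param segments list of [vessel_segment()]s.
#' @param stenoses list of [stenosis_spec()]s.
#' @param ostial_diameter_mm ostial diameter, mm; defaults to the proximal
#'   diameter of the root segment.
#' @param dominance one of `"right"`, `"left"`, `"co-dominant"`.
#' @return an object of class `coronary_tree`.
#' @export
coronary_tree <- function(segments, stenoses = list(), ostial_diameter_mm = NULL,
                          dominance = c("right", "left", "co-dominant")) {
  dominance <- match.arg(dominance)
  if (length(segments) < 1) stop("tree needs at least one segment")
  ids <- vapply(segments, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate segment ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(segments) <- ids
  parents <- vapply(segments, function(s) s$parent %||% NA_character_, character(1))
  roots <- ids[is.na(parents)]
  if (length(roots) != 1)
    stop(sprintf("topology error: expected exactly one root, found %d (%s)",
                 length(roots), paste(roots, collapse = ", ")))
  missing_parents <- setdiff(parents[!is.na(parents)], ids)
  if (length(missing_parents))
    stop("topology error: child references missing parent '",
         missing_parents[1], "'")
  nchild <- table(factor(parents[!is.na(parents)], levels = ids))
  bad <- names(nchild)[!(nchild %in% c(0, 2))]
  if (length(bad))
    stop(sprintf("topology error: segment '%s' has %d children (trees must be strictly bifurcating)",
                 bad[1], nchild[bad[1]]))
  # reachability from the root rules out cycles among non-root components
  reached <- character(0); frontier <- roots
  while (length(frontier)) {
    reached <- c(reached, frontier)
    frontier <- ids[!is.na(parents) & parents %in% frontier]
  }
  if (length(setdiff(ids, reached)))
    stop("topology error: cycle or disconnected segments: ",
         paste(setdiff(ids, reached), collapse = ", "))
  for (s in segments) {
    is_leaf <- nchild[s$id] == 0
    if (is_leaf != isTRUE(s$terminal))
      stop(sprintf("segment '%s': terminal flag (%s) disagrees with child count (%d)",
                   s$id, s$terminal, nchild[s$id]))
  }
  for (st in stenoses) {
    if (!inherits(st, "stenosis_spec")) stop("stenoses must be stenosis_spec objects")
    if (!st$segment_id %in% ids)
      stop("stenosis references missing segment '", st$segment_id, "'")
    L <- segments[[st$segment_id]]$length_mm
    if (st$position_mm + st$length_mm > L + 1e-9)
      stop(sprintf("stenosis on '%s' extends past segment end (%.3g + %.3g > %.3g mm)",
                   st$segment_id, st$position_mm, st$length_mm, L))
  }
  if (is.null(ostial_diameter_mm))
    ostial_diameter_mm <- 2 * radius_at(segments[[roots]], 0)
  structure(list(version = 1L, dominance = dominance,
                 ostial_diameter_mm = ostial_diameter_mm,
                 segments = segments, stenoses = stenoses, root = roots),
            class = "coronary_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coronary_tree <- function(x, ...) {
  terms <- sum(vapply(x$segments, function(s) s$terminal, logical(1)))
  cat(sprintf("Coronary tree: %d segments (%d terminal), %d stenoses, %s dominance, ostium %.2f mm\n",
              length(x$segments), terms, length(x$stenoses), x$dominance,
              x$ostial_diameter_mm))
  invisible(x)
}

tree_children <- function(tree, id) {
  ids <- names(tree$segments)
  ids[vapply(tree$segments, function(s) identical(s$parent, id), logical(1))]
}

tree_terminals <- function(tree) {
  names(tree$segments)[vapply(tree$segments, function(s) s$terminal, logical(1))]
}

#' Save a coronary tree as a versioned JSON document
#'
#' The tree-json schema is
#' `{version, dominance, ostial_diameter_mm, segments: [{id, parent,
#' length_mm, radius_mm | centerline, terminal}], stenoses: [{segment,
#' position_mm, length_mm, rs_mm, degree_pct}]}`. Numbers are written at
#' full precision so a save/load round trip is lossless.
#'
#' @param tree a [coronary_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_tree <- function(tree, path) {
  stopifnot(inherits(tree, "coronary_tree"))
  segs <- lapply(tree$segments, function(s) {
    out <- list(id = s$id, parent = s$parent, length_mm = s$length_mm,
                terminal = s$terminal)
    if (is.null(s$centerline)) out$radius_mm <- s$radius_mm
    else out$centerline <- unname(s$centerline)
    out
  })
  sts <- lapply(tree$stenoses, function(st)
    list(segment = st$segment_id, position_mm = st$position_mm,
         length_mm = st$length_mm, rs_mm = st$rs_mm, degree_pct = st$degree_pct))
  doc <- list(version = tree$version, dominance = tree$dominance,
              ostial_diameter_mm = tree$ostial_diameter_mm,
              segments = unname(segs), stenoses = unname(sts))
  # digits = I(17): full IEEE double precision, so save -> load is lossless
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Load a coronary tree from tree-json or a centerline CSV
#'
#' The centerline CSV dialect has one sampled point per row with columns
#' `segment_id, parent_id, arclength_mm, radius_mm`; the root has an empty
#' or `NA` parent, and terminal segments are those without children.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tree-json"`, or
#'   `"centerline-csv"`.
#' @return a validated [coronary_tree()].
#' @export
load_tree <- function(path, format = c("auto", "tree-json", "centerline-csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "centerline-csv" else "tree-json"
  if (format == "tree-json") load_tree_json(path) else load_tree_csv(path)
}

load_tree_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("parse error in '", path, "': ",
                                           conditionMessage(e)))
  if (is.null(doc$segments)) stop("parse error: no 'segments' array in ", path)
  segs <- lapply(doc$segments, function(s) {
    if (is.null(s$id)) stop("parse error: segment record without 'id'")
    cl <- if (!is.null(s$centerline))
      do.call(rbind, lapply(s$centerline, function(p) as.numeric(unlist(p))))
    vessel_segment(id = s$id,
                   parent = if (is.null(s$parent)) NA_character_ else s$parent,
                   length_mm = s$length_mm %||%
                     stop(sprintf("parse error: segment '%s' lacks length_mm", s$id)),
                   radius_mm = if (is.null(cl)) unlist(s$radius_mm),
                   centerline = cl,
                   terminal = isTRUE(s$terminal))
  })
  sts <- lapply(doc$stenoses %||% list(), function(st)
    stenosis_spec(segment_id = st$segment,
                  position_mm = st$position_mm, length_mm = st$length_mm,
                  rs_mm = st$rs_mm, degree_pct = st$degree_pct))
  coronary_tree(segs, sts,
                ostial_diameter_mm = doc$ostial_diameter_mm,
                dominance = doc$dominance %||% "right")
}

load_tree_csv <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("parse error in '", path, "': ",
                                          conditionMessage(e)))
  need <- c("segment_id", "parent_id", "arclength_mm", "radius_mm")
  if (!all(need %in% names(df)))
    stop("parse error: centerline CSV needs columns ",
         paste(need, collapse = ", "))
  df$segment_id <- as.character(df$segment_id)
  df$parent_id <- as.character(df$parent_id)
  df$parent_id[df$parent_id %in% c("", "NA")] <- NA_character_
  ids <- unique(df$segment_id)
  has_child <- ids %in% df$parent_id[!is.na(df$parent_id)]
  segs <- lapply(seq_along(ids), function(i) {
    rows <- df[df$segment_id == ids[i], ]
    rows <- rows[order(rows$arclength_mm), ]
    if (nrow(rows) < 2)
      stop(sprintf("parse error: segment '%s' needs >= 2 centerline rows", ids[i]))
    vessel_segment(id = ids[i], parent = rows$parent_id[1],
                   length_mm = max(rows$arclength_mm),
                   centerline = cbind(rows$arclength_mm, rows$radius_mm),
                   terminal = !has_child[i])
  })
  coronary_tree(segs)
}

#' Discretize a coronary tree onto uniform 1D grids
#'
#' Each segment is meshed with uniform spacing no larger than `dx_um`
#' (cells = `ceiling(L/dx)`, so end nodes fall exactly on segment
#' boundaries and total arc length is preserved). Segments hosting a
#' stenosis are split at the arc-length midpoint of the stenotic span into
#' two computational pieces joined by a zero-length pressure-loss
#' interface. Reference areas `A0` are interpolated from the radius
#' profile.
#'
#' @param tree a [coronary_tree()].
#' @param dx_um target grid spacing in micrometers (default 500).
#' @return a `gridded_tree` list: per-piece grids (`A0` in m^2, `dx` in m),
#'   junctions, stenosis interfaces, inlet and terminal piece indices.
#' @export
discretize <- function(tree, dx_um = 500) {
  stopifnot(inherits(tree, "coronary_tree"))
  if (dx_um <= 0) stop("dx must be positive")
  dx_mm <- dx_um / 1e3
  sten_by_seg <- split(tree$stenoses,
                       vapply(tree$stenoses, function(s) s$segment_id, character(1)))
  pieces <- list(); piece_of_seg_start <- list(); piece_of_seg_end <- list()
  sten_ifaces <- list()
  for (sid in names(tree$segments)) {
    seg <- tree$segments[[sid]]
    cuts <- 0
    sts <- sten_by_seg[[sid]]
    if (!is.null(sts)) {
      sts <- sts[order(vapply(sts, function(s) s$position_mm, numeric(1)))]
      cuts <- c(cuts, vapply(sts, function(s) s$position_mm + s$length_mm / 2,
                             numeric(1)))
    }
    cuts <- c(cuts, seg$length_mm)
    prev_piece <- NA_integer_
    for (j in seq_len(length(cuts) - 1)) {
      s0 <- cuts[j]; s1 <- cuts[j + 1]; L <- s1 - s0
      if (L < 2 * dx_mm)
        stop(sprintf("discretization error: piece of segment '%s' is %.3g mm < 2*dx = %.3g mm; use a smaller dx",
                     sid, L, 2 * dx_mm))
      ncell <- ceiling(L / dx_mm - 1e-12)
      s <- s0 + (L / ncell) * (0:ncell)
      r_mm <- radius_at(seg, s)
      k <- length(pieces) + 1L
      pieces[[k]] <- list(segment_id = sid, s0_mm = s0, s1_mm = s1,
                          n = ncell + 1L, dx = (L / ncell) * MM_M,
                          s_mm = s, A0 = pi * (r_mm * MM_M)^2)
      if (j == 1) piece_of_seg_start[[sid]] <- k
      if (!is.na(prev_piece))
        sten_ifaces[[length(sten_ifaces) + 1L]] <-
          list(up = prev_piece, down = k, stenosis = sts[[j - 1]])
      prev_piece <- k
    }
    piece_of_seg_end[[sid]] <- prev_piece
  }
  junctions <- list()
  for (sid in names(tree$segments)) {
    ch <- tree_children(tree, sid)
    if (length(ch) == 2)
      junctions[[length(junctions) + 1L]] <-
        list(parent = piece_of_seg_end[[sid]],
             child1 = piece_of_seg_start[[ch[1]]],
             child2 = piece_of_seg_start[[ch[2]]])
  }
  terminals <- tree_terminals(tree)
  structure(list(tree = tree, dx_um = dx_um, pieces = pieces,
                 junctions = junctions, stenosis_ifaces = sten_ifaces,
                 inlet_piece = piece_of_seg_start[[tree$root]],
                 terminal_pieces = vapply(terminals,
                                          function(s) piece_of_seg_end[[s]],
                                          integer(1)),
                 piece_start = piece_of_seg_start,
                 piece_end = piece_of_seg_end),
            class = "gridded_tree")
}

# map (segment_id, arc position mm) -> c(piece index, node index 1-based)
grid_locate <- function(gridded, segment_id, position_mm) {
  hits <- which(vapply(gridded$pieces, function(p)
    p$segment_id == segment_id && position_mm >= p$s0_mm - 1e-9 &&
      position_mm <= p$s1_mm + 1e-9, logical(1)))
  if (!length(hits)) stop(sprintf("no grid piece covers segment '%s' at %.3g mm",
                                  segment_id, position_mm))
  pc <- hits[1]
  node <- which.min(abs(gridded$pieces[[pc]]$s_mm - position_mm))
  c(piece = pc, node = node)
}
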
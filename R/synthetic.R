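# Synthetic RNA 3D structures with provable ground truth. The fixtures use
# chemically implausible but geometrically exact coordinates (ideal base-pair
# templates, circular loop rings, straight threading polylines): the
# entanglement detector is purely geometric, and exactness makes the ground
# truth provable by construction arithmetic (plane-crossing counts of the
# designed polylines inside the designed rings), independently of the
# detection pipeline.
#
# Layout conventions (before any rigid transform): a hairpin's innermost
# stem pair lies at z = 0 and closes a loop ring in the z = 0 plane (circle
# of radius 7.2 around (-1.15, -1, 0)); outer stem pairs stack downwards at
# 4.5 A rise, which keeps cross-rung candidates outside the hydrogen-bond
# gate of the pair detector.

.pair_rise <- 4.5
.ring_center <- c(-1.15, -1, 0)
.ring_radius <- 7.2
.arc_from <- 167.4        # degrees, attachment at the 5' (G) side
.arc_span <- 184.4        # degrees, swept through the bottom of the ring

# local-frame coordinates of an ideal purine-pyrimidine pair (z = 0 plane,
# hydrogen-bonded ring atoms 2.9 A apart across the pair axis)
purine_local <- function(type = c("G", "A")) {
  type <- match.arg(type)
  m <- rbind(
    N1 = c(-1.45, 0, 0), C2 = c(-2.14, -1.195, 0), N3 = c(-3.52, -1.195, 0),
    C4 = c(-4.21, 0, 0), C5 = c(-3.52, 1.195, 0), C6 = c(-2.14, 1.195, 0),
    N7 = c(-4.30, 2.20, 0), C8 = c(-5.55, 1.80, 0), N9 = c(-5.50, 0.45, 0),
    "C1'" = c(-6.55, -0.45, 0), "O2'" = c(-6.40, -1.90, 0.30),
    "C4'" = c(-8.25, -0.90, 0.80), P = c(-7.65, 0.45, 0.45))
  extra <- if (type == "G") {
    rbind(O6 = c(-1.50, 2.30, 0), N2 = c(-1.50, -2.30, 0))
  } else {
    rbind(N6 = c(-1.45, 2.30, 0))
  }
  rbind(m, extra)
}

pyrimidine_local <- function(type = c("C", "U")) {
  type <- match.arg(type)
  m <- rbind(
    N3 = c(1.45, 0, 0), C2 = c(2.14, -1.195, 0), N1 = c(3.52, -1.195, 0),
    C6 = c(4.21, 0, 0), C5 = c(3.52, 1.195, 0), C4 = c(2.14, 1.195, 0),
    "C1'" = c(4.255, -2.468, 0), "O2'" = c(4.00, -3.90, 0.30),
    "C4'" = c(5.955, -2.018, 0.80), P = c(5.355, -3.368, 0.45))
  extra <- if (type == "C") {
    rbind(O2 = c(1.50, -2.30, 0), N4 = c(1.50, 2.30, 0))
  } else {
    rbind(O2 = c(1.50, -2.30, 0), O4 = c(1.50, 2.30, 0))
  }
  rbind(m, extra)
}

place_atoms <- function(local, origin, ex, ey) {
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2], ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  world <- t(apply(local, 1, function(p)
    origin + p[1] * ex + p[2] * ey + p[3] * ez))
  world
}

atom_rows <- function(coords, chain, resno, resname) {
  data.frame(chain = chain, resno = resno, ins = "", resname = resname,
             atom = rownames(coords), elem = guess_element(rownames(coords)),
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             occ = 1, alt = "", stringsAsFactors = FALSE)
}

# an unpaired residue: explicit backbone points, base ring on a small
# polygon pointing along base_dir (plane content is irrelevant for unpaired
# residues; only named-atom presence, plane existence, and the COM matter)
free_residue_rows <- function(chain, resno, resname, P, C4, base_dir) {
  u <- base_dir / sqrt(sum(base_dir^2))
  w0 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- c(u[2] * w0[3] - u[3] * w0[2], u[3] * w0[1] - u[1] * w0[3],
         u[1] * w0[2] - u[2] * w0[1])
  v <- v / sqrt(sum(v^2))
  c1 <- C4 + 1.3 * u
  o2 <- c1 + 1.2 * v
  ctr <- C4 + 3.4 * u
  purine <- parent_nucleotide(resname) %in% .purines
  ring_names <- if (purine) c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
                else c("N1", "C2", "N3", "C4", "C5", "C6")
  nr <- length(ring_names)
  ring <- t(vapply(seq_len(nr), function(k) {
    th <- 2 * pi * (k - 1) / nr
    ctr + 1.5 * (cos(th) * (-u) + sin(th) * v)
  }, numeric(3)))
  rownames(ring) <- ring_names
  coords <- rbind(ring, "C1'" = c1, "O2'" = o2, "C4'" = C4)
  if (!is.null(P)) coords <- rbind(coords, P = P)
  atom_rows(coords, chain, resno, resname)
}

deg2rad <- function(d) d * pi / 180
radial <- function(phi_deg) c(cos(deg2rad(phi_deg)), sin(deg2rad(phi_deg)), 0)

arc_point <- function(phi_deg) .ring_center + .ring_radius * radial(phi_deg)

loop_arc_angles <- function(m) .arc_from + .arc_span * seq_len(m) / (m + 1)

# G-C pair placed in a frame: origin + x along ex, y along ey
gc_pair_rows <- function(chain, resno_g, resno_c, origin, ex = c(1, 0, 0),
                         ey = c(0, 1, 0)) {
  rbind(atom_rows(place_atoms(purine_local("G"), origin, ex, ey),
                  chain, resno_g, "G"),
        atom_rows(place_atoms(pyrimidine_local("C"), origin, ex, ey),
                  chain, resno_c, "C"))
}

# sample 2*n points (P and C4' per residue) evenly along a waypoint polyline
sample_polyline <- function(waypoints, n_residues) {
  wp <- do.call(rbind, waypoints)
  seg <- sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = 2 * n_residues)
  t(vapply(s, function(si) {
    k <- max(which(cum <= si + 1e-12))
    if (k >= nrow(wp)) return(wp[nrow(wp), ])
    f <- (si - cum[k]) / max(seg[k], 1e-12)
    wp[k, ] + f * (wp[k + 1, ] - wp[k, ])
  }, numeric(3)))
}

strand_rows <- function(chain, resnos, pts, resname = "A",
                        base_dir = c(0, -1, 0), drop_first_P = FALSE) {
  rows <- list()
  for (k in seq_along(resnos)) {
    P <- pts[2 * k - 1, ]
    C4 <- pts[2 * k, ]
    if (k == 1 && drop_first_P) {
      rows[[k]] <- free_residue_rows(chain, resnos[k], resname, NULL, C4, base_dir)
    } else {
      rows[[k]] <- free_residue_rows(chain, resnos[k], resname, P, C4, base_dir)
    }
  }
  do.call(rbind, rows)
}

# core hairpin scaffold: k G-C stem pairs + m loop residues (adenines on the
# ring arc); residue numbering starts at `start`, chain `chain`
hairpin_rows <- function(k = 4, m = 8, chain = "A", start = 1L,
                         skip_loop = integer(0)) {
  rows <- list()
  for (p in seq_len(k)) {
    z <- -.pair_rise * (k - p)
    rows[[length(rows) + 1]] <- gc_pair_rows(
      chain, start + p - 1L, start + 2L * k + m - p,
      origin = c(0, 0, z))
  }
  ang <- loop_arc_angles(m)
  half <- .arc_span / (m + 1) / 4
  for (t in seq_len(m)) {
    resno <- start + k + t - 1L
    if (resno %in% skip_loop) next
    P <- arc_point(ang[t] - half)
    C4 <- arc_point(ang[t] + half)
    rows[[length(rows) + 1]] <- free_residue_rows(
      chain, resno, "A", P, C4, base_dir = radial(ang[t]))
  }
  do.call(rbind, rows)
}

# threading-tail waypoint tables for 1..3 ring crossings (z = 0 plane of
# the standard hairpin); crossing x-positions stay >= 1 A from every ring
# vertex and >= 1.6 A apart
tail_points <- function(punctures) {
  a <- .ring_center[1]
  y <- .ring_center[2] - 4.2
  base <- list(c(9, y, -11), c(6, y, -8.5), c(3, y, -6.5), c(0.5, y, -5),
               c(a, y, -3), c(a, y, -1.2), c(a, y, 1.2))
  if (punctures == 1) {
    pts <- c(base, list(c(a, y, 3), c(a, y, 6), c(a, -9, 8), c(a, -13, 9),
                        c(a, -16, 10)))
  } else if (punctures == 2) {
    pts <- c(base, list(c(a + 1.6, y, 1.2), c(a + 1.6, y, -1.2),
                        c(3, y, -3), c(8, y - 0.8, -5), c(12, y - 1.8, -6)))
  } else if (punctures == 3) {
    pts <- c(base, list(c(a + 1.6, y, 1.2), c(a + 1.6, y, -1.2),
                        c(a + 3.2, y, -1.2), c(a + 3.2, y, 1.2),
                        c(a + 3.2, y, 4), c(a + 3.2, -9, 7),
                        c(a + 3.2, -13, 9)))
  } else {
    stop("infeasible fixture: supported puncture counts are 1..3")
  }
  do.call(rbind, pts)
}

# the designed ring polygon of the standard hairpin (xy projection),
# independent construction arithmetic used to validate ground truth
ring_polygon_xy <- function(m) {
  pu <- purine_local("G"); py <- pyrimidine_local("C")
  ang <- loop_arc_angles(m)
  half <- .arc_span / (m + 1) / 4
  arc <- do.call(rbind, lapply(ang, function(aa)
    rbind(arc_point(aa - half)[1:2], arc_point(aa + half)[1:2])))
  com_g <- colMeans(pu[c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"), 1:2])
  com_c <- colMeans(py[c("N1", "C2", "N3", "C4", "C5", "C6"), 1:2])
  rbind(pu["P", 1:2], pu["C4'", 1:2], arc, py["P", 1:2], py["C4'", 1:2],
        com_c, com_g)
}

point_in_polygon_2d <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# number of z = 0 plane crossings of a polyline whose xy falls inside the
# ring polygon
count_plane_crossings <- function(pts, poly) {
  n <- 0L
  for (k in seq_len(nrow(pts) - 1)) {
    z1 <- pts[k, 3]; z2 <- pts[k + 1, 3]
    if ((z1 > 0) == (z2 > 0) || z1 == z2) next
    f <- z1 / (z1 - z2)
    xy <- pts[k, 1:2] + f * (pts[k + 1, 1:2] - pts[k, 1:2])
    if (point_in_polygon_2d(xy, poly)) n <- n + 1L
  }
  n
}

fixture_model <- function(rows, family, seed) {
  rows <- rows[order(match(rows$chain, unique(rows$chain)), rows$resno), ,
               drop = FALSE]
  m <- build_rna_structure(rows, model_id = 1L,
                           source = list(path = paste0("synthetic:", family),
                                         format = "generated"))
  m
}

#' Generate a synthetic RNA 3D structure with known ground truth
#'
#' Families:
#' \describe{
#'   \item{clean_hairpin}{4 G-C stem pairs and a loop; no entanglement.}
#'   \item{lassoed_hairpin}{hairpin whose loop ring is threaded by the 3'
#'     single strand `punctures` times: classes L(S), L(S.), L(S..).}
#'   \item{multi_weave}{alias for lassoed_hairpin with 3 punctures.}
#'   \item{interlaced_hairpins}{two hairpin loops linked like chain links
#'     (one L&L interlace).}
#'   \item{knotlike_pseudoknot}{a core helix crossed by two pseudoknotted
#'     pairs of order 1 whose ring is threaded by the 5' strand: a
#'     higher-order L(S) lasso, detected only when pseudoknots are
#'     accepted. Built as a synthetic stand-in for the xrRNA knot-like
#'     fold: the order-1 loop is closed by pair G33-C49, the threading
#'     strand is the 5' end g1-G31, and the puncture falls between the C4'
#'     atom of residue 2 and the P atom of residue 3.}
#'   \item{non_rna_contaminated}{clean hairpin plus a peptide chain and a
#'     water, exercising the cleaning stage.}
#' }
#'
#' The generator validates its own ground truth by independent construction
#' arithmetic (plane-crossing counts of the designed polylines inside the
#' designed ring polygons) and stops on an infeasible specification.
#'
#' @param family Fixture family name.
#' @param loop_size Loop residue count (ring sampling density; the ring
#'   radius is fixed by the pair template).
#' @param punctures Intended crossing count (lassoed_hairpin only, 1..3).
#' @param seed Optional seed; when given, a random rigid motion is applied
#'   to all coordinates.
#' @param transform Optional explicit list(R, t) rigid motion (overrides
#'   `seed`).
#' @param dir Optional directory: when given, the fixture is written as
#'   PDB and mmCIF files plus a JSON ground-truth sidecar.
#' @return list(model, truth, files) where truth records the expected
#'   pairs, orders, and entanglements.
#' @export
rna_fixture <- function(family = c("clean_hairpin", "lassoed_hairpin",
                                   "multi_weave", "interlaced_hairpins",
                                   "knotlike_pseudoknot",
                                   "non_rna_contaminated"),
                        loop_size = 8L, punctures = 1L, seed = NULL,
                        transform = NULL, dir = NULL) {
  family <- match.arg(family)
  if (missing(loop_size) && family == "knotlike_pseudoknot") loop_size <- 15L
  m <- as.integer(loop_size)
  if (m < 3) stop("infeasible fixture: loop too small to thread (loop_size < 3)")
  k <- 4L

  truth <- list(family = family, loop_size = m, punctures = 0L)
  ent <- data.frame(level = integer(), topology = character(),
                    class = character(), n_punctures = integer(),
                    stringsAsFactors = FALSE)

  if (family == "multi_weave") {
    family2 <- "lassoed_hairpin"
    punctures <- 3L
  } else family2 <- family

  if (family2 == "clean_hairpin" || family2 == "non_rna_contaminated") {
    rows <- hairpin_rows(k, m)
    truth$pairs <- data.frame(i = seq_len(k), j = 2L * k + m - seq_len(k) + 1L,
                              order = 0L)
    if (family2 == "non_rna_contaminated") {
      pep <- do.call(rbind, lapply(1:3, function(r) {
        base <- c(40 + 4 * r, 0, 0)
        coords <- rbind(N = base, CA = base + c(1.5, 0.3, 0),
                        C = base + c(2.6, -0.4, 0.4), O = base + c(3.1, -1.5, 0.4),
                        CB = base + c(1.6, 1.2, 1.1))
        atom_rows(coords, "P", r, "ALA")
      }))
      wat <- atom_rows(rbind(O = c(25, 25, 25)), "A", 999L, "HOH")
      rows <- rbind(rows, wat, pep)
      truth$contaminants <- c("peptide chain P", "water A999")
    }
  } else if (family2 == "lassoed_hairpin") {
    punctures <- as.integer(punctures)
    pts <- tail_points(punctures)
    n_tail <- nrow(pts) / 2
    rows <- rbind(hairpin_rows(k, m),
                  strand_rows("A", 2L * k + m + seq_len(n_tail), pts))
    crossings <- count_plane_crossings(pts, ring_polygon_xy(m))
    if (crossings != punctures) {
      stop("infeasible fixture: designed tail crosses the ring ", crossings,
           " times, wanted ", punctures)
    }
    truth$punctures <- punctures
    truth$pairs <- data.frame(i = seq_len(k), j = 2L * k + m - seq_len(k) + 1L,
                              order = 0L)
    ent <- data.frame(level = 0L, topology = "lasso",
                      class = class_code("L", "S", "lasso", punctures),
                      n_punctures = punctures, stringsAsFactors = FALSE)
  } else if (family2 == "interlaced_hairpins") {
    rows_a <- hairpin_rows(k, m, chain = "A")
    rows_b <- hairpin_rows(k, m, chain = "B")
    # rigid motion of hairpin B: local (x,y,z) -> world (z,x,y) + q0, which
    # stands its ring plane perpendicular to A's and links the two rings.
    # B's plane is aimed at the midpoint of the ring-arc chord nearest 292
    # degrees so that A crosses it mid-segment, well away from chain
    # vertices (the overlapping-atom guard would discard grazing hits)
    ang <- loop_arc_angles(m)
    half <- .arc_span / (m + 1) / 4
    verts <- sort(c(ang - half, ang + half))
    mids <- (verts[-1] + verts[-length(verts)]) / 2
    theta <- mids[which.min(abs(mids - 292))]
    wx <- .ring_center[1] + .ring_radius * cos(deg2rad(theta))
    wy <- .ring_center[2] + .ring_radius * sin(deg2rad(theta))
    q0 <- c(wx, wy + 1.15, 5.2)
    pb <- as.matrix(rows_b[, c("x", "y", "z")])
    rows_b$x <- q0[1] + pb[, 3]
    rows_b$y <- q0[2] + pb[, 1]
    rows_b$z <- q0[3] + pb[, 2]
    rows <- rbind(rows_a, rows_b)
    # linking validation: B's ring must cross A's plane exactly once inside
    # A's ring polygon (and symmetrically for A through B's plane x = q0[1])
    poly <- ring_polygon_xy(m)
    ring_local <- cbind(poly, 0)
    ring_b <- cbind(q0[1] + ring_local[, 3], q0[2] + ring_local[, 1],
                    q0[3] + ring_local[, 2])
    ring_b_closed <- rbind(ring_b, ring_b[1, , drop = FALSE])
    if (count_plane_crossings(ring_b_closed, poly) != 1) {
      stop("infeasible fixture: hairpin rings are not singly linked")
    }
    ring_a_in_b_frame <- cbind(ring_local[, 1] - q0[2] + 0,
                               ring_local[, 2] - q0[3],
                               ring_local[, 1] * 0 + (0 - q0[1]))
    # A's ring in B's local frame: local = M^T (world - q0), M p = (p3,p1,p2)
    ring_a <- cbind(poly[, 1], poly[, 2], 0)  # world coords of A's ring
    a_local <- cbind(ring_a[, 2] - q0[2], ring_a[, 3] - q0[3],
                     ring_a[, 1] - q0[1])
    a_local_closed <- rbind(a_local, a_local[1, , drop = FALSE])
    if (count_plane_crossings(a_local_closed, poly) != 1) {
      stop("infeasible fixture: hairpin rings are not singly linked")
    }
    truth$pairs <- rbind(
      data.frame(i = seq_len(k), j = 2L * k + m - seq_len(k) + 1L, order = 0L,
                 chain = "A"),
      data.frame(i = seq_len(k), j = 2L * k + m - seq_len(k) + 1L, order = 0L,
                 chain = "B"))
    truth$punctures <- 1L
    ent <- data.frame(level = 0L, topology = "interlace", class = "L&L",
                      n_punctures = 2L, stringsAsFactors = FALSE)
  } else if (family2 == "knotlike_pseudoknot") {
    rows <- knotlike_rows(m)
    rc <- 34L + m
    truth$pairs <- data.frame(
      i = c(37L, 38L, 39L, 32L, 33L),
      j = c(rc + 8L, rc + 7L, rc + 6L, rc + 1L, rc),
      order = c(0L, 0L, 0L, 1L, 1L))
    truth$punctures <- 1L
    truth$closing_pair <- c(33L, rc)
    truth$strand_range <- c(1L, 31L)
    truth$puncture_segment <- list(res = c(2L, 3L), atoms = c("C4'", "P"))
    ent <- data.frame(level = 1L, topology = "lasso", class = "L(S)",
                      n_punctures = 1L, stringsAsFactors = FALSE)
    # construction arithmetic: the designed 5' corridor crosses the designed
    # order-1 ring exactly once
    corridor <- rbind(c(-5.1, -2.44, -3), c(-5.1, -2.44, -1.2),
                      c(-5.1, -2.44, 1.2), c(-5.1, -2.44, 2.1))
    if (count_plane_crossings(corridor, ring_polygon_xy(m)) != 1) {
      stop("infeasible fixture: corridor does not thread the pseudoknot ring")
    }
  }

  model <- fixture_model(rows, family, seed)

  if (is.null(transform) && !is.null(seed)) {
    transform <- random_rigid_transform(seed)
  }
  if (!is.null(transform)) {
    model <- transform_structure(model, transform$R, transform$t)
    truth$transform <- transform
  }
  truth$entanglements <- ent

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(dir, sprintf("%s_m%d", family, m))
    files <- c(pdb = paste0(stem, ".pdb"), cif = paste0(stem, ".cif"),
               truth = paste0(stem, "_truth.json"))
    write_rna_structure(model, files[["pdb"]], "pdb")
    write_rna_structure(model, files[["cif"]], "mmcif")
    jsonlite::write_json(truth[setdiff(names(truth), "transform")],
                         files[["truth"]], auto_unbox = TRUE, digits = NA)
  }
  list(model = model, truth = truth, files = files)
}

# the knot-like pseudoknot scaffold (see rna_fixture docs); m = ring loop
# residue count, residues 34..(33+m) on the arc
knotlike_rows <- function(m) {
  if (m < 8) stop("infeasible fixture: knotlike_pseudoknot needs loop_size >= 8")
  rc <- 34L + m                      # ring-closing C of pair (33, rc)
  rows <- list()
  # pseudoknotted rungs: (33, rc) closes the ring at z = 0, (32, rc+1)
  # stacks below it
  rows[[1]] <- gc_pair_rows("A", 33L, rc, origin = c(0, 0, 0))
  rows[[2]] <- gc_pair_rows("A", 32L, rc + 1L, origin = c(0, 0, -.pair_rise))
  # ring arc residues (adenines), skipping the core-paired positions 37-39
  ang <- loop_arc_angles(m)
  half <- .arc_span / (m + 1) / 4
  for (t in seq_len(m)) {
    resno <- 33L + t
    if (resno %in% c(37L, 38L, 39L)) next
    rows[[length(rows) + 1]] <- free_residue_rows(
      "A", resno, "A", arc_point(ang[t] - half), arc_point(ang[t] + half),
      base_dir = radial(ang[t]))
  }
  # core pairs: arc residues 37,38,39 paired vertically downwards with
  # rc+8, rc+7, rc+6 -- these cross the pseudoknotted rungs, making the
  # rungs order 1
  for (idx in 1:3) {
    g <- 36L + idx                   # 37, 38, 39
    c_ <- rc + 9L - idx              # rc+8, rc+7, rc+6
    phi <- ang[g - 33L]
    r_hat <- radial(phi)
    t_hat <- c(r_hat[2], -r_hat[1], 0)
    q <- arc_point(phi)
    origin <- q + 0.9 * r_hat - 0.8 * t_hat - c(0, 0, 8.25)
    rows[[length(rows) + 1]] <- gc_pair_rows("A", g, c_, origin = origin,
                                             ex = c(0, 0, -1), ey = r_hat)
  }
  # 5' threading strand: residues 1..3 form the corridor through the ring
  # (puncture between C4' of residue 2 and P of residue 3); residues 4..31
  # climb out, descend outside the ring, and approach residue 32
  a <- c(-5.1, -2.44)
  rows[[length(rows) + 1]] <- free_residue_rows(
    "A", 1L, "G", NULL, c(a, -3), base_dir = c(0, -1, 0))
  rows[[length(rows) + 1]] <- free_residue_rows(
    "A", 2L, "A", c(a, -2.1), c(a, -1.2), base_dir = c(0, -1, 0))
  rows[[length(rows) + 1]] <- free_residue_rows(
    "A", 3L, "A", c(a, 1.2), c(a, 2.1), base_dir = c(0, -1, 0))
  climb <- list(c(a, 3.2), c(-5.1, -2.44, 5), c(-6.5, -2.44, 6.5),
                c(-9, -2.2, 7.5), c(-12, -1.5, 7), c(-13.5, -1, 3),
                c(-13.5, -0.7, -1), c(-13, -0.6, -4.3), c(-11, -0.7, -4.3),
                c(-9.6, -0.8, -4.0))
  pts <- sample_polyline(climb, 28L)
  tail_names <- rep("A", 28L)
  tail_names[28L] <- "G"             # residue 31
  rows[[length(rows) + 1]] <- strand_rows("A", 4:31, pts, resname = "A")
  # overwrite residue 31 as G (strand end named in the ground truth)
  rows[[length(rows)]]$resname[rows[[length(rows)]]$resno == 31L] <- "G"
  # linker between the pseudoknot rungs and the core partners
  route <- list(c(8, -4, -6.5), c(8.5, -5, -8), c(8, -6.5, -9.5),
                c(6.5, -7.5, -10.5), c(5, -8, -11.5), c(3.5, -8, -12.2),
                c(2, -8, -12.7), c(0.5, -8, -13))
  rows[[length(rows) + 1]] <- strand_rows("A", (rc + 2L):(rc + 5L),
                                          do.call(rbind, route))
  # 3' exit after the core partners
  exit <- list(c(-8, -4, -15.5), c(-9.5, -3.5, -16.5), c(-11, -3, -17.5),
               c(-12.5, -3, -18.5), c(-14, -3, -19.5), c(-15.5, -3, -20.5))
  rows[[length(rows) + 1]] <- strand_rows("A", (rc + 9L):(rc + 11L),
                                          do.call(rbind, exit))
  do.call(rbind, rows)
}

#' Apply a rigid motion to all atoms of a structure
#'
#' @param model An `rna_structure`.
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation vector.
#' @return The transformed `rna_structure`.
#' @export
transform_structure <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

#' Random rigid motion
#'
#' @param seed Integer seed.
#' @return list(R, t): a uniform random rotation (det +1) and a translation
#'   with coordinates in \[-20, 20\] Angstrom.
#' @export
random_rigid_transform <- function(seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::runif(3, -20, 20))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Jitter all atom coordinates with Gaussian noise
#'
#' @param model An `rna_structure`.
#' @param noise_sd Standard deviation of the jitter, Angstrom.
#' @param seed Optional seed for reproducibility.
#' @return The perturbed `rna_structure`.
#' @export
perturb_structure <- function(model, noise_sd, seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(model)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n <- nrow(model$atoms)
  model$atoms$x <- model$atoms$x + stats::rnorm(n, 0, noise_sd)
  model$atoms$y <- model$atoms$y + stats::rnorm(n, 0, noise_sd)
  model$atoms$z <- model$atoms$z + stats::rnorm(n, 0, noise_sd)
  model
}
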
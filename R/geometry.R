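# Geometry stage: polygonal chains for elements, triangle meshes spanned on
# closed chains, and puncture detection by segment-triangle intersection.

#' Geometry parameters
#'
#' @param chain_atoms Backbone atoms used as polygonal-chain vertices, in
#'   within-residue order (default P then C4').
#' @param edge_target Target maximum triangle edge length for mesh
#'   refinement, Angstrom.
#' @param max_depth Recursion cap for the longest-edge subdivision.
#' @param eps_det Determinant tolerance of the Moller-Trumbore test
#'   (parallel segment and triangle).
#' @param eps_bary Tolerance on the barycentric gates.
#' @param merge_radius Hits closer than this collapse to one puncture,
#'   Angstrom.
#' @param overlap_radius Crossings whose chain segment has an endpoint
#'   within this distance of a mesh vertex are discarded as
#'   overlapping-atom artifacts, Angstrom.
#' @param weighted_com Mass-weighted base centers of mass instead of plain
#'   centroids.
#' @return A list of geometry parameters.
#' @export
geometry_params <- function(chain_atoms = c("P", "C4'"), edge_target = 2.0,
                            max_depth = 8L, eps_det = 1e-9, eps_bary = 1e-7,
                            merge_radius = 0.05, overlap_radius = 0.2,
                            weighted_com = FALSE) {
  list(chain_atoms = chain_atoms, edge_target = edge_target,
       max_depth = as.integer(max_depth), eps_det = eps_det,
       eps_bary = eps_bary, merge_radius = merge_radius,
       overlap_radius = overlap_radius, weighted_com = weighted_com)
}

#' Build the polygonal chain of a structural element
#'
#' Open elements (S) connect the selected backbone atoms of every residue
#' in 5'->3' order (P omitted where absent at a 5' terminus). Closed
#' elements (L, D) follow the boundary: backbone atoms along each strand
#' run, bridged at every closing pair by the base center-of-mass
#' pseudoatoms of the two paired nucleotides, forming one closed ring.
#'
#' @param element A structural element from [build_elements()].
#' @param model The `rna_structure` the element belongs to.
#' @param params See [geometry_params()].
#' @return A `polygonal_chain` (list with `element_id`, `points` matrix,
#'   `sources` data.frame, `closed` flag), or `NULL` when fewer than 2
#'   (open) / 3 (closed) points are available.
#' @export
build_polygonal_chain <- function(element, model, params = geometry_params()) {
  res <- model$residues
  pts <- list()
  src_gi <- integer(0)
  src_atom <- character(0)
  add_point <- function(p, gi, atom) {
    pts[[length(pts) + 1]] <<- p
    src_gi[length(src_gi) + 1] <<- gi
    src_atom[length(src_atom) + 1] <<- atom
  }
  add_residue_backbone <- function(gi) {
    for (at in params$chain_atoms) {
      p <- atom_xyz(model, gi, at)
      if (is.null(p)) {
        if (at == "P" && res$seq_index[gi] == 0) next  # 5'-terminal residue
        stop(sprintf("missing atom %s in residue %s (chain %s)",
                     at, res_label(model, gi), res$chain[gi]))
      }
      add_point(p, gi, at)
    }
  }
  add_com <- function(gi) {
    p <- base_center_of_mass(model, gi, weighted = params$weighted_com)
    if (is.null(p)) stop("no base ring atoms for residue ", res_label(model, gi))
    add_point(p, gi, "base-COM")
  }

  closed <- element$kind %in% c("L", "D")
  for (seg in element$boundary) {
    if (seg$type == "run") {
      for (gi in seg$gi) add_residue_backbone(gi)
    } else {
      add_com(seg$gi[1])
      add_com(seg$gi[2])
    }
  }
  if (!length(pts)) return(NULL)
  m <- do.call(rbind, pts)
  # drop repeated consecutive points (and, for rings, a repeated closure)
  keep <- c(TRUE, rowSums((m[-1, , drop = FALSE] -
                             m[-nrow(m), , drop = FALSE])^2) > 1e-12)
  if (closed && nrow(m) > 1 && sum((m[1, ] - m[nrow(m), ])^2) <= 1e-12) {
    keep[nrow(m)] <- FALSE
  }
  m <- m[keep, , drop = FALSE]
  src_gi <- src_gi[keep]
  src_atom <- src_atom[keep]
  if ((closed && nrow(m) < 3) || (!closed && nrow(m) < 2)) return(NULL)
  structure(list(element_id = element$id, points = m,
                 sources = data.frame(gi = src_gi, atom = src_atom,
                                      stringsAsFactors = FALSE),
                 closed = closed),
            class = "polygonal_chain")
}

#' Triangulate a closed polygonal chain
#'
#' Centroid-fan construction (one triangle per boundary edge, apex at the
#' chain centroid), followed by recursive longest-edge midpoint subdivision
#' of every triangle whose longest edge exceeds `edge_target`, down to a
#' recursion cap. Midpoints are shared between triangles, and boundary
#' edges are subdivided consistently, so the traversed mesh boundary equals
#' the refined chain. Non-planar rings are meshed as-is from the fan.
#'
#' @param chain A closed `polygonal_chain`.
#' @param params See [geometry_params()].
#' @return An `rna_mesh`: list(element_id, vertices, triangles, e1, e2,
#'   boundary) where `boundary` is the refined boundary vertex cycle.
#' @export
triangulate_chain <- function(chain, params = geometry_params()) {
  stopifnot(inherits(chain, "polygonal_chain"), chain$closed)
  v <- chain$points
  nb <- nrow(v)
  centroid <- colMeans(v)
  verts <- rbind(v, centroid)
  ci <- nb + 1L

  # degeneracy: all fan triangles with (near-)zero area
  areas <- vapply(seq_len(nb), function(k) {
    a <- v[k, ]; b <- v[if (k == nb) 1L else k + 1L, ]
    cr <- crossp(b - a, centroid - a)
    sqrt(sum(cr^2)) / 2
  }, numeric(1))
  scale2 <- max(1, max(abs(v))^2)
  if (all(areas < 1e-9 * scale2)) {
    stop(structure(class = c("rnatangle_degenerate", "error", "condition"),
                   list(message = paste0("degenerate (collinear) chain for ",
                                         chain$element_id),
                        call = sys.call())))
  }

  # triangle rows: v1 v2 v3 depth b12 b23 b31 (b: edge lies on the boundary)
  tri <- matrix(0L, nrow = nb, ncol = 7)
  for (k in seq_len(nb)) {
    tri[k, ] <- c(k, if (k == nb) 1L else k + 1L, ci, 0L, 1L, 0L, 0L)
  }

  midpoint_env <- new.env(hash = TRUE, parent = emptyenv())
  boundary_edges <- list()
  out <- matrix(0L, nrow = 0, ncol = 7)
  stack <- tri
  n_alloc <- nrow(verts)
  while (nrow(stack)) {
    t1 <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    ids <- t1[1:3]
    d <- t1[4]
    p <- verts[ids, , drop = FALSE]
    el <- c(sum((p[1, ] - p[2, ])^2), sum((p[2, ] - p[3, ])^2),
            sum((p[3, ] - p[1, ])^2))
    longest <- which.max(el)
    if (sqrt(el[longest]) <= params$edge_target || d >= params$max_depth) {
      out <- rbind(out, t1)
      next
    }
    a <- ids[longest]
    b <- ids[if (longest == 3) 1 else longest + 1]
    cc <- ids[setdiff(1:3, c(longest, if (longest == 3) 1 else longest + 1))]
    key <- paste(min(a, b), max(a, b))
    mid <- get0(key, envir = midpoint_env)
    if (is.null(mid)) {
      verts <- rbind(verts, (verts[a, ] + verts[b, ]) / 2)
      mid <- nrow(verts)
      assign(key, mid, envir = midpoint_env)
    }
    on_boundary <- t1[4 + longest] == 1L
    # children inherit boundary flags of the split edge and the kept edges
    flags <- t1[5:7]
    # edges of t1: (1:a-b, 2:b-c, 3:c-a) relative to rotation starting at `longest`
    eb <- flags[longest]
    ebc <- flags[if (longest == 3) 1 else longest + 1]
    eca <- flags[if (longest == 1) 3 else longest - 1]
    child1 <- c(a, mid, cc, d + 1L, eb, 0L, eca)
    child2 <- c(mid, b, cc, d + 1L, eb, ebc, 0L)
    stack <- rbind(stack, child1, child2)
  }

  tris <- out[, 1:3, drop = FALSE]
  # boundary edge list from the flags
  be <- list()
  for (k in seq_len(nrow(out))) {
    ids <- out[k, 1:3]
    fl <- out[k, 5:7]
    if (fl[1]) be[[length(be) + 1]] <- c(ids[1], ids[2])
    if (fl[2]) be[[length(be) + 1]] <- c(ids[2], ids[3])
    if (fl[3]) be[[length(be) + 1]] <- c(ids[3], ids[1])
  }
  boundary <- order_boundary_cycle(be)

  e1 <- verts[tris[, 2], , drop = FALSE] - verts[tris[, 1], , drop = FALSE]
  e2 <- verts[tris[, 3], , drop = FALSE] - verts[tris[, 1], , drop = FALSE]
  structure(list(element_id = chain$element_id, vertices = verts,
                 triangles = tris, e1 = e1, e2 = e2, boundary = boundary,
                 chain = chain),
            class = "rna_mesh")
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# order directed boundary edges into the vertex cycle starting at vertex 1
order_boundary_cycle <- function(edges) {
  if (!length(edges)) return(integer(0))
  from <- vapply(edges, `[`, integer(1), 1)
  to <- vapply(edges, `[`, integer(1), 2)
  nxt <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(from)) assign(as.character(from[k]), to[k], envir = nxt)
  start <- 1L
  cyc <- start
  cur <- start
  for (k in seq_along(from)) {
    cur <- get0(as.character(cur), envir = nxt)
    if (is.null(cur) || cur == start) break
    cyc <- c(cyc, cur)
  }
  cyc
}

mesh_area <- function(mesh) {
  s <- 0
  for (k in seq_len(nrow(mesh$triangles))) {
    cr <- crossp(mesh$e1[k, ], mesh$e2[k, ])
    s <- s + sqrt(sum(cr^2)) / 2
  }
  s
}

#' Segment-triangle intersection (Moller-Trumbore)
#'
#' @param p0,p1 Segment endpoints (length-3 numeric).
#' @param tri 3x3 matrix of triangle vertices (rows).
#' @param eps_det Determinant tolerance (parallel rejection).
#' @param eps_bary Barycentric-gate tolerance.
#' @return The intersection point as a length-3 vector, or `NULL`.
#' @export
segment_triangle_intersection <- function(p0, p1, tri, eps_det = 1e-9,
                                          eps_bary = 1e-7) {
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  d <- p1 - p0
  pv <- crossp(d, e2)
  det <- sum(e1 * pv)
  if (abs(det) < eps_det) return(NULL)
  tv <- p0 - tri[1, ]
  u <- sum(tv * pv) / det
  if (u < -eps_bary) return(NULL)
  qv <- crossp(tv, e1)
  v <- sum(d * qv) / det
  if (v < -eps_bary || u + v > 1 + eps_bary) return(NULL)
  t <- sum(e2 * qv) / det
  if (t < 0 || t > 1) return(NULL)
  p0 + t * d
}

# vectorized Moller-Trumbore of one segment against all mesh triangles;
# returns a matrix of hits: columns t, x, y, z, triangle
segment_mesh_hits <- function(mesh, p0, p1, eps_det = 1e-9, eps_bary = 1e-7) {
  d <- p1 - p0
  e1 <- mesh$e1
  e2 <- mesh$e2
  v0 <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
              d[3] * e2[, 1] - d[1] * e2[, 3],
              d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) >= eps_det
  if (!any(ok)) return(NULL)
  tv <- sweep(-v0, 2, p0, "+")
  u <- rowSums(tv * pv) / det
  ok <- ok & u >= -eps_bary
  if (!any(ok)) return(NULL)
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  v <- (qv %*% d)[, 1] / det
  ok <- ok & v >= -eps_bary & (u + v) <= 1 + eps_bary
  tt <- rowSums(e2 * qv) / det
  ok <- ok & tt >= 0 & tt <= 1
  hits <- which(ok)
  if (!length(hits)) return(NULL)
  pts <- matrix(p0, nrow = length(hits), ncol = 3, byrow = TRUE) +
    tt[hits] %o% d
  cbind(t = tt[hits], x = pts[, 1], y = pts[, 2], z = pts[, 3],
        triangle = hits)
}

#' Count punctures of a mesh by a polygonal chain
#'
#' Every chain segment is tested against every mesh triangle with the
#' Moller-Trumbore algorithm. Segments with an endpoint belonging to a
#' residue of the mesh's own element (including closing-pair residues) are
#' excluded (shared backbone cannot entangle with itself). Hits from
#' adjacent triangles within the merge radius collapse to one puncture,
#' and crossings whose segment has an endpoint within the overlap radius
#' of a mesh vertex are discarded as overlapping-atom artifacts.
#'
#' @param mesh An `rna_mesh`.
#' @param chain A `polygonal_chain` (open or closed).
#' @param exclude_gi Residues owned by the mesh's element.
#' @param params See [geometry_params()].
#' @return A data.frame of punctures: point coordinates, bracketing chain
#'   segment (residue indices and atom names), and triangle index.
#' @export
count_punctures <- function(mesh, chain, exclude_gi = integer(0),
                            params = geometry_params()) {
  pts <- chain$points
  src <- chain$sources
  nseg <- nrow(pts) - 1L
  segs <- cbind(seq_len(nseg), seq_len(nseg) + 1L)
  if (chain$closed && nrow(pts) >= 3) {
    segs <- rbind(segs, c(nrow(pts), 1L))
  }
  hits <- list()
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1]; b <- segs[s, 2]
    if (src$gi[a] %in% exclude_gi || src$gi[b] %in% exclude_gi) next
    h <- segment_mesh_hits(mesh, pts[a, ], pts[b, ],
                           eps_det = params$eps_det,
                           eps_bary = params$eps_bary)
    if (is.null(h)) next
    # overlapping-atom guard: segment endpoint too close to a mesh vertex
    dmin <- min(sqrt(rowSums(sweep(mesh$vertices, 2, pts[a, ])^2)),
                sqrt(rowSums(sweep(mesh$vertices, 2, pts[b, ])^2)))
    if (dmin < params$overlap_radius) next
    for (r in seq_len(nrow(h))) {
      hits[[length(hits) + 1]] <- data.frame(
        x = h[r, "x"], y = h[r, "y"], z = h[r, "z"],
        seg_gi1 = src$gi[a], seg_atom1 = src$atom[a],
        seg_gi2 = src$gi[b], seg_atom2 = src$atom[b],
        triangle = as.integer(h[r, "triangle"]),
        mesh_element = mesh$element_id, chain_element = chain$element_id,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      seg_gi1 = integer(), seg_atom1 = character(),
                      seg_gi2 = integer(), seg_atom2 = character(),
                      triangle = integer(), mesh_element = character(),
                      chain_element = character(), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  # merge duplicate hits (shared edges of adjacent triangles)
  keep <- rep(TRUE, nrow(h))
  for (r in seq_len(nrow(h))) {
    if (!keep[r]) next
    if (r < nrow(h)) {
      for (s in seq(r + 1, nrow(h))) {
        if (!keep[s]) next
        d2 <- (h$x[r] - h$x[s])^2 + (h$y[r] - h$y[s])^2 + (h$z[r] - h$z[s])^2
        if (d2 <= params$merge_radius^2) keep[s] <- FALSE
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Write puncture sites as a PDB-style pseudoatom bead file
#'
#' One HETATM bead per puncture, loadable in any molecular viewer.
#'
#' @param punctures A puncture data.frame (see [count_punctures()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_puncture_beads <- function(punctures, path) {
  lines <- character(0)
  for (k in seq_len(nrow(punctures))) {
    lines <- c(lines, sprintf(
      "HETATM%5d  O   PNC X%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
      k, k, punctures$x[k], punctures$y[k], punctures$z[k]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
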
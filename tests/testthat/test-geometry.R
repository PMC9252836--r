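make_chain <- function(points, closed = FALSE, gi = NULL, atoms = NULL) {
  n <- nrow(points)
  structure(list(element_id = "test", points = points,
                 sources = data.frame(gi = gi %||% seq_len(n),
                                      atom = atoms %||% rep("C4'", n)),
                 closed = closed),
            class = "polygonal_chain")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("polygonal chains follow backbone order and bridge closing pairs", {
  fx <- rna_fixture("lassoed_hairpin", loop_size = 6)
  m <- clean_rna_structure(fx$model)
  ss <- secondary_structure(m)
  es <- build_elements(ss, 0L)
  strand <- es$open[[1]]
  ch <- build_polygonal_chain(strand, m)
  expect_false(ch$closed)
  # per residue: P then C4', 5'->3'
  expect_equal(ch$sources$atom[1:4], c("P", "C4'", "P", "C4'"))
  expect_equal(ch$sources$gi[1:4], rep(strand$residues[1:2], each = 2))

  loop <- Filter(function(e) e$kind == "L", es$closed)[[1]]
  lch <- build_polygonal_chain(loop, m)
  expect_true(lch$closed)
  expect_equal(tail(lch$sources$atom, 2), c("base-COM", "base-COM"))
  # the two pseudoatoms bridge the closing pair, 3' partner first
  expect_equal(tail(lch$sources$gi, 2),
               c(loop$closing[1, 2], loop$closing[1, 1]))
})

test_that("base centers of mass are centroids of the ring atoms", {
  fx <- rna_fixture("clean_hairpin", loop_size = 6)
  m <- clean_rna_structure(fx$model)
  gi <- 1L
  ring <- rnatangle:::base_ring_coords(m, gi)
  expect_equal(base_center_of_mass(m, gi), colMeans(ring))
  w <- base_center_of_mass(m, gi, weighted = TRUE)
  expect_false(isTRUE(all.equal(w, colMeans(ring))))  # N vs C masses differ
  expect_lt(sqrt(sum((w - colMeans(ring))^2)), 0.5)
})

test_that("a missing chain atom in a non-terminal residue is an error", {
  fx <- rna_fixture("clean_hairpin", loop_size = 6)
  m <- clean_rna_structure(fx$model)
  ss <- secondary_structure(m)
  es <- build_elements(ss, 0L)
  loop <- Filter(function(e) e$kind == "L", es$closed)[[1]]
  m$atoms <- m$atoms[!(m$atoms$ri == 6 & m$atoms$atom == "P"), ]
  expect_error(build_polygonal_chain(loop, m), "missing atom P")
})

test_that("triangulation refines to the target edge length and keeps area", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  ch <- make_chain(sq, closed = TRUE)
  mesh <- triangulate_chain(ch, geometry_params(edge_target = 2))
  expect_equal(nrow(mesh$triangles), 4)  # pure centroid fan

  mesh2 <- triangulate_chain(ch, geometry_params(edge_target = 0.6))
  lens <- apply(mesh2$triangles, 1, function(tr) {
    v <- mesh2$vertices[tr, ]
    max(sqrt(sum((v[1, ] - v[2, ])^2)), sqrt(sum((v[2, ] - v[3, ])^2)),
        sqrt(sum((v[3, ] - v[1, ])^2)))
  })
  expect_lte(max(lens), 0.6)

  # area equals the shoelace value for random planar convex polygons
  set.seed(5)
  for (rep in 1:5) {
    pts <- matrix(stats::runif(24, -5, 5), ncol = 2)
    hull <- grDevices::chull(pts)
    poly <- cbind(pts[hull, , drop = FALSE], 0)
    shoelace <- abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                          poly[, 2] * c(poly[-1, 1], poly[1, 1]))) / 2
    msh <- triangulate_chain(make_chain(poly, closed = TRUE),
                             geometry_params(edge_target = 1))
    expect_equal(rnatangle:::mesh_area(msh), shoelace, tolerance = 1e-6)
  }
})

test_that("collinear chains raise a degenerate-mesh error", {
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(triangulate_chain(make_chain(line, closed = TRUE)),
               class = "rnatangle_degenerate")
})

test_that("the mesh boundary reproduces the refined chain", {
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  mesh <- triangulate_chain(make_chain(sq, closed = TRUE),
                            geometry_params(edge_target = 1.2))
  b <- mesh$boundary
  # original vertices appear in order within the refined cycle
  expect_equal(b[b <= 4], 1:4)
  pts <- mesh$vertices[b, ]
  nxt <- rbind(pts[-1, ], pts[1, ])
  expect_lte(max(sqrt(rowSums((nxt - pts)^2))), 1.2 + 1e-9)
})

test_that("Moller-Trumbore handles the textbook cases", {
  tri <- rbind(c(-1, -1, 0), c(3, -1, 0), c(-1, 3, 0))
  hit <- segment_triangle_intersection(c(0, 0, -1), c(0, 0, 1), tri)
  expect_equal(hit, c(0, 0, 0))
  expect_null(segment_triangle_intersection(c(0, 0, 1), c(0, 0, 3), tri))
  expect_null(segment_triangle_intersection(c(5, 5, -1), c(5, 5, 1), tri))
  # parallel segment
  expect_null(segment_triangle_intersection(c(0, 0, 1), c(1, 0, 1), tri))
})

test_that("Moller-Trumbore agrees with the brute-force oracle on random cases", {
  set.seed(123)
  n <- 10000
  disagreements <- 0
  for (k in seq_len(n)) {
    tri <- matrix(stats::runif(9, -2, 2), 3, 3, byrow = TRUE)
    p0 <- stats::runif(3, -3, 3)
    p1 <- stats::runif(3, -3, 3)
    a <- segment_triangle_intersection(p0, p1, tri)
    b <- brute_segment_triangle(p0, p1, tri)
    if (is.null(a) != is.null(b)) {
      disagreements <- disagreements + 1
    } else if (!is.null(a) && sqrt(sum((a - b)^2)) > 1e-6) {
      disagreements <- disagreements + 1
    }
  }
  expect_equal(disagreements, 0)
})

test_that("puncture counting matches fixture construction and excludes self", {
  fx <- rna_fixture("lassoed_hairpin", loop_size = 8)
  m <- clean_rna_structure(fx$model)
  ss <- secondary_structure(m)
  es <- build_elements(ss, 0L)
  loop <- Filter(function(e) e$kind == "L", es$closed)[[1]]
  strand <- es$open[[1]]
  lch <- build_polygonal_chain(loop, m)
  mesh <- triangulate_chain(lch)
  exclude <- unique(c(loop$residues, as.vector(loop$closing)))
  hits <- count_punctures(mesh, build_polygonal_chain(strand, m),
                          exclude_gi = exclude)
  expect_equal(nrow(hits), 1)
  # the mesh's own boundary chain yields no punctures
  self_hits <- count_punctures(mesh, lch, exclude_gi = exclude)
  expect_equal(nrow(self_hits), 0)

  fx3 <- rna_fixture("multi_weave", loop_size = 8)
  sc3 <- entanglement_scan(fx3$model)
  expect_equal(sc3$table$n_punctures, 3)
})
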
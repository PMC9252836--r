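# Independent oracles used across the suite.

# brute-force maximum non-crossing subset size by exhaustive enumeration
brute_max_noncrossing <- function(pairs) {
  np <- nrow(pairs)
  if (np == 0) return(0L)
  best <- 0L
  for (mask in 0:(2^np - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1) {
      for (u in seq_len(length(sel) - 1)) {
        for (v in seq(u + 1, length(sel))) {
          i1 <- pairs$i[sel[u]]; j1 <- pairs$j[sel[u]]
          i2 <- pairs$i[sel[v]]; j2 <- pairs$j[sel[v]]
          if ((i1 < i2 && i2 < j1 && j1 < j2) ||
              (i2 < i1 && i1 < j2 && j2 < j1)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- length(sel)
  }
  best
}

# random set of disjoint (one partner per residue) pairs on n positions
random_pair_set <- function(n, npairs) {
  pos <- sample(n, 2 * npairs)
  i <- pmin(pos[seq_len(npairs)], pos[npairs + seq_len(npairs)])
  j <- pmax(pos[seq_len(npairs)], pos[npairs + seq_len(npairs)])
  ord <- order(i)
  data.frame(i = i[ord], j = j[ord], class = "WC-GC", score = 2.9,
             order = NA_integer_, isolated = FALSE)
}

# brute-force segment/triangle verdict: plane intersection followed by
# barycentric coordinates from a least-squares solve (independent of the
# Moller-Trumbore formulation)
brute_segment_triangle <- function(p0, p1, tri, eps_det = 1e-9,
                                   eps_bary = 1e-7) {
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  d <- p1 - p0
  denom <- sum(nrm * d)
  # scale-match the Moller-Trumbore determinant gate: det = n . d
  if (abs(denom) < eps_det) return(NULL)
  t <- sum(nrm * (tri[1, ] - p0)) / denom
  if (t < 0 || t > 1) return(NULL)
  pt <- p0 + t * d
  # barycentric via normal equations
  A <- cbind(e1, e2)
  rhs <- pt - tri[1, ]
  uv <- solve(crossprod(A), crossprod(A, rhs))
  u <- uv[1]; v <- uv[2]
  if (u < -eps_bary || v < -eps_bary || u + v > 1 + eps_bary) return(NULL)
  pt
}

# helix bookkeeping: number of dinucleotide steps expected from a pair set
# (sum over helices of length - 1), computed by run-length grouping
expected_d_steps <- function(pairs) {
  if (!nrow(pairs)) return(0L)
  key <- paste(pairs$i, pairs$j)
  sum(paste(pairs$i + 1, pairs$j - 1) %in% key)
}

# random nested (non-crossing) pair set: recursive interval splitting
random_nested_pairs <- function(n, p_pair = 0.4) {
  pairs <- list()
  rec <- function(l, r) {
    while (l < r) {
      if (stats::runif(1) < p_pair && r - l >= 3) {
        cand <- seq(l + 3, min(r, l + 15))
        j <- cand[sample.int(length(cand), 1)]
        pairs[[length(pairs) + 1]] <<- c(l, j)
        rec(l + 1, j - 1)
        l <- j + 1
      } else l <- l + 1
    }
  }
  rec(1, n)
  if (!length(pairs)) {
    return(data.frame(i = integer(), j = integer(), class = character(),
                      score = numeric(), order = integer(),
                      isolated = logical()))
  }
  m <- do.call(rbind, pairs)
  ord <- order(m[, 1])
  data.frame(i = m[ord, 1], j = m[ord, 2], class = "WC-GC", score = 2.9,
             order = NA_integer_, isolated = FALSE)
}

scan_matches_truth <- function(fx, ...) {
  sc <- entanglement_scan(fx$model, ...)
  tr <- fx$truth$entanglements
  nrow(sc$table) == nrow(tr) &&
    (nrow(tr) == 0 ||
       (all(sc$table$level == tr$level) &&
          all(sc$table$topology == tr$topology) &&
          all(sc$table$class == tr$class) &&
          all(sc$table$n_punctures == tr$n_punctures)))
}
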
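# Secondary structure from 3D coordinates: geometric detection of canonical
# base pairs (A-U, G-C, G-U), pseudoknot order assignment by iterative
# extraction of maximum non-crossing pair subsets, and extended dot-bracket
# input/output with one bracket alphabet per order.

#' Geometric gates for canonical base-pair detection
#'
#' @param c1_range C1'-C1' distance window in Angstrom.
#' @param hbond_max Maximum donor/acceptor ring-atom distance in Angstrom.
#' @param hbond_tol Additional tolerance per hydrogen bond, Angstrom.
#' @param plane_angle_max Maximum angle between base-plane normals, degrees.
#' @return A list of pairing parameters.
#' @export
pairing_params <- function(c1_range = c(8.5, 12.0), hbond_max = 3.5,
                           hbond_tol = 1.0, plane_angle_max = 65) {
  list(c1_range = c1_range, hbond_max = hbond_max, hbond_tol = hbond_tol,
       plane_angle_max = plane_angle_max)
}

base_ring_coords <- function(model, gi) {
  res <- model$residues[gi, ]
  parent <- res$parent
  ring <- if (!is.na(parent)) .base_ring_atoms[[parent]] else
    unique(unlist(.base_ring_atoms))
  a <- residue_atoms(model, gi)
  a <- a[a$atom %in% ring, , drop = FALSE]
  if (!nrow(a)) return(NULL)
  as.matrix(a[, c("x", "y", "z")])
}

base_plane_normal <- function(coords) {
  if (is.null(coords) || nrow(coords) < 3) return(NULL)
  cc <- sweep(coords, 2, colMeans(coords))
  sv <- svd(cc)
  sv$v[, 3]
}

#' Center of mass of a nucleobase
#'
#' Unweighted centroid of the base ring heavy atoms by default; set
#' `weighted = TRUE` for a mass-weighted center.
#'
#' @param model An `rna_structure`.
#' @param gi Global residue index.
#' @param weighted Use atomic masses as weights.
#' @return A length-3 numeric vector, or `NULL` when no ring atoms exist.
#' @export
base_center_of_mass <- function(model, gi, weighted = FALSE) {
  res <- model$residues[gi, ]
  parent <- res$parent
  ring <- if (!is.na(parent)) .base_ring_atoms[[parent]] else
    unique(unlist(.base_ring_atoms))
  a <- residue_atoms(model, gi)
  a <- a[a$atom %in% ring, , drop = FALSE]
  if (!nrow(a)) return(NULL)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!weighted) return(colMeans(xyz))
  w <- .atomic_mass[a$elem]
  w[is.na(w)] <- 12
  colSums(xyz * w) / sum(w)
}

pair_hbond_distance <- function(model, gi_pu, gi_py, class) {
  d <- function(a1, a2) {
    p1 <- atom_xyz(model, gi_pu, a1); p2 <- atom_xyz(model, gi_py, a2)
    if (is.null(p1) || is.null(p2)) return(Inf)
    sqrt(sum((p1 - p2)^2))
  }
  if (class == "wobble-GU") min(d("N1", "O2"), d("O6", "N3")) else d("N1", "N3")
}

#' Detect canonical base pairs from 3D coordinates
#'
#' Candidate residue pairs of complementary parent types (A-U, G-C, G-U)
#' pass three gates: C1'-C1' distance inside a window, hydrogen-bond
#' donor/acceptor ring-atom distance below a cutoff, and near-parallel base
#' planes. When a residue satisfies the gates with several partners, the
#' pair with the smallest hydrogen-bond distance wins (deterministic).
#' Pairs are reported with the 5' partner first under the global ordering
#' (chain order, then sequence); inter-chain pairs are allowed.
#'
#' @param model A cleaned `rna_structure`.
#' @param params See [pairing_params()].
#' @return A data.frame with columns `i`, `j` (global residue indices),
#'   `class`, `score` (hydrogen-bond distance, Angstrom), `order` (`NA`,
#'   set by [assign_pseudoknot_orders()]), and `isolated`.
#' @export
detect_canonical_pairs <- function(model, params = pairing_params()) {
  res <- model$residues
  n <- nrow(res)
  empty <- data.frame(i = integer(), j = integer(), class = character(),
                      score = numeric(), order = integer(),
                      isolated = logical(), stringsAsFactors = FALSE)
  if (n < 2) return(empty)

  c1 <- matrix(NA_real_, n, 3)
  for (g in seq_len(n)) {
    p <- atom_xyz(model, g, "C1'")
    if (!is.null(p)) c1[g, ] <- p
  }
  normals <- lapply(seq_len(n), function(g) base_plane_normal(base_ring_coords(model, g)))
  parent <- res$parent

  cand <- list()
  for (i in seq_len(n - 1)) {
    if (is.na(parent[i]) || anyNA(c1[i, ])) next
    for (j in seq(i + 1, n)) {
      if (is.na(parent[j]) || anyNA(c1[j, ])) next
      combo <- paste(sort(c(parent[i], parent[j])), collapse = "")
      class <- switch(combo, "AU" = "WC-AU", "CG" = "WC-GC",
                      "GU" = "wobble-GU", NULL)
      if (is.null(class)) next
      d <- sqrt(sum((c1[i, ] - c1[j, ])^2))
      if (d < params$c1_range[1] || d > params$c1_range[2]) next
      pu <- if (parent[i] %in% .purines) i else j
      py <- if (pu == i) j else i
      hb <- pair_hbond_distance(model, pu, py, class)
      if (hb > params$hbond_max + params$hbond_tol) next
      ni <- normals[[i]]; nj <- normals[[j]]
      if (is.null(ni) || is.null(nj)) next
      ang <- acos(pmin(1, abs(sum(ni * nj)))) * 180 / pi
      if (ang > params$plane_angle_max) next
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, j = j, class = class, score = hb, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$score, cand$i, cand$j), , drop = FALSE]
  used <- rep(FALSE, n)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used[cand$i[k]] && !used[cand$j[k]]) {
      keep[k] <- TRUE
      used[cand$i[k]] <- TRUE
      used[cand$j[k]] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  pairs$order <- NA_integer_
  pairs$isolated <- flag_isolated(pairs)
  rownames(pairs) <- NULL
  pairs
}

# a pair is isolated when it has no stacked neighbour (i+1,j-1) or (i-1,j+1)
flag_isolated <- function(pairs) {
  if (!nrow(pairs)) return(logical(0))
  key <- paste(pairs$i, pairs$j)
  !(paste(pairs$i + 1, pairs$j - 1) %in% key |
      paste(pairs$i - 1, pairs$j + 1) %in% key)
}

crossing <- function(i1, j1, i2, j2) {
  (i1 < i2 & i2 < j1 & j1 < j2) | (i2 < i1 & i1 < j2 & j2 < j1)
}

# maximum-cardinality non-crossing subset of pairs, deterministic tie-break:
# prefer including the pair with the smaller i, then the smaller j.
max_noncrossing_subset <- function(pairs) {
  np <- nrow(pairs)
  if (np <= 1) return(seq_len(np))
  pos <- sort(unique(c(pairs$i, pairs$j)))
  m <- length(pos)
  pi_ <- match(pairs$i, pos)
  pj <- match(pairs$j, pos)
  by_open <- split(seq_len(np), factor(pi_, levels = seq_len(m)))
  memo <- matrix(NA_integer_, m + 2, m + 2)
  best <- function(l, r) {
    if (l > r) return(0L)
    if (!is.na(memo[l, r + 1L])) return(memo[l, r + 1L])
    v <- best(l + 1L, r)
    for (k in by_open[[l]]) {
      q <- pj[k]
      if (q <= r) v <- max(v, 1L + best(l + 1L, q - 1L) + best(q + 1L, r))
    }
    memo[l, r + 1L] <<- v
    v
  }
  total <- best(1L, m)
  sel <- integer(0)
  rec <- function(l, r) {
    while (l <= r) {
      target <- best(l, r)
      if (target == 0L) return(invisible())
      taken <- FALSE
      ks <- by_open[[l]]
      if (length(ks)) {
        ks <- ks[order(pj[ks])]
        for (k in ks) {
          q <- pj[k]
          if (q <= r && 1L + best(l + 1L, q - 1L) + best(q + 1L, r) == target) {
            sel <<- c(sel, k)
            rec(l + 1L, q - 1L)
            l <- q + 1L
            taken <- TRUE
            break
          }
        }
      }
      if (!taken) l <- l + 1L
    }
    invisible()
  }
  rec(1L, m)
  sort(sel)
}

#' Assign pseudoknot orders to a set of base pairs
#'
#' Order 0 (the core) is a maximum-cardinality non-crossing subset of the
#' pairs; each order k >= 1 is a maximum non-crossing subset of the pairs
#' left after removing lower orders. Ties are broken deterministically by
#' preferring the pair with the smaller 5' index, then the smaller 3'
#' index. Within every order the pairs are mutually non-crossing.
#'
#' @param pairs A pair data.frame as returned by
#'   [detect_canonical_pairs()]. If the `order` column is already set, the
#'   assignment is validated instead (crossing pairs within one claimed
#'   order raise an error).
#' @return The pair data.frame with `order` filled in.
#' @export
assign_pseudoknot_orders <- function(pairs) {
  if (!nrow(pairs)) {
    pairs$order <- integer(0)
    return(pairs)
  }
  if (anyDuplicated(c(pairs$i, pairs$j))) {
    stop("invalid pair list: a residue participates in more than one pair")
  }
  if (!all(is.na(pairs$order))) {
    for (k in unique(pairs$order)) {
      p <- pairs[pairs$order == k, , drop = FALSE]
      if (nrow(p) > 1) {
        for (u in seq_len(nrow(p) - 1)) for (v in seq(u + 1, nrow(p))) {
          if (crossing(p$i[u], p$j[u], p$i[v], p$j[v])) {
            stop(sprintf("validation error: pairs (%d,%d) and (%d,%d) cross within order %d",
                         p$i[u], p$j[u], p$i[v], p$j[v], k))
          }
        }
      }
    }
    return(pairs)
  }
  remaining <- seq_len(nrow(pairs))
  ord <- integer(nrow(pairs))
  level <- 0L
  while (length(remaining)) {
    sel <- max_noncrossing_subset(pairs[remaining, , drop = FALSE])
    ord[remaining[sel]] <- level
    remaining <- remaining[-sel]
    level <- level + 1L
  }
  pairs$order <- ord
  pairs
}

#' Derive the secondary structure of a cleaned model
#'
#' Runs [detect_canonical_pairs()] and [assign_pseudoknot_orders()], and
#' packages the result with the residue table.
#'
#' @param model A cleaned `rna_structure`.
#' @param params See [pairing_params()].
#' @param ignore_isolated Drop isolated pairs (no stacked neighbour) before
#'   order assignment.
#' @return An `rna_secondary` object: list(residues, pairs, max_order).
#' @export
secondary_structure <- function(model, params = pairing_params(),
                                ignore_isolated = FALSE) {
  pairs <- detect_canonical_pairs(model, params)
  if (ignore_isolated && nrow(pairs)) {
    pairs <- pairs[!pairs$isolated, , drop = FALSE]
  }
  pairs <- assign_pseudoknot_orders(pairs)
  new_rna_secondary(model$residues, pairs)
}

new_rna_secondary <- function(residues, pairs) {
  structure(list(residues = residues, pairs = pairs,
                 max_order = if (nrow(pairs)) max(pairs$order) else 0L),
            class = "rna_secondary")
}

bracket_alphabet <- function(order) {
  if (order < 0) stop("negative pseudoknot order")
  base <- c("()", "[]", "{}", "<>")
  if (order < length(base)) {
    strsplit(base[order + 1], "")[[1]]
  } else {
    k <- order - length(base) + 1L
    if (k > 26) stop("no bracket alphabet for pseudoknot order ", order)
    c(LETTERS[k], letters[k])
  }
}

#' Render a secondary structure as extended dot-bracket text
#'
#' One bracket alphabet per pseudoknot order: `()` for order 0, `[]` for
#' 1, `{}` for 2, `<>` for 3, then letter pairs `Aa`, `Bb`, ... Unpaired
#' residues are dots. Each chain is rendered as three lines: a `>`-header
#' with the chain identifier, the sequence, and the structure line.
#'
#' @param ss An `rna_secondary`.
#' @return A single character string (lines joined by newline).
#' @export
to_extended_dotbracket <- function(ss) {
  res <- ss$residues
  n <- nrow(res)
  chars <- rep(".", n)
  p <- ss$pairs
  for (k in seq_len(nrow(p))) {
    br <- bracket_alphabet(p$order[k])
    chars[p$i[k]] <- br[1]
    chars[p$j[k]] <- br[2]
  }
  seq_letters <- ifelse(is.na(res$parent), "N",
                        ifelse(res$modified, tolower(res$parent), res$parent))
  out <- character(0)
  for (ch in unique(res$chain)) {
    ix <- which(res$chain == ch)
    out <- c(out, paste0(">", ch),
             paste(seq_letters[ix], collapse = ""),
             paste(chars[ix], collapse = ""))
  }
  paste(out, collapse = "\n")
}

#' Parse extended dot-bracket text
#'
#' Accepts either the chain-per-block format written by
#' [to_extended_dotbracket()] (`>chain` / sequence / structure lines) or a
#' bare structure line (single unnamed chain, sequence filled with N).
#'
#' @param text Character scalar or vector of lines.
#' @return An `rna_secondary` (residue coordinates absent).
#' @export
parse_extended_dotbracket <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  blocks <- list()
  if (any(startsWith(lines, ">"))) {
    i <- 1
    while (i <= length(lines)) {
      if (!startsWith(lines[i], ">")) stop("malformed dot-bracket block near line ", i)
      if (i + 2 > length(lines)) stop("truncated dot-bracket block for ", lines[i])
      blocks[[length(blocks) + 1]] <- list(chain = sub("^>\\s*", "", lines[i]),
                                           seq = trimws(lines[i + 1]),
                                           db = trimws(lines[i + 2]))
      i <- i + 3
    }
  } else if (length(lines) == 2) {
    blocks[[1]] <- list(chain = "A", seq = trimws(lines[1]), db = trimws(lines[2]))
  } else if (length(lines) == 1) {
    db <- trimws(lines[1])
    blocks[[1]] <- list(chain = "A", seq = strrep("N", nchar(db)), db = db)
  } else {
    stop("cannot interpret dot-bracket input")
  }

  res_list <- list()
  pair_list <- list()
  offset <- 0L
  for (b in blocks) {
    if (nchar(b$seq) != nchar(b$db)) {
      stop("sequence and structure lines differ in length for chain ", b$chain)
    }
    db <- strsplit(b$db, "")[[1]]
    stacks <- list()
    for (pos in seq_along(db)) {
      ch <- db[pos]
      if (ch == "." || ch == "-") next
      ord <- NA_integer_
      opening <- NA
      for (o in 0:29) {
        br <- bracket_alphabet(o)
        if (ch == br[1]) { ord <- o; opening <- TRUE; break }
        if (ch == br[2]) { ord <- o; opening <- FALSE; break }
      }
      if (is.na(ord)) stop("unknown character '", ch, "' at position ",
                           pos, " of chain ", b$chain)
      key <- as.character(ord)
      if (opening) {
        stacks[[key]] <- c(stacks[[key]], offset + pos)
      } else {
        st <- stacks[[key]]
        if (!length(st)) stop("unbalanced bracket '", ch, "' at position ",
                              pos, " of chain ", b$chain)
        pair_list[[length(pair_list) + 1]] <- data.frame(
          i = st[length(st)], j = offset + pos, class = NA_character_,
          score = NA_real_, order = ord, stringsAsFactors = FALSE)
        stacks[[key]] <- st[-length(st)]
      }
    }
    open_left <- sum(lengths(stacks))
    if (open_left) stop("unbalanced brackets: ", open_left,
                        " unmatched opening bracket(s) in chain ", b$chain)
    sq <- strsplit(toupper(b$seq), "")[[1]]
    res_list[[length(res_list) + 1]] <- data.frame(
      chain = b$chain, resno = seq_along(sq), ins = "",
      resname = sq, parent = ifelse(sq %in% .standard_rna, sq, NA),
      modified = FALSE, seq_index = seq_along(sq) - 1L,
      gi = offset + seq_along(sq), stringsAsFactors = FALSE)
    offset <- offset + length(sq)
  }
  res <- do.call(rbind, res_list)
  pairs <- if (length(pair_list)) do.call(rbind, pair_list) else
    data.frame(i = integer(), j = integer(), class = character(),
               score = numeric(), order = integer(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$isolated <- flag_isolated(pairs)
  new_rna_secondary(res, pairs)
}

#' @export
print.rna_secondary <- function(x, ...) {
  cat(sprintf("RNA secondary structure: %d residues, %d pairs, max order %d\n",
              nrow(x$residues), nrow(x$pairs), x$max_order))
  cat(to_extended_dotbracket(x), "\n")
  invisible(x)
}
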
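# Partition of the structure at a given level (core = 0, pseudoknot order
# k >= 1) into closed elements (loops L, dinucleotide steps D) and open
# elements (single strands S). At level k only pairs of order k count as
# paired; all other residues are treated as unpaired, so core residues can
# end up embedded inside higher-order loops and vice versa.
#
# A structural element is a list with
#   id       : stable string, e.g. "L-level0-33:49" (author numbering)
#   kind     : "L", "S", or "D"
#   level    : integer
#   residues : global residue indices tracing the element 5'->3'
#   closing  : matrix of closing pairs (columns i, j), empty for S
#   boundary : for closed elements, alternating run/bridge segments used to
#              build the polygonal chain

#' Levels (pseudoknot orders) to analyze
#'
#' @param ss An `rna_secondary` with orders assigned.
#' @param ignore_pseudoknots If `TRUE`, only the core level 0 is analyzed.
#' @param order_cap Optional maximum order to analyze.
#' @return Integer vector of levels.
#' @export
enumerate_levels <- function(ss, ignore_pseudoknots = FALSE, order_cap = NULL) {
  if (ignore_pseudoknots) return(0L)
  top <- ss$max_order
  if (!is.null(order_cap)) top <- min(top, as.integer(order_cap))
  0:max(0L, top)
}

#' Element-construction options
#'
#' @param max_loop_length Loops with more boundary residues than this are
#'   not treated as closed elements (default 40; bounds triangulation cost).
#' @param ignore_isolated Whether isolated pairs were dropped upstream
#'   (recorded in the element set for provenance).
#' @param pseudoknots `"accept"` or `"ignore"` (recorded for provenance).
#' @return A list of options for [build_elements()].
#' @export
element_options <- function(max_loop_length = 40L, ignore_isolated = FALSE,
                            pseudoknots = c("accept", "ignore")) {
  list(max_loop_length = as.integer(max_loop_length),
       ignore_isolated = isTRUE(ignore_isolated),
       pseudoknots = match.arg(pseudoknots))
}

element_range_label <- function(residues_df, gi_first, gi_last) {
  paste0(residues_df$chain[gi_first], residues_df$resno[gi_first],
         residues_df$ins[gi_first], ":", residues_df$chain[gi_last],
         residues_df$resno[gi_last], residues_df$ins[gi_last])
}

#' Build the structural elements of one level
#'
#' At level `k`, only base pairs of order `k` are considered paired. Loops
#' are cycles closed by order-`k` pairs (hairpin, internal, and multibranch
#' loops all report as L); every two adjacent stacked pairs form a
#' dinucleotide step D (a helix of n pairs yields n-1 steps); single
#' strands S are maximal unpaired runs not enclosed by any order-`k` pair
#' (dangling ends and exterior linkers), split at chain boundaries. Loops
#' whose boundary residue count exceeds `max_loop_length` are discarded
#' from the closed set; their interior unpaired runs are added to the open
#' set instead.
#'
#' @param ss An `rna_secondary` with orders assigned.
#' @param level The level to build (0 = core).
#' @param options See [element_options()].
#' @return A list with `level`, `closed` (L and D elements), `open` (S
#'   elements), and `options`.
#' @export
build_elements <- function(ss, level, options = element_options()) {
  if (level > ss$max_order) {
    stop(sprintf("level %d exceeds the maximum pseudoknot order %d",
                 level, ss$max_order))
  }
  res <- ss$residues
  n <- nrow(res)
  p <- ss$pairs[!is.na(ss$pairs$order) & ss$pairs$order == level, , drop = FALSE]
  p <- p[order(p$i), , drop = FALSE]
  partner <- rep(NA_integer_, n)
  partner[p$i] <- p$j
  partner[p$j] <- p$i

  closed <- list()
  open <- list()

  pair_key <- paste(p$i, p$j)

  # dinucleotide steps: strictly adjacent stacked pairs (i,j) and (i+1,j-1)
  for (k in seq_len(nrow(p))) {
    i <- p$i[k]; j <- p$j[k]
    if (paste(i + 1, j - 1) %in% pair_key) {
      closed[[length(closed) + 1]] <- list(
        id = sprintf("D-level%d-%s", level, element_range_label(res, i, j)),
        kind = "D", level = level,
        residues = c(i, i + 1L, j - 1L, j),
        closing = rbind(c(i, j), c(i + 1L, j - 1L)),
        boundary = list(list(type = "run", gi = c(i, i + 1L)),
                        list(type = "bridge", gi = c(i + 1L, j - 1L)),
                        list(type = "run", gi = c(j - 1L, j)),
                        list(type = "bridge", gi = c(j, i))))
    }
  }

  # loops: pairs whose accessible interior is not a pure helix stack
  big_loop_runs <- list()
  for (k in seq_len(nrow(p))) {
    i <- p$i[k]; j <- p$j[k]
    if (paste(i + 1, j - 1) %in% pair_key) next  # stacked: covered by a D step
    boundary <- list()
    closing <- rbind(c(i, j))
    run_start <- i
    pos <- i + 1L
    interior_runs <- list()
    ok <- TRUE
    while (pos < j) {
      q <- partner[pos]
      if (!is.na(q) && q > pos && q < j) {
        boundary[[length(boundary) + 1]] <- list(type = "run", gi = run_start:pos)
        boundary[[length(boundary) + 1]] <- list(type = "bridge", gi = c(pos, q))
        closing <- rbind(closing, c(pos, q))
        if (pos - run_start > 1) {
          interior_runs[[length(interior_runs) + 1]] <- (run_start + 1L):(pos - 1L)
        }
        run_start <- q
        pos <- q + 1L
      } else if (!is.na(q)) {
        # partner behind or outside (i,j): cannot happen in a non-crossing set
        ok <- FALSE
        break
      } else {
        pos <- pos + 1L
      }
    }
    if (!ok) next
    boundary[[length(boundary) + 1]] <- list(type = "run", gi = run_start:j)
    boundary[[length(boundary) + 1]] <- list(type = "bridge", gi = c(j, i))
    if (j - run_start > 1) {
      interior_runs[[length(interior_runs) + 1]] <- (run_start + 1L):(j - 1L)
    }
    residues <- unlist(lapply(boundary, function(b)
      if (b$type == "run") b$gi else NULL))
    residues <- unique(residues)
    if (length(residues) > options$max_loop_length) {
      big_loop_runs <- c(big_loop_runs, interior_runs)
      next
    }
    closed[[length(closed) + 1]] <- list(
      id = sprintf("L-level%d-%s", level, element_range_label(res, i, j)),
      kind = "L", level = level, residues = residues,
      closing = closing, boundary = boundary)
  }

  # single strands: maximal unpaired runs not enclosed by any level pair
  enclosed <- rep(FALSE, n)
  for (k in seq_len(nrow(p))) {
    if (p$j[k] - p$i[k] > 1) enclosed[(p$i[k] + 1L):(p$j[k] - 1L)] <- TRUE
  }
  free <- is.na(partner) & !enclosed
  runs <- split_runs(which(free), res$chain)
  # interior runs of oversized, discarded loops contribute open elements
  for (r in big_loop_runs) runs <- c(runs, split_runs(r, res$chain))
  for (r in runs) {
    if (!length(r)) next
    open[[length(open) + 1]] <- list(
      id = sprintf("S-level%d-%s", level, element_range_label(res, r[1], r[length(r)])),
      kind = "S", level = level, residues = r,
      closing = matrix(integer(0), ncol = 2),
      boundary = list(list(type = "run", gi = r)))
  }

  list(level = level, closed = closed, open = open, options = options)
}

# split an increasing index vector into maximal consecutive runs, breaking
# at chain boundaries
split_runs <- function(ix, chains) {
  if (!length(ix)) return(list())
  brk <- c(TRUE, diff(ix) != 1 | chains[ix[-1]] != chains[ix[-length(ix)]])
  split(ix, cumsum(brk))
}

#' Tabulate the elements of one or more levels
#'
#' @param element_sets A list of element sets from [build_elements()].
#' @param residues The residue table of the secondary structure (for author
#'   numbering).
#' @return A data.frame: element_id, kind, level, chain, residue range, and
#'   closing pairs in author numbering.
#' @export
element_table <- function(element_sets, residues) {
  rows <- list()
  for (es in element_sets) {
    for (el in c(es$closed, es$open)) {
      gi <- el$residues
      rows[[length(rows) + 1]] <- data.frame(
        element_id = el$id, kind = el$kind, level = el$level,
        chain = residues$chain[gi[1]],
        first_residue = paste0(residues$resname[gi[1]], residues$resno[gi[1]],
                               residues$ins[gi[1]]),
        last_residue = paste0(residues$resname[gi[length(gi)]],
                              residues$resno[gi[length(gi)]],
                              residues$ins[gi[length(gi)]]),
        n_residues = length(gi),
        closing_pairs = if (nrow(el$closing)) {
          paste(apply(el$closing, 1, function(pr)
            paste0(residues$resname[pr[1]], residues$resno[pr[1]], "-",
                   residues$resname[pr[2]], residues$resno[pr[2]])),
            collapse = ";")
        } else "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(element_id = character(), kind = character(),
                      level = integer(), chain = character(),
                      first_residue = character(), last_residue = character(),
                      n_residues = integer(), closing_pairs = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
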
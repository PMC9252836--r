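# Entanglement classification: pair up elements by their mutual punctures,
# assign topology (lasso / interlace) and a class code with multi-puncture
# dots, and deduplicate reports within a level.
#
# Lasso: one element only punctures, the other is only punctured; coded
# X(Y), with one dot per extra puncture, e.g. L(S..) for a strand crossing
# a loop three times. Interlace: both elements puncture each other; coded
# X&Y. Single strands have no spanned surface, so S is never punctured.

#' Build an entanglement class code
#'
#' @param kind_punctured Kind of the punctured element (`"L"` or `"D"`;
#'   for interlaces, the first element).
#' @param kind_puncturing Kind of the puncturing (second) element
#'   (`"L"`, `"S"`, or `"D"`).
#' @param topology `"lasso"` or `"interlace"`.
#' @param n_forward Punctures through the first element's surface.
#' @param n_backward Punctures through the second element's surface
#'   (interlaces only).
#' @return The class string, e.g. `"L(S..)"` or `"L&D"`. Extra punctures
#'   of an interlace appear as dots after the element they pass through:
#'   `"L.&L"` marks a second puncture of the first loop.
#' @export
class_code <- function(kind_punctured, kind_puncturing,
                       topology = c("lasso", "interlace"),
                       n_forward = 1L, n_backward = 0L) {
  topology <- match.arg(topology)
  stopifnot(kind_punctured %in% c("L", "D"),
            kind_puncturing %in% c("L", "S", "D"))
  if (topology == "lasso") {
    if (n_forward < 1) stop("a lasso requires at least one puncture")
    paste0(kind_punctured, "(", kind_puncturing,
           strrep(".", n_forward - 1L), ")")
  } else {
    if (n_forward < 1 || n_backward < 1) {
      stop("an interlace requires punctures in both directions")
    }
    if (kind_puncturing == "S") stop("a single strand cannot be interlaced")
    paste0(kind_punctured, strrep(".", n_forward - 1L), "&",
           kind_puncturing, strrep(".", n_backward - 1L))
  }
}

#' Parse an entanglement class code
#'
#' Inverse of [class_code()].
#'
#' @param code Class string such as `"L(S..)"` or `"L.&L"`.
#' @return list(kind_punctured, kind_puncturing, topology, n_forward,
#'   n_backward).
#' @export
parse_class_code <- function(code) {
  m <- regmatches(code, regexec("^([LD])\\(([LSD])(\\.*)\\)$", code))[[1]]
  if (length(m)) {
    return(list(kind_punctured = m[2], kind_puncturing = m[3],
                topology = "lasso", n_forward = nchar(m[4]) + 1L,
                n_backward = 0L))
  }
  m <- regmatches(code, regexec("^([LD])(\\.*)&([LD])(\\.*)$", code))[[1]]
  if (length(m)) {
    return(list(kind_punctured = m[2], kind_puncturing = m[4],
                topology = "interlace", n_forward = nchar(m[3]) + 1L,
                n_backward = nchar(m[5]) + 1L))
  }
  stop("unparsable class code: ", code)
}

# deterministic element ordering for interlaces: L before D, then by first
# residue
interlace_order <- function(el_a, el_b) {
  rank <- c(L = 1, D = 2)
  ka <- rank[el_a$kind]; kb <- rank[el_b$kind]
  if (ka < kb) return(TRUE)
  if (ka > kb) return(FALSE)
  el_a$residues[1] <= el_b$residues[1]
}

# detect entanglements at one level given built chains and meshes
detect_level_entanglements <- function(element_set, chains, meshes, params) {
  closed <- element_set$closed
  open <- element_set$open
  level <- element_set$level
  out <- list()

  n_punct <- function(mesh_el, chain_el) {
    mesh <- meshes[[mesh_el$id]]
    chain <- chains[[chain_el$id]]
    if (is.null(mesh) || is.null(chain)) return(NULL)
    exclude <- unique(c(mesh_el$residues, as.vector(mesh_el$closing)))
    count_punctures(mesh, chain, exclude_gi = exclude, params = params)
  }

  # closed vs open: lasso only
  for (a in closed) {
    for (b in open) {
      h <- n_punct(a, b)
      if (!is.null(h) && nrow(h)) {
        out[[length(out) + 1]] <- list(
          level = level, topology = "lasso", punctured = a, puncturing = b,
          n_forward = nrow(h), n_backward = 0L, punctures = h)
      }
    }
  }

  # closed vs closed: lasso or interlace, each unordered pair once
  if (length(closed) >= 2) {
    for (ai in seq_len(length(closed) - 1)) {
      for (bi in seq(ai + 1, length(closed))) {
        a <- closed[[ai]]; b <- closed[[bi]]
        hab <- n_punct(a, b)  # b's chain through a's mesh
        hba <- n_punct(b, a)
        nab <- if (is.null(hab)) 0L else nrow(hab)
        nba <- if (is.null(hba)) 0L else nrow(hba)
        if (nab > 0 && nba > 0) {
          first_a <- interlace_order(a, b)
          out[[length(out) + 1]] <- list(
            level = level, topology = "interlace",
            punctured = if (first_a) a else b,
            puncturing = if (first_a) b else a,
            n_forward = if (first_a) nab else nba,
            n_backward = if (first_a) nba else nab,
            punctures = rbind(hab, hba))
        } else if (nab > 0) {
          out[[length(out) + 1]] <- list(
            level = level, topology = "lasso", punctured = a, puncturing = b,
            n_forward = nab, n_backward = 0L, punctures = hab)
        } else if (nba > 0) {
          out[[length(out) + 1]] <- list(
            level = level, topology = "lasso", punctured = b, puncturing = a,
            n_forward = nba, n_backward = 0L, punctures = hba)
        }
      }
    }
  }

  dedupe_entanglements(out)
}

# merge rule: two entanglements sharing >= 1 closing pair of the punctured
# element and the same partner element collapse, keeping the one with more
# punctures (helix D steps overlap their flanking loops)
dedupe_entanglements <- function(ents) {
  if (length(ents) <= 1) return(ents)
  closing_keys <- lapply(ents, function(e)
    apply(e$punctured$closing, 1, paste, collapse = ":"))
  keep <- rep(TRUE, length(ents))
  for (r in seq_len(length(ents) - 1)) {
    if (!keep[r]) next
    for (s in seq(r + 1, length(ents))) {
      if (!keep[s]) next
      er <- ents[[r]]; es <- ents[[s]]
      if (er$puncturing$id != es$puncturing$id) next
      if (er$topology != es$topology) next
      if (!length(intersect(closing_keys[[r]], closing_keys[[s]]))) next
      # keep the report with more punctures; ties favour the loop (L)
      nr <- er$n_forward + er$n_backward
      ns <- es$n_forward + es$n_backward
      drop_s <- ns < nr || (ns == nr && es$punctured$kind == "D")
      if (drop_s) {
        keep[s] <- FALSE
        ents[[r]]$merged_from <- c(ents[[r]]$merged_from, es$punctured$id)
      } else {
        keep[r] <- FALSE
        ents[[s]]$merged_from <- c(ents[[s]]$merged_from, er$punctured$id)
        break
      }
    }
  }
  ents[keep]
}

entanglement_record <- function(e, id, residues) {
  rng <- function(el) {
    gi <- el$residues
    sprintf("%s %s%s-%s%s", el$kind,
            residues$resname[min(gi)], residues$resno[min(gi)],
            residues$resname[max(gi)], residues$resno[max(gi)])
  }
  data.frame(
    id = id, level = e$level, topology = e$topology,
    class = class_code(e$punctured$kind, e$puncturing$kind, e$topology,
                       e$n_forward, e$n_backward),
    punctured_id = e$punctured$id, puncturing_id = e$puncturing$id,
    punctured = rng(e$punctured), puncturing = rng(e$puncturing),
    n_punctures = e$n_forward + e$n_backward,
    stringsAsFactors = FALSE)
}

#' Summarize entanglements in the survey-table layout
#'
#' Counts per class, split into primary (level 0) and higher-order rows,
#' plus lasso / interlace / overall totals. Row sums always satisfy
#' lassos + interlaces = all.
#'
#' @param entanglements A data.frame with columns `level`, `topology`,
#'   `class` (e.g. `as.data.frame` of an `entanglement_scan`).
#' @return A data.frame with rows primary / higher_order / total.
#' @export
entanglement_summary <- function(entanglements) {
  base_class <- function(cl) {
    vapply(cl, function(x) {
      p <- parse_class_code(x)
      class_code(p$kind_punctured, p$kind_puncturing, p$topology, 1,
                 if (p$topology == "interlace") 1 else 0)
    }, character(1))
  }
  classes <- c("L(S)", "L(D)", "L(L)", "D(S)", "D(D)", "D(L)",
               "L&L", "D&L", "D&D", "L&D")
  rows <- c("primary", "higher_order", "total")
  tab <- matrix(0L, nrow = 3, ncol = length(classes) + 3,
                dimnames = list(rows, c("lassos", classes, "interlaces", "all")))
  if (nrow(entanglements)) {
    bc <- base_class(entanglements$class)
    bucket <- ifelse(entanglements$level == 0, "primary", "higher_order")
    for (k in seq_len(nrow(entanglements))) {
      for (rw in c(bucket[k], "total")) {
        if (bc[k] %in% classes) tab[rw, bc[k]] <- tab[rw, bc[k]] + 1L
        if (entanglements$topology[k] == "lasso") {
          tab[rw, "lassos"] <- tab[rw, "lassos"] + 1L
        } else {
          tab[rw, "interlaces"] <- tab[rw, "interlaces"] + 1L
        }
        tab[rw, "all"] <- tab[rw, "all"] + 1L
      }
    }
  }
  as.data.frame(tab)
}
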
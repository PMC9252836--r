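# Top-level driver: one call runs the whole pipeline on a single model and
# returns a classed result object with print/summary/plot methods.

#' Scan an RNA 3D structure for entanglements
#'
#' Runs the full pipeline on one structure model: cleaning (unless already
#' cleaned), canonical-pair detection, pseudoknot-order assignment,
#' level-wise element construction, polygonal chains and triangle meshes,
#' puncture detection, and entanglement classification. Primary
#' entanglements come from the core level 0 (pseudoknotted residues
#' treated as unpaired); each pseudoknot order k >= 1 is then analyzed
#' separately, with elements rebuilt from order-k pairs only, yielding
#' higher-order entanglements. Elements of different levels are never
#' tested against each other.
#'
#' @param x A file path (PDB or mmCIF) or an `rna_structure`.
#' @param ss Optional user-supplied secondary structure: an
#'   `rna_secondary` or extended dot-bracket text, overriding geometric
#'   pair detection. Must match the cleaned model's residue count.
#' @param pseudoknots `"accept"` (default) analyzes every pseudoknot
#'   order; `"ignore"` restricts the analysis to the core level.
#' @param ignore_isolated_pairs Drop base pairs with no stacked neighbour
#'   before element construction.
#' @param max_loop_length Loops with more boundary residues are not closed
#'   elements (their interior runs become single strands).
#' @param order_cap Optional highest pseudoknot order to analyze.
#' @param pairing See [pairing_params()].
#' @param geometry See [geometry_params()].
#' @param model_index Which model of a multi-model file to scan.
#' @return An `entanglement_scan` object.
#' @examples
#' fx <- rna_fixture("lassoed_hairpin", loop_size = 8)
#' sc <- entanglement_scan(fx$model)
#' summary(sc)
#' @export
entanglement_scan <- function(x, ss = NULL,
                              pseudoknots = c("accept", "ignore"),
                              ignore_isolated_pairs = FALSE,
                              max_loop_length = 40L,
                              order_cap = NULL,
                              pairing = pairing_params(),
                              geometry = geometry_params(),
                              model_index = 1L) {
  pseudoknots <- match.arg(pseudoknots)
  if (pseudoknots == "ignore" && !is.null(order_cap)) {
    stop("order_cap cannot be combined with pseudoknots = \"ignore\"")
  }
  if (is.character(x)) {
    models <- read_rna_structure(x)
    if (model_index > length(models)) {
      stop("model_index exceeds the number of models (", length(models), ")")
    }
    model <- models[[model_index]]
  } else {
    stopifnot(inherits(x, "rna_structure"))
    model <- x
  }
  if (!isTRUE(attr(model, "cleaned"))) model <- clean_rna_structure(model)

  if (is.null(ss)) {
    ss <- secondary_structure(model, params = pairing,
                              ignore_isolated = ignore_isolated_pairs)
  } else {
    if (is.character(ss)) ss <- parse_extended_dotbracket(ss)
    stopifnot(inherits(ss, "rna_secondary"))
    if (nrow(ss$residues) != nrow(model$residues)) {
      stop("supplied secondary structure has ", nrow(ss$residues),
           " residues but the cleaned model has ", nrow(model$residues))
    }
    ss <- new_rna_secondary(model$residues, ss$pairs)
  }

  opts <- element_options(max_loop_length = max_loop_length,
                          ignore_isolated = ignore_isolated_pairs,
                          pseudoknots = pseudoknots)
  levels <- enumerate_levels(ss, ignore_pseudoknots = pseudoknots == "ignore",
                             order_cap = order_cap)

  element_sets <- list()
  all_ents <- list()
  warnings <- character(0)
  for (lev in levels) {
    es <- build_elements(ss, lev, opts)
    chains <- list()
    meshes <- list()
    for (el in c(es$closed, es$open)) {
      ch <- build_polygonal_chain(el, model, params = geometry)
      if (is.null(ch)) next
      chains[[el$id]] <- ch
      if (el$kind %in% c("L", "D")) {
        mesh <- tryCatch(triangulate_chain(ch, params = geometry),
                         rnatangle_degenerate = function(e) {
                           warnings <<- c(warnings, conditionMessage(e))
                           NULL
                         })
        if (!is.null(mesh)) meshes[[el$id]] <- mesh
      }
    }
    ents <- detect_level_entanglements(es, chains, meshes, geometry)
    all_ents <- c(all_ents, ents)
    element_sets[[as.character(lev)]] <- es
  }

  tab <- if (length(all_ents)) {
    do.call(rbind, lapply(seq_along(all_ents), function(k)
      entanglement_record(all_ents[[k]], k, ss$residues)))
  } else {
    data.frame(id = integer(), level = integer(), topology = character(),
               class = character(), punctured_id = character(),
               puncturing_id = character(), punctured = character(),
               puncturing = character(), n_punctures = integer(),
               stringsAsFactors = FALSE)
  }

  structure(list(model = model, secondary = ss, levels = levels,
                 element_sets = element_sets, entanglements = all_ents,
                 table = tab,
                 options = c(opts, list(order_cap = order_cap)),
                 geometry = geometry, warnings = warnings),
            class = "entanglement_scan")
}

#' @export
print.entanglement_scan <- function(x, ...) {
  cat(sprintf("Entanglement scan of %s (model %d)\n",
              basename(x$model$source$path %||% "<memory>"), x$model$model_id))
  cat(sprintf("  %d residues, %d canonical pairs, max pseudoknot order %d\n",
              nrow(x$model$residues), nrow(x$secondary$pairs),
              x$secondary$max_order))
  cat(sprintf("  levels analyzed: %s\n", paste(x$levels, collapse = ", ")))
  if (!nrow(x$table)) {
    cat("  no entanglements detected\n")
  } else {
    cat(sprintf("  %d entanglement(s):\n", nrow(x$table)))
    for (k in seq_len(nrow(x$table))) {
      r <- x$table[k, ]
      cat(sprintf("    [%d] level %d %s %s: %s punctured by %s (%d puncture%s)\n",
                  r$id, r$level, r$topology, r$class, r$punctured,
                  r$puncturing, r$n_punctures,
                  if (r$n_punctures > 1) "s" else ""))
    }
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    ", w, "\n")
  }
  invisible(x)
}

#' @export
summary.entanglement_scan <- function(object, ...) {
  out <- list(table = object$table,
              by_class = entanglement_summary(object$table),
              n = nrow(object$table))
  class(out) <- "summary.entanglement_scan"
  out
}

#' @export
print.summary.entanglement_scan <- function(x, ...) {
  cat("Entanglement summary\n")
  print(x$by_class[, colSums(x$by_class != 0) > 0 | colnames(x$by_class) %in%
                     c("lassos", "interlaces", "all"), drop = FALSE])
  invisible(x)
}

#' @export
as.data.frame.entanglement_scan <- function(x, ...) x$table

#' Arc-diagram plot of a scanned structure
#'
#' Base-graphics arc diagram of the canonical pairs, one color per
#' pseudoknot order, with entangled elements marked along the sequence
#' axis.
#'
#' @param x An `entanglement_scan`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.entanglement_scan <- function(x, ...) {
  res <- x$secondary$residues
  p <- x$secondary$pairs
  n <- nrow(res)
  graphics::plot(NULL, xlim = c(1, max(2, n)), ylim = c(-1.5, max(2, n) / 3),
                 xlab = "residue (global index)", ylab = "",
                 yaxt = "n", bty = "n",
                 main = "canonical pairs by pseudoknot order", ...)
  graphics::segments(1, 0, n, 0, col = "grey40")
  if (nrow(p)) {
    cols <- grDevices::hcl.colors(max(3, x$secondary$max_order + 1), "Dark 3")
    for (k in seq_len(nrow(p))) {
      i <- p$i[k]; j <- p$j[k]
      r <- (j - i) / 2
      theta <- seq(0, pi, length.out = 32)
      graphics::lines((i + j) / 2 + r * cos(theta), r * sin(theta) / 3,
                      col = cols[p$order[k] + 1])
    }
    graphics::legend("topright", bty = "n", lty = 1, col = cols[seq_len(x$secondary$max_order + 1)],
                     legend = paste("order", 0:x$secondary$max_order))
  }
  if (nrow(x$table)) {
    for (k in seq_len(nrow(x$table))) {
      e <- x$entanglements[[k]]
      gi <- e$puncturing$residues
      graphics::segments(min(gi), -0.7 - 0.25 * (k - 1), max(gi),
                         -0.7 - 0.25 * (k - 1), col = "red3", lwd = 2)
      graphics::text(mean(range(gi)), -0.7 - 0.25 * (k - 1),
                     labels = x$table$class[k], pos = 1, col = "red3",
                     cex = 0.8)
    }
  }
  invisible(x)
}
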
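# Reading, validation, cleaning, and writing of RNA 3D structures.
#
# The in-memory representation (class "rna_structure") is a list with
#   model_id : integer model number
#   source   : list(path, format)
#   atoms    : data.frame(chain, resno, ins, resname, atom, elem, x, y, z,
#                         occ, ri) -- one row per atom, ri indexes residues
#   residues : data.frame(chain, resno, ins, resname, parent, modified,
#                         seq_index, gi) -- gi is the 1-based global index
#                         (chain order, then 5'->3'), seq_index is 0-based
#                         within each chain
#   cleaning_report : data.frame(action, chain, residue, reason)
# Author numbering (resno + insertion code) is preserved and used in all
# reports; seq_index/gi are internal.

#' Read an RNA 3D structure from a PDB or PDBx/mmCIF file
#'
#' Parses a (possibly multi-model) structure file and returns one
#' `rna_structure` per model. Hydrogen atoms are dropped on read; alternate
#' locations are reduced to the highest-occupancy conformer (ties broken by
#' the alphabetically first label), with a note in the cleaning report.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (decide by extension, then content sniffing),
#'   `"pdb"`, or `"mmcif"`.
#' @param max_size Maximum input size in bytes; larger files are rejected
#'   before parsing (default 50 MB).
#' @return A list of `rna_structure` objects, one per model.
#' @examples
#' fx <- rna_fixture("clean_hairpin")
#' tf <- tempfile(fileext = ".pdb")
#' write_rna_structure(fx$model, tf, format = "pdb")
#' mods <- read_rna_structure(tf)
#' length(mods[[1]]$residues$gi)
#' @export
read_rna_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                               max_size = 50e6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.finite(sz) && sz > max_size) {
    stop(sprintf("input exceeds the size limit (%d > %d bytes)", sz, max_size))
  }
  if (format == "auto") format <- sniff_structure_format(path)

  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) {
      stop(sprintf("parse error (%s dialect) in '%s': %s",
                   format, path, conditionMessage(e)), call. = FALSE)
    })

  at <- parsed$atom
  # bio3d's mmCIF reader keeps CIF quoting on atom names like "C4'"
  at$elety <- gsub('^"|"$', "", at$elety)
  at$resid <- trimws(at$resid)
  at$chain[is.na(at$chain)] <- "A"
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  if (is.null(at$o)) at$o <- 1
  at$o[is.na(at$o)] <- 1

  n_models <- max(1L, nrow(parsed$xyz))
  out <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    xyz <- parsed$xyz[m, ]
    a <- data.frame(
      chain = at$chain, resno = at$resno, ins = at$insert,
      resname = at$resid, atom = at$elety,
      elem = if (!is.null(at$elesy)) at$elesy else guess_element(at$elety),
      x = xyz[seq(1, length(xyz), 3)],
      y = xyz[seq(2, length(xyz), 3)],
      z = xyz[seq(3, length(xyz), 3)],
      occ = at$o, alt = at$alt,
      stringsAsFactors = FALSE)
    a$elem[is.na(a$elem) | a$elem == ""] <- guess_element(a$atom[is.na(a$elem) | a$elem == ""])
    out[[m]] <- build_rna_structure(a, model_id = m,
                                    source = list(path = path, format = format))
  }
  any_rna <- any(vapply(out, function(mm) {
    any(!is.na(mm$residues$parent)) || any(mm$atoms$atom == "O2'")
  }, logical(1)))
  if (!any_rna) stop("no RNA content in '", path, "'")
  out
}

sniff_structure_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_", head_lines)) || any(grepl("_atom_site", head_lines,
                                                   fixed = TRUE))) {
    return("mmcif")
  }
  "pdb"
}

guess_element <- function(atom) {
  e <- sub("^([0-9]*)([A-Za-z]).*$", "\\2", atom)
  toupper(e)
}

# assemble an rna_structure from a raw atom table (drops H, resolves alt-locs)
build_rna_structure <- function(a, model_id, source,
                                report = empty_cleaning_report()) {
  stopifnot(all(is.finite(a$x)), all(is.finite(a$y)), all(is.finite(a$z)))
  a <- a[!(a$elem %in% c("H", "D")), , drop = FALSE]
  if (is.null(a$alt)) a$alt <- ""

  key <- paste(a$chain, a$resno, a$ins, a$atom, sep = "\r")
  if (anyDuplicated(key)) {
    # alternate locations: keep highest occupancy, ties -> first label
    ord <- order(key, -a$occ, a$alt)
    a2 <- a[ord, , drop = FALSE]
    keep <- !duplicated(key[ord])
    dropped <- a2[!keep, , drop = FALSE]
    if (nrow(dropped)) {
      for (rk in unique(paste(dropped$chain, dropped$resno, dropped$ins))) {
        parts <- strsplit(rk, " ")[[1]]
        report <- rbind(report, data.frame(
          action = "drop_altloc", chain = parts[1],
          residue = paste0(parts[2], parts[3]),
          reason = "alternate location removed (kept highest occupancy)",
          stringsAsFactors = FALSE))
      }
    }
    a <- a2[keep, , drop = FALSE]
    a <- a[order(match(paste(a$chain, a$resno, a$ins, a$atom, sep = "\r"),
                       unique(key))), , drop = FALSE]
  }
  a$alt <- NULL

  rk <- paste(a$chain, a$resno, a$ins, sep = "\r")
  ri <- match(rk, unique(rk))
  a$ri <- ri
  first <- !duplicated(rk)
  res <- data.frame(
    chain = a$chain[first], resno = a$resno[first], ins = a$ins[first],
    resname = a$resname[first], stringsAsFactors = FALSE)
  res$parent <- parent_nucleotide(res$resname)
  res$modified <- !is.na(res$parent) & !(res$resname %in% .standard_rna)
  # order residues by chain appearance, then file order within chain
  chain_order <- match(res$chain, unique(res$chain))
  ord <- order(chain_order, seq_len(nrow(res)))
  res <- res[ord, , drop = FALSE]
  a$ri <- match(a$ri, ord)
  res$seq_index <- unlist(lapply(split(seq_len(nrow(res)), factor(res$chain, levels = unique(res$chain))),
                                 function(ix) seq_along(ix) - 1L), use.names = FALSE)
  res$gi <- seq_len(nrow(res))
  rownames(res) <- NULL
  rownames(a) <- NULL

  structure(list(model_id = model_id, source = source, atoms = a,
                 residues = res, cleaning_report = report),
            class = "rna_structure")
}

empty_cleaning_report <- function() {
  data.frame(action = character(), chain = character(), residue = character(),
             reason = character(), stringsAsFactors = FALSE)
}

res_label <- function(model, gi) {
  r <- model$residues[gi, , drop = FALSE]
  paste0(r$resname, r$resno, ifelse(r$ins == "", "", r$ins))
}

# coordinates of a named atom of residue gi, or NULL if absent
atom_xyz <- function(model, gi, atom) {
  a <- model$atoms
  hit <- which(a$ri == gi & a$atom == atom)
  if (!length(hit)) return(NULL)
  as.numeric(a[hit[1], c("x", "y", "z")])
}

residue_atoms <- function(model, gi) {
  model$atoms[model$atoms$ri == gi, , drop = FALSE]
}

#' Clean an RNA structure model
#'
#' Removes non-RNA chains (protein, DNA, ligands, water), surplus atoms of
#' modified residues that do not map onto the parent ribonucleotide atom
#' set, and incomplete nucleotides lacking the atoms needed downstream
#' (C4' and the glycosidic base nitrogen; P is optional only for the
#' 5'-terminal residue of a chain). Every removal is appended to the
#' model's cleaning report. The operation is idempotent.
#'
#' A chain counts as RNA when more than half of its residues are standard
#' ribonucleotides, mapped modified ribonucleotides, or carry an O2' atom
#' (which excludes DNA).
#'
#' @param model An `rna_structure`.
#' @return The cleaned `rna_structure`.
#' @export
clean_rna_structure <- function(model) {
  stopifnot(inherits(model, "rna_structure"))
  a <- model$atoms
  res <- model$residues
  report <- model$cleaning_report

  has_o2p <- tapply(a$atom == "O2'", a$ri, any)
  res$has_o2p <- as.logical(has_o2p[as.character(seq_len(nrow(res)))])
  res$has_o2p[is.na(res$has_o2p)] <- FALSE

  ring_names <- unique(unlist(.base_ring_atoms))
  n_ring <- tapply(a$atom %in% ring_names, a$ri, sum)
  res$n_ring <- as.integer(n_ring[as.character(seq_len(nrow(res)))])
  res$n_ring[is.na(res$n_ring)] <- 0L
  has_ribose <- tapply(a$atom %in% c("C1'", "C4'"), a$ri, any)
  res$has_ribose <- as.logical(has_ribose[as.character(seq_len(nrow(res)))])
  res$has_ribose[is.na(res$has_ribose)] <- FALSE

  res$rna_like <- !is.na(res$parent) | res$has_o2p
  keep_res <- rep(TRUE, nrow(res))

  # chain-level filter
  for (ch in unique(res$chain)) {
    ix <- which(res$chain == ch)
    frac <- mean(res$rna_like[ix])
    if (frac <= 0.5) {
      keep_res[ix] <- FALSE
      report <- rbind(report, data.frame(
        action = "remove_chain", chain = ch, residue = "*",
        reason = sprintf("non-RNA chain (%d/%d RNA-like residues)",
                         sum(res$rna_like[ix]), length(ix)),
        stringsAsFactors = FALSE))
    }
  }

  # residue-level: non-nucleotide residues inside RNA chains (ions, waters)
  for (i in which(keep_res)) {
    if (is.na(res$parent[i]) && !(res$has_ribose[i] && res$n_ring[i] >= 3)) {
      keep_res[i] <- FALSE
      report <- rbind(report, data.frame(
        action = "remove_residue", chain = res$chain[i],
        residue = paste0(res$resname[i], res$resno[i], res$ins[i]),
        reason = "not a nucleotide", stringsAsFactors = FALSE))
    }
  }

  # surplus atoms of mapped modified residues
  keep_atom <- rep(TRUE, nrow(a))
  for (i in which(keep_res & res$modified)) {
    tmpl <- parent_atom_set(res$parent[i])
    ix <- which(a$ri == i & !(a$atom %in% tmpl))
    if (length(ix)) {
      keep_atom[ix] <- FALSE
      report <- rbind(report, data.frame(
        action = "remove_surplus_atoms", chain = res$chain[i],
        residue = paste0(res$resname[i], res$resno[i], res$ins[i]),
        reason = sprintf("%d atoms absent from parent %s template (%s)",
                         length(ix), res$parent[i],
                         paste(a$atom[ix], collapse = ",")),
        stringsAsFactors = FALSE))
    }
  }

  # incomplete nucleotides
  atom_ok <- function(i, name) any(a$atom[keep_atom & a$ri == i] == name)
  for (i in which(keep_res)) {
    gly <- if (!is.na(res$parent[i])) glycosidic_atom(res$parent[i]) else NA
    has_gly <- if (!is.na(gly)) atom_ok(i, gly) else
      (atom_ok(i, "N9") || atom_ok(i, "N1"))
    is_5prime <- res$seq_index[i] == min(res$seq_index[keep_res & res$chain == res$chain[i]])
    miss <- character()
    if (!atom_ok(i, "C4'")) miss <- c(miss, "C4'")
    if (!has_gly) miss <- c(miss, "glycosidic base atom")
    if (!is_5prime && !atom_ok(i, "P")) miss <- c(miss, "P")
    if (length(miss)) {
      keep_res[i] <- FALSE
      report <- rbind(report, data.frame(
        action = "remove_residue", chain = res$chain[i],
        residue = paste0(res$resname[i], res$resno[i], res$ins[i]),
        reason = paste("incomplete nucleotide: missing",
                       paste(miss, collapse = ", ")),
        stringsAsFactors = FALSE))
    }
  }

  if (!any(keep_res)) stop("no RNA content after cleaning")

  a2 <- a[keep_atom & keep_res[a$ri], , drop = FALSE]
  a2$ri <- NULL
  a2$alt <- ""
  out <- build_rna_structure(a2, model_id = model$model_id,
                             source = model$source, report = report)
  attr(out, "cleaned") <- TRUE
  out
}

#' Write an RNA structure to a PDB or mmCIF file
#'
#' Re-parsing the written file reproduces the model (residue identities,
#' insertion codes, and coordinates to the printed precision).
#'
#' @param model An `rna_structure`.
#' @param path Output file path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_rna_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  a <- model$atoms
  res <- model$residues
  if (format == "pdb") {
    ok <- tryCatch({
      bio3d::write.pdb(
        file = path,
        xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
        type = rep("ATOM", nrow(a)),
        resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
        elety = a$atom, chain = a$chain,
        insert = ifelse(a$ins == "", NA, a$ins),
        o = a$occ, b = rep(0, nrow(a)), elesy = a$elem)
      TRUE
    }, error = function(e) stop("cannot write '", path, "': ",
                                conditionMessage(e), call. = FALSE))
  } else {
    write_mmcif_atoms(model, path)
  }
  invisible(path)
}

# minimal PDBx/mmCIF writer: a single atom_site loop (bio3d reads it back)
write_mmcif_atoms <- function(model, path) {
  a <- model$atoms
  q <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'), x)
  lines <- c(
    "data_rnatangle",
    sprintf("_entry.id %s", "rnatangle"),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
            seq_len(nrow(a)), a$elem, q(a$atom), a$resname, a$chain, a$resno,
            ifelse(a$ins == "", "?", a$ins), a$x, a$y, a$z, a$occ,
            a$resno, a$resname, a$chain, q(a$atom)),
    "#")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "'",
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @export
print.rna_structure <- function(x, ...) {
  res <- x$residues
  cat(sprintf("RNA structure model %d (%s, %s)\n", x$model_id,
              basename(x$source$path %||% "<memory>"),
              x$source$format %||% "generated"))
  for (ch in unique(res$chain)) {
    n <- sum(res$chain == ch)
    cat(sprintf("  chain %s: %d residues\n", ch, n))
  }
  if (nrow(x$cleaning_report)) {
    cat(sprintf("  cleaning report: %d records\n", nrow(x$cleaning_report)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
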
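# Reference atom sets for the four ribonucleotides and a table of common
# modified residues mapped to their parent. Used by structure cleaning
# (surplus-atom removal, completeness checks) and by base-pair detection.

.ribose_atoms <- c("P", "OP1", "OP2", "OP3", "O5'", "C5'", "C4'", "O4'",
                   "C3'", "O3'", "C2'", "O2'", "C1'")

.base_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
)

# ring heavy atoms used for base planes and base centers of mass
.base_ring_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.purines <- c("A", "G")
.pyrimidines <- c("C", "U")

# common modified ribonucleotides -> parent; deliberately modest, unmapped
# residues carrying a ribose and a base ring are kept as generic
.modified_map <- c(
  PSU = "U", H2U = "U", "5MU" = "U", "4SU" = "U", OMU = "U", UR3 = "U",
  "3TD" = "U", "70U" = "U", DHU = "U",
  "1MA" = "A", MA6 = "A", A2M = "A", MIA = "A", "6MZ" = "A", T6A = "A",
  "2MG" = "G", M2G = "G", "7MG" = "G", OMG = "G", "1MG" = "G", G7M = "G",
  YG = "G", QUO = "G", GTP = "G", GDP = "G", I = "G",
  "5MC" = "C", OMC = "C", "4OC" = "C", M4C = "C", "5IC" = "C"
)

.atomic_mass <- c(C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)

.standard_rna <- c("A", "C", "G", "U")

# parent ribonucleotide for a residue name, or NA
parent_nucleotide <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- ifelse(resname %in% .standard_rna, resname,
                unname(.modified_map[resname]))
  out
}

is_purine_parent <- function(parent) !is.na(parent) & parent %in% .purines

# glycosidic nitrogen: N9 for purines, N1 for pyrimidines
glycosidic_atom <- function(parent) {
  ifelse(is_purine_parent(parent), "N9", "N1")
}

# full atom template (ribose + base) for a parent nucleotide
parent_atom_set <- function(parent) {
  c(.ribose_atoms, .base_atoms[[parent]])
}
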
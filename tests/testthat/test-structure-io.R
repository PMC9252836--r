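test_that("a synthetic hairpin parses identically from PDB and mmCIF", {
  td <- withr::local_tempdir()
  fx <- rna_fixture("clean_hairpin", loop_size = 6, dir = td)
  mods_pdb <- read_rna_structure(fx$files[["pdb"]])
  mods_cif <- read_rna_structure(fx$files[["cif"]])
  expect_length(mods_pdb, 1)
  m1 <- mods_pdb[[1]]; m2 <- mods_cif[[1]]
  expect_equal(unique(m1$residues$chain), "A")
  expect_equal(nrow(m1$residues), 14)  # 2*4 stem + 6 loop
  expect_equal(m1$residues$resname, m2$residues$resname)
  expect_equal(m1$residues$resno, m2$residues$resno)
  expect_lt(max(abs(as.matrix(m1$atoms[, c("x", "y", "z")]) -
                      as.matrix(m2$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("format sniffing and guards reject bad inputs", {
  td <- withr::local_tempdir()
  fx <- rna_fixture("clean_hairpin", loop_size = 6)
  noext <- file.path(td, "structure_noext")
  write_rna_structure(fx$model, paste0(noext, ".cif"), "mmcif")
  file.rename(paste0(noext, ".cif"), noext)
  expect_length(read_rna_structure(noext), 1)  # content sniffing finds mmCIF
  expect_error(read_rna_structure(file.path(td, "absent.pdb")), "not found")
  big <- file.path(td, "big.pdb")
  write_rna_structure(fx$model, big, "pdb")
  expect_error(read_rna_structure(big, max_size = 10), "size limit")
  pep <- file.path(td, "pep.pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "END"), pep)
  expect_error(read_rna_structure(pep), "no RNA content")
})

test_that("cleaning removes non-RNA chains, waters, and incomplete residues", {
  fx <- rna_fixture("non_rna_contaminated", loop_size = 6)
  cleaned <- clean_rna_structure(fx$model)
  expect_setequal(unique(cleaned$residues$chain), "A")
  expect_false(any(cleaned$residues$resname %in% c("ALA", "HOH")))
  rep <- cleaned$cleaning_report
  expect_equal(sum(rep$action == "remove_chain"), 1)
  expect_true(any(rep$action == "remove_residue" & grepl("HOH", rep$residue)))

  # deleting C4' makes a residue incomplete
  m <- fx$model
  drop <- which(m$atoms$resno == 7 & m$atoms$chain == "A" & m$atoms$atom == "C4'")
  m$atoms <- m$atoms[-drop, ]
  cleaned2 <- clean_rna_structure(m)
  expect_false(any(cleaned2$residues$resno == 7 & cleaned2$residues$chain == "A"))
  expect_true(any(grepl("incomplete", cleaned2$cleaning_report$reason) &
                    grepl("7", cleaned2$cleaning_report$residue)))
})

test_that("modified residues keep template atoms and shed surplus ones", {
  fx <- rna_fixture("clean_hairpin", loop_size = 6)
  m <- fx$model
  # turn loop residue 6 into a pseudouridine-like record with a stray atom
  sel <- m$atoms$resno == 6
  m$atoms$resname[sel] <- "PSU"
  m$residues$resname[m$residues$resno == 6] <- "PSU"
  m$residues$parent[m$residues$resno == 6] <- "U"
  m$residues$modified[m$residues$resno == 6] <- TRUE
  stray <- m$atoms[which(sel)[1], ]
  stray$atom <- "CM9"; stray$elem <- "C"; stray$x <- stray$x + 2
  m$atoms <- rbind(m$atoms, stray)
  cleaned <- clean_rna_structure(m)
  kept <- cleaned$residues[cleaned$residues$resno == 6, ]
  expect_equal(nrow(kept), 1)
  expect_false("CM9" %in% cleaned$atoms$atom[cleaned$atoms$ri == kept$gi])
  expect_true(any(cleaned$cleaning_report$action == "remove_surplus_atoms"))
})

test_that("write/parse round trip preserves identity, coordinates, insertion codes", {
  td <- withr::local_tempdir()
  fx <- rna_fixture("lassoed_hairpin", loop_size = 6)
  m <- clean_rna_structure(fx$model)
  m$atoms$ins[m$atoms$resno == 5] <- "A"
  m$residues$ins[m$residues$resno == 5] <- "A"
  for (fmt in c("pdb", "mmcif")) {
    f <- file.path(td, paste0("rt.", fmt))
    write_rna_structure(m, f, fmt)
    back <- read_rna_structure(f)[[1]]
    expect_equal(nrow(back$residues), nrow(m$residues))
    expect_equal(back$residues$resno, m$residues$resno)
    expect_equal(back$residues$ins, m$residues$ins)
    expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                        as.matrix(m$atoms[, c("x", "y", "z")]))), 1e-3)
  }
})

test_that("cleaning is idempotent and alt-locs resolve to highest occupancy", {
  fx <- rna_fixture("clean_hairpin", loop_size = 6)
  c1 <- clean_rna_structure(fx$model)
  c2 <- clean_rna_structure(c1)
  expect_identical(c1$residues, c2$residues)
  expect_equal(nrow(c1$atoms), nrow(c2$atoms))

  m <- fx$model
  row <- m$atoms[m$atoms$resno == 1 & m$atoms$atom == "C4'", ][1, ]
  m$atoms$alt[m$atoms$resno == 1 & m$atoms$atom == "C4'"] <- "A"
  m$atoms$occ[m$atoms$resno == 1 & m$atoms$atom == "C4'"] <- 0.4
  row$alt <- "B"; row$occ <- 0.6; row$x <- row$x + 0.5
  m2 <- rnatangle:::build_rna_structure(rbind(m$atoms, row), 1L, m$source)
  kept <- m2$atoms[m2$atoms$resno == 1 & m2$atoms$atom == "C4'", ]
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x, row$x)  # occupancy 0.6 conformer wins
  expect_true(any(m2$cleaning_report$action == "drop_altloc"))
})
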
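test_that("the scan object carries results and methods work", {
  fx <- rna_fixture("lassoed_hairpin", loop_size = 8)
  sc <- entanglement_scan(fx$model)
  expect_s3_class(sc, "entanglement_scan")
  expect_equal(nrow(as.data.frame(sc)), 1)
  expect_output(print(sc), "L\\(S\\)")
  s <- summary(sc)
  expect_equal(s$n, 1)
  expect_output(print(s), "lassos")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(sc))
})

test_that("a clean hairpin reports no entanglements", {
  fx <- rna_fixture("clean_hairpin", loop_size = 8)
  sc <- entanglement_scan(fx$model)
  expect_equal(nrow(sc$table), 0)
  expect_output(print(sc), "no entanglements")
})

test_that("a user-supplied secondary structure overrides detection", {
  fx <- rna_fixture("lassoed_hairpin", loop_size = 8)
  m <- clean_rna_structure(fx$model)
  n <- nrow(m$residues)
  # claim everything unpaired: no closed elements, hence no entanglements
  sc <- entanglement_scan(m, ss = strrep(".", n))
  expect_equal(nrow(sc$table), 0)
  expect_error(entanglement_scan(m, ss = "(((...)))"), "residues")
})

test_that("the pseudoknot option gates knot-like fold detection", {
  fx <- rna_fixture("knotlike_pseudoknot", loop_size = 15)
  acc <- entanglement_scan(fx$model, pseudoknots = "accept")
  ign <- entanglement_scan(fx$model, pseudoknots = "ignore")
  expect_equal(nrow(acc$table), 1)
  expect_equal(acc$table$level, 1)
  expect_equal(acc$table$class, "L(S)")
  expect_equal(nrow(ign$table), 0)
  expect_equal(ign$levels, 0L)
  expect_error(entanglement_scan(fx$model, pseudoknots = "ignore",
                                 order_cap = 2), "order_cap")
})

test_that("the pipeline writes a deterministic output bundle", {
  td <- withr::local_tempdir()
  fx <- rna_fixture("lassoed_hairpin", loop_size = 8,
                    dir = file.path(td, "fx"))
  out1 <- file.path(td, "out1"); out2 <- file.path(td, "out2")
  r1 <- run_entanglement_pipeline(fx$files[["pdb"]], out1)
  r2 <- run_entanglement_pipeline(fx$files[["pdb"]], out2)
  expect_true(file.exists(file.path(out1, "summary.txt")))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  tab <- r1$results[[1]]$table
  expect_equal(tab$class, "L(S)")
  s <- r1$summary
  expect_true(all(s$lassos + s$interlaces == s$all))
  # entanglement json round trips
  js <- jsonlite::read_json(file.path(out1, list.files(out1, "entanglements.json")))
  expect_equal(js[[1]]$class, "L(S)")
})

test_that("multi-model files scan per model", {
  td <- withr::local_tempdir()
  fx <- rna_fixture("lassoed_hairpin", loop_size = 8)
  single <- file.path(td, "single.pdb")
  write_rna_structure(fx$model, single, "pdb")
  body <- grep("^ATOM", readLines(single), value = TRUE)
  multi <- file.path(td, "multi.pdb")
  writeLines(c("MODEL        1", body, "ENDMDL",
               "MODEL        2", body, "ENDMDL", "END"), multi)
  mods <- read_rna_structure(multi)
  expect_length(mods, 2)
  r <- run_entanglement_pipeline(multi, file.path(td, "out"), models = "all")
  expect_length(r$results, 2)
  r1 <- run_entanglement_pipeline(multi, file.path(td, "out_first"),
                                  models = "first")
  expect_length(r1$results, 1)
})

test_that("rigid motions and mesh refinement leave verdicts unchanged", {
  specs <- list(list(f = "lassoed_hairpin", p = 1),
                list(f = "multi_weave", p = 3),
                list(f = "interlaced_hairpins", p = 1),
                list(f = "knotlike_pseudoknot", p = 1))
  for (spec in specs) {
    base <- rna_fixture(spec$f, loop_size = 10, punctures = spec$p)
    ref <- entanglement_scan(base$model)$table
    for (seed in c(2, 31)) {
      fx <- rna_fixture(spec$f, loop_size = 10, punctures = spec$p, seed = seed)
      got <- entanglement_scan(fx$model)$table
      expect_equal(got[, c("level", "topology", "class", "n_punctures")],
                   ref[, c("level", "topology", "class", "n_punctures")],
                   info = sprintf("%s seed %d", spec$f, seed))
    }
    for (et in c(1.0, 0.5)) {
      got <- entanglement_scan(base$model,
                               geometry = geometry_params(edge_target = et))$table
      expect_equal(got[, c("level", "topology", "class", "n_punctures")],
                   ref[, c("level", "topology", "class", "n_punctures")],
                   info = sprintf("%s edge %.1f", spec$f, et))
    }
  }
})
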
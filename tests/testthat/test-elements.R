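test_that("a flanked hairpin decomposes into loop, steps, and dangles", {
  ss <- parse_extended_dotbracket("..(((....)))..")
  es <- build_elements(ss, 0L)
  kinds <- sapply(es$closed, `[[`, "kind")
  expect_equal(sum(kinds == "L"), 1)
  expect_equal(sum(kinds == "D"), 2)
  expect_equal(length(es$open), 2)
  loop <- es$closed[[which(kinds == "L")]]
  expect_equal(range(loop$residues), c(5, 10))
  dangles <- lapply(es$open, `[[`, "residues")
  expect_setequal(vapply(dangles, paste, "", collapse = ","),
                  c("1,2", "13,14"))
})

test_that("an unpaired sequence is one single strand", {
  ss <- parse_extended_dotbracket("..........")
  es <- build_elements(ss, 0L)
  expect_length(es$closed, 0)
  expect_length(es$open, 1)
  expect_equal(es$open[[1]]$residues, 1:10)
})

test_that("dinucleotide-step counts match the helix bookkeeping oracle", {
  set.seed(11)
  for (rep in 1:20) {
    pairs <- assign_pseudoknot_orders(random_nested_pairs(60))
    res <- data.frame(chain = "A", resno = 1:60, ins = "", resname = "G",
                      parent = "G", modified = FALSE, seq_index = 0:59,
                      gi = 1:60)
    ss <- rnatangle:::new_rna_secondary(res, pairs)
    es <- build_elements(ss, 0L)
    expect_equal(sum(sapply(es$closed, `[[`, "kind") == "D"),
                 expected_d_steps(pairs), info = paste("rep", rep))
  }
})

test_that("levels enumerate up to the maximum order unless capped or ignored", {
  ss <- parse_extended_dotbracket(".((.[[.{{.)).]].}}.")
  expect_equal(ss$max_order, 2)
  expect_equal(enumerate_levels(ss), 0:2)
  expect_equal(enumerate_levels(ss, ignore_pseudoknots = TRUE), 0L)
  expect_equal(enumerate_levels(ss, order_cap = 1), 0:1)
  ss0 <- parse_extended_dotbracket("(((...)))")
  expect_equal(enumerate_levels(ss0), 0L)
  expect_error(build_elements(ss, 3L), "exceeds")
})

test_that("at level k only order-k pairs close elements", {
  ss <- parse_extended_dotbracket(".((..[[..))..]].")
  es0 <- build_elements(ss, 0L)
  es1 <- build_elements(ss, 1L)
  loop0 <- Filter(function(e) e$kind == "L", es0$closed)[[1]]
  loop1 <- Filter(function(e) e$kind == "L", es1$closed)[[1]]
  expect_equal(range(loop0$residues), c(3, 10))   # order-0 pair (3,10)
  expect_equal(range(loop1$residues), c(7, 14))   # order-1 pair (7,14)
  # pseudoknotted residues are embedded inside the level-0 loop, and the
  # level-1 single strands span everything before/after the order-1 pairs
  open1 <- lapply(es1$open, `[[`, "residues")
  expect_true(any(vapply(open1, function(r) identical(r, 1:5), logical(1))))
})

test_that("oversized loops are discarded and their runs become strands", {
  ss <- parse_extended_dotbracket("(..........)")
  es <- build_elements(ss, 0L, element_options(max_loop_length = 8))
  expect_length(es$closed, 0)
  runs <- lapply(es$open, `[[`, "residues")
  expect_true(any(vapply(runs, function(r) identical(r, 2:11), logical(1))))
  es2 <- build_elements(ss, 0L, element_options(max_loop_length = 40))
  expect_equal(sum(sapply(es2$closed, `[[`, "kind") == "L"), 1)
})

test_that("level-0 decomposition of a pseudoknot-free structure ignores the option", {
  ss <- parse_extended_dotbracket("..(((....)))..")
  a <- build_elements(ss, 0L, element_options(pseudoknots = "accept"))
  b <- build_elements(ss, 0L, element_options(pseudoknots = "ignore"))
  expect_equal(sapply(a$closed, `[[`, "id"), sapply(b$closed, `[[`, "id"))
  expect_equal(sapply(a$open, `[[`, "id"), sapply(b$open, `[[`, "id"))
})

test_that("loop boundaries are simple cycles", {
  ss <- parse_extended_dotbracket("((..((...))..((...))..))")
  es <- build_elements(ss, 0L)
  for (el in es$closed) {
    if (el$kind != "L") next
    expect_equal(anyDuplicated(el$residues), 0)
  }
  # the multibranch loop closed by (2,23) contains both child pairs
  multi <- Filter(function(e) e$kind == "L" && nrow(e$closing) == 3, es$closed)
  expect_length(multi, 1)
})
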
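test_that("the geometric detector recovers exactly the designed pairs", {
  fx <- rna_fixture("clean_hairpin", loop_size = 8)
  m <- clean_rna_structure(fx$model)
  pairs <- detect_canonical_pairs(m)
  expect_equal(nrow(pairs), 4)
  expect_equal(pairs$i, 1:4)
  expect_equal(pairs$j, 16:13)
  expect_true(all(pairs$class == "WC-GC"))

  # pulling one pair's partners 15 A apart breaks that pair only
  m2 <- m
  sel <- m2$atoms$ri == 16
  m2$atoms$x[sel] <- m2$atoms$x[sel] + 15
  pairs2 <- detect_canonical_pairs(m2)
  expect_equal(nrow(pairs2), 3)
  expect_false(16 %in% pairs2$j)
})

test_that("pair detection is invariant under rigid motion", {
  fx <- rna_fixture("clean_hairpin", loop_size = 8)
  m <- clean_rna_structure(fx$model)
  base <- detect_canonical_pairs(m)
  for (seed in c(3, 14)) {
    tr <- random_rigid_transform(seed)
    rot <- detect_canonical_pairs(transform_structure(m, tr$R, tr$t))
    expect_equal(rot[, c("i", "j", "class")], base[, c("i", "j", "class")])
  }
})

test_that("pseudoknot order assignment layers pairs correctly", {
  nested <- data.frame(i = c(1, 2, 3), j = c(10, 9, 8), class = "WC-GC",
                       score = 2.9, order = NA_integer_, isolated = FALSE)
  expect_true(all(assign_pseudoknot_orders(nested)$order == 0))

  crossing <- data.frame(i = c(1, 3), j = c(5, 8), class = "WC-GC",
                         score = 2.9, order = NA_integer_, isolated = FALSE)
  out <- assign_pseudoknot_orders(crossing)
  expect_equal(out$order[out$i == 1], 0)   # tie broken toward smaller i
  expect_equal(out$order[out$i == 3], 1)

  preset <- data.frame(i = c(1, 3), j = c(5, 8), class = "WC-GC",
                       score = 2.9, order = c(0L, 0L), isolated = FALSE)
  expect_error(assign_pseudoknot_orders(preset), "cross")
  dup <- data.frame(i = c(1, 1), j = c(5, 8), class = "WC-GC",
                    score = 2.9, order = NA_integer_, isolated = FALSE)
  expect_error(assign_pseudoknot_orders(dup), "more than one pair")
})

test_that("order-0 cardinality matches the exhaustive oracle on random sets", {
  set.seed(42)
  for (rep in 1:40) {
    np <- sample(2:12, 1)
    pairs <- random_pair_set(40, np)
    out <- assign_pseudoknot_orders(pairs)
    expect_equal(sum(out$order == 0), brute_max_noncrossing(pairs),
                 info = paste("rep", rep))
    # non-crossing within every order
    for (k in unique(out$order)) {
      p <- out[out$order == k, ]
      if (nrow(p) < 2) next
      for (u in seq_len(nrow(p) - 1)) for (v in seq(u + 1, nrow(p))) {
        expect_false((p$i[u] < p$i[v] && p$i[v] < p$j[u] && p$j[u] < p$j[v]) ||
                       (p$i[v] < p$i[u] && p$i[u] < p$j[v] && p$j[v] < p$j[u]))
      }
    }
  }
})

test_that("extended dot-bracket rendering follows the per-order alphabets", {
  hp <- parse_extended_dotbracket("(((....)))")
  expect_equal(nrow(hp$pairs), 3)
  expect_true(all(hp$pairs$order == 0))
  expect_equal(strsplit(to_extended_dotbracket(hp), "\n")[[1]][3], "(((....)))")

  mixed <- data.frame(i = c(2, 4), j = c(6, 9), class = "WC-GC", score = 2.9,
                      order = c(0L, 1L), isolated = TRUE)
  res <- data.frame(chain = "A", resno = 1:10, ins = "", resname = "A",
                    parent = "A", modified = FALSE, seq_index = 0:9, gi = 1:10)
  ss <- rnatangle:::new_rna_secondary(res, mixed)
  expect_equal(strsplit(to_extended_dotbracket(ss), "\n")[[1]][3], ".(.[.)..].")

  cross <- parse_extended_dotbracket("([)]")
  expect_equal(cross$pairs$i, c(1, 2))
  expect_equal(cross$pairs$j, c(3, 4))
  expect_equal(cross$pairs$order, c(0, 1))

  expect_error(parse_extended_dotbracket("(("), "unbalanced")
  expect_error(parse_extended_dotbracket("())"), "unbalanced")
})

test_that("dot-bracket round trips on random structures", {
  set.seed(7)
  for (rep in 1:10) {
    pairs <- assign_pseudoknot_orders(random_pair_set(30, sample(3:10, 1)))
    res <- data.frame(chain = "A", resno = 1:30, ins = "", resname = "G",
                      parent = "G", modified = FALSE, seq_index = 0:29,
                      gi = 1:30)
    ss <- rnatangle:::new_rna_secondary(res, pairs)
    back <- parse_extended_dotbracket(to_extended_dotbracket(ss))
    expect_equal(back$pairs[, c("i", "j", "order")],
                 ss$pairs[, c("i", "j", "order")])
  }
})

test_that("isolated pairs are flagged and can be ignored", {
  pairs <- data.frame(i = c(1, 2, 12), j = c(10, 9, 20), class = "WC-GC",
                      score = 2.9, order = NA_integer_, isolated = NA)
  pairs$isolated <- rnatangle:::flag_isolated(pairs)
  expect_equal(pairs$isolated, c(FALSE, FALSE, TRUE))
})
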
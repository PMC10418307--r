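test_that("local motif enumeration respects the trimmed region", {
  m <- enumerate_motifs("CASSLGEQYF", k_range = 4)
  expect_setequal(names(m), c("SLGE", "LGEQ"))  # trimmed region SLGEQ

  # trimmed region shorter than k contributes nothing
  expect_length(enumerate_motifs("CASSQF", k_range = 4), 0)

  m2 <- enumerate_motifs(c("CASSLGETTTQYF", "CAWSLGEPPPQYF"), k_range = 4)
  expect_equal(sort(m2[["SLGE"]]), c("CASSLGETTTQYF", "CAWSLGEPPPQYF"))
  expect_length(m2[["SLGE"]], 2)
})

test_that("enrichment test matches Fisher and applies the support/fold gates", {
  # a=5/n=50 vs b=2/m=5000: fold (5/50)/(2/5000) = 250
  r <- test_enrichment(5, 50, 2, 5000)
  expect_equal(r$fold, 250)
  oracle <- fisher.test(matrix(c(5, 45, 2, 4998), 2, byrow = TRUE),
                        alternative = "greater")$p.value
  expect_equal(r$p_value, oracle, tolerance = 1e-12)
  expect_true(r$pass)

  # support 2 is rejected no matter how small the p-value
  r2 <- test_enrichment(2, 50, 0, 5000)
  expect_false(r2$pass)

  # b = 0 uses the pseudocount for the fold only
  r3 <- test_enrichment(3, 100, 0, 1000)
  expect_equal(r3$fold, (3 / 100) / (0.5 / 1000))
  expect_equal(r3$pass, r3$p_value <= 1e-3)

  expect_error(test_enrichment(10, 5, 0, 100), "exceed")
})

test_that("global templates wildcard one trimmed-region position", {
  trio <- c("CASSLGEQYF", "CASSLGDQYF", "CASSLGNQYF")
  t1 <- global_templates(trio)
  expect_true("CASSLG%QYF" %in% names(t1))
  expect_setequal(t1[["CASSLG%QYF"]], trio)

  # two positions differ -> no template
  expect_length(global_templates(c("CASSLGEQYF", "CASSLGDQYA")), 0)

  # difference confined to the trimmed N-terminal stem -> not templated
  expect_length(global_templates(c("CASSLGEQYF", "CTSSLGEQYF")), 0)
})

test_that("discovered pattern members always contain or match the pattern", {
  set.seed(21)
  letters10 <- c("A", "D", "E", "G", "L", "N", "Q", "S", "T", "Y")
  bg <- unique(paste0("CASS", random_cdr3s(300, lengths = 5:9,
                                           alphabet = letters10), "QYF"))
  carriers <- paste0("CASS", c("A", "G", "T", "LD", "NQ"), "WRDM",
                     c("E", "Q", "", "Y", "S"), "QYF")
  pats <- discover_patterns(c(bg[1:50], carriers), reference = bg)
  expect_gt(nrow(pats), 0)
  for (i in seq_len(nrow(pats))) {
    members <- pats$members[[i]]
    if (pats$kind[i] == "local") {
      expect_true(all(grepl(pats$pattern[i], members, fixed = TRUE)))
    } else {
      rx <- paste0("^", gsub("%", ".", pats$pattern[i], fixed = TRUE), "$")
      expect_true(all(grepl(rx, members)))
    }
  }
  expect_true("WRDM" %in% pats$pattern[pats$kind == "local"])
})

test_that("pattern-set algebra removes shared and unstimulated patterns from both sides", {
  direct <- pat_df(c("AAAA", "BBBB", "CCCC"))
  indirect <- pat_df(c("BBBB", "DDDD"))
  sets <- pattern_set_algebra(direct, indirect)
  expect_setequal(sets$direct_exclusive$pattern, c("AAAA", "CCCC"))
  expect_setequal(sets$indirect_exclusive$pattern, "DDDD")
  expect_setequal(sets$shared_di$pattern, "BBBB")
  expect_length(intersect(sets$direct_exclusive$pattern,
                          sets$indirect_exclusive$pattern), 0)

  unstim <- pat_df("CCCC")
  sets2 <- pattern_set_algebra(direct, indirect, unstim, subtract_unstim = TRUE)
  expect_setequal(sets2$direct_exclusive$pattern, "AAAA")
  # accounting identity: direct = exclusive + shared + unstim-only removals
  cn <- sets2$counts
  removed_unstim_only <- cn$direct - cn$direct_exclusive - cn$shared_incl_unstim
  expect_equal(cn$direct,
               cn$direct_exclusive + cn$shared_incl_unstim + removed_unstim_only)
  expect_equal(removed_unstim_only, 1)

  # disjoint inputs pass through unchanged
  sets3 <- pattern_set_algebra(pat_df("AAAA"), pat_df("DDDD"))
  expect_equal(nrow(sets3$direct_exclusive), 1)
  expect_equal(nrow(sets3$indirect_exclusive), 1)
  expect_equal(nrow(sets3$shared_di), 0)
})

test_that("clonotype assignment follows the exclusive patterns and excludes ambiguity", {
  sets <- pattern_set_algebra(pat_df("SLGE"), pat_df("DAGG"))
  cdr3 <- c("CASSLGETTQYF",    # direct motif only
            "CASSDAGGYEQYF",   # indirect motif only
            "CASSLGEDAGGQYF",  # both -> ambiguous
            "CASSPPPPPPQYF")   # neither
  expect_message(lab <- assign_clonotypes(cdr3, sets), "ambiguous")
  expect_equal(lab$label, c("direct", "indirect", "ambiguous", "none"))
  expect_equal(attr(lab, "n_ambiguous"), 1)
})

test_that("cluster origin histogram sums to the number of patterns", {
  pats <- pat_df(c("AAAA", "BBBB", "CCCC"))
  pats$source_conditions <- list(c("BlL0", "VacDC"), "Trans",
                                 c("BlL0", "VacDC", "Trans"))
  org <- cluster_origins(pats)
  expect_equal(org$per_pattern$n_origins, c(2, 1, 3))
  expect_equal(sum(org$histogram), nrow(pats))
  expect_equal(unname(org$histogram[["2"]]), 1)
})
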
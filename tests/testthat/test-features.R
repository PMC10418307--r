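test_that("frequency statistics reproduce the worked examples", {
  rep <- toy_repertoire(paste0("CASS", c("A", "C", "D", "E"), "GGQYF"),
                        c(4, 6, 2, 8))
  keys <- rep$clonotypes$cdr3_aa

  fs <- frequency_stats(rep, keys)  # labeled = whole
  expect_equal(fs$sum_frequency, 1)
  expect_equal(fs$median_ratio, 1)

  # medians: labeled {4e-5, 6e-5} -> 5e-5; comparator median 2e-5 -> ratio 2.5
  freqs <- c(4e-5, 6e-5, 1e-5, 3e-5)
  rep2 <- toy_repertoire(paste0("CASS", c("A", "C", "D", "E"), "GGQYF"),
                         count = freqs * 1e5)
  fs2 <- frequency_stats(rep2, rep2$clonotypes$cdr3_aa[
    rep2$clonotypes$frequency %in% (c(4e-5, 6e-5) / sum(freqs))],
    comparator_keys = rep2$clonotypes$cdr3_aa[
      rep2$clonotypes$frequency %in% (c(1e-5, 3e-5) / sum(freqs))])
  expect_equal(fs2$median_ratio, 5e-5 / 2e-5)

  expect_error(frequency_stats(rep, "CASSNOTHEREQYF"), "subset")
})

test_that("the Mann-Whitney test is calibrated under the null", {
  set.seed(33)
  n <- 5000
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  code <- vapply(seq_len(n) - 1, function(i)
    paste0(aa20[(i %/% c(8000, 400, 20, 1)) %% 20 + 1], collapse = ""),
    character(1))
  rep <- toy_repertoire(paste0("CASS", code, "GQYF"), count = rexp(n))
  keys <- rep$clonotypes$cdr3_aa
  hits <- replicate(100, {
    lab <- sample(keys, 50)
    frequency_stats(rep, lab)$mw_p > 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("V usage supports both weightings and pools unknown genes", {
  rep <- toy_repertoire(c("CASSAAAQYF", "CASSGGGQYF"), c(30, 10),
                        v = c("TRBV31", "TRBV13-2"))
  expect_equal(unname(v_usage(rep, weighting = "read")[c("TRBV31", "TRBV13-2")]),
               c(0.75, 0.25))
  expect_equal(unname(v_usage(rep, weighting = "clonotype")[c("TRBV31", "TRBV13-2")]),
               c(0.5, 0.5))
  u <- v_usage(rep, genes = c("TRBV31", "TRBV1"))
  expect_equal(unname(u), c(0.5, 0, 0.5))  # TRBV13-2 pooled into "other"
  single <- v_usage(toy_repertoire("CASSAAAQYF", 5, v = "TRBV31"))
  expect_equal(unname(single), 1)
  expect_equal(names(single), "TRBV31")
})

test_that("cosine similarity matches its worked examples and properties", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  # symmetric, scale invariant, 1 iff proportional
  set.seed(4)
  u <- runif(6); v <- runif(6)
  expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
  expect_equal(cosine_similarity(u, v), cosine_similarity(5 * u, v / 3))
  expect_equal(cosine_similarity(u, 2 * u), 1)
  expect_lt(cosine_similarity(u, v), 1)
  expect_true(is.na(cosine_similarity(c(0, 0), c(1, 1))))
})

test_that("spectratype counts lengths and the >14 aa ratio", {
  cdr3 <- c(strrep("A", 12),
            paste0(strrep("G", 12), c("A", "C")),
            paste0(strrep("S", 13), c("A", "C", "D")),
            paste0(strrep("T", 14), c("A", "C")),
            paste0(strrep("L", 15), "A"))
  # lengths 12,13,14,15,16 with counts 1,2,3,2,1 -> ratio 3/6
  sp <- spectratype(cdr3)
  expect_equal(unname(sp$counts[c("12", "13", "14", "15", "16")]),
               c(1, 2, 3, 2, 1), ignore_attr = TRUE)
  expect_equal(sp$long_short_ratio, 0.5)
  expect_equal(sum(sp$counts), length(cdr3))

  expect_equal(spectratype(c("CASSAAAQYF", "CASSGGGQYF"))$long_short_ratio, 0)
  expect_true(is.na(spectratype(character(0))$long_short_ratio))
})

test_that("positional profiles count each clonotype once with rows summing to 1", {
  p <- positional_profile(c("CASF", "CTSF", "CASF"), L = 4)
  expect_equal(p["pos2", "A"], 0.5)
  expect_equal(p["pos2", "T"], 0.5)
  expect_equal(unname(rowSums(p)), rep(1, 4))

  p2 <- positional_profile(rep("CASSF", 3), L = 5)
  expect_true(all(apply(p2, 1, max) == 1))

  set.seed(8)
  p3 <- positional_profile(unique(random_cdr3s(60, lengths = 10,
                                               alphabet = c("A", "C", "G", "S"))),
                           L = 10)
  expect_equal(unname(rowSums(p3)), rep(1, 10))
  # clonotypes of other lengths are excluded
  expect_equal(sum(positional_profile("CASSAAAQYF", L = 14)), 0)
})
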
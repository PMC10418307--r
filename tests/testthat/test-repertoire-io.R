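test_that("read_mixcr maps fields, strips allele decorations and renormalizes", {
  f <- tempfile(fileext = ".tsv")
  write_mixcr_fixture(f, cloneCount = c(42, 8),
                      cloneFraction = c(0.64, 0.16),  # sums to 0.8
                      aaSeqCDR3 = c("CASSLGEQYF", "CASSDAGGYEQYF"),
                      bestVHit = c("TRBV31*01", "TRBV13-1*01"))
  rep <- read_mixcr(f, sample_id = "m1")
  df <- rep$clonotypes
  expect_equal(nrow(df), 2)
  r <- df[df$cdr3_aa == "CASSLGEQYF", ]
  expect_equal(r$v_gene, "TRBV31")
  expect_equal(r$count, 42)
  expect_equal(sum(df$frequency), 1, tolerance = 1e-12)
  expect_equal(r$frequency, 0.64 / 0.8)
})

test_that("read_mixcr drops out-of-frame CDR3s with a tally and errors on missing columns", {
  f <- tempfile(fileext = ".tsv")
  write_mixcr_fixture(f, cloneCount = c(10, 5), cloneFraction = c(2 / 3, 1 / 3),
                      aaSeqCDR3 = c("CASSLGEQYF", "CASS_LG"))
  expect_warning(rep <- read_mixcr(f), "dropped")
  expect_equal(nrow(rep$clonotypes), 1)
  expect_equal(attr(rep, "n_dropped"), 1)
  expect_equal(sum(rep$clonotypes$frequency), 1)

  f2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(aaSeqCDR3 = "CASSLGEQYF", cloneFraction = 1),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mixcr(f2), "clone count")
})

test_that("read_airr maps AIRR columns and falls back to consensus_count", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(junction_aa = "CASSDAGGYEQYF", v_call = "TRBV13-1*01",
                         duplicate_count = 7),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- read_airr(f)
  expect_equal(rep$clonotypes$cdr3_aa, "CASSDAGGYEQYF")
  expect_equal(rep$clonotypes$v_gene, "TRBV13-1")
  expect_equal(rep$clonotypes$count, 7)

  f2 <- tempfile(fileext = ".tsv")
  write.table(data.frame(junction_aa = "CASSLGEQYF", consensus_count = 9),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(rep2 <- read_airr(f2), "consensus_count")
  expect_equal(rep2$clonotypes$count, 9)

  f3 <- tempfile(fileext = ".tsv")
  writeLines("junction_aa\tv_call\tduplicate_count", f3)
  rep3 <- read_airr(f3)
  expect_s3_class(rep3, "repertoire")
  expect_equal(nrow(rep3$clonotypes), 0)
})

test_that("AIRR write/read round trip preserves keys, counts and V genes", {
  reps <- list(
    toy_repertoire(c("CASSLGEQYF", "CASSDAGGYEQYF"), c(10, 30),
                   v = c("TRBV31", "TRBV13-1")),
    toy_repertoire("CASSQETQYF", 5, v = "TRBV5"),
    toy_repertoire(c("CASSFGREQYF", "CASSPGQGAYF", "CASSLDRGQYF"),
                   c(3, 2, 1), v = c("TRBV1", "TRBV2", "TRBV3"))
  )
  for (rep in reps) {
    f <- tempfile(fileext = ".tsv")
    write_airr(rep, f)
    back <- read_airr(f)
    o1 <- order(rep$clonotypes$cdr3_aa)
    o2 <- order(back$clonotypes$cdr3_aa)
    expect_equal(back$clonotypes$cdr3_aa[o2], rep$clonotypes$cdr3_aa[o1])
    expect_equal(back$clonotypes$count[o2], rep$clonotypes$count[o1])
    expect_equal(back$clonotypes$v_gene[o2], rep$clonotypes$v_gene[o1])
  }
})

test_that("duplicate clonotype keys merge with count sum and majority V", {
  rep <- repertoire(c("CASSLGEQYF", "CASSLGEQYF", "CASSLGEQYF"),
                    c(5, 10, 5), v_gene = c("TRBV1", "TRBV2", "TRBV3"))
  expect_equal(nrow(rep$clonotypes), 1)
  expect_equal(rep$clonotypes$count, 20)
  expect_equal(rep$clonotypes$v_gene, "TRBV2")
  # tie on count -> lexicographically first V
  rep2 <- repertoire(c("CASSLGEQYF", "CASSLGEQYF"), c(5, 5),
                     v_gene = c("TRBV9", "TRBV2"))
  expect_equal(rep2$clonotypes$v_gene, "TRBV2")
})

test_that("pooling sums counts, is order-invariant, and identity on one input", {
  a <- toy_repertoire(c("CASSAAAQYF", "CASSGGGQYF"), c(10, 5), id = "a")
  b <- toy_repertoire(c("CASSAAAQYF", "CASSCCCQYF"), c(30, 5), id = "b")
  p <- pool_repertoires(list(a, b))
  expect_equal(p$clonotypes$count[p$clonotypes$cdr3_aa == "CASSAAAQYF"], 40)
  expect_equal(sum(p$clonotypes$frequency), 1, tolerance = 1e-12)

  p2 <- pool_repertoires(list(b, a))
  o1 <- order(p$clonotypes$cdr3_aa); o2 <- order(p2$clonotypes$cdr3_aa)
  expect_equal(p$clonotypes$count[o1], p2$clonotypes$count[o2])

  single <- pool_repertoires(list(a))
  expect_equal(single$clonotypes[order(single$clonotypes$cdr3_aa),
                                 c("cdr3_aa", "count")],
               a$clonotypes[order(a$clonotypes$cdr3_aa),
                            c("cdr3_aa", "count")],
               ignore_attr = TRUE)

  d1 <- toy_repertoire(paste0("CASS", c("A", "C", "D", "E", "G"), "GGQYF"), 1:5)
  d2 <- toy_repertoire(paste0("CASS", c("H", "I", "K", "L", "M"), "GGQYF"), 1:5)
  pd <- pool_repertoires(list(d1, d2))
  expect_equal(nrow(pd$clonotypes), 10)
  expect_equal(sum(pd$clonotypes$frequency), 1, tolerance = 1e-12)

  expect_error(pool_repertoires(list()), "at least one")
})

test_that("count matrix takes the key union with zero fill and correct column sums", {
  a <- toy_repertoire(c("CASSAAAQYF", "CASSGGGQYF"), c(10, 5), id = "a")
  b <- toy_repertoire(c("CASSGGGQYF", "CASSCCCQYF"), c(3, 7), id = "b")
  m <- build_count_matrix(list(a, b))
  expect_setequal(rownames(m), c("CASSAAAQYF", "CASSGGGQYF", "CASSCCCQYF"))
  expect_equal(colnames(m), c("a", "b"))
  expect_equal(m["CASSAAAQYF", "b"], 0)
  expect_equal(unname(colSums(m)),
               c(sum(a$clonotypes$count), sum(b$clonotypes$count)))
  expect_equal(unname(attr(m, "conditions")), c("BaL0", "BaL0"))
})
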
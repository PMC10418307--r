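small_spec <- function(...) {
  args <- list(n_background = 500, depth = 2e4, replicates = 2,
               n_groups_direct = 3, n_groups_indirect = 3,
               n_groups_shared = 1, seed = 11)
  do.call(simulation_spec, utils::modifyList(args, list(...)))
}

test_that("background generation is reproducible and respects the length model", {
  spec <- small_spec()
  a <- generate_background(spec)
  b <- generate_background(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 500)
  expect_false(anyDuplicated(a$cdr3_aa) > 0)
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", a$cdr3_aa)))

  degenerate <- small_spec(length_model = setNames(1, 14))
  expect_true(all(nchar(generate_background(degenerate)$cdr3_aa) == 14))
})

test_that("empirical V usage matches the baseline within sampling error", {
  spec <- simulation_spec(n_background = 10000, seed = 101)
  bg <- generate_background(spec)
  tab <- table(factor(bg$v_gene, levels = names(spec$v_usage_base)))
  p <- chisq.test(tab, p = spec$v_usage_base)$p.value
  expect_gt(p, 0.01)
})

test_that("planted group members contain their motif and seed HD-1 clusters", {
  spec <- small_spec()
  planted <- plant_groups(generate_background(spec), spec)
  truth <- planted$truth
  expect_equal(nrow(truth),
               7 * (spec$n_groups_direct + spec$n_groups_indirect +
                    spec$n_groups_shared))
  expect_true(all(mapply(grepl, truth$motif, truth$cdr3_aa, fixed = TRUE)))

  # each group's carrier + HD-1 variants form a component of size >= 3
  for (g in unique(truth$group)) {
    mem <- truth$cdr3_aa[truth$group == g]
    comp <- igraph::components(build_cdr3_graph(mem))
    expect_gte(max(comp$csize), 3)
  }

  empty <- plant_groups(generate_background(spec),
                        small_spec(n_groups_direct = 0, n_groups_indirect = 0,
                                   n_groups_shared = 0))
  expect_equal(nrow(empty$truth), 0)
})

test_that("condition sampling expands responsive groups and is seed-stable", {
  spec <- small_spec(expansion_factor = 32,
                     carrier_freq = c(1e-4, 1e-4), depth = 1e5)
  planted <- plant_groups(generate_background(spec), spec)
  r1 <- sample_condition(planted$pool, planted$truth, "BlL0", spec, 1)
  r2 <- sample_condition(planted$pool, planted$truth, "BlL0", spec, 1)
  expect_identical(r1, r2)

  # expected counts for the direct-responsive members: exact multinomial
  # expectation, observed within 3 sigma (Poisson bound)
  resp <- planted$truth$cdr3_aa[planted$truth$label %in% c("direct", "shared")]
  fac <- ifelse(planted$pool$cdr3_aa %in% resp, 32, 1)
  prob <- planted$pool$base_weight * fac
  prob <- prob / sum(prob)
  expected <- spec$depth * sum(prob[planted$pool$cdr3_aa %in% resp])
  observed <- sum(r1$clonotypes$count[r1$clonotypes$cdr3_aa %in% resp])
  expect_lt(abs(observed - expected), 3 * sqrt(expected))

  # control samples leave group frequencies at baseline
  ctrl <- sample_condition(planted$pool, planted$truth, "BaL0", spec, 1)
  obs_ctrl <- sum(ctrl$clonotypes$count[ctrl$clonotypes$cdr3_aa %in% resp])
  base_prob <- planted$pool$base_weight / sum(planted$pool$base_weight)
  exp_ctrl <- spec$depth * sum(base_prob[planted$pool$cdr3_aa %in% resp])
  expect_lt(abs(obs_ctrl - exp_ctrl), 4 * sqrt(exp_ctrl))
})

test_that("with all expansion factors 1, stimulated and control samples are exchangeable", {
  spec <- small_spec(expansion_factor = 1)
  scn <- simulate_scenario(spec)
  cnt <- function(r) setNames(r$clonotypes$count, r$clonotypes$cdr3_aa)
  mh_sc <- morisita_horn(cnt(scn$repertoires$BlL0_1), cnt(scn$repertoires$BaL0_1))
  mh_cc <- morisita_horn(cnt(scn$repertoires$BaL0_2), cnt(scn$repertoires$BaL0_1))
  expect_gte(mh_sc, mh_cc - 0.05)
})

test_that("scenario write/read round trip preserves samples and truth", {
  spec <- small_spec()
  scn <- simulate_scenario(spec)
  out <- tempfile("scenario")
  mpath <- write_scenario(scn, out)
  expect_true(file.exists(file.path(out, "truth.tsv")))
  man <- yaml::read_yaml(mpath)
  expect_equal(man$seed, spec$seed)
  expect_setequal(names(man$samples), names(scn$repertoires))

  back <- read_manifest(mpath)
  for (id in names(scn$repertoires)) {
    orig <- scn$repertoires[[id]]$clonotypes
    got <- back[[id]]$clonotypes
    o1 <- order(orig$cdr3_aa); o2 <- order(got$cdr3_aa)
    expect_equal(got$cdr3_aa[o2], orig$cdr3_aa[o1])
    expect_equal(got$count[o2], orig$count[o1])
    expect_equal(back[[id]]$condition, orig_cond <- scn$repertoires[[id]]$condition)
  }
})
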
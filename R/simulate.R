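# Fixed generator constants: CDR3 prefix/suffix and interior residue profile
# chosen to produce mouse-like TRB loops (germline-encoded CASS...F framing,
# glycine/serine-rich interiors). These are implementation constants of the
# simulator, not estimates from any particular dataset.
CDR3_PREFIX <- "CASS"
CDR3_SUFFIX <- "QYF"

INTERIOR_AA_PROFILE <- c(
  A = 0.06, C = 0.005, D = 0.05, E = 0.05, F = 0.02, G = 0.13, H = 0.01,
  I = 0.02, K = 0.02, L = 0.07, M = 0.01, N = 0.04, P = 0.03, Q = 0.06,
  R = 0.07, S = 0.14, T = 0.07, V = 0.04, W = 0.015, Y = 0.06)

MOUSE_TRBV <- c("TRBV1", "TRBV2", "TRBV3", "TRBV4", "TRBV5", "TRBV12-1",
                "TRBV12-2", "TRBV13-1", "TRBV13-2", "TRBV13-3", "TRBV14",
                "TRBV15", "TRBV16", "TRBV17", "TRBV19", "TRBV20", "TRBV23",
                "TRBV26", "TRBV29", "TRBV31")

DEFAULT_V_USAGE <- local({
  w <- setNames(
    c(0.03, 0.04, 0.05, 0.04, 0.08, 0.05,
      0.04, 0.08, 0.12, 0.06, 0.05,
      0.04, 0.05, 0.03, 0.09, 0.04, 0.03,
      0.04, 0.06, 0.08),
    MOUSE_TRBV)
  w / sum(w)
})

DEFAULT_LENGTH_MODEL <- setNames(
  c(1, 2, 5, 9, 14, 16, 14, 9, 5, 3, 1.5, 0.5) /
    sum(c(1, 2, 5, 9, 14, 16, 14, 9, 5, 3, 1.5, 0.5)),
  9:20)

#' Specify a synthetic repertoire scenario
#'
#' Defines the study conditions emulated by the simulator: a Zipf-distributed
#' background of CDR3 clonotypes, planted motif-sharing specificity groups
#' with Hamming-distance-1 neighbors, condition-specific clonal expansion,
#' V-usage skew (TRBV31 toward direct groups, TRBV13-1 toward indirect
#' groups), a shortened CDR3 length distribution for direct-group carriers,
#' and multinomial sequencing-depth sampling. All randomness flows from the
#' single `seed` via fixed per-stage offsets, so stages can be re-run
#' independently and reproducibly.
#'
#' @param n_background number of background clonotypes.
#' @param zipf_exponent power-law slope of background clone sizes.
#' @param depth reads per sample (multinomial total).
#' @param replicates samples per condition.
#' @param n_groups_direct,n_groups_indirect,n_groups_shared planted
#'   specificity-group counts; shared groups respond in both stimulated
#'   conditions.
#' @param group_size motif carriers per group.
#' @param hd1_variants additional HD-1 neighbors of a carrier per group.
#' @param motif_length_range lengths of planted motifs.
#' @param expansion_factor fold expansion of responsive groups in their
#'   stimulated condition (one of 2, 4, 8, 16, 32).
#' @param carrier_freq range of baseline frequencies for group carriers.
#' @param length_model named probability vector over CDR3 lengths.
#' @param direct_length_shift shift (aa) applied to direct-carrier lengths.
#' @param v_usage_base baseline V-usage probabilities.
#' @param conditions named character vector mapping condition label to role
#'   (`"direct"`, `"indirect"` or `"control"`).
#' @param seed master seed.
#' @return List of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_background = 3000, zipf_exponent = 1.1,
                            depth = 1e5, replicates = 3,
                            n_groups_direct = 10, n_groups_indirect = 10,
                            n_groups_shared = 3, group_size = 5,
                            hd1_variants = 2, motif_length_range = 4:6,
                            expansion_factor = 8,
                            carrier_freq = c(1e-4, 1e-3),
                            length_model = DEFAULT_LENGTH_MODEL,
                            direct_length_shift = -2,
                            v_usage_base = DEFAULT_V_USAGE,
                            conditions = c(BlL0 = "direct", BaLBl = "indirect",
                                           BaL0 = "control", BaLBa = "control"),
                            seed = 42) {
  stopifnot(n_background > 0, depth > 0, replicates >= 1,
            expansion_factor >= 1, all(carrier_freq > 0),
            abs(sum(length_model) - 1) < 1e-6)
  if (!any(conditions == "control")) stop("at least one control condition is required")
  structure(as.list(environment()), class = "simulation_spec")
}

# draw random interior strings of the given lengths from the aa profile
# (zero-length entries yield "")
.random_interiors <- function(lens) {
  out <- character(length(lens))
  pos <- which(lens > 0)
  if (length(pos)) {
    chars <- sample(names(INTERIOR_AA_PROFILE), sum(lens[pos]), replace = TRUE,
                    prob = INTERIOR_AA_PROFILE)
    grp <- factor(rep(pos, lens[pos]), levels = pos)
    out[pos] <- vapply(split(chars, grp), paste0, character(1), collapse = "")
  }
  out
}

#' Generate the background clonotype pool
#'
#' CDR3s are built as a conserved prefix, interior residues drawn from a
#' fixed amino-acid profile, and a conserved suffix; lengths follow the
#' spec's length model, V genes its baseline usage, and base clone sizes a
#' Zipf law with the spec's exponent (ranks randomly assigned). Sequences
#' are unique; generation is bit-for-bit reproducible under the same seed.
#'
#' @param spec a [simulation_spec()].
#' @return Data frame with `cdr3_aa`, `v_gene`, `base_weight`.
#' @export
generate_background <- function(spec) {
  set.seed(spec$seed + 1L)
  n <- spec$n_background
  fixed <- nchar(CDR3_PREFIX) + nchar(CDR3_SUFFIX)
  lens <- as.integer(sample(names(spec$length_model), n, replace = TRUE,
                            prob = spec$length_model))
  cdr3 <- paste0(CDR3_PREFIX, .random_interiors(pmax(lens - fixed, 2L)),
                 CDR3_SUFFIX)
  for (tries in 1:50) {
    dup <- duplicated(cdr3)
    if (!any(dup)) break
    cdr3[dup] <- paste0(CDR3_PREFIX,
                        .random_interiors(pmax(lens[dup] - fixed, 2L)),
                        CDR3_SUFFIX)
  }
  if (anyDuplicated(cdr3)) stop("could not generate unique background CDR3s")
  w <- seq_len(n)^(-spec$zipf_exponent)
  data.frame(
    cdr3_aa = cdr3,
    v_gene = sample(names(spec$v_usage_base), n, replace = TRUE,
                    prob = spec$v_usage_base),
    base_weight = w[sample.int(n)],
    stringsAsFactors = FALSE
  )
}

#' Plant motif-sharing specificity groups
#'
#' Each group gets a random interior motif; carriers are built by inserting
#' the motif at a random interior offset, and `hd1_variants` additional
#' members are HD-1 neighbors of a carrier mutated outside the motif span
#' (so every member still contains the motif and the group forms a connected
#' HD-1 cluster seed). Direct-group carriers use a shortened length
#' distribution and TRBV31-skewed V genes; indirect groups are skewed toward
#' TRBV13-1; shared groups respond in both stimulated conditions. Carrier
#' baseline frequencies are drawn uniformly from `spec$carrier_freq`.
#'
#' @param pool background pool from [generate_background()].
#' @param spec a [simulation_spec()].
#' @return List with `pool` (background plus planted members) and `truth`
#'   (class `"synthetic_truth"`): per member `cdr3_aa`, `group`, `label`,
#'   `motif`, `base_freq`.
#' @export
plant_groups <- function(pool, spec) {
  set.seed(spec$seed + 2L)
  labels <- rep(c("direct", "indirect", "shared"),
                c(spec$n_groups_direct, spec$n_groups_indirect,
                  spec$n_groups_shared))
  if (!length(labels)) {
    truth <- data.frame(cdr3_aa = character(), group = integer(),
                        label = character(), motif = character(),
                        base_freq = numeric(), stringsAsFactors = FALSE)
    class(truth) <- c("synthetic_truth", "data.frame")
    return(list(pool = pool, truth = truth))
  }
  fixed <- nchar(CDR3_PREFIX) + nchar(CDR3_SUFFIX)
  existing <- pool$cdr3_aa
  rows <- list()
  motifs <- character(0)
  for (g in seq_along(labels)) {
    lab <- labels[g]
    repeat {
      k <- if (length(spec$motif_length_range) == 1) spec$motif_length_range
           else sample(spec$motif_length_range, 1)
      motif <- paste0(sample(names(INTERIOR_AA_PROFILE), k, replace = TRUE,
                             prob = INTERIOR_AA_PROFILE), collapse = "")
      if (!motif %in% motifs) break
    }
    motifs <- c(motifs, motif)
    n_car <- spec$group_size
    members <- character(0)
    spans <- list()
    while (length(members) < n_car) {
      L <- as.integer(sample(names(spec$length_model), 1,
                             prob = spec$length_model))
      if (lab == "direct")
        L <- max(min(as.integer(names(spec$length_model))),
                 L + spec$direct_length_shift)
      ilen <- max(k, L - fixed)
      off <- sample.int(ilen - k + 1L, 1) - 1L
      pad <- .random_interiors(c(off, ilen - k - off))
      cand <- paste0(CDR3_PREFIX, pad[1], motif, pad[2], CDR3_SUFFIX)
      if (cand %in% existing || cand %in% members) next
      members <- c(members, cand)
      spans[[length(members)]] <- nchar(CDR3_PREFIX) + off + seq_len(k)
    }
    # HD-1 neighbors of the first carrier, mutated outside the motif span
    # and inside the loop body (conserved C and F untouched)
    n_var <- spec$hd1_variants
    while (n_var > 0) {
      base <- members[1]
      Lb <- nchar(base)
      free <- setdiff(2:(Lb - 1), spans[[1]])
      p <- if (length(free) == 1) free else sample(free, 1)
      old <- substr(base, p, p)
      repl <- sample(setdiff(AA_ALPHABET, old), 1)
      cand <- paste0(substr(base, 1, p - 1), repl, substr(base, p + 1, Lb))
      if (cand %in% existing || cand %in% members) next
      members <- c(members, cand)
      n_var <- n_var - 1
    }
    existing <- c(existing, members)
    vskew <- switch(lab, direct = "TRBV31", indirect = "TRBV13-1", NA)
    vg <- sample(names(spec$v_usage_base), length(members), replace = TRUE,
                 prob = spec$v_usage_base)
    if (!is.na(vskew)) {
      sk <- runif(length(members)) < 0.5
      vg[sk] <- vskew
    }
    rows[[g]] <- data.frame(
      cdr3_aa = members, v_gene = vg, group = g, label = lab, motif = motif,
      base_freq = runif(length(members), spec$carrier_freq[1],
                        spec$carrier_freq[2]),
      stringsAsFactors = FALSE)
  }
  mem <- do.call(rbind, rows)
  # convert target baseline frequencies to pool weights
  w_bg <- sum(pool$base_weight)
  mem$base_weight <- mem$base_freq * w_bg / (1 - sum(mem$base_freq))
  pool_out <- rbind(pool,
                    mem[, c("cdr3_aa", "v_gene", "base_weight")])
  truth <- mem[, c("cdr3_aa", "group", "label", "motif", "base_freq")]
  rownames(truth) <- NULL
  class(truth) <- c("synthetic_truth", "data.frame")
  list(pool = pool_out, truth = truth)
}

#' Draw one sample for a condition
#'
#' Expected frequencies are the base pool weights multiplied by the spec's
#' expansion factor for group members responsive in this condition (direct
#' and shared groups in `"direct"` conditions, indirect and shared groups in
#' `"indirect"` conditions, nothing in controls), renormalized; counts are a
#' multinomial draw at the spec's depth. The per-sample seed is derived from
#' the master seed, the condition index and the replicate number.
#'
#' @param pool augmented pool from [plant_groups()].
#' @param truth the matching `"synthetic_truth"` table.
#' @param condition a condition label from `spec$conditions`.
#' @param spec the [simulation_spec()].
#' @param replicate replicate number (1-based).
#' @return A [repertoire] named `<condition>_<replicate>`.
#' @export
sample_condition <- function(pool, truth, condition, spec, replicate = 1) {
  ci <- match(condition, names(spec$conditions))
  if (is.na(ci)) stop("unknown condition: ", condition)
  set.seed(spec$seed + 1000L + 97L * ci + replicate)
  role <- spec$conditions[[ci]]
  fac <- rep(1, nrow(pool))
  if (role %in% c("direct", "indirect")) {
    resp <- truth$cdr3_aa[truth$label %in% c(role, "shared")]
    fac[pool$cdr3_aa %in% resp] <- spec$expansion_factor
  }
  prob <- pool$base_weight * fac
  counts <- as.vector(rmultinom(1, spec$depth, prob))
  nz <- counts > 0
  repertoire(pool$cdr3_aa[nz], counts[nz], v_gene = pool$v_gene[nz],
             sample_id = paste0(condition, "_", replicate),
             condition = condition)
}

#' Simulate a full multi-sample scenario
#'
#' @param spec a [simulation_spec()].
#' @return Object of class `"tcr_scenario"`: list with `repertoires` (one
#'   per condition x replicate), `truth` and `spec`.
#' @export
simulate_scenario <- function(spec) {
  bg <- generate_background(spec)
  planted <- plant_groups(bg, spec)
  reps <- list()
  for (cond in names(spec$conditions)) {
    for (r in seq_len(spec$replicates)) {
      rep_ <- sample_condition(planted$pool, planted$truth, cond, spec, r)
      reps[[rep_$sample_id]] <- rep_
    }
  }
  structure(list(repertoires = reps, truth = planted$truth, spec = spec),
            class = "tcr_scenario")
}

#' @export
print.tcr_scenario <- function(x, ...) {
  cat(sprintf("<tcr_scenario> %d samples (%s); %d planted members in %d groups; seed %d\n",
              length(x$repertoires),
              paste(names(x$spec$conditions), collapse = ", "),
              nrow(x$truth),
              length(unique(x$truth$group)), x$spec$seed))
  invisible(x)
}

#' Write a scenario to disk
#'
#' One AIRR Rearrangement TSV per sample, a `truth.tsv` table, and a
#' `manifest.yaml` mapping sample_id to path/condition/assay (consumable by
#' [read_manifest()]).
#'
#' @param scenario a `"tcr_scenario"`.
#' @param outdir output directory (created if absent).
#' @param assay assay label written to the manifest.
#' @return The manifest path, invisibly.
#' @export
write_scenario <- function(scenario, outdir, assay = "in_vitro") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  samples <- list()
  for (rep_ in scenario$repertoires) {
    fn <- paste0(rep_$sample_id, ".airr.tsv")
    write_airr(rep_, file.path(outdir, fn))
    samples[[rep_$sample_id]] <- list(path = fn,
                                      condition = rep_$condition,
                                      assay = assay)
  }
  write.table(scenario$truth, file.path(outdir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(seed = scenario$spec$seed, samples = samples)
  mpath <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Read a dataset manifest
#'
#' Loads every sample listed in a YAML manifest (paths relative to the
#' manifest location) as AIRR Rearrangement tables.
#'
#' @param path path to `manifest.yaml`.
#' @return Named list of [repertoire] objects.
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  reps <- lapply(names(man$samples), function(id) {
    s <- man$samples[[id]]
    read_airr(file.path(base, s$path), sample_id = id,
              condition = s$condition %||% NA_character_)
  })
  setNames(reps, names(man$samples))
}
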
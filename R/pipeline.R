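#' Pipeline configuration
#'
#' Assigns condition labels to analysis roles and fixes every threshold used
#' downstream. Directly alloreactive arm = conditions stimulated through the
#' direct pathway; indirectly alloreactive arm = indirect-pathway
#' conditions; controls provide both the expansion-calling baseline and the
#' unstimulated arm / enrichment reference.
#'
#' @param direct_stim condition labels of direct-pathway stimulations.
#' @param indirect_stim condition labels of indirect-pathway stimulations.
#' @param control control condition labels (nonempty).
#' @param posterior posterior-likelihood threshold for expansion calls.
#' @param folds expansion multiplicity bins (sorted).
#' @param expansion_fold fold bin defining "expanded" clonotypes for the
#'   arm repertoires (2, per the twofold-expansion convention).
#' @param min_support,k_range,trim,min_fold,alpha pattern-discovery settings
#'   (see [discover_patterns()]).
#' @param min_cluster cluster-size threshold for [cluster_stats()].
#' @param unstim_top number of most abundant pooled control clonotypes
#'   forming the unstimulated arm.
#' @param subtract_unstim remove unstimulated-arm patterns from the
#'   exclusive sets (see [pattern_set_algebra()]).
#' @param seed seed for the stochastic stages (prior subsampling).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(direct_stim = "BlL0", indirect_stim = "BaLBl",
                       control = c("BaL0", "BaLBa"),
                       posterior = 0.95, folds = c(2, 4, 8, 16, 32),
                       expansion_fold = 2, min_support = 3, k_range = 4:7,
                       trim = c(3, 2), min_fold = 10, alpha = 1e-3,
                       min_cluster = 5, unstim_top = 1500,
                       subtract_unstim = TRUE, seed = 1) {
  if (!length(control)) stop("configuration error: control set is empty")
  if (is.unsorted(folds)) stop("configuration error: fold thresholds must be sorted")
  structure(as.list(environment()), class = "run_config")
}

# distinct condition labels contributing each key, over the given repertoires
.key_conditions <- function(reps, keys) {
  df <- do.call(rbind, lapply(reps, function(r)
    data.frame(key = repertoire_keys(r), condition = as.character(r$condition),
               stringsAsFactors = FALSE)))
  df <- unique(df[df$key %in% keys, , drop = FALSE])
  split(df$condition, df$key)
}

#' Run the full alloreactive-repertoire analysis
#'
#' Stages, in order: count matrix -> TMM normalization -> expansion calling
#' per arm against the pooled controls -> Morisita-Horn overlap grid across
#' expansion thresholds -> pooled arm repertoires of twofold-expanded
#' clonotypes -> Hamming-distance CDR3 graphs and cluster statistics ->
#' specificity-pattern discovery per arm against the pooled control
#' reference -> exclusive pattern-set algebra -> clonotype classification ->
#' repertoire features (frequency statistics, V usage and cosine
#' similarities, spectratypes, positional profiles) -> optional specificity
#' database annotation. The configuration and seed are carried in the
#' result; rerunning with the same inputs and config is deterministic.
#'
#' Pattern discovery in every arm, including the unstimulated one, tests
#' enrichment against the same reference. By default the reference is the
#' full pooled control repertoire — the unstimulated arm (its most abundant
#' subset) can then only report motifs genuinely concentrated among abundant
#' control clonotypes, i.e. convergent public expansions. Supplying
#' `naive_reference` (e.g. clonotypes of unrelated naive animals) replaces
#' the reference for all arms.
#'
#' @param reps list of [repertoire] objects (all samples).
#' @param config a [run_config()].
#' @param db optional `"specificity_db"` for the annotation stage.
#' @param naive_reference optional character vector of reference CDR3s
#'   replacing the pooled-control enrichment reference.
#' @return Object of class `"allorep_run"` with one element per stage.
#' @export
run_pipeline <- function(reps, config = run_config(), db = NULL,
                         naive_reference = NULL) {
  conds <- vapply(reps, function(r) as.character(r$condition), character(1))
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  samples_of <- function(condset) ids[conds %in% condset]
  for (role in c("direct_stim", "indirect_stim", "control")) {
    if (!length(samples_of(config[[role]])))
      stop("configuration error: no samples for role ", role,
           " (conditions ", paste(config[[role]], collapse = ", "), ")")
  }

  mat <- build_count_matrix(reps)
  norm <- tmm_normalize(mat)

  calls_direct <- call_expansions(
    norm, stim = samples_of(config$direct_stim),
    ctrl = samples_of(config$control),
    posterior_threshold = config$posterior, fold_thresholds = config$folds,
    seed = config$seed)
  calls_indirect <- call_expansions(
    norm, stim = samples_of(config$indirect_stim),
    ctrl = samples_of(config$control),
    posterior_threshold = config$posterior, fold_thresholds = config$folds,
    seed = config$seed + 1L)

  calls_by_sample <- setNames(vector("list", length(ids)), ids)
  for (id in samples_of(config$direct_stim)) calls_by_sample[[id]] <- calls_direct
  for (id in samples_of(config$indirect_stim)) calls_by_sample[[id]] <- calls_indirect
  overlap <- overlap_grid(reps, calls = calls_by_sample,
                          thresholds = c(1, config$folds))

  # pooled arm repertoires of expanded clonotypes; unstimulated arm = most
  # abundant pooled control clonotypes
  arm_reps <- function(condset) reps[conds %in% condset]
  direct_pool <- pool_repertoires(arm_reps(config$direct_stim), "direct_arm")
  indirect_pool <- pool_repertoires(arm_reps(config$indirect_stim), "indirect_arm")
  unstim_pool <- pool_repertoires(arm_reps(config$control), "unstim_pool")
  direct_rep <- restrict_repertoire(direct_pool,
                                    expanded_keys(calls_direct, config$expansion_fold))
  indirect_rep <- restrict_repertoire(indirect_pool,
                                      expanded_keys(calls_indirect, config$expansion_fold))
  n_top <- min(config$unstim_top, nrow(unstim_pool$clonotypes))
  unstim_rep <- restrict_repertoire(
    unstim_pool, head(unstim_pool$clonotypes$cdr3_aa, n_top))

  graphs <- lapply(list(direct = direct_rep, indirect = indirect_rep,
                        unstim = unstim_rep), function(r) {
    g <- build_cdr3_graph(r$clonotypes$cdr3_aa, r$clonotypes$count)
    list(graph = g, stats = cluster_stats(g, min_size = config$min_cluster,
                                          display_min = config$min_cluster))
  })

  reference <- if (is.null(naive_reference))
    unstim_pool$clonotypes$cdr3_aa else naive_reference
  disc <- function(arm_rep, condset) {
    cdr3 <- arm_rep$clonotypes$cdr3_aa
    discover_patterns(
      cdr3, reference = reference,
      conditions = .key_conditions(arm_reps(condset), cdr3),
      k_range = config$k_range, trim = config$trim,
      min_support = config$min_support, min_fold = config$min_fold,
      alpha = config$alpha)
  }
  patterns <- list(
    direct = disc(direct_rep, config$direct_stim),
    indirect = disc(indirect_rep, config$indirect_stim),
    unstim = disc(unstim_rep, config$control))
  sets <- pattern_set_algebra(patterns$direct, patterns$indirect,
                              patterns$unstim,
                              subtract_unstim = config$subtract_unstim)

  union_cdr3 <- unique(c(direct_rep$clonotypes$cdr3_aa,
                         indirect_rep$clonotypes$cdr3_aa))
  classification <- assign_clonotypes(union_cdr3, sets)
  direct_keys <- classification$key[classification$label == "direct"]
  indirect_keys <- classification$key[classification$label == "indirect"]

  freq <- list()
  for (id in samples_of(c(config$direct_stim, config$indirect_stim))) {
    r <- reps[[match(id, ids)]]
    is_direct <- conds[match(id, ids)] %in% config$direct_stim
    labeled <- if (is_direct) direct_keys else indirect_keys
    cls <- if (is_direct) calls_direct else calls_indirect
    rk <- repertoire_keys(r)
    freq[[id]] <- frequency_stats(
      r, intersect(labeled, rk),
      comparator_keys = intersect(expanded_keys(cls, config$expansion_fold), rk))
  }

  subsets <- list(
    direct = restrict_repertoire(direct_rep, direct_keys),
    indirect = restrict_repertoire(indirect_rep, indirect_keys),
    unstim = unstim_rep)
  genes <- sort(unique(unlist(lapply(subsets, function(r) r$clonotypes$v_gene))))
  usage <- lapply(subsets, v_usage, genes = genes)
  cosine <- outer(seq_along(usage), seq_along(usage),
                  Vectorize(function(i, j) cosine_similarity(usage[[i]], usage[[j]])))
  dimnames(cosine) <- list(names(usage), names(usage))
  features <- list(
    frequency = freq,
    v_usage = usage,
    cosine = cosine,
    spectratype = lapply(subsets, spectratype),
    positional = lapply(subsets, positional_profile, L = 14))

  annotation <- if (!is.null(db)) lapply(subsets, annotate_clonotypes, db = db)

  structure(
    list(config = config, norm = norm,
         calls = list(direct = calls_direct, indirect = calls_indirect),
         overlap = overlap, arms = subsets,
         graphs = graphs, patterns = patterns, sets = sets,
         classification = classification, features = features,
         annotation = annotation),
    class = "allorep_run"
  )
}

#' @export
print.allorep_run <- function(x, ...) {
  cn <- x$sets$counts
  cat("<allorep_run>\n")
  cat(sprintf("  expansion: %d direct / %d indirect clonotypes at >= %dx\n",
              sum(x$calls$direct$max_bin >= x$config$expansion_fold),
              sum(x$calls$indirect$max_bin >= x$config$expansion_fold),
              x$config$expansion_fold))
  cat(sprintf("  patterns: %d direct, %d indirect, %d unstim; %d shared; exclusive %d / %d\n",
              cn$direct, cn$indirect, cn$unstim, cn$shared_incl_unstim,
              cn$direct_exclusive, cn$indirect_exclusive))
  cat(sprintf("  classification: %d direct, %d indirect, %d ambiguous of %d clonotypes\n",
              sum(x$classification$label == "direct"),
              sum(x$classification$label == "indirect"),
              sum(x$classification$label == "ambiguous"),
              nrow(x$classification)))
  for (arm in names(x$graphs)) {
    s <- x$graphs[[arm]]$stats
    cat(sprintf("  %s graph: %d large clusters, edges/vertices %s\n",
                arm, s$n_large_clusters,
                format(round(s$edges_vertices_ratio, 3))))
  }
  invisible(x)
}
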
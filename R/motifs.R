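#' Enumerate local CDR3 motifs
#'
#' Contiguous k-mers from the paratope-facing region of each CDR3: positions
#' `trim[1] + 1` through `L - trim[2]` (1-based over the full loop including
#' the conserved C and F). The default trim of 3 N-terminal and 2 C-terminal
#' residues removes the germline-encoded loop stems. A CDR3 whose trimmed
#' region is shorter than k contributes nothing at that k.
#'
#' @param cdr3 CDR3 amino-acid sequences.
#' @param keys clonotype keys, one per sequence (default the sequences).
#' @param k_range motif lengths to enumerate.
#' @param trim integer pair: residues trimmed from the N and C termini.
#' @return Named list mapping each motif to the distinct clonotype keys
#'   whose trimmed region contains it.
#' @export
enumerate_motifs <- function(cdr3, keys = cdr3, k_range = 4:7, trim = c(3, 2)) {
  lo <- trim[1] + 1L
  L <- nchar(cdr3)
  reg_len <- L - trim[2] - trim[1]
  motif <- character(0)
  key <- character(0)
  for (k in k_range) {
    nk <- pmax(reg_len - k + 1L, 0L)
    use <- nk > 0L
    if (!any(use)) next
    idx <- rep(which(use), nk[use])
    starts <- unlist(lapply(nk[use], seq_len)) + lo - 2L
    motif <- c(motif, substring(cdr3[idx], starts + 1L, starts + k))
    key <- c(key, keys[idx])
  }
  if (!length(motif)) return(list())
  df <- unique(data.frame(motif = motif, key = key, stringsAsFactors = FALSE))
  split(df$key, df$motif)
}

#' Enumerate global templates
#'
#' Groups of same-length CDR3s identical everywhere except at one position of
#' the trimmed region form a template with a `%` wildcard at that position
#' (e.g. `CASSLG%QYF`) — the single-substitution "global similarity" pattern.
#' Positions inside the trimmed stems are never wildcarded.
#'
#' @inheritParams enumerate_motifs
#' @return Named list mapping each template to the distinct member keys.
#' @export
global_templates <- function(cdr3, keys = cdr3, trim = c(3, 2)) {
  out <- list()
  lens <- nchar(cdr3)
  for (L in unique(lens)) {
    sel <- lens == L
    s <- cdr3[sel]; k <- keys[sel]
    positions <- seq(trim[1] + 1L, L - trim[2])
    if (length(s) < 2 || !length(positions)) next
    for (p in positions) {
      mask <- paste0(substr(s, 1, p - 1), "%", substr(s, p + 1, L))
      groups <- split(seq_along(s), mask)
      groups <- groups[vapply(groups, function(i)
        length(unique(substr(s[i], p, p))) > 1, logical(1))]
      for (tmpl in names(groups)) {
        out[[tmpl]] <- sort(unique(c(out[[tmpl]], k[groups[[tmpl]]])))
      }
    }
  }
  out
}

#' One-sided enrichment test for a motif
#'
#' Fisher's exact test (upper hypergeometric tail) on the 2x2 table
#' `(a, n-a; b, m-b)`: `a` of `n` sample clonotypes versus `b` of `m`
#' reference clonotypes carry the motif. Fold change is `(a/n) / (b/m)`; a
#' pseudocount of 0.5 is added to `b` only when `b = 0`. Vectorized over
#' `a` and `b`.
#'
#' @param a motif-positive clonotypes in the sample.
#' @param n total sample clonotypes.
#' @param b motif-positive clonotypes in the reference.
#' @param m total reference clonotypes.
#' @param min_support minimum distinct member clonotypes.
#' @param min_fold minimum fold enrichment.
#' @param alpha significance level.
#' @param pseudocount applied to `b` when zero.
#' @return Data frame with `p_value`, `fold`, `pass`.
#' @export
test_enrichment <- function(a, n, b, m, min_support = 3, min_fold = 10,
                            alpha = 1e-3, pseudocount = 0.5) {
  if (n <= 0 || m <= 0) stop("n and m must be positive")
  if (any(a > n) || any(b > m)) stop("motif counts exceed totals")
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  p <- phyper(a - 1, a + b, n + m - a - b, n, lower.tail = FALSE)
  bb <- ifelse(b == 0, pseudocount, b)
  fold <- (a / n) / (bb / m)
  data.frame(p_value = p, fold = fold,
             pass = a >= min_support & fold >= min_fold & p <= alpha)
}

#' Discover specificity patterns (local motifs and global templates)
#'
#' GLIPH2-style pattern discovery: local k-mer motifs (lengths 4-7 by
#' default) and single-wildcard global templates are enumerated from the
#' trimmed CDR3 region, and each candidate is tested for enrichment against
#' a reference clonotype set with a one-sided Fisher exact test. A pattern
#' is reported when it has at least `min_support` distinct member
#' clonotypes, at least `min_fold` fold enrichment and `p <= alpha`. With
#' `enrich = FALSE` (e.g. when the sample IS the reference, as for an
#' unstimulated arm) patterns are reported on support alone.
#'
#' @param cdr3 sample CDR3 sequences (distinct clonotypes).
#' @param reference reference CDR3 sequences (distinct clonotypes).
#' @param keys clonotype keys for the sample sequences.
#' @param conditions optional named vector/list mapping keys to the condition
#'   label(s) their carriers came from; populates `source_conditions`.
#' @param k_range,trim see [enumerate_motifs()].
#' @param min_support,min_fold,alpha reporting thresholds.
#' @param kinds which pattern kinds to discover.
#' @param enrich apply the enrichment filter (fold and p-value).
#' @return An object of classes `"specificity_patterns"` and `"data.frame"`:
#'   columns `kind`, `pattern`, `support`, `fold`, `p_value`, plus list
#'   columns `members` and `source_conditions`.
#' @export
discover_patterns <- function(cdr3, reference, keys = cdr3, conditions = NULL,
                              k_range = 4:7, trim = c(3, 2),
                              min_support = 3, min_fold = 10, alpha = 1e-3,
                              kinds = c("local", "global"), enrich = TRUE) {
  reference <- unique(reference)
  n <- length(unique(keys))
  m <- length(reference)
  if (n == 0) stop("empty sample clonotype set")

  collect <- function(kind, cand, ref_counts) {
    support <- lengths(cand)
    keep <- support >= min_support
    cand <- cand[keep]; support <- support[keep]
    if (!length(cand)) return(NULL)
    b <- ref_counts[names(cand)]
    b[is.na(b)] <- 0
    if (enrich) {
      res <- test_enrichment(support, n, b, m, min_support = min_support,
                             min_fold = min_fold, alpha = alpha)
      sel <- res$pass
    } else {
      res <- data.frame(p_value = NA_real_, fold = NA_real_,
                        pass = rep(TRUE, length(cand)))
      sel <- res$pass
    }
    if (!any(sel)) return(NULL)
    out <- data.frame(kind = kind, pattern = names(cand)[sel],
                      support = support[sel], fold = res$fold[sel],
                      p_value = res$p_value[sel], stringsAsFactors = FALSE)
    out$members <- unname(cand[sel])
    out
  }

  parts <- list()
  if ("local" %in% kinds) {
    cand <- enumerate_motifs(cdr3, keys, k_range = k_range, trim = trim)
    refm <- enumerate_motifs(reference, k_range = k_range, trim = trim)
    parts$local <- collect("local", cand, lengths(refm))
  }
  if ("global" %in% kinds) {
    cand <- global_templates(cdr3, keys, trim = trim)
    reft <- global_templates(reference, trim = trim)
    # a reference sequence matches a template iff it shares the mask, with
    # any residue at the wildcard; count mask occupancy, not just variable
    # reference groups
    ref_counts <- .template_ref_counts(reference, names(cand), trim)
    parts$global <- collect("global", cand, ref_counts)
  }
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(kind = character(), pattern = character(),
                      support = integer(), fold = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
    out$members <- list()
  }
  rownames(out) <- NULL
  out$source_conditions <- lapply(out$members, function(mem) {
    if (is.null(conditions)) character(0)
    else sort(unique(unlist(conditions[mem], use.names = FALSE)))
  })
  structure(out, class = c("specificity_patterns", "data.frame"),
            n_sample = n, n_reference = m,
            params = list(k_range = k_range, trim = trim,
                          min_support = min_support, min_fold = min_fold,
                          alpha = alpha, enrich = enrich))
}

# number of distinct reference sequences matching each wildcard template
.template_ref_counts <- function(reference, templates, trim) {
  if (!length(templates)) return(integer(0))
  counts <- setNames(integer(length(templates)), templates)
  tl <- nchar(templates)
  lens <- nchar(reference)
  for (L in unique(tl)) {
    tt <- templates[tl == L]
    refL <- reference[lens == L]
    if (!length(refL)) next
    pos <- regexpr("%", tt, fixed = TRUE)
    for (p in unique(pos)) {
      masks <- paste0(substr(refL, 1, p - 1), "%", substr(refL, p + 1, L))
      tab <- table(masks)
      sel <- tt[pos == p]
      hit <- tab[sel]
      hit[is.na(hit)] <- 0
      counts[sel] <- as.integer(hit)
    }
  }
  counts
}

#' @export
print.specificity_patterns <- function(x, ...) {
  cat(sprintf("<specificity_patterns> %d patterns (%d local, %d global); sample n=%d vs reference m=%d\n",
              nrow(x), sum(x$kind == "local"), sum(x$kind == "global"),
              attr(x, "n_sample"), attr(x, "n_reference")))
  invisible(x)
}

#' Exclusive pattern-set algebra between conditions
#'
#' Patterns found in both the directly and indirectly alloreactive arms are
#' of unknown pathway origin, so they are excluded from BOTH exclusive sets;
#' with `subtract_unstim = TRUE` patterns also present in the unstimulated
#' arm are removed as well (public background). Pattern identity is the
#' `(kind, pattern)` pair.
#'
#' @param direct,indirect,unstim `"specificity_patterns"` objects (`unstim`
#'   may be `NULL`).
#' @param subtract_unstim remove unstimulated-arm patterns from the
#'   exclusive sets.
#' @return An object of class `"pattern_sets"`: the inputs plus `shared_di`,
#'   `direct_exclusive`, `indirect_exclusive` and a `counts` list.
#' @export
pattern_set_algebra <- function(direct, indirect, unstim = NULL,
                                subtract_unstim = TRUE) {
  pid <- function(x) if (is.null(x) || !nrow(x)) character(0) else
    paste(x$kind, x$pattern)
  d_id <- pid(direct); i_id <- pid(indirect); u_id <- pid(unstim)
  shared <- intersect(d_id, i_id)
  shared_incl_unstim <- shared
  drop_d <- d_id %in% shared
  drop_i <- i_id %in% shared
  if (subtract_unstim && length(u_id)) {
    drop_d <- drop_d | d_id %in% u_id
    drop_i <- drop_i | i_id %in% u_id
    shared <- setdiff(shared, u_id)
  }
  structure(
    list(direct = direct, indirect = indirect, unstim = unstim,
         shared_di = direct[d_id %in% shared_incl_unstim, , drop = FALSE],
         direct_exclusive = direct[!drop_d, , drop = FALSE],
         indirect_exclusive = indirect[!drop_i, , drop = FALSE],
         counts = list(
           direct = length(d_id), indirect = length(i_id),
           unstim = length(u_id),
           shared_excl_unstim = length(shared),
           shared_incl_unstim = length(shared_incl_unstim),
           direct_exclusive = sum(!drop_d),
           indirect_exclusive = sum(!drop_i)),
         subtract_unstim = subtract_unstim),
    class = "pattern_sets"
  )
}

#' @export
print.pattern_sets <- function(x, ...) {
  cn <- x$counts
  cat(sprintf("<pattern_sets> direct %d, indirect %d, unstim %d; shared %d (%d incl. unstim); exclusive %d / %d\n",
              cn$direct, cn$indirect, cn$unstim, cn$shared_excl_unstim,
              cn$shared_incl_unstim, cn$direct_exclusive, cn$indirect_exclusive))
  invisible(x)
}

# logical: which of cdr3 match at least one pattern in df
.match_patterns <- function(df, cdr3) {
  hit <- rep(FALSE, length(cdr3))
  if (is.null(df) || !nrow(df)) return(hit)
  for (r in seq_len(nrow(df))) {
    if (df$kind[r] == "local") {
      hit <- hit | grepl(df$pattern[r], cdr3, fixed = TRUE)
    } else {
      rx <- paste0("^", gsub("%", ".", df$pattern[r], fixed = TRUE), "$")
      hit <- hit | grepl(rx, cdr3)
    }
  }
  hit
}

#' Classify clonotypes by exclusive specificity patterns
#'
#' A clonotype is labeled `direct` (`indirect`) when its CDR3 contains at
#' least one directly (indirectly) exclusive pattern. Clonotypes matching
#' patterns of both arms are labeled `ambiguous` and excluded from both —
#' the clonotype-level extension of the pattern-level exclusion — and their
#' count is reported via a message and `attr(x, "n_ambiguous")`.
#'
#' @param cdr3 CDR3 sequences to classify.
#' @param sets a `"pattern_sets"` object.
#' @param keys clonotype keys (default the sequences).
#' @return Data frame with `key`, `cdr3_aa` and
#'   `label` in `c("direct", "indirect", "ambiguous", "none")`.
#' @export
assign_clonotypes <- function(cdr3, sets, keys = cdr3) {
  hd <- .match_patterns(sets$direct_exclusive, cdr3)
  hi <- .match_patterns(sets$indirect_exclusive, cdr3)
  label <- ifelse(hd & hi, "ambiguous",
           ifelse(hd, "direct", ifelse(hi, "indirect", "none")))
  n_amb <- sum(label == "ambiguous")
  if (n_amb > 0)
    message(n_amb, " clonotype(s) matched both arms and were excluded as ambiguous")
  structure(data.frame(key = keys, cdr3_aa = cdr3, label = label,
                       stringsAsFactors = FALSE),
            n_ambiguous = n_amb)
}

#' Sample-of-origin accounting for patterns
#'
#' How many distinct conditions contributed members to each pattern —
#' patterns fed by two or three conditions indicate that in vitro and
#' in vivo models of the same pathway converge on the same predicted pMHC.
#'
#' @param patterns a `"specificity_patterns"` object with populated
#'   `source_conditions`.
#' @return List with `per_pattern` (kind, pattern, n_origins) and
#'   `histogram` (table over the number of contributing conditions; sums to
#'   the number of patterns).
#' @export
cluster_origins <- function(patterns) {
  n_origins <- lengths(patterns$source_conditions)
  per <- data.frame(kind = patterns$kind, pattern = patterns$pattern,
                    n_origins = n_origins, stringsAsFactors = FALSE)
  hist <- table(factor(n_origins, levels = seq_len(max(c(n_origins, 1)))))
  list(per_pattern = per, histogram = hist)
}
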
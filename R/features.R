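#' Frequency statistics of a labeled clonotype subset
#'
#' Compares the within-sample frequencies of a labeled clonotype set (e.g.
#' clonotypes matching directly alloreactive patterns) with a comparator set
#' from the same repertoire — conventionally the whole repertoire restricted
#' by the same 2x expansion threshold that produced the labels. Reports the
#' summed frequency, the ratio of median frequencies, and a two-sided
#' Mann-Whitney U test on log10 frequencies (exact for small samples without
#' ties, normal approximation with tie correction otherwise, as
#' [stats::wilcox.test()] chooses).
#'
#' @param rep a [repertoire].
#' @param labeled_keys clonotype keys of the labeled subset (must be a
#'   subset of the repertoire's keys).
#' @param comparator_keys keys of the comparator set; defaults to the whole
#'   repertoire.
#' @return List of class `"frequency_stats"` with `sum_frequency`,
#'   `median_ratio`, `mw_p`, `n_labeled`, `n_comparator`.
#' @export
frequency_stats <- function(rep, labeled_keys, comparator_keys = NULL) {
  kv <- isTRUE(attr(rep, "key_by_v"))
  keys <- clonotype_key(rep$clonotypes, kv)
  if (!all(labeled_keys %in% keys))
    stop("labeled clonotypes must be a subset of the repertoire")
  if (is.null(comparator_keys)) comparator_keys <- keys
  lf <- rep$clonotypes$frequency[keys %in% labeled_keys]
  cf <- rep$clonotypes$frequency[keys %in% comparator_keys]
  lf <- lf[lf > 0]; cf <- cf[cf > 0]
  mw <- if (length(lf) && length(cf))
    suppressWarnings(wilcox.test(log10(lf), log10(cf))$p.value) else NA_real_
  structure(
    list(sum_frequency = sum(lf),
         median_ratio = if (length(cf) && median(cf) > 0)
           median(lf) / median(cf) else NA_real_,
         mw_p = mw, n_labeled = length(lf), n_comparator = length(cf)),
    class = "frequency_stats"
  )
}

#' @export
print.frequency_stats <- function(x, ...) {
  cat(sprintf("<frequency_stats> sum freq %.4f; median ratio %.3f; MW p = %.3g (n = %d vs %d)\n",
              x$sum_frequency, x$median_ratio, x$mw_p, x$n_labeled, x$n_comparator))
  invisible(x)
}

#' V-gene usage vector
#'
#' Relative V-gene usage, weighting each clonotype once (`"clonotype"`,
#' matching statements about numbers of clones) or by read count
#' (`"read"`). When a fixed `genes` ordering is supplied, genes outside it
#' are pooled into `"other"`.
#'
#' @param x a [repertoire] or a clonotype data frame with `v_gene` (and
#'   `count`) columns.
#' @param genes optional fixed gene ordering shared across samples.
#' @param weighting `"clonotype"` or `"read"`.
#' @return Named numeric vector summing to 1 (all zeros if empty input).
#' @export
v_usage <- function(x, genes = NULL, weighting = c("clonotype", "read")) {
  weighting <- match.arg(weighting)
  df <- if (inherits(x, "repertoire")) x$clonotypes else x
  if (!nrow(df)) {
    if (is.null(genes)) return(numeric(0))
    return(setNames(rep(0, length(genes) + 1), c(genes, "other")))
  }
  w <- if (weighting == "read") df$count else rep(1, nrow(df))
  tab <- tapply(w, df$v_gene, sum)
  u <- as.numeric(tab); names(u) <- names(tab)
  if (!is.null(genes)) {
    out <- setNames(rep(0, length(genes) + 1), c(genes, "other"))
    known <- names(u) %in% genes
    out[names(u)[known]] <- u[known]
    out["other"] <- sum(u[!known])
    u <- out
  }
  u / sum(u)
}

#' Cosine similarity between usage vectors
#'
#' Symmetric and invariant to rescaling; 1 iff the vectors are proportional,
#' 0 for disjoint supports. Named vectors are aligned on the union of names.
#'
#' @param u,v non-negative numeric vectors.
#' @return Value in \[0, 1\], or `NA` if either vector is all zero.
#' @export
cosine_similarity <- function(u, v) {
  if (!is.null(names(u)) && !is.null(names(v))) {
    keys <- union(names(u), names(v))
    u <- setNames(u[keys], keys); u[is.na(u)] <- 0
    v <- setNames(v[keys], keys); v[is.na(v)] <- 0
  }
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' CDR3 length spectratype
#'
#' Histogram of CDR3 amino-acid lengths over distinct clonotypes, plus the
#' long/short ratio: clonotypes longer than `split` residues over clonotypes
#' of at most `split` residues (default split at 14 aa, where a sharp
#' depletion of long loops marks directly alloreactive repertoires).
#'
#' @param x a [repertoire] or a character vector of CDR3 sequences.
#' @param split length split in amino acids.
#' @return Object of class `"spectratype"`: list with `counts` (named by
#'   length) and `long_short_ratio` (`NA` for empty input).
#' @export
spectratype <- function(x, split = 14) {
  cdr3 <- if (inherits(x, "repertoire")) x$clonotypes$cdr3_aa else x
  if (!length(cdr3))
    return(structure(list(counts = table(integer(0)),
                          long_short_ratio = NA_real_),
                     class = "spectratype"))
  len <- nchar(cdr3)
  counts <- table(len)
  n_short <- sum(len <= split)
  ratio <- if (n_short > 0) sum(len > split) / n_short else NA_real_
  structure(list(counts = counts, long_short_ratio = ratio,
                 split = split), class = "spectratype")
}

#' @export
print.spectratype <- function(x, ...) {
  cat(sprintf("<spectratype> %d clonotypes; long(>%d)/short ratio %s\n",
              sum(x$counts), x$split %||% 14,
              format(round(x$long_short_ratio, 3))))
  print(x$counts)
  invisible(x)
}

#' @export
plot.spectratype <- function(x, ...) {
  graphics::barplot(x$counts, xlab = "CDR3 length (aa)",
                    ylab = "clonotypes", ...)
  invisible(x)
}

#' Positional amino-acid occurrence probabilities
#'
#' For clonotypes of exactly length `L`, the L x 20 matrix of per-position
#' amino-acid relative frequencies (each clonotype counted once; rows sum
#' to 1). Positions are 1-based over the full CDR3 including the conserved
#' C and F.
#'
#' @param x a [repertoire] or character vector of CDR3 sequences.
#' @param L CDR3 length analyzed (default 14, the modal mouse TRB length).
#' @return L x 20 matrix, rows `pos1..posL`, columns the amino acids.
#' @export
positional_profile <- function(x, L = 14) {
  cdr3 <- if (inherits(x, "repertoire")) x$clonotypes$cdr3_aa else x
  cdr3 <- unique(cdr3[nchar(cdr3) == L])
  mat <- matrix(0, nrow = L, ncol = length(AA_ALPHABET),
                dimnames = list(paste0("pos", seq_len(L)), AA_ALPHABET))
  if (!length(cdr3)) return(mat)
  for (p in seq_len(L)) {
    tab <- table(factor(substr(cdr3, p, p), levels = AA_ALPHABET))
    mat[p, ] <- as.numeric(tab) / length(cdr3)
  }
  mat
}
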
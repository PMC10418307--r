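#' TMM normalization factors
#'
#' Trimmed mean of M-values (Robinson & Oshlack): for each sample, log2
#' count-per-total ratios against a reference sample are doubly trimmed (30%
#' of the most extreme M log-ratios and 5% of the most extreme A average
#' abundances, each side) and averaged with asymptotic precision weights.
#' Factors are rescaled so their geometric mean is 1; relative library
#' composition, not depth, is corrected.
#'
#' @param mat clonotype x sample count matrix ([build_count_matrix()]).
#' @param ref reference sample id or column index; by default the sample
#'   whose 75th percentile of count-per-total is closest to the mean.
#' @param logratio_trim fraction of M values trimmed from each tail (0.30).
#' @param sum_trim fraction of A values trimmed from each tail (0.05).
#' @param do_weighting use inverse asymptotic-variance weights.
#' @return Named vector of positive scale factors, geometric mean 1.
#' @export
tmm_factors <- function(mat, ref = NULL, logratio_trim = 0.3, sum_trim = 0.05,
                        do_weighting = TRUE) {
  if (ncol(mat) < 2) stop("TMM needs at least two samples")
  lib <- colSums(mat)
  if (any(lib <= 0)) stop("every sample must have a positive total count")
  if (is.null(ref)) {
    f75 <- apply(mat, 2, function(x) quantile(x / sum(x), 0.75))
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref)) {
    ref <- match(ref, colnames(mat))
    if (is.na(ref)) stop("unknown reference sample")
  }
  r <- mat[, ref]
  nR <- lib[ref]
  f <- vapply(seq_len(ncol(mat)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(mat[, j], r, lib[j], nR, logratio_trim, sum_trim, do_weighting,
              colnames(mat)[j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(mat))
}

.tmm_pair <- function(obs, ref, nO, nR, logratio_trim, sum_trim, do_weighting,
                      label) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    warning(sprintf("sample %s shares no nonzero clonotypes with the reference; factor set to 1",
                    label), call. = FALSE)
    return(1)
  }
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / nO) / (r / nR))
  A <- (log2(o / nO) + log2(r / nR)) / 2
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1;      hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep2)) return(1)
  w <- if (do_weighting) {
    1 / ((nO - o) / (nO * o) + (nR - r) / (nR * r))
  } else rep(1, n)
  2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
}

#' TMM-normalize a count matrix
#'
#' @param mat clonotype x sample count matrix.
#' @param ... passed to [tmm_factors()].
#' @return An object of class `"tmm_norm"`: list with `counts`, `factors`
#'   and `effective_lib_size` (total count times factor, per sample).
#' @export
tmm_normalize <- function(mat, ...) {
  f <- tmm_factors(mat, ...)
  structure(
    list(counts = mat, factors = f,
         effective_lib_size = colSums(mat) * f,
         conditions = attr(mat, "conditions")),
    class = "tmm_norm"
  )
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat(sprintf("<tmm_norm> %d clonotypes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(round(x$factors, 4))
  invisible(x)
}

#' Counts-per-million on the TMM-normalized scale
#'
#' @param norm a `"tmm_norm"` object.
#' @return Matrix of counts scaled by effective library size, times 1e6.
#' @export
normalized_cpm <- function(norm) {
  sweep(norm$counts, 2, norm$effective_lib_size, "/") * 1e6
}
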
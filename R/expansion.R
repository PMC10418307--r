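#' Call fold-expanded clonotypes with an empirical-Bayes negative-binomial model
#'
#' For each clonotype the counts across samples are modeled as negative
#' binomial with sample means proportional to effective library size. Two
#' models are scored: H0, one shared relative abundance across all samples;
#' H1, separate abundances for the stimulated and control groups. Marginal
#' likelihoods are obtained by discrete quadrature (equal-weight averaging)
#' over an empirical prior of (abundance, dispersion) points estimated from a
#' random subsample of clonotypes; under H1 each group averages over its own
#' group-wise abundance estimates. The proportion of differentially abundant
#' clonotypes is re-estimated iteratively from the mean posterior, and
#' `posterior_de = P(H1 | data)` is reported. A clonotype is assigned fold
#' bins (2, 4, 8, 16, 32 by default) only when `posterior_de` exceeds
#' `posterior_threshold` and its fold estimate — pooled stimulated over pooled
#' control normalized frequency, each pseudocounted with 0.5 reads — meets
#' the bin threshold. Bins are downward-closed by construction.
#'
#' Per-clonotype dispersions are method-of-moments estimates on counts scaled
#' to a common library size, shrunk 50/50 toward the trimmed-mean common
#' dispersion; this stabilizes the small-replicate (N = 3-5 per group)
#' designs typical of mouse TCR-seq.
#'
#' @param norm a `"tmm_norm"` object from [tmm_normalize()].
#' @param stim,ctrl disjoint, nonempty character vectors of sample ids
#'   (columns of the matrix) for the stimulated and control groups.
#' @param posterior_threshold posterior probability required to assign fold
#'   bins (0.95).
#' @param fold_thresholds expansion multiplicities defining the bins.
#' @param prior_size maximum number of clonotypes sampled for the empirical
#'   prior (at most 10000 are ever used).
#' @param n_iter iterations of prior-proportion re-estimation.
#' @param pseudocount pseudocount in reads added to pooled group counts for
#'   the fold estimate.
#' @param seed optional seed for the prior subsample, recorded in the result.
#' @return An object of classes `"expansion_calls"` and `"data.frame"` with
#'   columns `key`, `fold_estimate`, `posterior_de`, `max_bin` (0 when no bin
#'   is met) and a list column `bins`. All-zero rows are excluded.
#' @export
call_expansions <- function(norm, stim, ctrl,
                            posterior_threshold = 0.95,
                            fold_thresholds = c(2, 4, 8, 16, 32),
                            prior_size = 2000, n_iter = 10,
                            pseudocount = 0.5, seed = NULL) {
  stopifnot(inherits(norm, "tmm_norm"))
  if (!length(stim) || !length(ctrl)) stop("stim and ctrl must be nonempty")
  if (length(intersect(stim, ctrl))) stop("stim and ctrl sample sets must be disjoint")
  miss <- setdiff(c(stim, ctrl), colnames(norm$counts))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  fold_thresholds <- sort(fold_thresholds)

  Y <- norm$counts[, c(stim, ctrl), drop = FALSE]
  L <- norm$effective_lib_size[c(stim, ctrl)]
  if (sum(Y[, ctrl, drop = FALSE]) == 0)
    stop("configuration error: control samples contain no reads")
  keep <- rowSums(Y) > 0
  Y <- Y[keep, , drop = FALSE]
  n <- nrow(Y)
  iA <- seq_along(stim)
  iB <- length(stim) + seq_along(ctrl)

  # --- per-clonotype moments on the common-library-size scale -------------
  zfac <- mean(L) / L
  Z <- sweep(Y, 2, zfac, "*")
  m <- rowMeans(Z)
  v <- apply(Z, 1, var)
  phi <- pmax((v - m) / m^2, 1e-6)
  phi_common <- mean(phi[m > 0], trim = 0.2)
  phi <- 0.5 * phi + 0.5 * phi_common

  # group-wise and overall relative abundances (floored to keep prior points
  # proper when a group is all zero)
  sLA <- sum(L[iA]); sLB <- sum(L[iB])
  cA <- rowSums(Y[, iA, drop = FALSE]); cB <- rowSums(Y[, iB, drop = FALSE])
  q0 <- pmax(rowSums(Y) / sum(L), 0.25 / sum(L))
  qA <- pmax(cA / sLA, 0.25 / sLA)
  qB <- pmax(cB / sLB, 0.25 / sLB)

  # --- empirical prior ----------------------------------------------------
  if (!is.null(seed)) set.seed(seed)
  S <- min(n, prior_size, 10000L)
  idx <- if (S < n) sample.int(n, S) else seq_len(n)

  logL0 <- .nb_marginal(Y, L, q0[idx], phi[idx])
  logL1 <- .nb_marginal(Y[, iA, drop = FALSE], L[iA], qA[idx], phi[idx]) +
           .nb_marginal(Y[, iB, drop = FALSE], L[iB], qB[idx], phi[idx])

  # --- prior-proportion re-estimation ------------------------------------
  p_de <- 0.05
  post <- rep(p_de, n)
  for (it in seq_len(n_iter)) {
    post <- 1 / (1 + exp(log1p(-p_de) - log(p_de) + logL0 - logL1))
    p_de <- min(max(mean(post), 1e-6), 0.5)
  }

  fold <- ((cA + pseudocount) / sLA) / ((cB + pseudocount) / sLB)
  called <- post > posterior_threshold
  bins <- lapply(seq_len(n), function(i) {
    if (called[i]) fold_thresholds[fold[i] >= fold_thresholds] else numeric(0)
  })
  max_bin <- vapply(bins, function(b) if (length(b)) max(b) else 0, numeric(1))

  out <- data.frame(key = rownames(Y), fold_estimate = fold,
                    posterior_de = post, max_bin = max_bin,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$bins <- bins
  structure(out,
            class = c("expansion_calls", "data.frame"),
            stim = stim, ctrl = ctrl,
            posterior_threshold = posterior_threshold,
            fold_thresholds = fold_thresholds,
            p_de = p_de, prior_size = S, seed = seed)
}

# log of the quadrature average, over empirical prior points (qs, phis), of
# the NB likelihood of each count row; columns have means qs * L
.nb_marginal <- function(Y, L, qs, phis) {
  n <- nrow(Y); S <- length(qs)
  ll <- matrix(0, n, S)
  for (s in seq_len(S)) {
    mu <- matrix(qs[s] * L, n, length(L), byrow = TRUE)
    ll[, s] <- rowSums(dnbinom(Y, size = 1 / phis[s], mu = mu, log = TRUE))
  }
  mx <- apply(ll, 1, max)
  mx + log(rowMeans(exp(ll - mx)))
}

#' @export
print.expansion_calls <- function(x, ...) {
  thr <- attr(x, "fold_thresholds")
  cat(sprintf("<expansion_calls> %d clonotypes; posterior > %.2f; DE proportion %.4f\n",
              nrow(x), attr(x, "posterior_threshold"), attr(x, "p_de")))
  for (t in thr) cat(sprintf("  >= %2dx: %d clonotypes\n", t, sum(x$max_bin >= t)))
  invisible(x)
}

#' Keys of clonotypes expanded at a fold threshold
#'
#' @param calls an `"expansion_calls"` object.
#' @param fold minimum expansion multiplicity (a value of
#'   `fold_thresholds`); 1 returns every scored clonotype.
#' @return Character vector of clonotype keys.
#' @export
expanded_keys <- function(calls, fold = 2) {
  if (fold <= 1) return(calls$key)
  calls$key[calls$max_bin >= fold]
}

#' Restrict a repertoire to expanded clonotypes
#' @param rep a [repertoire].
#' @param calls an `"expansion_calls"` object.
#' @param fold minimum expansion multiplicity.
#' @return A [repertoire] of clonotypes meeting the fold bin.
#' @export
select_expanded <- function(rep, calls, fold = 2) {
  restrict_repertoire(rep, expanded_keys(calls, fold))
}

#' Restrict a repertoire to unexpanded clonotypes
#'
#' The complement of [select_expanded()]: clonotypes with no fold bin at the
#' given threshold (together the two partition the repertoire).
#'
#' @inheritParams select_expanded
#' @return A [repertoire].
#' @export
select_unexpanded <- function(rep, calls, fold = 2) {
  kv <- isTRUE(attr(rep, "key_by_v"))
  all_keys <- clonotype_key(rep$clonotypes, kv)
  restrict_repertoire(rep, setdiff(all_keys, expanded_keys(calls, fold)))
}
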
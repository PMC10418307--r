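#' Morisita-Horn overlap index
#'
#' Abundance-weighted repertoire overlap, bounded in \[0, 1\]:
#' `C = 2 * sum(x*y) / ((sum(x^2)/X^2 + sum(y^2)/Y^2) * X * Y)` with
#' `X = sum(x)`, `Y = sum(y)`. Equals 1 for proportional abundance vectors
#' and 0 for disjoint supports; invariant to rescaling either vector.
#'
#' @param x,y non-negative abundance vectors over the same (union) key set,
#'   aligned by position, or named vectors which are aligned by name.
#' @return The index, or `NA` when either vector has zero total.
#' @export
morisita_horn <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    keys <- union(names(x), names(y))
    x <- setNames(x[keys], keys); x[is.na(x)] <- 0
    y <- setNames(y[keys], keys); y[is.na(y)] <- 0
  }
  if (length(x) != length(y)) stop("x and y must cover the same key union")
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0 || length(x) == 0) return(NA_real_)
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' Pairwise Morisita-Horn overlap across expansion thresholds
#'
#' At each threshold every repertoire is first restricted to clonotypes whose
#' expansion call meets that fold bin (threshold 1 means no restriction), then
#' all pairwise Morisita-Horn indices are computed on counts. A repertoire
#' with no clonotypes at a threshold yields `NA` in its row and column —
#' mirroring samples that simply lack 16x/32x-expanded clonotypes.
#'
#' @param reps list of [repertoire] objects.
#' @param calls either a single `"expansion_calls"` object applied to every
#'   sample, or a named list keyed by `sample_id`. May be `NULL` when only
#'   threshold 1 is requested.
#' @param thresholds ordered expansion thresholds (1 = unrestricted).
#' @return An object of class `"overlap_grid"`: list with `thresholds` and
#'   `matrices`, one symmetric sample x sample matrix per threshold.
#' @export
overlap_grid <- function(reps, calls = NULL, thresholds = c(1, 2, 4, 8, 16, 32)) {
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  if (is.null(calls) && any(thresholds > 1))
    stop("expansion calls are required for thresholds above 1")
  get_calls <- function(id) {
    if (inherits(calls, "expansion_calls")) calls
    else if (is.list(calls)) calls[[id]]
    else NULL
  }
  counts_at <- function(rep, t) {
    df <- rep$clonotypes
    kv <- isTRUE(attr(rep, "key_by_v"))
    keys <- clonotype_key(df, kv)
    if (t > 1) {
      cl <- get_calls(rep$sample_id)
      sel <- if (is.null(cl)) rep(FALSE, nrow(df)) else
        keys %in% expanded_keys(cl, t)
      keys <- keys[sel]; df <- df[sel, , drop = FALSE]
    }
    setNames(df$count, keys)
  }
  mats <- lapply(thresholds, function(t) {
    vecs <- lapply(reps, counts_at, t = t)
    m <- matrix(NA_real_, length(reps), length(reps), dimnames = list(ids, ids))
    for (i in seq_along(reps)) {
      if (!length(vecs[[i]]) || sum(vecs[[i]]) == 0) next
      m[i, i] <- 1
      for (j in seq_along(reps)) {
        if (j <= i) next
        if (!length(vecs[[j]]) || sum(vecs[[j]]) == 0) next
        m[i, j] <- m[j, i] <- morisita_horn(vecs[[i]], vecs[[j]])
      }
    }
    m
  })
  structure(list(thresholds = thresholds, matrices = setNames(mats, thresholds)),
            class = "overlap_grid")
}

#' @export
print.overlap_grid <- function(x, ...) {
  cat(sprintf("<overlap_grid> %d samples at thresholds %s\n",
              nrow(x$matrices[[1]]), paste(x$thresholds, collapse = ", ")))
  invisible(x)
}

#' Flatten an overlap grid to long format
#'
#' @param grid an `"overlap_grid"`.
#' @return Data frame with `threshold`, `sample_a`, `sample_b`, `index`
#'   (upper triangle only).
#' @export
overlap_long <- function(grid) {
  do.call(rbind, lapply(seq_along(grid$thresholds), function(k) {
    m <- grid$matrices[[k]]
    ut <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(threshold = grid$thresholds[k],
               sample_a = rownames(m)[ut[, 1]],
               sample_b = colnames(m)[ut[, 2]],
               index = m[ut], stringsAsFactors = FALSE)
  }))
}
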
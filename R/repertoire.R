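#' Construct a repertoire
#'
#' A repertoire is one sample's clonotype table: CDR3 amino-acid sequences
#' (conserved C through conserved F, inclusive) with V/J gene calls, read
#' counts and within-sample frequencies. Clonotypes sharing the same identity
#' key (CDR3 alone by default, CDR3+V with `key_by_v = TRUE`) are merged by
#' summing counts; the majority V gene is kept (ties broken lexicographically).
#'
#' @param cdr3_aa character vector of CDR3 amino-acid sequences.
#' @param count non-negative read/UMI counts, recycled if length 1.
#' @param v_gene,j_gene gene symbols (allele suffixes should already be
#'   stripped; see [read_mixcr()]). Empty string if unknown.
#' @param frequency optional within-sample frequencies; recomputed from
#'   `count` when missing, rescaled to sum to 1 when off by more than 1e-6.
#' @param sample_id sample identifier.
#' @param condition condition label (e.g. `"BlL0"`, `"Trans"`, `"Int"`).
#' @param key_by_v key clonotypes by CDR3+V instead of CDR3 alone.
#' @return An object of class `"repertoire"`: a list with `sample_id`,
#'   `condition` and a `clonotypes` data frame (`cdr3_aa`, `v_gene`, `j_gene`,
#'   `count`, `frequency`).
#' @export
repertoire <- function(cdr3_aa, count, v_gene = "", j_gene = "",
                       frequency = NULL, sample_id = "sample",
                       condition = NA_character_, key_by_v = FALSE) {
  n <- length(cdr3_aa)
  df <- data.frame(
    cdr3_aa = as.character(cdr3_aa),
    v_gene = rep_len(as.character(v_gene), n),
    j_gene = rep_len(as.character(j_gene), n),
    count = rep_len(as.numeric(count), n),
    stringsAsFactors = FALSE
  )
  if (any(df$count < 0)) stop("clonotype counts must be non-negative")
  bad <- !grepl(AA_REGEX, df$cdr3_aa) | nchar(df$cdr3_aa) < 5L
  if (any(bad)) stop("invalid CDR3 amino-acid sequence(s): ",
                     paste(head(df$cdr3_aa[bad], 3), collapse = ", "))
  df$frequency <- if (is.null(frequency)) {
    if (sum(df$count) > 0) df$count / sum(df$count) else rep(0, n)
  } else rep_len(as.numeric(frequency), n)
  df <- merge_clonotype_rows(df, key_by_v = key_by_v)
  s <- sum(df$frequency)
  if (s > 0 && abs(s - 1) > 1e-6) df$frequency <- df$frequency / s
  structure(
    list(sample_id = sample_id, condition = condition, clonotypes = df),
    class = "repertoire", key_by_v = key_by_v
  )
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %s (%s): %d clonotypes, %s reads\n",
              x$sample_id,
              if (is.na(x$condition)) "?" else x$condition,
              nrow(x$clonotypes),
              format(sum(x$clonotypes$count), big.mark = ",")))
  invisible(x)
}

# identity keys for a clonotype table
clonotype_key <- function(df, key_by_v = FALSE) {
  if (key_by_v) paste(df$cdr3_aa, df$v_gene, sep = "|") else df$cdr3_aa
}

#' Clonotype identity keys of a repertoire
#' @param rep a `repertoire`.
#' @param key_by_v key by CDR3+V; defaults to how the repertoire was built.
#' @return character vector of keys, one per clonotype row.
#' @export
repertoire_keys <- function(rep, key_by_v = NULL) {
  if (is.null(key_by_v)) key_by_v <- isTRUE(attr(rep, "key_by_v"))
  clonotype_key(rep$clonotypes, key_by_v)
}

# merge duplicate keys: counts summed, majority V kept (ties -> first
# lexicographically), frequencies summed
merge_clonotype_rows <- function(df, key_by_v = FALSE) {
  key <- clonotype_key(df, key_by_v)
  if (!anyDuplicated(key)) return(df[order(-df$count, df$cdr3_aa), , drop = FALSE])
  o <- order(key, -df$count, df$v_gene)
  df <- df[o, , drop = FALSE]
  key <- key[o]
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$count <- as.numeric(rowsum(df$count, key)[unique(key), 1])
  out$frequency <- as.numeric(rowsum(df$frequency, key)[unique(key), 1])
  rownames(out) <- NULL
  out[order(-out$count, out$cdr3_aa), , drop = FALSE]
}

# strip allele suffix (*01) and score decorations from a gene call, keep the
# best (first) hit of a comma-separated list
normalize_gene_call <- function(x) {
  x[is.na(x)] <- ""
  x <- sub(",.*$", "", x)
  x <- sub("\\(.*\\)", "", x)
  x <- sub("\\*.*$", "", x)
  trimws(x)
}

.pick_column <- function(header, candidates, what, required = TRUE) {
  hit <- candidates[candidates %in% header]
  if (length(hit) == 0) {
    if (required)
      stop(sprintf("format error: no %s column (expected one of: %s)",
                   what, paste(candidates, collapse = ", ")))
    return(NA_character_)
  }
  hit[1]
}

# shared core of the two readers: filter non-amino-acid CDR3s (out-of-frame
# '_' or stop '*'), tally drops, build the repertoire
.build_repertoire_from_table <- function(cdr3, v, j, count, frequency,
                                         sample_id, condition, key_by_v) {
  ok <- grepl(AA_REGEX, cdr3) & nchar(cdr3) >= 5L
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    warning(sprintf("%d clonotype row(s) with non-amino-acid or short CDR3 dropped",
                    n_dropped), call. = FALSE)
  if (!is.null(frequency) && sum(ok) > 0) frequency <- frequency[ok]
  rep <- if (sum(ok) == 0) {
    structure(list(sample_id = sample_id, condition = condition,
                   clonotypes = data.frame(cdr3_aa = character(), v_gene = character(),
                                           j_gene = character(), count = numeric(),
                                           frequency = numeric())),
              class = "repertoire", key_by_v = key_by_v)
  } else {
    repertoire(cdr3[ok], count[ok], v[ok], j[ok], frequency = frequency,
               sample_id = sample_id, condition = condition, key_by_v = key_by_v)
  }
  attr(rep, "n_dropped") <- n_dropped
  rep
}

#' Read a MiXCR clonotype export
#'
#' Reads MiXCR's tab-separated clone table dialect (`cloneCount`,
#' `cloneFraction`, `aaSeqCDR3`, `bestVHit`/`allVHitsWithScore` columns).
#' V/J calls are normalized to bare gene symbols (allele suffixes such as
#' `*01` and score decorations stripped, best hit of a list kept).
#' Out-of-frame or stop-containing CDR3s (`_`/`*`) are dropped with a warning;
#' the number of dropped rows is available as `attr(x, "n_dropped")`.
#' Frequencies are rescaled to sum to 1 when off by more than 1e-6.
#'
#' @param path path to the TSV file.
#' @param sample_id sample identifier (defaults to the file name).
#' @param condition condition label.
#' @param key_by_v key clonotypes by CDR3+V instead of CDR3 alone.
#' @return A [repertoire].
#' @export
read_mixcr <- function(path, sample_id = basename(path),
                       condition = NA_character_, key_by_v = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  header <- names(tab)
  count_col <- .pick_column(header, c("cloneCount", "readCount", "count"), "clone count")
  frac_col <- .pick_column(header, c("cloneFraction", "clonalFraction", "frequency"),
                           "clone fraction")
  cdr3_col <- .pick_column(header, c("aaSeqCDR3", "aaSeqImputedCDR3"), "CDR3 amino-acid")
  v_col <- .pick_column(header, c("bestVHit", "allVHitsWithScore", "bestVGene"),
                        "V gene", required = FALSE)
  j_col <- .pick_column(header, c("bestJHit", "allJHitsWithScore", "bestJGene"),
                        "J gene", required = FALSE)
  v <- if (is.na(v_col)) rep("", nrow(tab)) else normalize_gene_call(tab[[v_col]])
  j <- if (is.na(j_col)) rep("", nrow(tab)) else normalize_gene_call(tab[[j_col]])
  .build_repertoire_from_table(
    cdr3 = tab[[cdr3_col]], v = v, j = j,
    count = as.numeric(tab[[count_col]]),
    frequency = as.numeric(tab[[frac_col]]),
    sample_id = sample_id, condition = condition, key_by_v = key_by_v
  )
}

#' Read an AIRR Rearrangement table
#'
#' Reads the AIRR Community Rearrangement TSV dialect: `junction_aa` is taken
#' as the CDR3 amino-acid sequence, `v_call`/`j_call` as gene calls and
#' `duplicate_count` as the clonotype count (falling back to
#' `consensus_count`, with a message, when `duplicate_count` is absent).
#' A header-only file yields a valid empty repertoire.
#'
#' @inheritParams read_mixcr
#' @return A [repertoire].
#' @export
read_airr <- function(path, sample_id = basename(path),
                      condition = NA_character_, key_by_v = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  header <- names(tab)
  cdr3_col <- .pick_column(header, c("junction_aa", "cdr3_aa"), "junction amino-acid")
  count_col <- .pick_column(header, c("duplicate_count"), "duplicate count",
                            required = FALSE)
  if (is.na(count_col)) {
    count_col <- .pick_column(header, c("consensus_count", "count"), "count")
    message("duplicate_count absent; using ", count_col)
  }
  v_col <- .pick_column(header, "v_call", "V call", required = FALSE)
  j_col <- .pick_column(header, "j_call", "J call", required = FALSE)
  if (nrow(tab) == 0) {
    return(.build_repertoire_from_table(character(), character(), character(),
                                        numeric(), NULL, sample_id, condition,
                                        key_by_v))
  }
  v <- if (is.na(v_col)) rep("", nrow(tab)) else normalize_gene_call(tab[[v_col]])
  j <- if (is.na(j_col)) rep("", nrow(tab)) else normalize_gene_call(tab[[j_col]])
  .build_repertoire_from_table(
    cdr3 = tab[[cdr3_col]], v = v, j = j,
    count = as.numeric(tab[[count_col]]), frequency = NULL,
    sample_id = sample_id, condition = condition, key_by_v = key_by_v
  )
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' Writes `sequence_id`, `junction_aa`, `v_call`, `j_call`, `duplicate_count`.
#' The round trip `read_airr(write_airr(rep))` reproduces CDR3s, V genes and
#' counts exactly.
#'
#' @param rep a [repertoire].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(rep, path) {
  df <- rep$clonotypes
  out <- data.frame(
    sequence_id = sprintf("%s_%06d", rep$sample_id, seq_len(nrow(df))),
    junction_aa = df$cdr3_aa,
    v_call = df$v_gene,
    j_call = df$j_gene,
    duplicate_count = df$count,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool repertoires into one combined sample
#'
#' Counts are summed per clonotype key across the input repertoires and
#' frequencies recomputed from the pooled counts. Used to combine repertoires
#' of different mice given the same stimulation before overlap and clustering.
#'
#' @param reps a list of [repertoire] objects (at least one).
#' @param label sample_id of the pooled repertoire.
#' @param condition condition label of the pool.
#' @param key_by_v key clonotypes by CDR3+V.
#' @return A [repertoire].
#' @export
pool_repertoires <- function(reps, label = "pooled", condition = NA_character_,
                             key_by_v = FALSE) {
  if (!length(reps)) stop("pool_repertoires() needs at least one repertoire")
  if (inherits(reps, "repertoire")) reps <- list(reps)
  df <- do.call(rbind, lapply(reps, function(r) r$clonotypes))
  repertoire(df$cdr3_aa, df$count, df$v_gene, df$j_gene,
             sample_id = label, condition = condition, key_by_v = key_by_v)
}

#' Build a clonotype x sample count matrix
#'
#' Rows are the union of clonotype keys across samples (absent entries 0),
#' columns follow the input order. Condition labels are carried in
#' `attr(m, "conditions")`.
#'
#' @param reps list of [repertoire] objects with unique `sample_id`s.
#' @param key_by_v key clonotypes by CDR3+V.
#' @return Numeric matrix of counts with clonotype keys as row names and
#'   sample ids as column names.
#' @export
build_count_matrix <- function(reps, key_by_v = FALSE) {
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id in input repertoires")
  keys <- unique(unlist(lapply(reps, function(r)
    clonotype_key(r$clonotypes, key_by_v))))
  m <- matrix(0, nrow = length(keys), ncol = length(reps),
              dimnames = list(keys, ids))
  for (i in seq_along(reps)) {
    k <- clonotype_key(reps[[i]]$clonotypes, key_by_v)
    m[k, i] <- reps[[i]]$clonotypes$count
  }
  attr(m, "conditions") <- setNames(
    vapply(reps, function(r) as.character(r$condition), character(1)), ids)
  m
}

#' Restrict a repertoire to a set of clonotype keys
#'
#' Frequencies are kept on the original within-sample scale (they are not
#' renormalized), so sums over the subset remain interpretable as a share of
#' the whole sample.
#'
#' @param rep a [repertoire].
#' @param keys clonotype keys to keep.
#' @param renormalize recompute frequencies within the subset.
#' @return A [repertoire] containing only the requested clonotypes.
#' @export
restrict_repertoire <- function(rep, keys, renormalize = FALSE) {
  kv <- isTRUE(attr(rep, "key_by_v"))
  sel <- clonotype_key(rep$clonotypes, kv) %in% keys
  out <- rep
  out$clonotypes <- rep$clonotypes[sel, , drop = FALSE]
  rownames(out$clonotypes) <- NULL
  if (renormalize && nrow(out$clonotypes) > 0) {
    s <- sum(out$clonotypes$frequency)
    if (s > 0) out$clonotypes$frequency <- out$clonotypes$frequency / s
  }
  out
}
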
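# fixtures and independent oracles used across test files

toy_repertoire <- function(cdr3, count, v = "TRBV1", id = "s1", cond = "BaL0") {
  repertoire(cdr3, count, v_gene = v, sample_id = id, condition = cond)
}

# minimal expansion-call object for functions that only need (key, max_bin)
fake_calls <- function(keys, max_bin) {
  structure(data.frame(key = keys, fold_estimate = max_bin,
                       posterior_de = 1, max_bin = max_bin,
                       stringsAsFactors = FALSE),
            class = c("expansion_calls", "data.frame"))
}

write_mixcr_fixture <- function(path, cloneCount, cloneFraction, aaSeqCDR3,
                                bestVHit = "TRBV1*00") {
  df <- data.frame(cloneCount = cloneCount, cloneFraction = cloneFraction,
                   aaSeqCDR3 = aaSeqCDR3,
                   bestVHit = rep_len(bestVHit, length(aaSeqCDR3)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# O(n^2) brute-force HD-1 edge set, independent of the hashed construction
brute_hd1_edges <- function(cdr3) {
  from <- character(0); to <- character(0)
  n <- length(cdr3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- cdr3[i]; b <- cdr3[j]
      if (nchar(a) == nchar(b) &&
          sum(utf8ToInt(a) != utf8ToInt(b)) == 1L) {
        from <- c(from, min(a, b)); to <- c(to, max(a, b))
      }
    }
  }
  df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}

# edge set of an igraph graph in the same canonical form
graph_edge_df <- function(g) {
  e <- igraph::as_edgelist(g)
  if (!nrow(e)) return(data.frame(from = character(0), to = character(0)))
  df <- data.frame(from = pmin(e[, 1], e[, 2]), to = pmax(e[, 1], e[, 2]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# literal evaluation of the Morisita-Horn formula
brute_morisita <- function(x, y) {
  X <- sum(x); Y <- sum(y)
  num <- 2 * sum(x * y)
  den <- (sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y
  num / den
}

# n distinct CDR3-like keys (valid amino-acid strings)
aa_keys <- function(n, prefix = "CASS", suffix = "GQYF") {
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  code <- vapply(seq_len(n) - 1, function(i)
    paste0(aa20[(i %/% c(8000, 400, 20, 1)) %% 20 + 1], collapse = ""),
    character(1))
  paste0(prefix, code, suffix)
}

random_cdr3s <- function(n, lengths = 10:14, alphabet = c("A", "G", "S", "T")) {
  vapply(seq_len(n), function(i) {
    L <- sample(lengths, 1)
    paste0(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

# small specificity-pattern table for set-algebra tests
pat_df <- function(patterns, kind = "local") {
  df <- data.frame(kind = kind, pattern = patterns,
                   support = 3L, fold = 100, p_value = 1e-6,
                   stringsAsFactors = FALSE)
  df$members <- replicate(length(patterns), character(0), simplify = FALSE)
  df$source_conditions <- replicate(length(patterns), character(0),
                                    simplify = FALSE)
  class(df) <- c("specificity_patterns", "data.frame")
  df
}
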
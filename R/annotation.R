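#' Load a TCR specificity database
#'
#' Reads a VDJdb export TSV, a McPAS-TCR CSV, or a generic TSV with columns
#' `cdr3_aa`, `epitope`, `pathology`, `species` into a uniform record table.
#' Duplicate (CDR3, pathology) rows are collapsed.
#'
#' @param path path to the database file.
#' @param dialect `"generic"`, `"vdjdb"` or `"mcpas"`.
#' @return Data frame of class `"specificity_db"` with columns `cdr3_aa`,
#'   `epitope`, `pathology`, `species`, `source`.
#' @export
load_specificity_db <- function(path, dialect = c("generic", "vdjdb", "mcpas")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- switch(dialect,
    mcpas = utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE))
  cols <- switch(dialect,
    vdjdb = c(cdr3 = "cdr3", epitope = "antigen.epitope",
              pathology = "antigen.species", species = "species"),
    mcpas = c(cdr3 = "CDR3.beta.aa", epitope = "Epitope.peptide",
              pathology = "Pathology", species = "Species"),
    generic = c(cdr3 = "cdr3_aa", epitope = "epitope",
                pathology = "pathology", species = "species"))
  miss <- setdiff(cols[["cdr3"]], names(raw))
  if (length(miss)) stop("format error: missing column ", miss)
  get <- function(nm) if (nm %in% names(raw)) as.character(raw[[nm]]) else
    rep(NA_character_, nrow(raw))
  db <- data.frame(cdr3_aa = as.character(raw[[cols[["cdr3"]]]]),
                   epitope = get(cols[["epitope"]]),
                   pathology = get(cols[["pathology"]]),
                   species = get(cols[["species"]]),
                   source = dialect, stringsAsFactors = FALSE)
  db <- db[grepl(AA_REGEX, db$cdr3_aa), , drop = FALSE]
  db <- db[!duplicated(db[, c("cdr3_aa", "pathology")]), , drop = FALSE]
  rownames(db) <- NULL
  class(db) <- c("specificity_db", "data.frame")
  db
}

#' Annotate clonotypes against a specificity database
#'
#' Exact, case-sensitive CDR3 amino-acid matching. The matched share is the
#' number of matched distinct clonotypes over all distinct clonotypes; the
#' pathology breakdown gives, per pathology label, the share of matched
#' clonotypes carrying it (a clonotype matching records of several
#' pathologies contributes once to the share but once to each label, so
#' label counts can sum to more than the matched count).
#'
#' @param x a [repertoire] or character vector of CDR3 sequences.
#' @param db a `"specificity_db"` from [load_specificity_db()].
#' @param species optional host-species filter applied to the database
#'   (e.g. `"Mouse"`); off by default since cross-species CDR3 matches are
#'   often intended.
#' @return List of class `"annotation"`: `matches` (clonotype/epitope/
#'   pathology rows), `share`, `n_matched`, `n_total` and
#'   `pathology_share` (named vector).
#' @export
annotate_clonotypes <- function(x, db, species = NULL) {
  cdr3 <- unique(if (inherits(x, "repertoire")) x$clonotypes$cdr3_aa else x)
  if (!is.null(species)) db <- db[db$species %in% species, , drop = FALSE]
  if (!nrow(db)) warning("empty specificity database; all shares are 0")
  hits <- db[db$cdr3_aa %in% cdr3, , drop = FALSE]
  n_matched <- length(unique(hits$cdr3_aa))
  n_total <- length(cdr3)
  pat <- hits[!is.na(hits$pathology) & nzchar(hits$pathology), , drop = FALSE]
  breakdown <- if (nrow(pat)) {
    counts <- tapply(pat$cdr3_aa, pat$pathology, function(z) length(unique(z)))
    counts <- setNames(as.numeric(counts), names(counts))
    sort(counts / max(n_matched, 1), decreasing = TRUE)
  } else setNames(numeric(0), character(0))
  structure(
    list(matches = hits, share = if (n_total) n_matched / n_total else NA_real_,
         n_matched = n_matched, n_total = n_total,
         pathology_share = breakdown),
    class = "annotation"
  )
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %d / %d clonotypes matched (share %.4f)\n",
              x$n_matched, x$n_total, x$share))
  if (length(x$pathology_share)) {
    cat("pathology shares of matched clonotypes:\n")
    print(round(x$pathology_share, 3))
  }
  invisible(x)
}
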
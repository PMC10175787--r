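#' Collapse an isoform accession to its canonical accession
#'
#' Splice-isoform accessions carry a numeric suffix (`"P12345-2"`,
#' `"SYN00007-3"`); the canonical accession is obtained by stripping it.
#' Accessions without a suffix are returned unchanged.
#'
#' @param accession Character vector of protein accessions.
#' @return Character vector of canonical accessions.
#' @examples
#' canonical_accession(c("SYN00007-2", "P60709"))
#' @export
canonical_accession <- function(accession) {
  sub("-[0-9]+$", "", accession)
}

# stop() wrappers: the error class distinguishes user-facing failure modes
# (bad configuration vs malformed input file vs API misuse).
config_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("aap_config_error", "error")))
}

format_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("aap_format_error", "error")))
}

usage_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("aap_usage_error", "error")))
}

# read a TSV with a header, keeping strings as strings
read_tsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

# write a TSV deterministically (no quoting, no row names)
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    format_error("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", "))
  }
  invisible(df)
}

# semicolon-joined set fields used throughout the tabular interfaces
split_set <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
}

join_set <- function(x) {
  vapply(x, function(v) paste(sort(unique(v)), collapse = ";"), character(1))
}

#' Path to a curated data file shipped with the package
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @examples
#' aap_extdata("abd_families.tsv")
#' @export
aap_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "aapcensus")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) config_error("no shipped data file named '%s'", file)
  path
}

#' The curated actin query set
#'
#' The six reviewed conventional human actins (four muscle alpha/gamma actins
#' and the two cytoplasmic beta/gamma actins) whose interaction partners seed
#' the PPI evidence line.
#'
#' @return A data frame with columns `accession`, `gene`, `protein_name`,
#'   `length`.
#' @examples
#' actin_queries()$accession
#' @export
actin_queries <- function() {
  read_tsv(aap_extdata("actin_queries.tsv"))
}

#' Curated actin-binding Pfam family list
#'
#' Classical actin-binding domain (ABD) families such as the calponin homology
#' (CH) domain, villin headpiece and gelsolin repeat. Membership of one of
#' these families in a protein's resolved domain architecture is one evidence
#' line of the census. The shipped list is a curated starting point; users can
#' supply their own via the `abd_families` arguments.
#'
#' @return Character vector of family names.
#' @export
abd_family_list <- function() {
  read_tsv(aap_extdata("abd_families.tsv"))$family
}

#' Curated actin-related GO term list
#'
#' GO identifiers for actin binding and actin-cytoskeleton terms used by the
#' annotation-mining evidence line.
#'
#' @return Character vector of GO identifiers.
#' @export
actin_go_term_list <- function() {
  read_tsv(aap_extdata("actin_go_terms.tsv"))$go_id
}
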
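#' Per-database PPI confidence thresholds
#'
#' The score filter applied to each interaction database before an edge may
#' contribute evidence. Defaults cover the ten databases commonly mined for
#' high-confidence physical interactions: STRING (combined score scale
#' 0-1000, kept above 700), BioGRID/IntAct/MINT/mentha (0-1 scale, kept above
#' 0.6), HIPPIE (above 0.73), HitPredict (annotation score above 0.5 AND
#' method-based score above 0.485), and DIP/HINT/HuRI, which curate only
#' high-confidence interactions and carry no score filter. All thresholds are
#' strict (`score > score_min`); only edges typed `physical` count when
#' `requires_physical` is set (the default everywhere, so functional or
#' predicted associations never yield evidence).
#'
#' @param databases Optional character vector restricting the table to a
#'   subset of the defaults.
#' @return Data frame with columns `database`, `score_min`,
#'   `method_score_min`, `scale_max`, `requires_physical`, `strict`.
#' @examples
#' threshold_table()
#' @export
threshold_table <- function(databases = NULL) {
  tab <- data.frame(
    database = c("string", "biogrid", "intact", "mint", "mentha",
                 "hippie", "hitpredict", "dip", "hint", "huri"),
    score_min = c(700, 0.6, 0.6, 0.6, 0.6, 0.73, 0.5, NA, NA, NA),
    method_score_min = c(NA, NA, NA, NA, NA, NA, 0.485, NA, NA, NA),
    scale_max = c(1000, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    requires_physical = TRUE,
    strict = TRUE,
    stringsAsFactors = FALSE
  )
  if (!is.null(databases)) {
    unknown <- setdiff(databases, tab$database)
    if (length(unknown) > 0)
      config_error("unknown PPI database(s): %s", paste(unknown, collapse = ", "))
    tab <- tab[match(databases, tab$database), ]
    rownames(tab) <- NULL
  }
  tab
}

validate_edges <- function(edges, thresholds) {
  require_columns(edges, c("database", "a", "b", "score", "interaction_type"),
                  "PPI edge table")
  if (!"method_score" %in% names(edges)) edges$method_score <- NA_real_
  unknown <- setdiff(unique(edges$database), thresholds$database)
  if (length(unknown) > 0)
    config_error("edge(s) from database(s) not present in the threshold table: %s",
                 paste(unknown, collapse = ", "))
  idx <- match(edges$database, thresholds$database)
  bad <- which(!is.na(edges$score) &
                 (edges$score < 0 | edges$score > thresholds$scale_max[idx]))
  if (length(bad) > 0)
    format_error("edge score %g outside scale [0, %g] for database '%s' (row %d)",
                 edges$score[bad[1]], thresholds$scale_max[idx[bad[1]]],
                 edges$database[bad[1]], bad[1])
  edges
}

#' Harvest PPI evidence for partners of the actin query set
#'
#' Scans per-database edge lists for edges touching an actin query accession
#' and emits one evidence record for the non-actin endpoint of every edge
#' that passes the database's confidence filter: interaction type `physical`
#' (where required) and score strictly above the database threshold (both
#' scores for two-score databases; databases without a threshold pass all
#' physical edges). Actin query accessions themselves are not emitted as
#' partners unless `include_actins` is set. Partner accessions are collapsed
#' to canonical form.
#'
#' @param edges Data frame with columns `database`, `a`, `b`, `score`,
#'   `interaction_type` and optionally `method_score`; see
#'   [read_ppi_edges()].
#' @param actin_set Character vector of actin query accessions.
#' @param thresholds A [threshold_table()] covering every database in
#'   `edges`.
#' @param include_actins Emit records for actin-actin edges as well (default
#'   `FALSE`).
#' @return Evidence-record data frame: `protein` (canonical accession),
#'   `source` (`"ppi:<database>"`), `detail` (the actin partner), `score`.
#' @export
ppi_evidence <- function(edges, actin_set, thresholds = threshold_table(),
                         include_actins = FALSE) {
  edges <- validate_edges(edges, thresholds)
  if (nrow(edges) == 0) return(empty_records())
  idx <- match(edges$database, thresholds$database)
  score_min <- thresholds$score_min[idx]
  method_min <- thresholds$method_score_min[idx]
  strict <- thresholds$strict[idx]
  pass_score <- is.na(score_min) |
    ifelse(strict, edges$score > score_min, edges$score >= score_min)
  pass_score[is.na(pass_score)] <- FALSE
  pass_method <- is.na(method_min) |
    ifelse(strict, edges$method_score > method_min, edges$method_score >= method_min)
  pass_method[is.na(pass_method)] <- FALSE
  pass_type <- !thresholds$requires_physical[idx] | edges$interaction_type == "physical"
  a_actin <- canonical_accession(edges$a) %in% actin_set
  b_actin <- canonical_accession(edges$b) %in% actin_set
  keep <- pass_score & pass_method & pass_type & (a_actin | b_actin)
  recs <- lapply(which(keep), function(i) {
    partners <- character(0)
    actins <- character(0)
    if (a_actin[i]) actins <- c(actins, edges$a[i]) else partners <- c(partners, edges$a[i])
    if (b_actin[i]) actins <- c(actins, edges$b[i]) else partners <- c(partners, edges$b[i])
    if (length(partners) == 0) {
      if (!include_actins) return(NULL)
      partners <- actins[1]
      actins <- actins[2]
    }
    data.frame(protein = canonical_accession(partners),
               source = paste0("ppi:", edges$database[i]),
               detail = canonical_accession(actins[1]),
               score = edges$score[i],
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) empty_records() else recs
}

empty_records <- function() {
  data.frame(protein = character(0), source = character(0),
             detail = character(0), score = numeric(0), stringsAsFactors = FALSE)
}

#' Harvest actin-binding-domain evidence from resolved architectures
#'
#' A protein whose accepted (filtered, overlap-resolved) domain architecture
#' contains at least one family from the curated actin-binding family list is
#' annotated as an AAP. Hits removed by filtering or overlap resolution never
#' contribute: evidence is read from accepted domains only.
#'
#' @param accepted Accepted-hit table from [resolve_architectures()].
#' @param abd_families Character vector of actin-binding family names
#'   (default: the shipped curated list, [abd_family_list()]).
#' @return Evidence-record data frame (`source = "pfam_domain"`, `detail` =
#'   matched families joined by `;`), one row per protein sequence.
#' @export
domain_evidence <- function(accepted, abd_families = abd_family_list()) {
  if (length(abd_families) == 0)
    config_error("abd_families must contain at least one family")
  require_columns(accepted, c("protein", "family"), "accepted hit table")
  hit <- accepted[accepted$family %in% abd_families, , drop = FALSE]
  if (nrow(hit) == 0) return(empty_records())
  fams <- lapply(split(hit$family, hit$protein), function(v) sort(unique(v)))
  data.frame(protein = canonical_accession(names(fams)),
             source = "pfam_domain",
             detail = vapply(fams, paste, character(1), collapse = ";"),
             score = NA_real_,
             stringsAsFactors = FALSE)
}

#' Harvest GO-annotation evidence
#'
#' Three flavours of Gene Ontology evidence share one interface, selected by
#' `source_tag`:
#' \describe{
#'   \item{`go:uniprot`}{proteins whose protein-level GO annotation set (the
#'     `go_terms` metadata column, `;`-separated) intersects the actin-related
#'     term list;}
#'   \item{`go:pfam2go`}{proteins with an accepted domain family that maps,
#'     via the Pfam2GO file, to a term in the list;}
#'   \item{`go:pdb`}{proteins named in a supplied curated accession list
#'     (e.g. derived from structure-database annotation).}
#' }
#'
#' @param metadata Protein metadata data frame with columns `accession`,
#'   `go_terms` (required for `go:uniprot`).
#' @param pfam2go Data frame with columns `family`, `go_id`, or a path to a
#'   two-column TSV (required for `go:pfam2go`).
#' @param accepted Accepted-hit table (required for `go:pfam2go`).
#' @param go_terms Character vector of actin-related GO identifiers.
#' @param source_tag One of `"go:uniprot"`, `"go:pfam2go"`, `"go:pdb"`.
#' @param curated_list Character vector of accessions (required for
#'   `go:pdb`), or a path to a one-accession-per-line file.
#' @return Evidence-record data frame.
#' @export
go_evidence <- function(go_terms = actin_go_term_list(),
                        source_tag = c("go:uniprot", "go:pfam2go", "go:pdb"),
                        metadata = NULL, pfam2go = NULL, accepted = NULL,
                        curated_list = NULL) {
  source_tag <- match.arg(source_tag)
  if (source_tag != "go:pdb" && length(go_terms) == 0)
    config_error("go_terms must be nonempty")
  if (source_tag == "go:uniprot") {
    if (is.null(metadata)) usage_error("go:uniprot evidence requires `metadata`")
    require_columns(metadata, c("accession", "go_terms"), "protein metadata")
    sets <- split_set(metadata$go_terms)
    hit <- vapply(sets, function(v) any(v %in% go_terms), logical(1))
    detail <- vapply(sets, function(v) paste(sort(intersect(v, go_terms)),
                                             collapse = ";"), character(1))
    out <- data.frame(protein = canonical_accession(metadata$accession[hit]),
                      source = source_tag, detail = detail[hit],
                      score = NA_real_, stringsAsFactors = FALSE)
  } else if (source_tag == "go:pfam2go") {
    if (is.null(pfam2go) || is.null(accepted))
      usage_error("go:pfam2go evidence requires `pfam2go` and `accepted`")
    if (is.character(pfam2go) && length(pfam2go) == 1) pfam2go <- read_pfam2go(pfam2go)
    require_columns(pfam2go, c("family", "go_id"), "pfam2go map")
    actin_fams <- unique(pfam2go$family[pfam2go$go_id %in% go_terms])
    hit <- accepted[accepted$family %in% actin_fams, , drop = FALSE]
    if (nrow(hit) == 0) return(empty_records())
    fams <- lapply(split(hit$family, hit$protein), function(v) sort(unique(v)))
    out <- data.frame(protein = canonical_accession(names(fams)),
                      source = source_tag,
                      detail = vapply(fams, paste, character(1), collapse = ";"),
                      score = NA_real_, stringsAsFactors = FALSE)
  } else {
    if (is.null(curated_list)) usage_error("go:pdb evidence requires `curated_list`")
    if (is.character(curated_list) && length(curated_list) == 1 &&
        file.exists(curated_list)) {
      curated_list <- readLines(curated_list)
      curated_list <- curated_list[nzchar(trimws(curated_list))]
    }
    if (length(curated_list) == 0) return(empty_records())
    out <- data.frame(protein = canonical_accession(curated_list),
                      source = source_tag, detail = "curated",
                      score = NA_real_, stringsAsFactors = FALSE)
  }
  out <- out[!duplicated(out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a Pfam2GO-style mapping
#'
#' Two-column tab-separated file (`family`, `go_id`); one family may map to
#' several terms across rows. Malformed lines are reported by line number.
#'
#' @param path Path to the mapping file.
#' @return Data frame with columns `family`, `go_id`.
#' @export
read_pfam2go <- function(path) {
  if (!file.exists(path)) format_error("pfam2go file '%s' does not exist", path)
  lines <- readLines(path)
  body <- lines[-1]
  bad <- which(nzchar(body) & !grepl("^[^\t]+\t[^\t]+$", body))
  if (length(bad) > 0)
    format_error("pfam2go file '%s': malformed mapping at line %d", path, bad[1] + 1L)
  read_tsv(path)
}

#' Merge evidence streams into the AAP census
#'
#' Collapses isoform accessions to canonical form, adds manually curated
#' literature proteins (`source = "literature"`), optionally removes the
#' actin query accessions themselves, and unions all evidence into one entry
#' per canonical accession with full provenance.
#'
#' @param ... Evidence-record data frames (from [ppi_evidence()],
#'   [domain_evidence()], [go_evidence()]); streams may overlap and repeat.
#' @param literature Character vector of literature-curated AAP accessions
#'   (or a path to a one-per-line file), or `NULL`.
#' @param actin_set Actin query accessions to exclude from the census
#'   (default none).
#' @param include_actins Keep actin query accessions if they acquired
#'   evidence (default `FALSE`).
#' @return An object of class `aap_census`: a data frame with one row per
#'   canonical accession (`protein`, `sources` as a `;`-joined sorted set,
#'   `n_sources`) carrying the full record table in attribute `"records"`.
#' @export
build_census <- function(..., literature = NULL, actin_set = character(0),
                         include_actins = FALSE) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  records <- if (length(parts) > 0) {
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  } else empty_records()
  if (!is.null(literature)) {
    if (is.character(literature) && length(literature) == 1 &&
        file.exists(literature)) {
      literature <- readLines(literature)
      literature <- literature[nzchar(trimws(literature))]
    }
    if (length(literature) > 0) {
      records <- rbind(records,
                       data.frame(protein = literature, source = "literature",
                                  detail = "curated", score = NA_real_,
                                  stringsAsFactors = FALSE))
    }
  }
  records$protein <- canonical_accession(records$protein)
  if (!include_actins) {
    records <- records[!records$protein %in% canonical_accession(actin_set), ,
                       drop = FALSE]
  }
  src <- lapply(split(records$source, records$protein), function(v) sort(unique(v)))
  entries <- data.frame(protein = names(src),
                        sources = vapply(src, paste, character(1), collapse = ";"),
                        n_sources = vapply(src, length, integer(1)),
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$protein), , drop = FALSE]
  rownames(entries) <- NULL
  records <- records[order(records$protein, records$source, records$detail), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(entries, records = records, class = c("aap_census", "data.frame"))
}

#' @export
print.aap_census <- function(x, ...) {
  cat(sprintf("<aap_census> %d proteins, %d evidence records\n",
              nrow(x), nrow(attr(x, "records"))))
  counts <- census_source_counts(x)
  if (length(counts) > 0) {
    cat("per-source protein counts:\n")
    for (s in names(counts)) cat(sprintf("  %-14s %d\n", s, counts[[s]]))
  }
  invisible(x)
}

#' Per-source protein counts of a census
#'
#' The number of distinct canonical proteins carrying each evidence source.
#' A protein with several sources is counted once under each.
#'
#' @param census An `aap_census` from [build_census()].
#' @return Named integer vector, sorted by source name.
#' @export
census_source_counts <- function(census) {
  src <- unlist(split_set(census$sources))
  if (length(src) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(src)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-actin partner counts of a census
#'
#' For the PPI evidence line, how many distinct partner proteins each actin
#' query accession contributed.
#'
#' @param census An `aap_census` from [build_census()].
#' @return Named integer vector keyed by actin accession.
#' @export
census_actin_partner_counts <- function(census) {
  rec <- attr(census, "records")
  rec <- rec[startsWith(rec$source, "ppi:"), , drop = FALSE]
  if (nrow(rec) == 0) return(stats::setNames(integer(0), character(0)))
  pairs <- unique(rec[, c("protein", "detail")])
  tab <- table(pairs$detail)
  stats::setNames(as.integer(tab), names(tab))
}
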
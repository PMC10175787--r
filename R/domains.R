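#' Filtering parameters for domain-architecture assignment
#'
#' Post-scan filters applied to HMM domain hits before architecture
#' resolution. Defaults reproduce the standard stringent setting for
#' proteome-wide Pfam annotation: per-domain independent E-value at most
#' 0.001, at least 70% of the profile model covered by the alignment, and
#' pairwise residue overlaps of up to 25 residues tolerated between accepted
#' domains.
#'
#' `scan_evalue_max` documents the sequence-level E-value cutoff (together
#' with the model gathering thresholds) applied by the upstream HMM scan that
#' produced the hit table; it is a property of the scan stage and is not
#' re-applied here.
#'
#' @param scan_evalue_max Sequence E-value used at the scan stage (default
#'   0.01; informational).
#' @param independent_evalue_max Maximum per-domain independent E-value for a
#'   hit to be retained (default 0.001); boundary value retained.
#' @param model_coverage_min Minimum fraction of the HMM model length spanned
#'   by the hit's model coordinates (default 0.7); boundary value retained.
#' @param overlap_tolerance Maximum residue overlap allowed between two
#'   accepted domains (default 25); an overlap of exactly `overlap_tolerance`
#'   residues is allowed, one residue more is a conflict.
#' @return An object of class `filter_config`.
#' @examples
#' filter_config()
#' @export
filter_config <- function(scan_evalue_max = 0.01,
                          independent_evalue_max = 0.001,
                          model_coverage_min = 0.7,
                          overlap_tolerance = 25L) {
  if (!is.numeric(scan_evalue_max) || length(scan_evalue_max) != 1 || scan_evalue_max <= 0)
    config_error("filter_config field 'scan_evalue_max' must be a positive number")
  if (!is.numeric(independent_evalue_max) || length(independent_evalue_max) != 1 ||
      independent_evalue_max <= 0)
    config_error("filter_config field 'independent_evalue_max' must be a positive number")
  if (!is.numeric(model_coverage_min) || length(model_coverage_min) != 1 ||
      model_coverage_min <= 0 || model_coverage_min > 1)
    config_error("filter_config field 'model_coverage_min' must be in (0, 1]")
  if (!is.numeric(overlap_tolerance) || length(overlap_tolerance) != 1 || overlap_tolerance < 0)
    config_error("filter_config field 'overlap_tolerance' must be a non-negative number")
  structure(list(scan_evalue_max = scan_evalue_max,
                 independent_evalue_max = independent_evalue_max,
                 model_coverage_min = model_coverage_min,
                 overlap_tolerance = as.integer(overlap_tolerance)),
            class = "filter_config")
}

.hit_columns <- c("protein", "family", "clan", "ali_from", "ali_to",
                  "hmm_from", "hmm_to", "model_length",
                  "full_sequence_evalue", "independent_evalue", "bit_score")

.hit_numeric <- c("ali_from", "ali_to", "hmm_from", "hmm_to", "model_length",
                  "full_sequence_evalue", "independent_evalue", "bit_score")

validate_hits <- function(hits, what = "hit table") {
  require_columns(hits, .hit_columns, what)
  for (col in .hit_numeric) {
    if (!is.numeric(hits[[col]])) {
      suppressWarnings(v <- as.numeric(hits[[col]]))
      bad <- which(is.na(v) & !is.na(hits[[col]]) & nzchar(hits[[col]]))
      if (length(bad) > 0)
        format_error("%s: non-numeric value in column '%s' at row %d",
                     what, col, bad[1])
      hits[[col]] <- v
    }
  }
  bad <- which(hits$ali_to < hits$ali_from)
  if (length(bad) > 0)
    format_error("%s: ali_to < ali_from at row %d", what, bad[1])
  bad <- which(hits$hmm_to < hits$hmm_from | hits$hmm_from < 1 |
                 hits$hmm_to > hits$model_length)
  if (length(bad) > 0)
    format_error("%s: model coordinates outside [1, model_length] at row %d",
                 what, bad[1])
  bad <- which(hits$independent_evalue <= 0 | hits$full_sequence_evalue <= 0)
  if (length(bad) > 0)
    format_error("%s: E-values must be positive (row %d)", what, bad[1])
  hits$clan[is.na(hits$clan)] <- ""
  hits
}

#' Read a domain hit table
#'
#' Reads one HMM domain hit per row from a tab-separated file with columns
#' `protein`, `family`, `clan`, `ali_from`, `ali_to`, `hmm_from`, `hmm_to`,
#' `model_length`, `full_sequence_evalue`, `independent_evalue`, `bit_score`
#' (the package's hit-table dialect, as emitted by
#' [simulate_census_inputs()]). Coordinates are 1-based inclusive; `ali_*`
#' are residue positions on the protein, `hmm_*` positions on the profile
#' model. Malformed rows are rejected with their row number. For the raw
#' space-delimited per-domain tabular output of `hmmscan --domtblout`, use
#' [read_hmmscan_domtblout()].
#'
#' @param path Path to the tab-separated hit table.
#' @return A data frame of validated domain hits.
#' @seealso [filter_hits()], [resolve_architectures()]
#' @export
parse_hits <- function(path) {
  if (!file.exists(path)) format_error("hit table '%s' does not exist", path)
  hits <- read_tsv(path)
  validate_hits(hits, sprintf("hit table '%s'", path))
}

#' Read hmmscan per-domain tabular output
#'
#' Maps the standard 22+-column space-delimited `--domtblout` format of the
#' HMMER suite into the package's hit-table dialect by column position
#' (target = profile model, query = protein). The clan column is left empty;
#' populate it with [assign_clans()].
#'
#' @param path Path to a `--domtblout` file.
#' @return A data frame of validated domain hits.
#' @export
read_hmmscan_domtblout <- function(path) {
  if (!file.exists(path)) format_error("domtblout file '%s' does not exist", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    hits <- as.data.frame(stats::setNames(rep(list(character(0)), length(.hit_columns)),
                                          .hit_columns))
    for (col in .hit_numeric) hits[[col]] <- numeric(0)
    return(hits)
  }
  fields <- strsplit(lines, "[[:space:]]+")
  short <- which(vapply(fields, length, integer(1)) < 22L)
  if (length(short) > 0)
    format_error("domtblout '%s': fewer than 22 fields at data row %d", path, short[1])
  grab <- function(i) vapply(fields, `[[`, character(1), i)
  hits <- data.frame(
    protein = grab(4),
    family = grab(1),
    clan = "",
    ali_from = as.numeric(grab(18)),
    ali_to = as.numeric(grab(19)),
    hmm_from = as.numeric(grab(16)),
    hmm_to = as.numeric(grab(17)),
    model_length = as.numeric(grab(3)),
    full_sequence_evalue = as.numeric(grab(7)),
    independent_evalue = as.numeric(grab(13)),
    bit_score = as.numeric(grab(14)),
    stringsAsFactors = FALSE
  )
  validate_hits(hits, sprintf("domtblout '%s'", path))
}

#' Filter domain hits by independent E-value and model coverage
#'
#' Retains exactly the hits with independent E-value at most
#' `config$independent_evalue_max` and model coverage
#' `(hmm_to - hmm_from + 1) / model_length` at least
#' `config$model_coverage_min`. Input order is preserved.
#'
#' @param hits Data frame of domain hits (see [parse_hits()]).
#' @param config A [filter_config()].
#' @return The retained subset of `hits`.
#' @export
filter_hits <- function(hits, config = filter_config()) {
  hits <- validate_hits(hits, "hit table")
  coverage <- (hits$hmm_to - hits$hmm_from + 1) / hits$model_length
  keep <- hits$independent_evalue <= config$independent_evalue_max &
    coverage >= config$model_coverage_min
  hits[keep, , drop = FALSE]
}

# residue overlap between two 1-based inclusive intervals; 0 when disjoint
hit_overlap <- function(from1, to1, from2, to2) {
  pmax(0, pmin(to1, to2) - pmax(from1, from2) + 1)
}

# deterministic acceptance order: ascending independent E-value, ties broken
# by longer alignment, then smaller ali_from, then family accession
hit_order <- function(hits) {
  order(hits$independent_evalue,
        -(hits$ali_to - hits$ali_from + 1),
        hits$ali_from,
        hits$family)
}

#' Resolve overlapping domain hits into one protein's architecture
#'
#' Greedy overlap resolution: candidate hits are taken in ascending order of
#' independent E-value (the most significant model wins a contested region)
#' and a candidate is accepted if and only if its residue overlap with every
#' already-accepted domain is at most `config$overlap_tolerance`. The
#' accepted set is maximal: every rejected hit conflicts with some accepted
#' hit of lower-or-equal independent E-value. Ties on E-value are broken
#' deterministically (longer alignment, then smaller start, then family
#' name).
#'
#' All hits must belong to one protein and should already have passed
#' [filter_hits()].
#'
#' @param hits Data frame of filtered hits for a single protein.
#' @param config A [filter_config()]; only `overlap_tolerance` is used.
#' @return An object of class `domain_architecture`: a list with `protein`,
#'   `domains` (accepted hits ordered by `ali_from`, ties by `ali_to`) and
#'   `architecture` (the canonical `"FamA~FamB"` string).
#' @examples
#' hits <- data.frame(
#'   protein = "SYN00001", family = c("CH", "PH"), clan = "",
#'   ali_from = c(1, 80), ali_to = c(109, 180), hmm_from = 1,
#'   hmm_to = c(109, 101), model_length = c(109, 101),
#'   full_sequence_evalue = 1e-12, independent_evalue = c(1e-10, 1e-5),
#'   bit_score = 100
#' )
#' resolve_architecture(hits)$architecture  # 30-residue conflict: CH wins
#' @export
resolve_architecture <- function(hits, config = filter_config()) {
  protein <- unique(hits$protein)
  if (length(protein) > 1)
    usage_error("resolve_architecture() expects hits for a single protein, got %d",
                length(protein))
  if (nrow(hits) == 0) {
    return(structure(list(protein = character(0),
                          domains = hits,
                          architecture = ""),
                     class = "domain_architecture"))
  }
  h <- hits[hit_order(hits), , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(h))) {
    compatible <- all(hit_overlap(h$ali_from[i], h$ali_to[i],
                                  h$ali_from[accepted], h$ali_to[accepted]) <=
                        config$overlap_tolerance)
    if (compatible) accepted <- c(accepted, i)
  }
  kept <- h[accepted, , drop = FALSE]
  kept <- kept[order(kept$ali_from, kept$ali_to), , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(protein = protein,
                 domains = kept,
                 architecture = paste(kept$family, collapse = "~")),
            class = "domain_architecture")
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("<domain_architecture> %s: %s (%d domain%s)\n",
              if (length(x$protein)) x$protein else "(empty)",
              if (nzchar(x$architecture)) x$architecture else "-",
              nrow(x$domains), if (nrow(x$domains) == 1) "" else "s"))
  invisible(x)
}

#' Resolve architectures for every protein in a hit table
#'
#' Applies [resolve_architecture()] per protein (each sequence, canonical or
#' isoform, gets its own architecture) and returns the accepted hits of all
#' proteins in one table.
#'
#' @param hits Data frame of filtered hits, any number of proteins.
#' @param config A [filter_config()].
#' @return Data frame of accepted hits, ordered by protein then `ali_from`.
#' @export
resolve_architectures <- function(hits, config = filter_config()) {
  hits <- validate_hits(hits, "hit table")
  parts <- lapply(split(hits, hits$protein),
                  function(h) resolve_architecture(h, config)$domains)
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) out <- hits[0, , drop = FALSE]
  out[order(out$protein, out$ali_from, out$ali_to), , drop = FALSE]
}

#' Canonical architecture strings per protein
#'
#' @param accepted Accepted-hit table from [resolve_architectures()].
#' @return Data frame with one row per protein: `protein`, `architecture`
#'   (domains joined by `~` in sequence order), `n_domains`.
#' @export
architecture_table <- function(accepted) {
  require_columns(accepted, c("protein", "family", "ali_from", "ali_to"),
                  "accepted hit table")
  accepted <- accepted[order(accepted$protein, accepted$ali_from, accepted$ali_to), ]
  arch <- vapply(split(accepted$family, accepted$protein),
                 paste, character(1), collapse = "~")
  n <- vapply(split(accepted$family, accepted$protein), length, integer(1))
  data.frame(protein = names(arch), architecture = unname(arch),
             n_domains = unname(n), stringsAsFactors = FALSE)
}

#' Populate clan membership of accepted domains
#'
#' Pfam clans group related families into superfamilies. Families absent from
#' the mapping keep an empty clan; a family mapped to two different clans is
#' a format error.
#'
#' @param accepted Accepted-hit table (or any hit table) with `family` and
#'   `clan` columns.
#' @param clan_map Data frame with columns `family`, `clan`, or a path to a
#'   two-column TSV.
#' @return `accepted` with the `clan` column filled from the map.
#' @export
assign_clans <- function(accepted, clan_map) {
  if (is.character(clan_map) && length(clan_map) == 1) clan_map <- read_tsv(clan_map)
  require_columns(clan_map, c("family", "clan"), "clan map")
  conflict <- tapply(clan_map$clan, clan_map$family,
                     function(v) length(unique(v[nzchar(v)])) > 1)
  if (any(conflict))
    format_error("clan map assigns conflicting clans to family '%s'",
                 names(conflict)[conflict][1])
  clan_map <- clan_map[!duplicated(clan_map$family), ]
  idx <- match(accepted$family, clan_map$family)
  accepted$clan <- ifelse(is.na(idx), "", clan_map$clan[idx])
  accepted
}
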
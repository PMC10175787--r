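.lipid_mods <- c("farnesylation", "myristoylation", "palmitoylation",
                 "geranylgeranylation")

# fixed COG one-letter category -> broad functional group table
.cog_groups <- c(
  J = "information storage and processing", A = "information storage and processing",
  K = "information storage and processing", L = "information storage and processing",
  B = "information storage and processing",
  D = "cellular processes and signaling", Y = "cellular processes and signaling",
  V = "cellular processes and signaling", T = "cellular processes and signaling",
  M = "cellular processes and signaling", N = "cellular processes and signaling",
  Z = "cellular processes and signaling", W = "cellular processes and signaling",
  U = "cellular processes and signaling", O = "cellular processes and signaling",
  X = "cellular processes and signaling",
  C = "metabolism", G = "metabolism", E = "metabolism", F = "metabolism",
  H = "metabolism", I = "metabolism", P = "metabolism", Q = "metabolism",
  R = "poorly characterized", S = "poorly characterized"
)

#' COG category to broad-group mapping
#'
#' The fixed table mapping the one-letter COG functional categories to the
#' four broad groups (information storage and processing; cellular processes
#' and signaling; metabolism; poorly characterized). The S category (function
#' unknown) and R (general prediction only) map to poorly characterized.
#'
#' @return Data frame with columns `category`, `broad_group`.
#' @export
cog_group_table <- function() {
  data.frame(category = names(.cog_groups), broad_group = unname(.cog_groups),
             stringsAsFactors = FALSE)
}

#' Classify membrane localization from protein metadata
#'
#' Applies the annotation-based rules, in order of precedence, to each
#' metadata row:
#' \enumerate{
#'   \item `integral_membrane` if any of the `intramembrane`,
#'     `topological_domain` or `transmembrane` flags is set;
#'   \item `peripheral_membrane` if the subcellular-location text mentions a
#'     peripheral membrane association, or the protein carries at least one
#'     lipid modification (lipid anchors attach otherwise-soluble proteins to
#'     the membrane);
#'   \item `cytoplasmic` if the location mentions cytoplasm or cytoskeleton;
#'   \item `other` otherwise (including rows with missing annotation).
#' }
#' The classes are disjoint; integral evidence wins over lipidation.
#'
#' @param metadata Data frame with columns `accession`,
#'   `subcellular_location`, `lipidation` (`;`-separated modification names),
#'   and 0/1 flags `transmembrane`, `intramembrane`, `topological_domain`.
#' @return Data frame with one row per input row: `protein`, `cls`,
#'   `lipid_mods` (`;`-joined subset of farnesylation, myristoylation,
#'   palmitoylation, geranylgeranylation).
#' @export
classify_localization <- function(metadata) {
  require_columns(metadata, c("accession", "subcellular_location", "lipidation",
                              "transmembrane", "intramembrane",
                              "topological_domain"), "protein metadata")
  flag <- function(x) !is.na(x) & x %in% c(1, "1", TRUE, "TRUE")
  loc <- tolower(ifelse(is.na(metadata$subcellular_location), "",
                        metadata$subcellular_location))
  mods <- split_set(tolower(metadata$lipidation))
  mods <- lapply(mods, intersect, .lipid_mods)
  has_lipid <- vapply(mods, length, integer(1)) > 0
  integral <- flag(metadata$transmembrane) | flag(metadata$intramembrane) |
    flag(metadata$topological_domain)
  peripheral <- !integral & (grepl("peripheral membrane", loc, fixed = TRUE) | has_lipid)
  cytoplasmic <- !integral & !peripheral &
    (grepl("cytoplasm", loc, fixed = TRUE) | grepl("cytoskeleton", loc, fixed = TRUE))
  cls <- rep("other", nrow(metadata))
  cls[cytoplasmic] <- "cytoplasmic"
  cls[peripheral] <- "peripheral_membrane"
  cls[integral] <- "integral_membrane"
  data.frame(protein = metadata$accession, cls = cls,
             lipid_mods = join_set(mods), stringsAsFactors = FALSE)
}

#' Tally lipid modifications across localization calls
#'
#' @param calls Data frame from [classify_localization()].
#' @return Named list: one integer per modification type (a protein with two
#'   types counts once under each) plus `multi_modified`, the number of
#'   proteins carrying more than one modification type.
#' @export
lipidation_summary <- function(calls) {
  require_columns(calls, c("protein", "lipid_mods"), "localization calls")
  mods <- split_set(calls$lipid_mods)
  counts <- lapply(stats::setNames(.lipid_mods, .lipid_mods), function(m) {
    sum(vapply(mods, function(v) m %in% v, logical(1)))
  })
  counts$multi_modified <- sum(vapply(mods, length, integer(1)) > 1)
  counts
}

.reliability_levels <- c("enhanced", "supported", "approved", "uncertain")
.expression_levels <- c("high", "medium", "low", "not_detected")

normalize_token <- function(x) gsub(" ", "_", tolower(trimws(x)), fixed = TRUE)

#' Filter tissue-expression records by reliability and level
#'
#' Retains exactly the rows whose reliability is not `uncertain` and whose
#' expression level is not `not detected`. Both vocabularies are closed;
#' unknown tokens are a format error. Tokens are case-insensitive and may use
#' spaces or underscores.
#'
#' @param records Data frame with columns `protein`, `tissue`, `level`,
#'   `reliability`.
#' @return The retained subset, with tokens normalized to lower-case
#'   underscore form.
#' @export
filter_expression <- function(records) {
  require_columns(records, c("protein", "tissue", "level", "reliability"),
                  "expression table")
  records$level <- normalize_token(records$level)
  records$reliability <- normalize_token(records$reliability)
  bad <- setdiff(unique(records$level), .expression_levels)
  if (length(bad) > 0)
    format_error("unknown expression level token '%s'", bad[1])
  bad <- setdiff(unique(records$reliability), .reliability_levels)
  if (length(bad) > 0)
    format_error("unknown reliability token '%s'", bad[1])
  out <- records[records$reliability != "uncertain" &
                   records$level != "not_detected", , drop = FALSE]
  rownames(out) <- NULL
  out
}

.breadth_bins <- c("1", "2-5", "6-40", ">40")

#' Tissue breadth per protein and its histogram
#'
#' Counts, for each protein with at least one retained expression row, the
#' number of distinct tissues it is detected in, and bins the counts into
#' `1`, `2-5`, `6-40`, `>40`. The bins are exhaustive and mutually exclusive.
#' Apply [filter_expression()] first.
#'
#' @param records Filtered expression records.
#' @return List with `breadth` (data frame `protein`, `n_tissues`, `bin`) and
#'   `histogram` (named integer vector over the four bins).
#' @export
tissue_breadth <- function(records) {
  require_columns(records, c("protein", "tissue"), "expression table")
  n <- vapply(split(records$tissue, records$protein),
              function(v) length(unique(v)), integer(1))
  bin <- cut(n, breaks = c(0, 1, 5, 40, Inf), labels = .breadth_bins)
  breadth <- data.frame(protein = names(n), n_tissues = unname(n),
                        bin = as.character(bin), stringsAsFactors = FALSE)
  hist <- table(factor(breadth$bin, levels = .breadth_bins))
  list(breadth = breadth,
       histogram = stats::setNames(as.integer(hist), .breadth_bins))
}

#' Summarize COG functional categories for census proteins
#'
#' Splits multi-letter COG strings into one category per letter, maps each
#' letter to its broad functional group via the fixed [cog_group_table()],
#' and tallies single- versus multi-category proteins and per-group totals
#' (a protein contributes to every group one of its letters maps to).
#'
#' @param cog Data frame with columns `protein`, `categories` (a string of
#'   one-letter COG codes, e.g. `"TZ"`), and optionally `tax_level`.
#' @param census_proteins Optional character vector restricting the summary
#'   to census members.
#' @return List with `assignments` (data frame `protein`, `categories`,
#'   `broad_groups`), `n_single`, `n_multi`, `per_category` and
#'   `per_broad_group` named counts.
#' @export
summarize_cog <- function(cog, census_proteins = NULL) {
  require_columns(cog, c("protein", "categories"), "COG table")
  if (!is.null(census_proteins)) {
    cog <- cog[canonical_accession(cog$protein) %in% census_proteins, ,
               drop = FALSE]
  }
  letters_list <- strsplit(toupper(trimws(cog$categories)), "")
  letters_list <- lapply(letters_list, unique)
  unknown <- setdiff(unique(unlist(letters_list)), names(.cog_groups))
  if (length(unknown) > 0)
    format_error("unknown COG category letter '%s'", unknown[1])
  groups <- lapply(letters_list, function(v) sort(unique(unname(.cog_groups[v]))))
  assignments <- data.frame(protein = cog$protein,
                            categories = vapply(letters_list, paste, character(1),
                                                collapse = ""),
                            broad_groups = vapply(groups, paste, character(1),
                                                  collapse = ";"),
                            stringsAsFactors = FALSE)
  nlet <- vapply(letters_list, length, integer(1))
  per_cat <- table(factor(unlist(letters_list), levels = names(.cog_groups)))
  group_levels <- unique(unname(.cog_groups))
  per_grp <- table(factor(unlist(groups), levels = group_levels))
  list(assignments = assignments,
       n_single = sum(nlet == 1),
       n_multi = sum(nlet > 1),
       per_category = stats::setNames(as.integer(per_cat), names(.cog_groups)),
       per_broad_group = stats::setNames(as.integer(per_grp), group_levels))
}
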
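#' Read per-database PPI edge lists from a directory
#'
#' Collects every `ppi_<database>.tsv` file under `dir` (columns `a`, `b`,
#' `score`, `method_score`, `interaction_type`; `method_score` optional)
#' into one table with the database name taken from the file name.
#'
#' @param dir Directory containing the edge files, or a named character
#'   vector of file paths (names = database names).
#' @return Data frame with columns `database`, `a`, `b`, `score`,
#'   `method_score`, `interaction_type`.
#' @export
read_ppi_edges <- function(dir) {
  if (length(dir) == 1 && dir.exists(dir)) {
    files <- list.files(dir, pattern = "^ppi_.*\\.tsv$", full.names = TRUE)
    names(files) <- sub("^ppi_(.*)\\.tsv$", "\\1", basename(files))
  } else {
    files <- dir
    if (is.null(names(files)))
      usage_error("read_ppi_edges() needs a directory or a named vector of files")
  }
  if (length(files) == 0) format_error("no ppi_<database>.tsv files found")
  parts <- lapply(names(files), function(db) {
    tab <- read_tsv(files[[db]])
    require_columns(tab, c("a", "b", "score", "interaction_type"),
                    sprintf("edge file '%s'", files[[db]]))
    if (!"method_score" %in% names(tab)) tab$method_score <- NA_real_
    tab$score <- suppressWarnings(as.numeric(tab$score))
    tab$method_score <- suppressWarnings(as.numeric(tab$method_score))
    cbind(database = db, tab[, c("a", "b", "score", "method_score",
                                 "interaction_type")])
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Configure a full pipeline run
#'
#' Bundles every input path and every analysis parameter so that one object
#' drives all stages; all thresholds default to the package's standard
#' values, so the default configuration is the reference parameterization.
#' Inputs are read from `input_dir` using the file names written by
#' [simulate_census_inputs()].
#'
#' @param input_dir Directory holding the input files.
#' @param output_dir Directory for pipeline outputs.
#' @param filter A [filter_config()].
#' @param thresholds A [threshold_table()].
#' @param fdr_max Enrichment reporting cutoff on the BH-adjusted value
#'   (default 0.001).
#' @param include_actins Keep the actin query accessions in the census.
#' @param simulate Optional [simulation_config()]: generate the inputs into
#'   `input_dir` before running.
#' @param force Overwrite existing outputs (and fixture inputs when
#'   `simulate` is given).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            filter = filter_config(),
                            thresholds = threshold_table(),
                            fdr_max = 0.001,
                            include_actins = FALSE,
                            simulate = NULL,
                            force = FALSE) {
  stopifnot(inherits(filter, "filter_config"))
  if (!is.null(simulate)) stopifnot(inherits(simulate, "simulation_config"))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 filter = filter, thresholds = thresholds, fdr_max = fdr_max,
                 include_actins = include_actins, simulate = simulate,
                 force = force),
            class = "pipeline_config")
}

.required_inputs <- c("protein_metadata.tsv", "domain_hits.tsv",
                      "expression.tsv", "cog.tsv", "clan_map.tsv",
                      "pfam2go.tsv", "abd_families.txt", "actin_go_terms.txt",
                      "actin_queries.txt")

#' Run the complete census pipeline
#'
#' Executes, in order: optional fixture generation, domain-architecture
#' assignment (parse, filter, overlap-resolve, clan assignment), evidence
#' harvesting (PPI, actin-binding domains, three GO flavours), census
#' construction, classification (localization, lipidation, tissue breadth,
#' COG), term enrichment against the whole-proteome background, and summary.
#' All referenced inputs and the completeness of the threshold table are
#' checked before any stage runs; a stage failure aborts with the failing
#' stage named. Outputs (census, per-stage tables, enrichment results and a
#' JSON summary) are written under `config$output_dir`; an existing
#' non-empty output directory is refused unless `config$force` is set. Runs
#' with identical configuration and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `census`, `summary`, `output_dir` and the
#'   intermediate tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulate))
    simulate_census_inputs(config$simulate, config$input_dir,
                           force = config$force)

  inp <- function(name) file.path(config$input_dir, name)
  missing <- .required_inputs[!file.exists(inp(.required_inputs))]
  if (length(missing) > 0)
    config_error("missing input file(s) under '%s': %s", config$input_dir,
                 paste(missing, collapse = ", "))
  ppi_files <- list.files(config$input_dir, pattern = "^ppi_.*\\.tsv$")
  if (length(ppi_files) == 0)
    config_error("no ppi_<database>.tsv edge files under '%s'", config$input_dir)
  file_dbs <- sub("^ppi_(.*)\\.tsv$", "\\1", ppi_files)
  unknown <- setdiff(file_dbs, config$thresholds$database)
  if (length(unknown) > 0)
    config_error("threshold table has no entry for database(s): %s",
                 paste(unknown, collapse = ", "))
  if (dir.exists(config$output_dir) &&
      length(list.files(config$output_dir)) > 0 && !config$force)
    config_error("output directory '%s' is not empty; pass force = TRUE to overwrite",
                 config$output_dir)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log_stage <- function(name, n) message(sprintf("[%s] %d rows", name, n))

  metadata <- stage("read-inputs", read_tsv(inp("protein_metadata.tsv")))
  actins <- stage("read-inputs", readLines(inp("actin_queries.txt")))
  abd <- stage("read-inputs", readLines(inp("abd_families.txt")))
  go_terms <- stage("read-inputs", readLines(inp("actin_go_terms.txt")))
  edges <- stage("read-inputs", read_ppi_edges(config$input_dir))
  log_stage("read-inputs", nrow(metadata) + nrow(edges))

  accepted <- stage("annotate-domains", {
    hits <- parse_hits(inp("domain_hits.tsv"))
    kept <- filter_hits(hits, config$filter)
    acc <- resolve_architectures(kept, config$filter)
    assign_clans(acc, inp("clan_map.tsv"))
  })
  arch <- architecture_table(accepted)
  log_stage("annotate-domains", nrow(accepted))

  census <- stage("integrate", {
    recs <- list(
      ppi_evidence(edges, actins, config$thresholds,
                   include_actins = config$include_actins),
      domain_evidence(accepted, abd),
      go_evidence(go_terms, "go:uniprot", metadata = metadata),
      go_evidence(go_terms, "go:pfam2go", pfam2go = inp("pfam2go.tsv"),
                  accepted = accepted)
    )
    if (file.exists(inp("go_pdb_list.txt")))
      recs <- c(recs, list(go_evidence(go_terms, "go:pdb",
                                       curated_list = inp("go_pdb_list.txt"))))
    literature <- if (file.exists(inp("literature_list.txt")))
      inp("literature_list.txt") else NULL
    do.call(build_census, c(recs, list(literature = literature,
                                       actin_set = actins,
                                       include_actins = config$include_actins)))
  })
  log_stage("integrate", nrow(census))

  classify <- stage("classify", {
    canon <- metadata[metadata$accession == metadata$canonical, , drop = FALSE]
    calls <- classify_localization(canon)
    expr_tab <- filter_expression(read_tsv(inp("expression.tsv")))
    breadth <- tissue_breadth(expr_tab[expr_tab$protein %in% census$protein, ,
                                       drop = FALSE])
    cogs <- summarize_cog(read_tsv(inp("cog.tsv")), census$protein)
    list(calls = calls, expression = expr_tab, breadth = breadth, cogs = cogs)
  })
  log_stage("classify", nrow(classify$calls))

  enrichment <- stage("enrich", {
    canon <- metadata[metadata$accession == metadata$canonical, , drop = FALSE]
    sets <- split_set(canon$go_terms)
    term_map <- data.frame(
      term = unlist(sets),
      protein = rep(canon$accession, lengths(sets)),
      stringsAsFactors = FALSE
    )
    enrich_terms(census$protein, canon$accession, term_map)
  })
  log_stage("enrich", nrow(enrichment))

  summary <- stage("report",
                   summarize_census(census, accepted, classify$calls,
                                    classify$breadth, classify$cogs,
                                    enrichment = enrichment,
                                    fdr_max = config$fdr_max))

  out <- function(name) file.path(config$output_dir, name)
  write_tsv(as.data.frame(census), out("census.tsv"))
  write_tsv(attr(census, "records"), out("census_records.tsv"))
  write_tsv(arch, out("architectures.tsv"))
  write_tsv(classify$calls, out("localization.tsv"))
  write_tsv(classify$breadth$breadth, out("tissue_breadth.tsv"))
  write_tsv(classify$cogs$assignments, out("cog_assignments.tsv"))
  write_tsv(enrichment, out("enrichment.tsv"))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message(sprintf("pipeline complete: %d census proteins -> %s",
                  nrow(census), config$output_dir))
  invisible(list(census = census, summary = summary, accepted = accepted,
                 architectures = arch, classify = classify,
                 enrichment = enrichment, output_dir = config$output_dir))
}

count_named <- function(x) {
  if (length(x) == 0) return(stats::setNames(list(), character(0)))
  as.list(x)
}

#' Summarize a census into the standard report figures
#'
#' Every figure is a direct recount of the underlying tables: per-source and
#' per-actin evidence counts, distinct family / clan / architecture counts
#' over the census members (canonical sequences, with isoform-inclusive
#' architecture counts alongside), top families and clans (sorted by count,
#' ties by name), localization and lipidation breakdown, tissue-breadth
#' histogram, and COG totals.
#'
#' @param census An `aap_census`.
#' @param accepted Accepted-hit table (clans assigned) for all sequences.
#' @param calls Localization calls from [classify_localization()].
#' @param breadth Result of [tissue_breadth()] (census members).
#' @param cogs Result of [summarize_cog()] (census members).
#' @param enrichment Optional enrichment table from [enrich_terms()].
#' @param fdr_max Cutoff used for the significant-term count.
#' @param top_n Number of top families/clans to report (default 10).
#' @return A list (class `census_summary`) of summary figures, JSON-ready.
#' @export
summarize_census <- function(census, accepted, calls = NULL, breadth = NULL,
                             cogs = NULL, enrichment = NULL, fdr_max = 0.001,
                             top_n = 10L) {
  members <- census$protein
  canon_hits <- accepted[accepted$protein == canonical_accession(accepted$protein) &
                           accepted$protein %in% members, , drop = FALSE]
  all_hits <- accepted[canonical_accession(accepted$protein) %in% members, ,
                       drop = FALSE]
  arch_can <- architecture_table(canon_hits)
  arch_all <- architecture_table(all_hits)
  top_table <- function(x, n) {
    if (length(x) == 0) return(list())
    tab <- table(x)
    tab <- tab[order(-tab, names(tab))]
    count_named(stats::setNames(as.integer(tab), names(tab))[seq_len(min(n, length(tab)))])
  }
  s <- list(
    n_proteins = nrow(census),
    per_source = count_named(census_source_counts(census)),
    per_actin = count_named(census_actin_partner_counts(census)),
    n_distinct_families = length(unique(canon_hits$family)),
    n_distinct_clans = length(unique(canon_hits$clan[nzchar(canon_hits$clan)])),
    n_distinct_architectures = length(unique(arch_can$architecture)),
    n_distinct_architectures_incl_isoforms = length(unique(arch_all$architecture)),
    top_families = top_table(canon_hits$family[!duplicated(
      paste(canon_hits$protein, canon_hits$family))], top_n),
    top_clans = top_table(canon_hits$clan[nzchar(canon_hits$clan) & !duplicated(
      paste(canon_hits$protein, canon_hits$clan))], top_n)
  )
  if (!is.null(calls)) {
    member_calls <- calls[calls$protein %in% members, , drop = FALSE]
    s$localization <- count_named(stats::setNames(
      as.integer(table(factor(member_calls$cls,
                              levels = c("integral_membrane", "peripheral_membrane",
                                         "cytoplasmic", "other")))),
      c("integral_membrane", "peripheral_membrane", "cytoplasmic", "other")))
    s$lipidation <- lipidation_summary(member_calls)
  }
  if (!is.null(breadth)) s$tissue_histogram <- count_named(breadth$histogram)
  if (!is.null(cogs)) {
    s$cog <- list(n_single = cogs$n_single, n_multi = cogs$n_multi,
                  per_broad_group = count_named(cogs$per_broad_group))
  }
  if (!is.null(enrichment)) {
    s$enrichment <- list(n_terms_tested = nrow(enrichment),
                         n_significant = sum(enrichment$fdr <= fdr_max),
                         fdr_max = fdr_max)
  }
  structure(s, class = c("census_summary", "list"))
}

#' @export
print.census_summary <- function(x, ...) {
  cat(sprintf("<census_summary> %d proteins; %d families, %d clans, %d architectures\n",
              x$n_proteins, x$n_distinct_families, x$n_distinct_clans,
              x$n_distinct_architectures))
  if (length(x$per_source) > 0) {
    cat("per-source counts:",
        paste(sprintf("%s=%d", names(x$per_source), unlist(x$per_source)),
              collapse = ", "), "\n")
  }
  invisible(x)
}
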
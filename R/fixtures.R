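# Family pools used by the generator. The actin-binding (ABD) pool is the
# shipped curated list; the Pfam2GO pool maps to actin GO terms but is kept
# disjoint from the ABD pool so the domain and Pfam2GO evidence lines stay
# separately countable against the planted truth; the benign pool never
# yields actin evidence.
.benign_families <- c("Pkinase", "PH", "SH3_1", "LIM", "PDZ", "RRM_1",
                      "Ank_2", "EF-hand_1", "C2", "WD40", "zf-C2H2", "BTB",
                      "Death", "I-set", "fn3", "TPR_1", "ArfGap", "RhoGEF",
                      "HEAT_2", "Sushi")
.p2g_families <- c("Coronin", "Drebrin", "Caldesmon", "Tropomodulin", "Adducin")
.background_go <- c("GO:0005634", "GO:0005739", "GO:0005783", "GO:0005794",
                    "GO:0005886", "GO:0006412", "GO:0016301", "GO:0046872",
                    "GO:0005615", "GO:0007165")
.location_pool <- c("Cytoplasm", "Nucleus", "Cytoplasm, cytoskeleton",
                    "Cell membrane", "Cell membrane; Peripheral membrane protein",
                    "Secreted", "Mitochondrion", "Endoplasmic reticulum membrane")
.amino_acids <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.evidence_mix_sources <- c("ppi", "pfam_domain", "go_uniprot", "go_pfam2go",
                           "go_pdb", "literature")

# synthetic family -> clan map, fixed across seeds: families are grouped
# pairwise into synthetic clans (CLS####), every third family left unmapped
sim_clan_map <- function() {
  fams <- sort(c(abd_family_list(), .benign_families, .p2g_families, "Actin"))
  clan <- sprintf("CLS%04d", (seq_along(fams) - 1L) %/% 2L + 1L)
  clan[seq_along(fams) %% 3L == 0L] <- ""
  data.frame(family = fams, clan = clan, stringsAsFactors = FALSE)
}

# synthetic Pfam2GO mapping, fixed across seeds: each Pfam2GO-pool family
# maps to an actin GO term; a few benign families map to background terms
sim_pfam2go <- function() {
  actin_terms <- actin_go_term_list()
  rbind(
    data.frame(family = .p2g_families,
               go_id = actin_terms[(seq_along(.p2g_families) - 1L) %%
                                     length(actin_terms) + 1L],
               stringsAsFactors = FALSE),
    data.frame(family = .benign_families[1:5],
               go_id = .background_go[1:5], stringsAsFactors = FALSE)
  )
}

#' Configuration of the synthetic study
#'
#' Defines the conditions the generator emulates: proteome size, the actin
#' query set, the number of planted true AAPs, and the fraction of planted
#' AAPs discoverable through each evidence line. Defaults describe the
#' package's reference synthetic study: 500 proteins, the six conventional
#' actins as queries, and 120 planted AAPs with an evidence mix proportioned
#' like a real census (PPI the dominant line, protein-level GO annotation
#' next, then domain membership, with small Pfam2GO, structure-derived and
#' literature contributions).
#'
#' The same configuration and seed always produce byte-identical output
#' files.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins Total canonical proteins, actins included.
#' @param n_actins Number of actin query proteins (default 6; the first six
#'   use the shipped curated query accessions).
#' @param n_true_aaps Number of planted true AAPs among the non-actin
#'   proteins; must not exceed `n_proteins - n_actins`.
#' @param n_tissues Number of tissues in the expression table (default 45,
#'   so that breadths above 40 tissues occur).
#' @param isoform_fraction Fraction of non-actin proteins that also get a
#'   splice-isoform record (`-2` suffix; exercises isoform collapsing).
#' @param length_range Range of canonical sequence lengths (residues).
#' @param mean_domains_per_protein Poisson mean of benign background domains
#'   per sequence.
#' @param decoy_rates Named list of per-protein probabilities for planted
#'   negative cases: `evalue_fail` (an ABD hit failing the independent
#'   E-value filter on a non-planted protein), `coverage_fail`,
#'   `overlap_pair` (two passing hits overlapping more than the tolerance,
#'   with a known resolution winner).
#' @param evidence_mix Named fractions in \[0, 1\] of planted AAPs
#'   discoverable per evidence source (`ppi`, `pfam_domain`, `go_uniprot`,
#'   `go_pfam2go`, `go_pdb`, `literature`). When the mix is not all zero,
#'   any planted protein left without a source is given PPI evidence so that
#'   every planted AAP is recoverable.
#' @return An object of class `simulation_config`.
#' @examples
#' simulation_config(seed = 1, n_proteins = 50, n_true_aaps = 10)
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 500L,
                              n_actins = 6L,
                              n_true_aaps = 120L,
                              n_tissues = 45L,
                              isoform_fraction = 0.15,
                              length_range = c(150L, 1200L),
                              mean_domains_per_protein = 2,
                              decoy_rates = list(evalue_fail = 0.2,
                                                 coverage_fail = 0.2,
                                                 overlap_pair = 0.15),
                              evidence_mix = c(ppi = 0.73,
                                               pfam_domain = 0.10,
                                               go_uniprot = 0.31,
                                               go_pfam2go = 0.035,
                                               go_pdb = 0.011,
                                               literature = 0.02)) {
  chk_count <- function(x, field, min = 0L) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min)
      config_error("simulation_config field '%s' must be an integer >= %d", field, min)
    as.integer(x)
  }
  chk_frac <- function(x, field) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1))
      config_error("simulation_config field '%s' must lie in [0, 1]", field)
    x
  }
  seed <- chk_count(seed, "seed")
  if (seed >= 2^31 - 16) config_error("simulation_config field 'seed' too large")
  n_proteins <- chk_count(n_proteins, "n_proteins", 2L)
  n_actins <- chk_count(n_actins, "n_actins", 1L)
  n_true_aaps <- chk_count(n_true_aaps, "n_true_aaps")
  n_tissues <- chk_count(n_tissues, "n_tissues", 1L)
  if (n_actins >= n_proteins)
    config_error("simulation_config field 'n_actins' must be smaller than n_proteins")
  if (n_true_aaps > n_proteins - n_actins)
    config_error("simulation_config field 'n_true_aaps' exceeds n_proteins - n_actins")
  chk_frac(isoform_fraction, "isoform_fraction")
  if (length(length_range) != 2 || length_range[1] < 50 ||
      length_range[2] < length_range[1])
    config_error("simulation_config field 'length_range' must be ascending and >= 50")
  if (mean_domains_per_protein < 0)
    config_error("simulation_config field 'mean_domains_per_protein' must be >= 0")
  for (r in names(decoy_rates)) chk_frac(decoy_rates[[r]], paste0("decoy_rates$", r))
  unknown <- setdiff(names(evidence_mix), .evidence_mix_sources)
  if (length(unknown) > 0)
    config_error("simulation_config field 'evidence_mix' has unknown source(s): %s",
                 paste(unknown, collapse = ", "))
  mix <- stats::setNames(rep(0, length(.evidence_mix_sources)), .evidence_mix_sources)
  mix[names(evidence_mix)] <- chk_frac(unname(evidence_mix), "evidence_mix")
  structure(list(seed = seed, n_proteins = n_proteins, n_actins = n_actins,
                 n_true_aaps = n_true_aaps, n_tissues = n_tissues,
                 isoform_fraction = isoform_fraction,
                 length_range = as.integer(length_range),
                 mean_domains_per_protein = mean_domains_per_protein,
                 decoy_rates = decoy_rates, evidence_mix = mix),
            class = "simulation_config")
}

sim_actins <- function(config) {
  shipped <- actin_queries()
  n <- config$n_actins
  if (n <= nrow(shipped)) return(shipped[seq_len(n), , drop = FALSE])
  extra <- data.frame(accession = sprintf("ACTS%02d", seq_len(n - nrow(shipped))),
                      gene = sprintf("ACTS%02d", seq_len(n - nrow(shipped))),
                      protein_name = "Actin, synthetic", length = 375L,
                      stringsAsFactors = FALSE)
  rbind(shipped, extra)
}

#' Simulate a proteome with planted AAP ground truth
#'
#' Generates canonical proteins (actin queries first, then `SYN#####`
#' accessions), splice-isoform records for a configured fraction, random
#' amino-acid sequences (residue identity is never interpreted downstream;
#' only identifiers and lengths matter), a protein metadata table with GO
#' annotations, subcellular-location strings, lipidation and membrane flags,
#' and a ground-truth table naming the planted AAPs and the evidence sources
#' each will be discoverable through. Planted GO-annotation evidence places
#' an actin-related GO term in the metadata; no non-planted protein ever
#' receives one.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_proteome`: a list with `sequences`
#'   (named character vector, canonical then isoforms), `metadata` (one row
#'   per sequence), `actins` (query accessions) and `truth` (data frame
#'   `accession`, `sources` as `;`-joined evidence tags, `ppi_database`).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  actins <- sim_actins(config)
  n_other <- config$n_proteins - config$n_actins
  other <- sprintf("SYN%05d", seq_len(n_other))
  planted <- sort(sample(other, config$n_true_aaps))

  # evidence plan: independent draws per source at the configured fractions
  plan <- matrix(FALSE, nrow = length(planted), ncol = length(.evidence_mix_sources),
                 dimnames = list(planted, .evidence_mix_sources))
  for (s in .evidence_mix_sources) {
    n_s <- round(config$evidence_mix[[s]] * length(planted))
    if (n_s > 0) plan[sample(planted, n_s), s] <- TRUE
  }
  if (sum(config$evidence_mix) > 0 && length(planted) > 0) {
    orphan <- rownames(plan)[rowSums(plan) == 0]
    plan[orphan, "ppi"] <- TRUE          # every planted AAP must be recoverable
  }
  dbs <- threshold_table()$database
  ppi_db <- rep(NA_character_, length(planted))
  names(ppi_db) <- planted
  has_ppi <- plan[, "ppi"]
  ppi_db[has_ppi] <- sample(dbs, sum(has_ppi), replace = TRUE)

  source_tag <- c(ppi = "ppi", pfam_domain = "pfam_domain",
                  go_uniprot = "go:uniprot", go_pfam2go = "go:pfam2go",
                  go_pdb = "go:pdb", literature = "literature")
  sources <- vapply(planted, function(p) {
    tags <- source_tag[.evidence_mix_sources[plan[p, ]]]
    tags[tags == "ppi"] <- paste0("ppi:", ppi_db[[p]])
    paste(sort(tags), collapse = ";")
  }, character(1))
  truth <- data.frame(accession = planted, sources = unname(sources),
                      ppi_database = unname(ppi_db), stringsAsFactors = FALSE)

  lengths <- c(actins$length,
               sample(seq(config$length_range[1], config$length_range[2]),
                      n_other, replace = TRUE))
  canonical <- c(actins$accession, other)
  genes <- c(actins$gene, sprintf("GENE%05d", seq_len(n_other)))

  n_iso <- round(config$isoform_fraction * n_other)
  iso_of <- if (n_iso > 0) sort(sample(other, n_iso)) else character(0)
  iso_acc <- paste0(iso_of, "-2")
  iso_len <- lengths[match(iso_of, canonical)] + sample(0:60, length(iso_of),
                                                        replace = TRUE)

  go_uniprot_set <- truth$accession[grepl("go:uniprot", truth$sources, fixed = TRUE)]
  actin_terms <- actin_go_term_list()
  go_for <- function(acc) {
    base <- sample(.background_go, sample(0:3, 1))
    if (acc %in% go_uniprot_set)
      base <- c(base, sample(actin_terms, sample(1:2, 1)))
    paste(sort(unique(base)), collapse = ";")
  }
  go_terms <- vapply(canonical, go_for, character(1))

  lip_for <- function() {
    if (stats::runif(1) >= 0.08) return("")
    k <- if (stats::runif(1) < 0.15) 2L else 1L
    paste(sort(sample(.lipid_mods, k)), collapse = ";")
  }
  lipidation <- vapply(seq_along(canonical), function(i) lip_for(), character(1))
  location <- sample(.location_pool, length(canonical), replace = TRUE)
  location[seq_len(config$n_actins)] <- "Cytoplasm, cytoskeleton"
  tm <- stats::rbinom(length(canonical), 1, 0.10)
  im <- stats::rbinom(length(canonical), 1, 0.02)
  td <- stats::rbinom(length(canonical), 1, 0.06)

  metadata <- data.frame(
    accession = canonical, canonical = canonical, gene = genes,
    length = lengths, go_terms = unname(go_terms),
    subcellular_location = location, lipidation = lipidation,
    transmembrane = tm, intramembrane = im, topological_domain = td,
    stringsAsFactors = FALSE
  )
  if (length(iso_acc) > 0) {
    idx <- match(iso_of, canonical)
    iso_meta <- metadata[idx, , drop = FALSE]
    iso_meta$accession <- iso_acc
    iso_meta$length <- iso_len
    metadata <- rbind(metadata, iso_meta)
  }
  rownames(metadata) <- NULL

  sequences <- vapply(metadata$length, function(L) {
    paste(sample(.amino_acids, L, replace = TRUE), collapse = "")
  }, character(1))
  names(sequences) <- metadata$accession

  structure(list(sequences = sequences, metadata = metadata,
                 actins = actins$accession, truth = truth),
            class = "synthetic_proteome")
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf("<synthetic_proteome> %d sequences (%d canonical, %d actins), %d planted AAPs\n",
              nrow(x$metadata), sum(x$metadata$accession == x$metadata$canonical),
              length(x$actins), nrow(x$truth)))
  invisible(x)
}

passing_hit <- function(protein, family, clan, ali_from, len) {
  cov <- stats::runif(1, 0.75, 1)
  span <- max(1L, round(cov * len))
  hmm_from <- sample.int(len - span + 1L, 1)
  ie <- 10^stats::runif(1, -30, -4)
  data.frame(protein = protein, family = family, clan = clan,
             ali_from = ali_from, ali_to = ali_from + len - 1L,
             hmm_from = hmm_from, hmm_to = hmm_from + span - 1L,
             model_length = len,
             full_sequence_evalue = ie * 10^stats::runif(1, -3, 0),
             independent_evalue = ie,
             bit_score = round(stats::runif(1, 25, 500), 1),
             stringsAsFactors = FALSE)
}

#' Simulate an HMM-scan domain hit table
#'
#' Emits one hit row per domain match in the package's hit-table dialect.
#' Planted actin-binding-domain and Pfam2GO-family hits (for proteins whose
#' evidence plan includes those sources) always pass the downstream filters
#' and survive overlap resolution; non-planted proteins never receive a
#' passing hit from either pool. Controlled negative cases are planted at
#' the configured `decoy_rates`: ABD hits failing the independent E-value
#' filter, hits failing model coverage, and mutually overlapping passing-hit
#' pairs whose resolution winner (the lower independent E-value) is known.
#'
#' @param proteome A [simulate_proteome()] result.
#' @param config The same [simulation_config()].
#' @return Data frame of domain hits (see [parse_hits()] for the dialect).
#' @export
simulate_domain_hits <- function(proteome, config) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  set.seed(config$seed + 1L)
  clan_map <- sim_clan_map()
  clan_of <- function(f) {
    i <- match(f, clan_map$family)
    ifelse(is.na(i), "", clan_map$clan[i])
  }
  truth <- proteome$truth
  abd_set <- truth$accession[grepl("pfam_domain", truth$sources, fixed = TRUE)]
  p2g_set <- truth$accession[grepl("go:pfam2go", truth$sources, fixed = TRUE)]
  abd_pool <- abd_family_list()
  rates <- config$decoy_rates

  rows <- vector("list", nrow(proteome$metadata))
  for (i in seq_len(nrow(proteome$metadata))) {
    acc <- proteome$metadata$accession[i]
    can <- proteome$metadata$canonical[i]
    L <- proteome$metadata$length[i]
    out <- list()
    if (can %in% proteome$actins) {
      len <- min(L, 370L)
      out[[length(out) + 1L]] <- passing_hit(acc, "Actin", clan_of("Actin"), 1L, len)
    } else {
      planted_fams <- character(0)
      if (can %in% abd_set) planted_fams <- c(planted_fams, sample(abd_pool, 1))
      if (can %in% p2g_set) planted_fams <- c(planted_fams, sample(.p2g_families, 1))
      n_bg <- stats::rpois(1, config$mean_domains_per_protein)
      fams <- c(planted_fams, sample(.benign_families, n_bg, replace = TRUE))
      pos <- 1L
      for (j in seq_along(fams)) {
        # planted hits are short and tightly packed so they always fit and
        # always survive resolution; background domains spread out behind
        len <- if (j <= length(planted_fams)) sample(40:60, 1) else sample(40:120, 1)
        if (pos + len - 1L > L) break
        out[[length(out) + 1L]] <- passing_hit(acc, fams[j], clan_of(fams[j]),
                                               pos, len)
        gap <- if (j <= length(planted_fams)) {
          5L
        } else if (stats::runif(1) < 0.25) {
          -sample(0:25, 1)          # allowed overlap with the previous domain
        } else sample(0:30, 1)
        pos <- pos + len + gap
        if (pos < 1L) pos <- 1L
      }
      # decoy: ABD hit failing the independent E-value filter, only on
      # proteins without planted domain evidence
      if (!can %in% abd_set && !can %in% p2g_set &&
          stats::runif(1) < rates$evalue_fail && L >= 80) {
        h <- passing_hit(acc, sample(abd_pool, 1), "", sample.int(L - 79L, 1), 80L)
        h$clan <- clan_of(h$family)
        h$independent_evalue <- 10^stats::runif(1, -2.9, -1.2)   # > 0.001
        out[[length(out) + 1L]] <- h
      }
      # decoy: hit failing model coverage
      if (stats::runif(1) < rates$coverage_fail && L >= 100) {
        fam <- if (!can %in% abd_set && !can %in% p2g_set &&
                   stats::runif(1) < 0.5) sample(abd_pool, 1) else sample(.benign_families, 1)
        h <- passing_hit(acc, fam, clan_of(fam), sample.int(L - 59L, 1), 60L)
        h$model_length <- 120L                      # coverage <= 0.5 < 0.7
        h$hmm_from <- 1L
        h$hmm_to <- 60L
        out[[length(out) + 1L]] <- h
      }
      # decoy: two passing benign hits overlapping > tolerance; the lower
      # independent E-value must win resolution. Placed in the free region
      # beyond all other passing hits so the outcome is forced.
      if (stats::runif(1) < rates$overlap_pair && pos + 159L <= L) {
        fams2 <- sample(.benign_families, 2)
        start <- pos
        a <- passing_hit(acc, fams2[1], clan_of(fams2[1]), start, 100L)
        b <- passing_hit(acc, fams2[2], clan_of(fams2[2]),
                         start + 100L - sample(30:60, 1), 60L)
        a$independent_evalue <- 1e-10
        b$independent_evalue <- 1e-5
        out[[length(out) + 1L]] <- a
        out[[length(out) + 1L]] <- b
      }
    }
    rows[[i]] <- do.call(rbind, out)
  }
  hits <- do.call(rbind, c(Filter(Negate(is.null), rows),
                           list(make.row.names = FALSE)))
  validate_hits(hits, "simulated hit table")
}

#' Simulate per-database PPI edge lists
#'
#' Every planted PPI-evidence protein receives one edge to a random actin
#' query in its assigned database, typed `physical`, with score strictly
#' above that database's threshold (for two-score databases, both scores
#' pass; for databases without a score filter the score is left empty). A
#' fifth of planted edges attach to the protein's isoform accession when one
#' exists, exercising isoform collapsing. Decoy proteins (never planted)
#' receive edges that must not yield evidence: sub-threshold physical edges,
#' high-scoring `functional` edges, or (for the two-score database) a
#' passing annotation score with a failing method score. Background noise
#' edges between non-actin pairs are added and must be ignored downstream.
#'
#' @param proteome A [simulate_proteome()] result.
#' @param config The same [simulation_config()].
#' @return Data frame with columns `database`, `a`, `b`, `score`,
#'   `method_score`, `interaction_type`.
#' @export
simulate_ppi_edges <- function(proteome, config) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  set.seed(config$seed + 2L)
  thresholds <- threshold_table()
  truth <- proteome$truth
  meta <- proteome$metadata
  has_iso <- unique(meta$canonical[meta$accession != meta$canonical])
  non_actin <- setdiff(meta$canonical, proteome$actins)
  decoy_pool <- setdiff(non_actin, truth$accession)

  above <- function(db, lo) {
    i <- match(db, thresholds$database)
    hi <- thresholds$scale_max[i]
    lo + (0.01 + 0.98 * stats::runif(length(db))) * (hi - lo)
  }
  edge <- function(db, a, b, score, method_score, type) {
    data.frame(database = db, a = a, b = b, score = score,
               method_score = method_score, interaction_type = type,
               stringsAsFactors = FALSE)
  }

  out <- list()
  ppi_truth <- truth[!is.na(truth$ppi_database), , drop = FALSE]
  if (nrow(ppi_truth) > 0) {
    b_acc <- ppi_truth$accession
    use_iso <- b_acc %in% has_iso & stats::runif(length(b_acc)) < 0.2
    b_acc[use_iso] <- paste0(b_acc[use_iso], "-2")
    db <- ppi_truth$ppi_database
    i <- match(db, thresholds$database)
    score <- ifelse(is.na(thresholds$score_min[i]), NA_real_,
                    above(db, thresholds$score_min[i]))
    method <- ifelse(is.na(thresholds$method_score_min[i]), NA_real_,
                     above(db, thresholds$method_score_min[i]))
    out[[length(out) + 1L]] <- edge(db, sample(proteome$actins, nrow(ppi_truth),
                                               replace = TRUE),
                                    b_acc, score, method, "physical")
  }

  n_decoy <- min(length(decoy_pool), max(20L, round(0.3 * config$n_true_aaps)))
  if (n_decoy > 0) {
    decoys <- sample(decoy_pool, n_decoy)
    db <- sample(thresholds$database, n_decoy, replace = TRUE)
    i <- match(db, thresholds$database)
    kind <- stats::runif(n_decoy)
    score <- numeric(n_decoy)
    method <- rep(NA_real_, n_decoy)
    type <- character(n_decoy)
    for (j in seq_len(n_decoy)) {
      if (is.na(thresholds$score_min[i[j]])) {
        score[j] <- NA_real_; type[j] <- "functional"
      } else if (kind[j] < 0.5) {       # physical but sub-threshold
        score[j] <- stats::runif(1, 0, thresholds$score_min[i[j]])
        type[j] <- "physical"
        if (!is.na(thresholds$method_score_min[i[j]]))
          method[j] <- above(db[j], thresholds$method_score_min[i[j]])
      } else if (!is.na(thresholds$method_score_min[i[j]]) && kind[j] < 0.75) {
        # annotation score passes, method score fails
        score[j] <- above(db[j], thresholds$score_min[i[j]])
        method[j] <- stats::runif(1, 0, thresholds$method_score_min[i[j]])
        type[j] <- "physical"
      } else {                          # high score but non-physical
        score[j] <- above(db[j], thresholds$score_min[i[j]])
        if (!is.na(thresholds$method_score_min[i[j]]))
          method[j] <- above(db[j], thresholds$method_score_min[i[j]])
        type[j] <- "functional"
      }
    }
    out[[length(out) + 1L]] <- edge(db, sample(proteome$actins, n_decoy,
                                               replace = TRUE),
                                    decoys, score, method, type)
  }

  n_noise <- min(length(non_actin) %/% 2L, 50L)
  if (n_noise > 1) {
    pair <- matrix(sample(non_actin, 2L * n_noise), ncol = 2)
    db <- sample(thresholds$database, n_noise, replace = TRUE)
    i <- match(db, thresholds$database)
    score <- ifelse(is.na(thresholds$score_min[i]), NA_real_,
                    above(db, thresholds$score_min[i]))
    method <- ifelse(is.na(thresholds$method_score_min[i]), NA_real_,
                     above(db, thresholds$method_score_min[i]))
    out[[length(out) + 1L]] <- edge(db, pair[, 1], pair[, 2], score, method,
                                    "physical")
  }
  edges <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  edges[order(edges$database, edges$a, edges$b), , drop = FALSE]
}

#' Simulate a tissue-expression table
#'
#' One row per (protein, tissue) with an expression level (`high`, `medium`,
#' `low`, `not detected`) and an annotation reliability (`enhanced`,
#' `supported`, `approved`, `uncertain`). Per-protein tissue breadth is drawn
#' from a mixture over the breadth classes 1, 2-5, 6-40 and >40 tissues
#' (where `n_tissues` permits); noise rows carrying `uncertain` reliability
#' or `not detected` levels are added in otherwise-unused tissues and must
#' be removed by the downstream filter without changing any breadth.
#'
#' @param proteome A [simulate_proteome()] result.
#' @param config The same [simulation_config()].
#' @return Data frame with columns `protein`, `tissue`, `level`,
#'   `reliability`.
#' @export
simulate_expression <- function(proteome, config) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  set.seed(config$seed + 3L)
  nt <- config$n_tissues
  tissues <- sprintf("tissue_%02d", seq_len(nt))
  bins <- list(1L, 2:5, 6:40, 41:200)
  probs <- c(0.02, 0.53, 0.40, 0.05)
  feasible <- vapply(bins, function(b) any(b <= nt), logical(1))
  bins <- lapply(bins[feasible], function(b) b[b <= nt])
  probs <- probs[feasible] / sum(probs[feasible])

  canonical <- unique(proteome$metadata$canonical)
  out <- vector("list", length(canonical))
  for (i in seq_along(canonical)) {
    b <- bins[[sample.int(length(bins), 1, prob = probs)]]
    breadth <- if (length(b) == 1) b else sample(b, 1)
    used <- sample(tissues, breadth)
    rows <- data.frame(protein = canonical[i], tissue = used,
                       level = sample(c("high", "medium", "low"), breadth,
                                      replace = TRUE, prob = c(0.35, 0.45, 0.2)),
                       reliability = sample(c("enhanced", "supported", "approved"),
                                            breadth, replace = TRUE),
                       stringsAsFactors = FALSE)
    unused <- setdiff(tissues, used)
    if (length(unused) > 0 && stats::runif(1) < 0.15) {
      rows <- rbind(rows, data.frame(protein = canonical[i],
                                     tissue = unused[1], level = "high",
                                     reliability = "uncertain",
                                     stringsAsFactors = FALSE))
      unused <- unused[-1]
    }
    if (length(unused) > 0 && stats::runif(1) < 0.15) {
      rows <- rbind(rows, data.frame(protein = canonical[i],
                                     tissue = unused[1], level = "not detected",
                                     reliability = "approved",
                                     stringsAsFactors = FALSE))
    }
    out[[i]] <- rows
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate an ortholog/COG assignment table
#'
#' One row per canonical protein with a string of one-letter COG functional
#' categories (about 5% of proteins get two letters, the rest one, weighted
#' toward the categories typical of cytoskeleton-associated proteins) and a
#' taxonomic level.
#'
#' @param proteome A [simulate_proteome()] result.
#' @param config The same [simulation_config()].
#' @return Data frame with columns `protein`, `categories`, `tax_level`.
#' @export
simulate_cog <- function(proteome, config) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  set.seed(config$seed + 4L)
  pool <- c(T = 0.20, Z = 0.15, K = 0.12, O = 0.10, U = 0.10, A = 0.08,
            C = 0.05, E = 0.05, J = 0.05, S = 0.10)
  canonical <- unique(proteome$metadata$canonical)
  cats <- vapply(canonical, function(p) {
    k <- if (stats::runif(1) < 0.05) 2L else 1L
    paste(sample(names(pool), k, prob = pool), collapse = "")
  }, character(1))
  data.frame(protein = canonical, categories = unname(cats),
             tax_level = sample(c("Metazoa", "Eukaryota"), length(canonical),
                                replace = TRUE, prob = c(0.8, 0.2)),
             stringsAsFactors = FALSE)
}

#' Generate and write the full synthetic input set
#'
#' Runs every simulator and writes all consumed input formats under one
#' directory: `proteome.fasta`, `protein_metadata.tsv`, `domain_hits.tsv`,
#' one `ppi_<database>.tsv` per configured database, `expression.tsv`,
#' `cog.tsv`, `clan_map.tsv`, `pfam2go.tsv`, the curated lists
#' (`abd_families.txt`, `actin_go_terms.txt`, `actin_queries.txt`,
#' `go_pdb_list.txt`, `literature_list.txt`) and `ground_truth.tsv`.
#' Identical configurations produce byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param force Overwrite an existing non-empty directory (default `FALSE`).
#' @return Invisibly, a list with `dir`, `paths` (named file paths),
#'   `proteome` and `truth`.
#' @export
simulate_census_inputs <- function(config, dir, force = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    config_error("directory '%s' is not empty; pass force = TRUE to overwrite", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  proteome <- simulate_proteome(config)
  hits <- simulate_domain_hits(proteome, config)
  edges <- simulate_ppi_edges(proteome, config)
  expression <- simulate_expression(proteome, config)
  cog <- simulate_cog(proteome, config)
  truth <- proteome$truth

  paths <- c()
  p <- function(name) file.path(dir, name)

  seqs <- Biostrings::AAStringSet(proteome$sequences)
  Biostrings::writeXStringSet(seqs, p("proteome.fasta"), width = 60L)
  paths["fasta"] <- p("proteome.fasta")
  paths["metadata"] <- write_tsv(proteome$metadata, p("protein_metadata.tsv"))
  paths["domain_hits"] <- write_tsv(hits, p("domain_hits.tsv"))
  for (db in threshold_table()$database) {
    sub <- edges[edges$database == db,
                 c("a", "b", "score", "method_score", "interaction_type")]
    paths[paste0("ppi_", db)] <- write_tsv(sub, p(sprintf("ppi_%s.tsv", db)))
  }
  paths["expression"] <- write_tsv(expression, p("expression.tsv"))
  paths["cog"] <- write_tsv(cog, p("cog.tsv"))
  paths["clan_map"] <- write_tsv(sim_clan_map(), p("clan_map.tsv"))
  paths["pfam2go"] <- write_tsv(sim_pfam2go(), p("pfam2go.tsv"))
  writeLines(abd_family_list(), p("abd_families.txt"))
  paths["abd_families"] <- p("abd_families.txt")
  writeLines(actin_go_term_list(), p("actin_go_terms.txt"))
  paths["actin_go_terms"] <- p("actin_go_terms.txt")
  writeLines(proteome$actins, p("actin_queries.txt"))
  paths["actin_queries"] <- p("actin_queries.txt")
  pdb <- truth$accession[grepl("go:pdb", truth$sources, fixed = TRUE)]
  writeLines(pdb, p("go_pdb_list.txt"))
  paths["go_pdb_list"] <- p("go_pdb_list.txt")
  lit <- truth$accession[grepl("literature", truth$sources, fixed = TRUE)]
  writeLines(lit, p("literature_list.txt"))
  paths["literature_list"] <- p("literature_list.txt")
  paths["ground_truth"] <- write_tsv(truth, p("ground_truth.tsv"))

  invisible(list(dir = dir, paths = paths, proteome = proteome, truth = truth))
}
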
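test_that("per-database score thresholds are strict and physical-only", {
  actins <- "P60709"
  # combined-score database on the 0-1000 scale
  expect_equal(nrow(ppi_evidence(default_edge("string", 850), actins)), 1)
  expect_equal(nrow(ppi_evidence(default_edge("string", 700), actins)), 0)
  # 0-1 scale database at its exact threshold
  expect_equal(nrow(ppi_evidence(default_edge("mentha", 0.6), actins)), 0)
  expect_equal(nrow(ppi_evidence(default_edge("mentha", 0.601), actins)), 1)
  # two-score database: both thresholds required
  expect_equal(nrow(ppi_evidence(default_edge("hitpredict", 0.7,
                                              method_score = 0.40), actins)), 0)
  expect_equal(nrow(ppi_evidence(default_edge("hitpredict", 0.7,
                                              method_score = 0.50), actins)), 1)
  # a high-scoring functional edge never yields evidence
  expect_equal(nrow(ppi_evidence(default_edge("mentha", 0.99, "functional"),
                                 actins)), 0)
  # no-threshold database: all physical edges pass, functional do not
  expect_equal(nrow(ppi_evidence(default_edge("dip", NA), actins)), 1)
  expect_equal(nrow(ppi_evidence(default_edge("dip", NA, "functional"),
                                 actins)), 0)
})

test_that("edge validation flags unknown databases and out-of-scale scores", {
  expect_error(ppi_evidence(default_edge("stringdb", 900), "P60709"),
               "threshold table", class = "aap_config_error")
  expect_error(ppi_evidence(default_edge("mentha", 1.4), "P60709"),
               "scale", class = "aap_format_error")
  # edges not touching an actin are silently ignored
  e <- default_edge("string", 900, a = "SYN00009")
  expect_equal(nrow(ppi_evidence(e, "P60709")), 0)
})

test_that("PPI records carry the actin partner and canonical accessions", {
  e <- rbind(default_edge("string", 900, b = "SYN00007-2"),
             default_edge("mentha", 0.9, a = "SYN00008", b = "P60709"))
  rec <- ppi_evidence(e, "P60709")
  expect_setequal(rec$protein, c("SYN00007", "SYN00008"))
  expect_setequal(rec$source, c("ppi:string", "ppi:mentha"))
  expect_equal(unique(rec$detail), "P60709")
})

test_that("domain evidence uses accepted domains only", {
  accepted <- rbind(mk_hit(family = "CH"),
                    mk_hit(protein = "SYN00002", family = "SH3_1"),
                    mk_hit(protein = "SYN00003", family = "PH"))
  rec <- domain_evidence(accepted, c("CH", "VHP"))
  expect_equal(rec$protein, "SYN00001")
  expect_equal(rec$source, "pfam_domain")
  expect_equal(rec$detail, "CH")
  # an ABD hit removed upstream (here: failing the E-value filter) never counts
  hits <- rbind(mk_hit(protein = "SYN00009", family = "CH", ie = 0.005),
                mk_hit(protein = "SYN00009", family = "PH", ali_from = 200,
                       ali_to = 300))
  acc <- resolve_architectures(filter_hits(hits))
  expect_equal(nrow(domain_evidence(acc, c("CH", "VHP"))), 0)
  expect_error(domain_evidence(accepted, character(0)),
               class = "aap_config_error")
})

test_that("the three GO evidence flavours are independent and deduplicated", {
  terms <- c("GO:0003779", "GO:0015629")
  meta <- data.frame(accession = c("SYN00001", "SYN00002"),
                     go_terms = c("GO:0003779;GO:0005634", "GO:0005634"))
  rec <- go_evidence(terms, "go:uniprot", metadata = meta)
  expect_equal(rec$protein, "SYN00001")
  expect_equal(rec$detail, "GO:0003779")

  p2g <- data.frame(family = c("Coronin", "PH"),
                    go_id = c("GO:0015629", "GO:0005634"))
  accepted <- rbind(mk_hit(family = "Coronin"),
                    mk_hit(protein = "SYN00002", family = "PH"))
  rec2 <- go_evidence(terms, "go:pfam2go", pfam2go = p2g, accepted = accepted)
  expect_equal(rec2$protein, "SYN00001")
  expect_equal(rec2$source, "go:pfam2go")

  rec3 <- go_evidence(terms, "go:pdb", curated_list = c("SYN00004", "SYN00004"))
  expect_equal(rec3$protein, "SYN00004")

  # a protein with both a listed term and a mapping family gets two records
  both <- rbind(rec, rec2)
  expect_equal(sum(both$protein == "SYN00001"), 2)
  expect_setequal(both$source[both$protein == "SYN00001"],
                  c("go:uniprot", "go:pfam2go"))
})

test_that("pfam2go reader reports malformed lines by number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family\tgo_id", "CH\tGO:0003779", "broken-line"), path)
  expect_error(read_pfam2go(path), "line 3", class = "aap_format_error")
})

test_that("census union collapses isoforms, adds literature, excludes actins", {
  r1 <- data.frame(protein = c("SYN00007", "SYN00007-2", "P60709"),
                   source = "ppi:string", detail = "P60709", score = 900)
  r2 <- data.frame(protein = "SYN00007", source = "pfam_domain",
                   detail = "CH", score = NA_real_)
  census <- build_census(r1, r2, literature = "SYN00099",
                         actin_set = "P60709")
  expect_equal(census$protein, c("SYN00007", "SYN00099"))
  expect_equal(census$sources[1], "pfam_domain;ppi:string")
  expect_equal(census$n_sources, c(2L, 1L))
  counts <- census_source_counts(census)
  expect_equal(counts[["literature"]], 1L)
  expect_equal(counts[["ppi:string"]], 1L)

  # union bound: census size between max single-source count and the sum
  expect_true(nrow(census) >= max(counts) && nrow(census) <= sum(counts))

  # provenance conservation: each record's canonical protein is in exactly
  # one entry, and that entry lists the record's source
  rec <- attr(census, "records")
  for (i in seq_len(nrow(rec))) {
    entry <- census[census$protein == rec$protein[i], ]
    expect_equal(nrow(entry), 1)
    expect_true(rec$source[i] %in% strsplit(entry$sources, ";")[[1]])
  }

  with_actin <- build_census(r1, r2, actin_set = "P60709",
                             include_actins = TRUE)
  expect_true("P60709" %in% with_actin$protein)
})

test_that("perturbing one edge score across the threshold flips one record", {
  actins <- "P60709"
  edges <- rbind(default_edge("mentha", 0.6, b = "SYN00001"),
                 default_edge("mentha", 0.9, b = "SYN00002"))
  before <- ppi_evidence(edges, actins)
  edges$score[1] <- 0.6 + 1e-9
  after <- ppi_evidence(edges, actins)
  expect_equal(nrow(after) - nrow(before), 1)
  expect_setequal(setdiff(after$protein, before$protein), "SYN00001")
})
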
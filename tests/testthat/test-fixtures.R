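small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_proteins = 60, n_true_aaps = 20,
                    n_tissues = 12, ...)
}

test_that("configuration invariants are enforced with the field named", {
  expect_error(simulation_config(n_proteins = 50, n_true_aaps = 60),
               "n_true_aaps", class = "aap_config_error")
  expect_error(simulation_config(seed = -1), "seed", class = "aap_config_error")
  expect_error(simulation_config(evidence_mix = c(ppi = 1.4)),
               "evidence_mix", class = "aap_config_error")
  expect_error(simulation_config(evidence_mix = c(nonsense = 0.5)),
               "nonsense", class = "aap_config_error")
  expect_error(simulation_config(n_tissues = 0), "n_tissues",
               class = "aap_config_error")
})

test_that("identical configurations produce byte-identical output files", {
  cfg <- small_config(seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_census_inputs(cfg, d1, force = TRUE)
  simulate_census_inputs(cfg, d2, force = TRUE)
  expect_identical(md5_tree(d1), md5_tree(d2))
  # a different seed changes the outputs
  d3 <- withr::local_tempdir()
  simulate_census_inputs(small_config(seed = 4), d3, force = TRUE)
  expect_false(identical(unname(md5_tree(d1)), unname(md5_tree(d3))))
  # refusal to overwrite without force
  expect_error(simulate_census_inputs(cfg, d1), "force",
               class = "aap_config_error")
})

test_that("an all-zero evidence mix leaves every evidence plan empty", {
  cfg <- small_config(evidence_mix = c(ppi = 0, pfam_domain = 0,
                                       go_uniprot = 0, go_pfam2go = 0,
                                       go_pdb = 0, literature = 0))
  prot <- simulate_proteome(cfg)
  expect_equal(nrow(prot$truth), 20)
  expect_true(all(prot$truth$sources == ""))
})

test_that("planted domain evidence passes the filters; decoys never do", {
  cfg <- small_config(seed = 8)
  prot <- simulate_proteome(cfg)
  hits <- simulate_domain_hits(prot, cfg)
  accepted <- resolve_architectures(filter_hits(hits))
  rec <- domain_evidence(accepted)
  planted <- prot$truth$accession[grepl("pfam_domain", prot$truth$sources)]
  expect_setequal(rec$protein, planted)
  # every emitted FASTA record has a metadata row and vice versa
  expect_setequal(names(prot$sequences), prot$metadata$accession)
  expect_equal(unname(nchar(prot$sequences)), prot$metadata$length)
})

test_that("planted overlap pairs resolve to the lower E-value hit", {
  cfg <- small_config(seed = 12)
  prot <- simulate_proteome(cfg)
  hits <- simulate_domain_hits(prot, cfg)
  pairs <- hits[hits$independent_evalue %in% c(1e-10, 1e-5), ]
  expect_gt(nrow(pairs), 0)
  accepted <- resolve_architectures(filter_hits(hits))
  for (p in unique(pairs$protein)) {
    strong <- pairs[pairs$protein == p & pairs$independent_evalue == 1e-10, ]
    weak <- pairs[pairs$protein == p & pairs$independent_evalue == 1e-5, ]
    acc_p <- accepted[accepted$protein == p, ]
    expect_true(all(hit_key(strong) %in% hit_key(acc_p)))
    expect_false(any(hit_key(weak) %in% hit_key(acc_p)))
  }
})

test_that("planted PPI edges pass their database filter and decoys fail", {
  cfg <- small_config(seed = 21)
  prot <- simulate_proteome(cfg)
  edges <- simulate_ppi_edges(prot, cfg)
  rec <- ppi_evidence(edges, prot$actins)
  truth_ppi <- prot$truth[!is.na(prot$truth$ppi_database), ]
  expect_setequal(rec$protein, truth_ppi$accession)
  planted_keys <- paste(truth_ppi$accession,
                        paste0("ppi:", truth_ppi$ppi_database))
  expect_true(all(planted_keys %in% paste(rec$protein, rec$source)))
})

test_that("expression noise rows are filtered without changing any breadth", {
  cfg <- small_config(seed = 31)
  prot <- simulate_proteome(cfg)
  tab <- simulate_expression(prot, cfg)
  expect_true(any(tab$reliability == "uncertain"))
  expect_true(any(tab$level == "not detected"))
  kept <- filter_expression(tab)
  expect_false(any(kept$reliability == "uncertain"))
  expect_false(any(kept$level == "not_detected"))
})
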
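test_that("parse_hits round-trips well-formed tables and rejects malformed rows", {
  tab <- rbind(mk_hit(family = "CH"), mk_hit(family = "PH", ali_from = 150,
                                             ali_to = 250),
               mk_hit(family = "LIM", ali_from = 300, ali_to = 350,
                      model_length = 51, hmm_to = 51))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- parse_hits(path)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$family, c("CH", "PH", "LIM"))

  # header-only file -> empty list
  write.table(tab[0, ], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(parse_hits(path)), 0)

  # inverted alignment coordinates -> format error naming the row
  bad <- tab
  bad$ali_to[2] <- 10
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_hits(path), "row 2", class = "aap_format_error")

  # non-numeric E-value -> format error with row number
  bad <- tab
  bad$independent_evalue <- as.character(bad$independent_evalue)
  bad$independent_evalue[3] <- "oops"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_hits(path), "row 3", class = "aap_format_error")

  # missing column -> format error
  write.table(tab[, -2], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_hits(path), "family", class = "aap_format_error")
})

test_that("hmmscan domtblout reader maps the standard columns by position", {
  row <- paste("CH", "PF00307.32", "109", "SYN00001", "-", "400",
               "1.2e-20", "80.1", "0.1", "1", "2", "3e-18", "4.5e-16",
               "70.2", "0.1", "3", "105", "12", "115", "10", "118", "0.95",
               "Calponin homology domain")
  path <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# comment line", row, "#"), path)
  hits <- read_hmmscan_domtblout(path)
  expect_equal(hits$protein, "SYN00001")
  expect_equal(hits$family, "CH")
  expect_equal(hits$model_length, 109)
  expect_equal(hits$ali_from, 12)
  expect_equal(hits$ali_to, 115)
  expect_equal(hits$hmm_from, 3)
  expect_equal(hits$hmm_to, 105)
  expect_equal(hits$independent_evalue, 4.5e-16)
  expect_equal(hits$full_sequence_evalue, 1.2e-20)
})

test_that("filter decisions at the exact boundaries follow the stated rules", {
  hits <- rbind(
    mk_hit(family = "AtThreshold", ie = 1e-3),                  # i-E == 0.001
    mk_hit(family = "AboveThreshold", ie = 1.0001e-3),
    mk_hit(family = "CovExact", ie = 1e-6, model_length = 100,
           hmm_from = 1, hmm_to = 70),                          # coverage 0.70
    mk_hit(family = "CovBelow", ie = 1e-6, model_length = 100,
           hmm_from = 1, hmm_to = 69),                          # coverage 0.69
    mk_hit(family = "BothPass", ie = 5e-4, model_length = 100,
           hmm_from = 1, hmm_to = 90),
    mk_hit(family = "ScanLevel", ie = 0.01)                     # 0.01 > 0.001
  )
  kept <- filter_hits(hits)
  expect_setequal(kept$family, c("AtThreshold", "CovExact", "BothPass"))
})

test_that("tightening either filter never adds a retained hit", {
  set.seed(41)
  hits <- do.call(rbind, lapply(1:60, function(i) {
    ml <- sample(50:200, 1)
    span <- sample.int(ml, 1)
    mk_hit(family = paste0("F", i), ali_from = i, ali_to = i + ml - 1,
           ie = 10^runif(1, -8, -1), model_length = ml, hmm_from = 1,
           hmm_to = span)
  }))
  loose <- filter_hits(hits, filter_config(independent_evalue_max = 0.01,
                                           model_coverage_min = 0.5))
  for (ie_max in c(0.001, 1e-5)) {
    for (cov_min in c(0.6, 0.8)) {
      tight <- filter_hits(hits, filter_config(independent_evalue_max = ie_max,
                                               model_coverage_min = cov_min))
      expect_true(all(hit_key(tight) %in% hit_key(loose)))
    }
  }
})

test_that("overlap resolution prefers the lowest independent E-value", {
  # 30-residue overlap, 1e-10 vs 1e-5: only the more significant hit stays
  hits <- rbind(mk_hit(family = "Strong", ali_from = 1, ali_to = 100, ie = 1e-10),
                mk_hit(family = "Weak", ali_from = 71, ali_to = 170, ie = 1e-5,
                       model_length = 100))
  arch <- resolve_architecture(hits)
  expect_equal(arch$architecture, "Strong")

  # exactly 25 residues of overlap is allowed, 26 is a conflict
  a25 <- resolve_architecture(rbind(
    mk_hit(family = "A", ali_from = 1, ali_to = 100, ie = 1e-10),
    mk_hit(family = "B", ali_from = 76, ali_to = 175, ie = 1e-5)))
  expect_equal(a25$architecture, "A~B")
  a26 <- resolve_architecture(rbind(
    mk_hit(family = "A", ali_from = 1, ali_to = 100, ie = 1e-10),
    mk_hit(family = "B", ali_from = 75, ali_to = 174, ie = 1e-5)))
  expect_equal(a26$architecture, "A")

  # single passing hit -> one-domain architecture
  expect_equal(resolve_architecture(mk_hit(family = "CH"))$architecture, "CH")

  # hits from two proteins -> usage error
  expect_error(resolve_architecture(rbind(mk_hit(), mk_hit(protein = "SYN2"))),
               "single protein", class = "aap_usage_error")
})

test_that("resolver is idempotent and its accepted set satisfies the overlap bound", {
  set.seed(99)
  for (rep in 1:25) {
    hits <- random_hit_set(sample(2:10, 1))
    arch <- resolve_architecture(hits)
    again <- resolve_architecture(arch$domains)
    expect_equal(hit_key(again$domains), hit_key(arch$domains))
    d <- arch$domains
    if (nrow(d) > 1) {
      pairs <- utils::combn(nrow(d), 2)
      ov <- apply(pairs, 2, function(p) {
        max(0, min(d$ali_to[p]) - max(d$ali_from[p]) + 1)
      })
      expect_true(all(ov <= 25))
    }
  }
})

test_that("architecture strings are canonical and ordered by start coordinate", {
  hits1 <- rbind(mk_hit(family = "CH", ali_from = 200, ali_to = 300, ie = 1e-9),
                 mk_hit(family = "PH", ali_from = 1, ali_to = 100, ie = 1e-4))
  hits2 <- hits1[2:1, ]
  hits2$protein <- "SYN00002"
  expect_equal(resolve_architecture(hits1)$architecture, "PH~CH")
  expect_equal(resolve_architecture(hits2)$architecture, "PH~CH")
  tab <- architecture_table(resolve_architectures(rbind(hits1, hits2)))
  expect_equal(unique(tab$architecture), "PH~CH")
})

test_that("clan assignment fills from the map and leaves unmapped families empty", {
  accepted <- rbind(mk_hit(family = "CH"), mk_hit(family = "Unmapped",
                                                  ali_from = 200, ali_to = 300))
  map <- data.frame(family = c("CH", "PH"), clan = c("CLS0001", "CLS0002"))
  out <- assign_clans(accepted, map)
  expect_equal(out$clan, c("CLS0001", ""))
  bad <- rbind(map, data.frame(family = "CH", clan = "CLS0009"))
  expect_error(assign_clans(accepted, bad), "conflicting",
               class = "aap_format_error")
})
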
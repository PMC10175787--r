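mk_meta <- function(accession = "SYN00001", location = "", lipidation = "",
                    tm = 0, im = 0, td = 0) {
  data.frame(accession = accession, subcellular_location = location,
             lipidation = lipidation, transmembrane = tm, intramembrane = im,
             topological_domain = td, stringsAsFactors = FALSE)
}

test_that("localization rules follow the annotation precedence", {
  expect_equal(classify_localization(mk_meta(tm = 1))$cls, "integral_membrane")
  expect_equal(classify_localization(mk_meta(im = 1))$cls, "integral_membrane")
  expect_equal(classify_localization(mk_meta(td = 1))$cls, "integral_membrane")
  # lipid anchors place otherwise-soluble proteins at the membrane
  expect_equal(classify_localization(mk_meta(lipidation = "myristoylation"))$cls,
               "peripheral_membrane")
  expect_equal(classify_localization(
    mk_meta(location = "Cell membrane; Peripheral membrane protein"))$cls,
    "peripheral_membrane")
  # integral evidence wins over lipidation: classes are disjoint
  expect_equal(classify_localization(
    mk_meta(lipidation = "palmitoylation", tm = 1))$cls, "integral_membrane")
  expect_equal(classify_localization(
    mk_meta(location = "Cytoplasm, cytoskeleton"))$cls, "cytoplasmic")
  expect_equal(classify_localization(mk_meta())$cls, "other")
  # pure function of the row: order never matters
  two <- classify_localization(rbind(mk_meta("A", lipidation = "farnesylation"),
                                     mk_meta("B", tm = 1)))
  expect_equal(two$cls, rev(classify_localization(
    rbind(mk_meta("B", tm = 1), mk_meta("A", lipidation = "farnesylation")))$cls))
})

test_that("lipidation tallies count each type and multi-modified proteins", {
  calls <- classify_localization(rbind(
    mk_meta("A", lipidation = "myristoylation"),
    mk_meta("B", lipidation = "myristoylation;palmitoylation"),
    mk_meta("C", lipidation = "farnesylation"),
    mk_meta("D")))
  tally <- lipidation_summary(calls)
  expect_equal(tally$myristoylation, 2)
  expect_equal(tally$palmitoylation, 1)
  expect_equal(tally$farnesylation, 1)
  expect_equal(tally$geranylgeranylation, 0)
  expect_equal(tally$multi_modified, 1)

  all4 <- classify_localization(mk_meta("E", lipidation = paste(
    c("farnesylation", "myristoylation", "palmitoylation",
      "geranylgeranylation"), collapse = ";")))
  t4 <- lipidation_summary(all4)
  expect_equal(unname(unlist(t4)), c(1, 1, 1, 1, 1))

  none <- lipidation_summary(classify_localization(mk_meta("F")))
  expect_equal(unname(unlist(none)), c(0, 0, 0, 0, 0))
})

test_that("expression filtering retains exactly reliable detected rows", {
  tab <- data.frame(
    protein = "SYN00001", tissue = paste0("t", 1:4),
    level = c("low", "high", "not detected", "medium"),
    reliability = c("approved", "uncertain", "enhanced", "supported"))
  kept <- filter_expression(tab)
  expect_equal(kept$tissue, c("t1", "t4"))
  # idempotent
  expect_equal(filter_expression(kept), kept)
  bad <- tab
  bad$level[1] <- "huge"
  expect_error(filter_expression(bad), "huge", class = "aap_format_error")
  bad <- tab
  bad$reliability[1] <- "guessed"
  expect_error(filter_expression(bad), "guessed", class = "aap_format_error")
})

test_that("tissue breadth counts distinct tissues and bins exhaustively", {
  tab <- data.frame(
    protein = c("A", "A", "A", "A", "B", rep("C", 7)),
    tissue = c("t1", "t1", "t2", "t3", "t9", paste0("t", 1:7)),
    level = "high", reliability = "approved")
  res <- tissue_breadth(filter_expression(tab))
  expect_equal(res$breadth$n_tissues[res$breadth$protein == "A"], 3)
  expect_equal(res$breadth$bin[res$breadth$protein == "A"], "2-5")
  expect_equal(res$breadth$bin[res$breadth$protein == "B"], "1")
  expect_equal(res$breadth$bin[res$breadth$protein == "C"], "6-40")
  expect_equal(sum(res$histogram), nrow(res$breadth))
  # a protein observed only at not-detected levels never enters the histogram
  gone <- data.frame(protein = "D", tissue = "t1", level = "not detected",
                     reliability = "approved")
  res2 <- tissue_breadth(filter_expression(rbind(tab, gone)))
  expect_false("D" %in% res2$breadth$protein)
})

test_that("COG strings split per letter with the fixed broad-group mapping", {
  cog <- data.frame(protein = c("A", "B", "C"),
                    categories = c("TZ", "S", "K"))
  res <- summarize_cog(cog)
  expect_equal(res$n_single, 2)
  expect_equal(res$n_multi, 1)
  expect_equal(res$assignments$broad_groups[2], "poorly characterized")
  expect_equal(res$per_broad_group[["cellular processes and signaling"]], 1L)
  expect_equal(res$per_broad_group[["information storage and processing"]], 1L)
  expect_equal(res$per_category[["T"]], 1L)
  expect_equal(res$per_category[["Z"]], 1L)
  expect_error(summarize_cog(data.frame(protein = "A", categories = "7")),
               "7", class = "aap_format_error")
  # restriction to census members
  res2 <- summarize_cog(cog, census_proteins = c("A", "C"))
  expect_equal(nrow(res2$assignments), 2)
})
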
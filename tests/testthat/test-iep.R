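test_that("ORF finding in DIV enumerates stop-to-stop spans and AUG modes", {
  tpl <- build_intron_template(family_spec("cox1", 199, "IIA1", "RTM"), seed = 4)
  lay <- parse_domains(tpl$sequence, tpl$dot_bracket)
  div <- tpl$truth$domains$DIV
  orfs <- find_div_orfs(substr(tpl$sequence, div[1], div[2]))
  expect_gt(nrow(orfs), 0)
  best <- orfs[1, ]
  expect_identical(best$mode, "span")
  expect_gte(best$n_codons, 450) # the planted 450-codon ORF (plus frame slack)
  expect_true("aug" %in% orfs$mode)

  # a short DIV yields nothing
  expect_equal(nrow(find_div_orfs(strrep("ACGU", 10))), 0)

  # a planted internal stop splits the ORF into two spans
  tps <- build_intron_template(
    family_spec("rns", 780, "IIB1", "RTM", degenerations = "orf_premature_stop"),
    seed = 4
  )
  div2 <- tps$truth$domains$DIV
  orfs2 <- find_div_orfs(substr(tps$sequence, div2[1], div2[2]))
  spans <- orfs2[orfs2$mode == "span" & orfs2$frame == orfs2$frame[1], ]
  expect_equal(nrow(spans), 2)
  expect_true(all(abs(sort(spans$n_codons) - c(200, 250)) <= 5))
})

test_that("IEP typing follows the motif rules", {
  tplR <- build_intron_template(family_spec("cox1", 199, "IIA1", "RTM"), seed = 6)
  annR <- annotate_intron(tplR$sequence, tplR$dot_bracket)
  expect_identical(annR$iep$type, "RTM")
  expect_identical(annR$iep$status, "intact")

  tplL <- build_intron_template(family_spec("rns", 670, "IIB2", "LHE"), seed = 6)
  annL <- annotate_intron(tplL$sequence, tplL$dot_bracket)
  expect_identical(annL$iep$type, "LHE")
  expect_identical(annL$iep$status, "intact")

  # direct classification of the proteins
  expect_identical(classify_iep(annR$iep$protein)$type, "RTM")
  expect_identical(classify_iep(annL$iep$protein)$type, "LHE")

  # two LAGLIDADG copies must be spaced 80-150 aa apart
  close_pair <- paste0(strrep("G", 60), "LAGLIDADG", strrep("G", 10),
                       "LAGLIDADG", strrep("G", 60))
  expect_identical(classify_iep(close_pair)$type, "none")

  # shuffled proteins are typed none in >= 95% of shuffles
  prot <- annR$iep$protein
  set.seed(99)
  fp <- mean(vapply(1:100, function(i) {
    p <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
    classify_iep(p)$type != "none"
  }, logical(1)))
  expect_lte(fp, 0.05)

  # C-terminal padding with non-motif residues never changes the call
  expect_identical(classify_iep(paste0(prot, strrep("G", 80)))$type, "RTM")
  expect_identical(classify_iep(paste0(annL$iep$protein, strrep("G", 80)))$type, "LHE")
})

test_that("intactness grading distinguishes intact, degenerated and absent", {
  tps <- build_intron_template(
    family_spec("rns", 780, "IIB1", "RTM", degenerations = "orf_premature_stop"),
    seed = 4
  )
  ann <- annotate_intron(tps$sequence, tps$dot_bracket)
  expect_identical(ann$iep$type, "RTM")
  expect_identical(ann$iep$status, "degenerated")
  expect_true(ann$iep$remnant_candidates)

  tpa <- build_intron_template(
    family_spec("rnl", 2698, "IIB1", "LHE", degenerations = "orf_absent"),
    seed = 4
  )
  ann2 <- annotate_intron(tpa$sequence, tpa$dot_bracket)
  expect_identical(ann2$iep$type, "none")
  expect_identical(ann2$iep$status, "absent")

  # assess_intactness unit semantics
  orfs <- data.frame(mode = "span", aa_start = 1L, aa_end = 500L)
  expect_identical(assess_intactness(orfs, c(50L, 400L), has_evidence = TRUE), "intact")
  orfs2 <- data.frame(mode = "span", aa_start = c(1L, 210L), aa_end = c(200L, 500L))
  expect_identical(assess_intactness(orfs2, c(50L, 400L), has_evidence = TRUE),
                   "degenerated")
  empty <- data.frame(mode = character(0), aa_start = integer(0), aa_end = integer(0))
  expect_identical(assess_intactness(empty, NULL, has_evidence = FALSE), "absent")
})

test_that("no IIA-subgroup synthetic intron is ever LHE-typed", {
  for (nm in c("clean0", "default")) {
    coh <- get_cohort(nm)
    ft <- annotate_cohort(coh)
    truth <- coh$truth[match(ft$key, coh$truth$key), ]
    iia <- truth$subgroup %in% c("IIA1", "IIA2")
    expect_gt(sum(iia), 0)
    expect_false(any(ft$iep_type[iia] == "LHE"))
  }
})

test_that("zero-mutation cohorts recover IEP type and status exactly", {
  coh <- get_cohort("clean0")
  ft <- annotate_cohort(coh)
  truth <- coh$truth[match(ft$key, coh$truth$key), ]
  expect_identical(ft$iep_type, truth$iep_type)
  expect_identical(ft$iep_status, truth$iep_status)
})
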
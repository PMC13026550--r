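# Helper: tiny hand-made six-domain intron with controllable DVI.
toy_intron <- function(dvi_seq, dvi_db, di_extra_seq = "", di_extra_db = "") {
  hp <- function(stem, loop) {
    list(seq = paste0(stem, loop, intronscape:::revcomp_rna(stem)),
         db = paste0(strrep("(", nchar(stem)), strrep(".", nchar(loop)),
                     strrep(")", nchar(stem))))
  }
  d1 <- list(seq = paste0("GGGGGG", di_extra_seq, "AAGGCAUCAA", "CCCCCC"),
             db = paste0("((((((", di_extra_db, "..........", "))))))"))
  d2 <- hp("GCGCGCGC", "AAUUAA")
  d3 <- hp("GGCCGG", "UUAA")
  d4 <- hp("GCGGCGGC", "AAUUCCGGAAUUCCGGAAUU")
  d5 <- hp("GGUACGCAGGAUCC", "GUAAGC")
  seq <- paste0("GUGCGA", d1$seq, "CA", d2$seq, "ACGA", d3$seq, "GU",
                d4$seq, "CC", d5$seq, "AG", dvi_seq, "AU")
  db <- paste0("......", d1$db, "..", d2$db, "....", d3$db, "..",
               d4$db, "..", d5$db, "..", dvi_db, "..")
  list(seq = seq, db = db)
}

test_that("parse_domains recovers generator truth intervals exactly", {
  coh <- get_cohort("clean0")
  for (fam in names(coh$templates)[c(1, 5, 9)]) {
    tpl <- coh$templates[[fam]]
    asm <- intronscape:::assemble_parts(tpl$parts)
    lay <- parse_domains(asm$sequence, asm$dot_bracket)
    for (d in c("DI", "DII", "DIII", "DIV", "DV", "DVI")) {
      iv <- lay$domains[lay$domains$domain == d, ]
      expect_equal(unname(c(iv$start, iv$end)), unname(tpl$truth$domains[[d]]),
                   info = paste(fam, d))
    }
  }
})

test_that("parse_domains rejects non-intron layouts and bad brackets", {
  expect_error(parse_domains("ACGUACGUACG", "((((...))))"), "layout error")
  expect_error(parse_domains("ACGU", "(().."), "length")
  expect_error(parse_domains("ACGUA", "(().."), "unbalanced")
  expect_error(parse_domains("ACGUA", "())(."), "unbalanced")
})

test_that("terminal element detection handles motif, linker and AY tail", {
  pad <- strrep("ACGU", 15)
  t1 <- detect_terminal_elements(paste0("GUGCGA", pad, "AU"))
  expect_identical(t1$five_prime_motif, "canonical")
  expect_equal(t1$linker_len, 0)
  expect_true(t1$three_prime_AY)

  t2 <- detect_terminal_elements(paste0("CAGUGCGA", pad, "AC"))
  expect_identical(t2$five_prime_motif, "canonical")
  expect_equal(t2$linker_len, 2)
  expect_true(t2$three_prime_AY)

  t3 <- detect_terminal_elements(paste0("GUGCGA", pad, "AA"))
  expect_false(t3$three_prime_AY) # A is not a pyrimidine

  t4 <- detect_terminal_elements(paste0("GUGGGA", pad, "AU"))
  expect_identical(t4$five_prime_motif, "variant") # one mismatch

  t5 <- detect_terminal_elements(paste0("CCCCCC", pad, "AU"))
  expect_identical(t5$five_prime_motif, "absent")
})

test_that("branch-point detection uses the 6-10 nt window within DVI", {
  # canonical bulged A at 8 nt from the 3' end -> present
  dvi_bulge <- list(seq = "GCAUGGGCUUUGCCCAUGCAU",
                    db = "((((((((....))).)))))")
  substr(dvi_bulge$seq, 16, 16) <- "A"
  toy <- toy_intron(dvi_bulge$seq, dvi_bulge$db)
  lay <- parse_domains(toy$seq, toy$db)
  bp <- detect_branchpoint(lay, toy$seq)
  expect_identical(bp$status, "present")
  expect_equal(nchar(toy$seq) - bp$position + 1, 8)

  # bulged G instead of A -> absent
  dvi_g <- dvi_bulge
  substr(dvi_g$seq, 16, 16) <- "G"
  toyg <- toy_intron(dvi_g$seq, dvi_g$db)
  expect_identical(detect_branchpoint(parse_domains(toyg$seq, toyg$db), toyg$seq)$status,
                   "absent")

  # unpaired A outside the window only (loop 12-15 nt from the end) -> absent
  dvi_far <- list(seq = paste0("GCAUGGGGG", "AAAA", "CCCCCAUGC"),
                  db = paste0("(((((((((", "....", ")))))))))"))
  toyf <- toy_intron(dvi_far$seq, dvi_far$db)
  expect_identical(detect_branchpoint(parse_domains(toyf$seq, toyf$db), toyf$seq)$status,
                   "absent")
})

test_that("junction motifs drive the subgroup decision tree", {
  feats <- function(tet = NA, dim = NA, five = "canonical", bp = "present",
                    e1 = "found", e2 = "found", len = 2000) {
    list(junction_DII_DIII = tet, junction_DIV_DV = dim, five_prime_motif = five,
         branchpoint = bp, ebs1 = e1, ebs2 = e2, length = len)
  }
  expect_identical(classify_subgroup(feats(tet = "CAGA"))$subgroup, "IIA1")
  expect_identical(classify_subgroup(feats(tet = "AAGA"))$subgroup, "IIA2")
  expect_identical(classify_subgroup(feats(tet = "GGGA"))$subgroup, "ambiguous-IIA")
  expect_identical(classify_subgroup(feats(tet = "GGGA"), clade_prior = "IIA2")$subgroup,
                   "IIA2")
  expect_identical(classify_subgroup(feats(tet = "ACGA", dim = "UA"))$subgroup, "IIB1")
  expect_identical(classify_subgroup(feats(tet = "ACGA", dim = "GG"))$subgroup, "IIB2")
  # IIB-like: no IEP, short, >= 2 core features gone
  iep_none <- list(type = "none", status = "absent")
  expect_identical(
    classify_subgroup(feats(tet = "ACGA", dim = "CC", bp = "absent", e2 = "lost",
                            len = 615), iep = iep_none)$subgroup,
    "IIB-like"
  )
  # same degeneration but an intact IEP -> unclassified, not IIB-like
  iep_rtm <- list(type = "RTM", status = "intact")
  expect_identical(
    classify_subgroup(feats(tet = "ACGA", dim = "CC", bp = "absent", e2 = "lost",
                            len = 615), iep = iep_rtm)$subgroup,
    "unclassified"
  )
})

test_that("EBS-IBS detection recovers planted interfaces and reports losses", {
  ctx <- list(up12 = "ACGUGGCUUCAG", down2 = "GA")
  up <- paste0("AAAAAAAA", ctx$up12)
  dn <- paste0(ctx$down2, "CCCCCC")
  tpl <- build_intron_template(family_spec("cox1", 199, "IIA1", "RTM"),
                               seed = 31, ibs_context = ctx)
  lay <- parse_domains(tpl$sequence, tpl$dot_bracket)
  rep <- detect_ebs_ibs(lay, tpl$sequence, up, dn)
  expect_identical(rep$EBS1$status, "found")
  expect_identical(rep$EBS1$seq, tpl$truth$ebs1$seq)
  expect_identical(rep$EBS1$seq, intronscape:::revcomp_rna("CUUCAG")) # IBS1 = last 6 nt
  expect_identical(rep$EBS2$status, "found")
  expect_identical(rep$EBS2$seq, tpl$truth$ebs2$seq)
  expect_identical(rep$EBS3$status, "found")

  tpl2 <- build_intron_template(family_spec("rns", 420, "IIB1", "LHE",
                                            degenerations = "lose_EBS2"),
                                seed = 32, ibs_context = ctx)
  lay2 <- parse_domains(tpl2$sequence, tpl2$dot_bracket)
  rep2 <- detect_ebs_ibs(lay2, tpl2$sequence, up, dn, allow_wobble = TRUE)
  expect_identical(rep2$EBS1$status, "found")
  expect_identical(rep2$EBS2$status, "lost")

  # short flanks are not assessable
  rep3 <- detect_ebs_ibs(lay, tpl$sequence, "ACGUAC", dn)
  expect_identical(rep3$EBS2$status, "not_assessable")
})

test_that("reported EBS pairings always satisfy the complementarity thresholds", {
  coh <- get_cohort("default")
  ft_keys <- sample(nrow(coh$introns), 10)
  for (k in ft_keys) {
    rec <- coh$introns[k, ]
    lay <- parse_domains(rec$sequence, rec$dot_bracket)
    rep <- detect_ebs_ibs(lay, rec$sequence, rec$upstream_flank, rec$downstream_flank)
    if (rep$EBS1$status == "found") {
      expect_gte(intronscape:::ebs_score(rep$EBS1$seq, rep$EBS1$ibs_seq), 5)
    }
    if (rep$EBS2$status == "found") {
      expect_gte(intronscape:::ebs_score(rep$EBS2$seq, rep$EBS2$ibs_seq), 4)
    }
    if (rep$EBS3$status == "found") {
      expect_true(intronscape:::pairs_with(rep$EBS3$seq, rep$EBS3$ibs_seq))
    }
  }
})

test_that("hand-checked EBS1: IBS1 CUUCAG pairs DI loop CUGAAG", {
  # reverse-complement by hand: CUUCAG -> CUGAAG (6/6 Watson-Crick)
  di_loop <- "CUGAAG"
  toy <- toy_intron("GCAUGGGCUUUGCCCAUGCAU", "((((((((....))).)))))",
                    di_extra_seq = paste0("GGG", di_loop, "CCC"),
                    di_extra_db = "(((......)))")
  lay <- parse_domains(toy$seq, toy$db)
  rep <- detect_ebs_ibs(lay, toy$seq, paste0("AAAAAAAAAAAAAA", "CUUCAG"), "GG")
  expect_identical(rep$EBS1$status, "found")
  expect_identical(rep$EBS1$seq, di_loop)
  expect_equal(rep$EBS1$score, 6)
})

test_that("consensus builder matches examples and flags ties", {
  c1 <- build_consensus(c("AUGC", "AUGC", "AUGC"))
  expect_identical(c1$representative, "AUGC")
  expect_length(c1$ties, 0)

  c2 <- build_consensus(c("A", "A", "G"))
  expect_identical(c2$representative, "A")

  c3 <- build_consensus(c("A", "G"))
  expect_identical(c3$representative, "A") # alphabetical tie-break
  expect_identical(c3$ties, 1L)

  expect_error(build_consensus(character(0)), "empty")
  expect_error(build_consensus(c("AC", "A")), "length")
})

test_that("consensus equals the column-majority oracle on random alignments", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(2:6, 1); w <- sample(3:12, 1)
    rows <- vapply(seq_len(n), function(j) {
      paste(sample(c("A", "C", "G", "U", "-"), w, TRUE,
                   prob = c(.22, .22, .22, .22, .12)), collapse = "")
    }, character(1))
    got <- build_consensus(rows)
    exp <- consensus_oracle(rows)
    expect_identical(got$representative, exp$representative)
    expect_identical(got$ties, exp$ties)
    expect_identical(got$kept_columns, exp$kept)
  }
})

test_that("linker-bearing synthetic introns always lack the branch point", {
  coh <- get_cohort("default")
  ft <- annotate_cohort(coh)
  truth <- coh$truth[match(ft$key, coh$truth$key), ]
  planted <- truth$linker_len > 0
  expect_gt(sum(planted), 0)
  expect_true(all(ft$branchpoint[planted] == "absent"))
})
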
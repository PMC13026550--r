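test_that("species trees are seeded Yule trees with the right shape", {
  t3 <- simulate_species_tree(3, 1.0, seed = 1)
  expect_equal(length(t3$tip.label), 3)
  expect_equal(t3$Nnode, 2) # rooted bifurcating: one split above the root split

  a <- ape::write.tree(simulate_species_tree(8, 1.0, seed = 7))
  b <- ape::write.tree(simulate_species_tree(8, 1.0, seed = 7))
  expect_identical(a, b)

  t50 <- simulate_species_tree(50, 1.0, seed = 3)
  expect_equal(length(t50$tip.label), 50)
  expect_equal(t50$Nnode, 49) # 2n - 1 nodes in a fully bifurcating rooted tree
  depths <- ape::node.depth.edgelength(t50)[1:50]
  expect_true(max(depths) - min(depths) < 1e-8) # ultrametric

  expect_error(simulate_species_tree(2, 1.0, seed = 1), "n_species")
})

test_that("templates carry the canonical architecture and terminal motifs", {
  spec <- family_spec("cox1", 199, "IIA1", "RTM")
  tpl <- build_intron_template(spec, seed = 3)
  expect_match(tpl$sequence, "^GUGCGA")
  expect_true(iupac_match(substr(tpl$sequence, nchar(tpl$sequence) - 1,
                                 nchar(tpl$sequence)), "AY"))
  lay <- parse_domains(tpl$sequence, tpl$dot_bracket)
  expect_identical(lay$domains$domain, c("DI", "DII", "DIII", "DIV", "DV", "DVI"))
  dv <- lay$domains[lay$domains$domain == "DV", ]
  expect_equal(dv$end - dv$start + 1, 34)
  expect_true(iupac_match(tpl$truth$tetramer, "BVGA"))
  expect_false(iupac_match(tpl$truth$tetramer, "RRGA"))
})

test_that("degeneration flags reshape the template as specified", {
  # linker + branch-point loss (coupled) in a IIB1-LHE intron
  spec <- family_spec("rns", 420, "IIB1", "LHE", degenerations = "linker")
  expect_true("no_branchpoint_A" %in% spec$degenerations)
  tpl <- build_intron_template(spec, seed = 5)
  expect_true(tpl$truth$linker_len >= 2 && tpl$truth$linker_len <= 10)
  expect_identical(substr(tpl$sequence, tpl$truth$linker_len + 1,
                          tpl$truth$linker_len + 6), "GUGCGA")
  expect_true(is.na(tpl$truth$branchpoint_pos))

  # DIIIa gives a seven-domain architecture with the extra stem-loop 4th
  tpl7 <- build_intron_template(family_spec("atp1", 990, "IIA1", "RTM",
                                            degenerations = "add_DIIIa"), seed = 8)
  lay7 <- parse_domains(tpl7$sequence, tpl7$dot_bracket)
  expect_identical(lay7$domains$domain,
                   c("DI", "DII", "DIII", "DIIIa", "DIV", "DV", "DVI"))

  # contradictory flags are rejected
  expect_error(family_spec("cox1", 199, "IIA1", "RTM", degenerations = "linker"),
               "IIB1/IIB2")
  expect_error(family_spec("cox1", 199, "IIA1", "LHE"), "RT/M")
})

test_that("zero substitution rates give copies identical to the template", {
  coh <- get_cohort("clean0")
  for (k in sample(nrow(coh$introns), 5)) {
    fam <- coh$introns$family[k]
    expect_identical(coh$introns$sequence[k], with(coh$templates[[fam]], {
      intronscape:::assemble_parts(parts)$sequence
    }))
  }
})

test_that("family presence follows the Bernoulli presence model", {
  # presence_prob = 1 puts the family in every genome
  fam1 <- list(family_spec("infA", 62, "IIB-like", "none", 1,
                           c("lose_EBS2", "no_branchpoint_A")))
  cfg1 <- sim_config(n_species = 5, seed = 2, subst_rate_rna = 0,
                     subst_rate_orf = 0, families = fam1, extra_scaffold = 0)
  coh1 <- simulate_cohort(cfg1)
  expect_true(all(coh1$presence))

  # presence_prob = 0.5 over 44 species: binomial mean/variance oracle
  tree44 <- simulate_species_tree(44, 1, seed = 9)
  tpl <- build_intron_template(fam1[[1]], seed = 1)
  tpl_entry <- list(list(spec = family_spec("infA", 62, "IIB-like", "none", 0.5,
                                            c("lose_EBS2", "no_branchpoint_A")),
                         parts = tpl$parts))
  names(tpl_entry) <- "infA-62"
  counts <- vapply(1:200, function(s) {
    cfg <- sim_config(n_species = 44, seed = 1000 + s, subst_rate_rna = 0,
                      subst_rate_orf = 0, families = fam1, extra_scaffold = 0)
    sum(evolve_cohort(tpl_entry, tree44, cfg)$presence)
  }, numeric(1))
  expect_true(abs(mean(counts) - 22) <= 3 * sqrt(44 * 0.25))
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- sim_config(n_species = 4, seed = 13)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(sim_config(n_species = 4, seed = 13))
  expect_identical(c1$introns, c2$introns)
  expect_identical(lapply(c1$genomes, `[[`, "sequence"),
                   lapply(c2$genomes, `[[`, "sequence"))
  expect_identical(ape::write.tree(c1$family_tree), ape::write.tree(c2$family_tree))
})
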
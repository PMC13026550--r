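#!/usr/bin/env Rscript
# Simulate the two study cohorts -- one mitochondrial, one chloroplast -- with
# full ground truth, and write them under results/. The mitochondrial set is
# the default 12-family mix (two LHE invasions, DIIIa lineages, a linker-and-
# branch-point-loss IIB1-LHE pair); the chloroplast set mirrors the observed
# cp repertoire: mostly RT/M families, one IEP-lacking IIB2 family and the
# ubiquitous, highly degenerated IIB-like infA-62.

library(intronscape)

cp_families <- list(
  family_spec("petD", 87, "IIA2", "RTM", 0.30),
  family_spec("petB", 169, "IIB1", "RTM", 0.20),
  family_spec("petB", 277, "IIB1", "RTM", 0.20),
  family_spec("psbC", 496, "IIB1", "RTM", 0.10, "lose_IC2"),
  family_spec("atpB", 537, "IIB1", "RTM", 0.10, "lose_IC2"),
  family_spec("atpB", 627, "IIB2", "RTM", 0.30),
  family_spec("atpI", 256, "IIB2", "RTM", 0.25),
  family_spec("petB", 69, "IIB2", "RTM", 0.48),
  family_spec("orf185", 47, "IIB2", "RTM", 0.08, "orf_absent"),
  family_spec("infA", 62, "IIB-like", "none", 1.00,
              c("lose_EBS2", "no_branchpoint_A", "lose_ID2", "lose_IC2"))
)

mt <- simulate_cohort(sim_config(n_species = 20, organelle = "mt", seed = 11))
cp <- simulate_cohort(sim_config(n_species = 20, organelle = "cp", seed = 12,
                                 families = cp_families, exon_len = 40))

emit_cohort(mt, "results/cohort_mt")
emit_cohort(cp, "results/cohort_cp")

for (coh in list(mt, cp)) {
  cat(sprintf("%s cohort: %d genomes, %d families, %d intron copies\n",
              coh$config$organelle, length(coh$genomes),
              length(coh$templates), nrow(coh$introns)))
}
cat("cohorts written to results/cohort_mt and results/cohort_cp\n")
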
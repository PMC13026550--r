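#!/usr/bin/env Rscript
# Family assignment (shared insertion site + homology), presence/absence,
# occurrence frequencies with distribution classes (broad > 40%, narrow < 15%)
# and the per-family feature bubble matrix. Denominators are kept separate per
# organellar compartment.

library(intronscape)

for (org in c("mt", "cp")) {
  dir <- file.path("results", paste0("cohort_", org))
  lc <- load_cohort(dir)
  ft <- read.delim(file.path("results", paste0("features_", org, ".tsv")))

  fam <- assign_families(lc$introns, lc$reference_genes)
  asg <- fam$assignments
  asg$genome_id <- lc$introns$genome_id[match(asg$key, lc$introns$key)]
  pm <- build_presence_matrix(asg, genome_ids = sort(unique(lc$introns$genome_id)))
  of <- occurrence_frequency(pm)
  of <- of[order(-of$percent), ]
  write.table(of, file.path("results", paste0("occurrence_", org, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("==", org, ":", nrow(of), "families;",
      sum(of$class == "broad"), "broad,",
      sum(of$class == "narrow"), "narrow\n")
  print(head(of, 4))

  bm <- bubble_matrix(ft, assignments = asg)
  bdf <- data.frame(family = rownames(bm$percent), n = bm$family_size,
                    bm$percent, check.names = FALSE)
  write.table(bdf, file.path("results", paste0("bubble_", org, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("occurrence and bubble tables written under results/\n")
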
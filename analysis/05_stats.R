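#!/usr/bin/env Rscript
# Length and GC contrasts across intron lineages and organellar compartments
# (two-way ANOVA + Tukey-Kramer HSD), and insertion-site sequence logos for
# the most broadly distributed family of each compartment.

library(intronscape)

lineage_of <- function(subgroup, iep) {
  ifelse(subgroup == "IIB-like", "IIB-like",
         ifelse(subgroup %in% c("IIA1", "IIA2"), paste0("IIA-", iep),
                paste0("IIB-", iep)))
}

ft <- do.call(rbind, lapply(c("mt", "cp"), function(org) {
  x <- read.delim(file.path("results", paste0("features_", org, ".tsv")))
  x$organelle <- org
  x
}))
ft$lineage <- lineage_of(ft$subgroup, ft$iep_type)
keep <- ft$lineage %in% c("IIA-RTM", "IIB-RTM", "IIB-LHE", "IIB-like")
ft <- ft[keep, ]

cat("== mean intron length (nt) by lineage x organelle\n")
print(round(tapply(ft$length, list(ft$lineage, ft$organelle), mean)))
cat("\n== mean GC (%) by lineage x organelle\n")
print(round(tapply(ft$gc, list(ft$lineage, ft$organelle), mean), 2))

for (response in c("length", "gc")) {
  cat("\n== two-way ANOVA on", response, "(lineage x organelle, Type-II SS)\n")
  res <- suppressWarnings(two_way_anova_tukey(ft[[response]], ft$lineage, ft$organelle))
  print(transform(res$anova, SS = signif(SS, 4), F = signif(F, 4),
                  p = signif(p, 3)))
  write.table(res$anova, file.path("results", paste0("anova_", response, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$tukey, file.path("results", paste0("tukey_", response, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# insertion-site logos: 40-nt windows around the splice junction of the most
# widespread family per compartment
for (org in c("mt", "cp")) {
  lc <- load_cohort(file.path("results", paste0("cohort_", org)))
  of <- read.delim(file.path("results", paste0("occurrence_", org, ".tsv")))
  fam <- of$family[1]
  members <- lc$introns[paste0(lc$introns$host_gene, "-", lc$introns$site) == fam, ]
  win <- paste0(members$upstream_flank, members$downstream_flank)
  lp <- insertion_site_logo(win, center = 20)
  tab <- data.frame(position = lp$positions, t(lp$freq), ic_bits = lp$ic)
  write.table(tab, file.path("results", paste0("logo_", org, "_", fam, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s logo (%s, %d members): IBS1 window mean IC = %.2f bits, background = %.2f\n",
              org, fam, nrow(members),
              mean(lp$ic[15:20]),  # positions -6..-1 (IBS1)
              mean(lp$ic[1:8])))
}
cat("statistics written under results/\n")
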
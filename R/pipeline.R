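# End-to-end pipeline glue: per-intron annotation, cohort feature tables,
# family-level and within-family alignments, RNA/protein tree building,
# congruence checks and truth-recovery scoring.

#' Annotate one intron: structure features, EBS report, IEP, subgroup
#'
#' @param sequence Intron RNA string.
#' @param structure Dot-bracket string.
#' @param upstream_flank,downstream_flank Exon flanks (NA tolerated).
#' @param allow_wobble Allow G.U pairs in EBS scoring.
#' @param translation_table Genetic code for the IEP (default 1).
#' @param min_codons Minimum ORF length (default 100).
#' @return List with `layout`, `terminal`, `branchpoint`, `junctions`, `ebs`,
#'   `iep`, `subgroup` and a flat `row` (data.frame) for feature tables.
#' @export
annotate_intron <- function(sequence, structure, upstream_flank = NA,
                            downstream_flank = NA, allow_wobble = FALSE,
                            translation_table = 1L, min_codons = 100L) {
  sequence <- dna_to_rna(sequence)
  layout <- parse_domains(sequence, structure)
  term <- detect_terminal_elements(sequence)
  bp <- detect_branchpoint(layout, sequence)
  jm <- extract_junction_motifs(layout, sequence)
  up <- if (is.na(upstream_flank)) "" else dna_to_rna(upstream_flank)
  dn <- if (is.na(downstream_flank)) "" else dna_to_rna(downstream_flank)
  ebs <- detect_ebs_ibs(layout, sequence, up, dn, allow_wobble = allow_wobble)
  iep <- annotate_iep(sequence, layout, translation_table, min_codons)
  feats <- list(
    junction_DII_DIII = jm$tetramer, junction_DIV_DV = jm$dimer,
    five_prime_motif = term$five_prime_motif, branchpoint = bp$status,
    ebs1 = ebs$EBS1$status, ebs2 = ebs$EBS2$status,
    length = nchar(sequence)
  )
  sg <- classify_subgroup(feats, layout, iep)
  row <- data.frame(
    length = nchar(sequence),
    gc = gc_content(sequence),
    five_prime_motif = term$five_prime_motif,
    linker_len = term$linker_len,
    three_prime_AY = term$three_prime_AY,
    branchpoint = bp$status, branchpoint_pos = bp$position,
    tetramer = jm$tetramer, dimer = jm$dimer,
    ebs1 = ebs$EBS1$status, ebs1_seq = ebs$EBS1$seq,
    ebs2 = ebs$EBS2$status, ebs2_seq = ebs$EBS2$seq,
    ebs3 = ebs$EBS3$status,
    has_diiia = "DIIIa" %in% layout$domains$domain,
    iep_type = iep$type, iep_status = iep$status,
    subgroup = sg$subgroup,
    stringsAsFactors = FALSE
  )
  list(layout = layout, terminal = term, branchpoint = bp, junctions = jm,
       ebs = ebs, iep = iep, subgroup = sg, row = row)
}

#' Annotate every intron of a cohort
#'
#' Accepts a simulated `intron_cohort` or the record list from
#' [load_cohort()]. Returns one feature row per intron, with logical
#' bubble-matrix columns (`f_*`) derived from the calls.
#'
#' @param cohort `intron_cohort` or [load_cohort()] output.
#' @param allow_wobble Allow G.U pairs in EBS scoring.
#' @return data.frame of per-intron features.
#' @export
annotate_cohort <- function(cohort, allow_wobble = FALSE) {
  recs <- cohort$introns
  struct_col <- if ("dot_bracket" %in% names(recs)) "dot_bracket" else "structure"
  tt <- if (inherits(cohort, "intron_cohort")) cohort$config$translation_table else 1L
  rows <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    ann <- annotate_intron(recs$sequence[i], recs[[struct_col]][i],
                           recs$upstream_flank[i], recs$downstream_flank[i],
                           allow_wobble = allow_wobble, translation_table = tt)
    r <- ann$row
    r$key <- recs$key[i]
    r$intron_id <- recs$intron_id[i]
    r$genome_id <- recs$genome_id[i]
    r$host_gene <- recs$host_gene[i]
    rows[[i]] <- r
  }
  ft <- do.call(rbind, rows)
  ft <- ft[, c("key", "intron_id", "genome_id", "host_gene",
               setdiff(names(ft), c("key", "intron_id", "genome_id", "host_gene")))]
  ft$f_canonical5 <- ft$five_prime_motif == "canonical"
  ft$f_linker <- !is.na(ft$linker_len) & ft$linker_len > 0L
  ft$f_branchpoint <- ft$branchpoint == "present"
  ft$f_ebs2 <- ft$ebs2 == "found"
  ft$f_diiia <- ft$has_diiia
  ft$f_iep_intact <- ft$iep_status == "intact"
  rownames(ft) <- NULL
  ft
}

# Rand index between two partitions given as label vectors over the same keys.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) return(1)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

#' Family-representative conserved-core alignment
#'
#' Concatenates, per family template, the conserved-core scaffold parts shared
#' by every family (outer DI stems, DI core hairpins, DII, DIII, DV, DVI, ...).
#' Because the cores are structurally invariant across families, the
#' concatenation is an alignment by construction; family-variable regions
#' (accessory domains, EBS loops, the DIV interior with the ORF, linkers) are
#' excluded -- the hotspot-exclusion step of the RNA phylogeny.
#'
#' @param cohort An `intron_cohort`.
#' @return Named character vector (one aligned row per family).
#' @export
family_core_alignment <- function(cohort) {
  tpls <- cohort$templates
  core_names <- lapply(tpls, function(t) {
    names(Filter(function(p) isTRUE(p$core), t$parts))
  })
  common <- Reduce(intersect, core_names)
  common <- intersect(PART_ORDER, common) # canonical order
  vapply(tpls, function(t) {
    paste(vapply(common, function(nm) t$parts[[nm]]$seq, character(1L)),
          collapse = "")
  }, character(1L))
}

#' Within-family alignments of member RNA scaffolds and ORFs
#'
#' Members of a family differ only by substitutions, so the full sequences are
#' aligned by construction. The RNA scaffold alignment excludes the DIV
#' interior ORF region (the coding signal); the ORF alignment is the ORF
#' region itself, also returned as amino acids.
#'
#' @param cohort An `intron_cohort`.
#' @param family Family id.
#' @return List with `rna` (named by genome), `orf_nt`, `orf_aa` (NULL when
#'   the family has no ORF).
#' @export
family_member_alignments <- function(cohort, family) {
  recs <- cohort$introns[cohort$introns$family == family, , drop = FALSE]
  if (!nrow(recs)) stop("no members of family ", family, call. = FALSE)
  tr <- cohort$templates[[family]]$truth
  seqs <- setNames(recs$sequence, recs$genome_id)
  orf_iv <- tr$orf_interval
  if (is.null(orf_iv)) {
    return(list(rna = seqs, orf_nt = NULL, orf_aa = NULL))
  }
  rna <- vapply(seqs, function(s) {
    paste0(substr(s, 1L, orf_iv[1L] - 1L), substr(s, orf_iv[2L] + 1L, nchar(s)))
  }, character(1L))
  orf_nt <- vapply(seqs, substr, character(1L), orf_iv[1L], orf_iv[2L])
  tt <- cohort$config$translation_table
  orf_aa <- vapply(orf_nt, translate_frame, character(1L), frame = 1L,
                   translation_table = tt)
  list(rna = rna, orf_nt = orf_nt, orf_aa = orf_aa)
}

#' RNA-scaffold vs IEP tree congruence within a family
#'
#' Builds the NJ tree of the member RNA scaffolds (ORF region excluded,
#' JC69) and of the member IEP proteins (p-distance) and returns their
#' Robinson-Foulds distance: 0 = fully congruent histories.
#'
#' @param cohort An `intron_cohort`.
#' @param family Family id (must have >= 4 members and an ORF).
#' @return List with `rna_tree`, `orf_tree`, `rf`.
#' @export
family_congruence <- function(cohort, family) {
  aln <- family_member_alignments(cohort, family)
  if (is.null(aln$orf_aa)) stop("family ", family, " has no ORF", call. = FALSE)
  rna_tree <- build_nj_tree(compute_distances(aln$rna, "JC69"))
  orf_tree <- build_nj_tree(compute_distances(aln$orf_aa, "p"))
  list(rna_tree = rna_tree, orf_tree = orf_tree,
       rf = rf_distance(rna_tree, orf_tree))
}

#' Family-level RNA tree and IEP protein trees of a cohort
#'
#' The RNA tree is the NJ (JC69) tree over the conserved-core alignment of
#' family representatives. The RT/M and LHE trees are NJ (p-distance) trees
#' over the family-level IEP proteins of families whose planted IEP is of that
#' type.
#'
#' @param cohort An `intron_cohort`.
#' @return List with `rna_tree`, `rtm_tree` (or NULL), `lhe_tree` (or NULL)
#'   and `lhe_families`.
#' @export
cohort_trees <- function(cohort) {
  aln <- family_core_alignment(cohort)
  rna_tree <- if (length(aln) >= 3L) {
    build_nj_tree(compute_distances(aln, "JC69"))
  } else NULL
  tt <- cohort$config$translation_table
  prot_of <- function(type) {
    ids <- names(Filter(function(t) t$spec$iep == type &&
                          !"orf_absent" %in% t$spec$degenerations,
                        cohort$templates))
    if (length(ids) < 3L) return(NULL)
    aa <- vapply(ids, function(id) {
      translate_frame(cohort$templates[[id]]$parts$div_core$seq, 1L, tt)
    }, character(1L))
    build_nj_tree(compute_distances(aa, "p"))
  }
  lhe_families <- names(Filter(function(t) t$spec$iep == "LHE", cohort$templates))
  list(rna_tree = rna_tree, rtm_tree = prot_of("RTM"), lhe_tree = prot_of("LHE"),
       lhe_families = lhe_families)
}

#' Default mutation-hotspot mask for a family template
#'
#' Builds a labeled region spec (for [mask_regions()]) covering the
#' fast-evolving or lineage-restricted regions of one template: the 5'
#' terminal sequence (linker + boundary motif), accessory DI elements (Ia,
#' IC2, ID2, ID2a, IE), the EBS loops, DIIIa, and the loop/interior regions of
#' DII, DIII and DIV.
#'
#' @param template A cohort family template (element of `cohort$templates`).
#' @return data.frame with `label`, `start`, `end`.
#' @export
default_hotspot_regions <- function(template) {
  idx <- template$truth$index
  parts <- template$parts
  rows <- list()
  addp <- function(label, name, loop_only = FALSE) {
    iv <- part_interval(idx, name)
    if (is.null(iv)) return()
    if (loop_only) {
      p <- parts[[name]]
      iv <- c(iv[1L] + p$meta$stem_len, iv[1L] + p$meta$stem_len + p$meta$loop_len - 1L)
    }
    rows[[length(rows) + 1L]] <<- data.frame(label = label, start = iv[1L],
                                             end = iv[2L], stringsAsFactors = FALSE)
  }
  five_start <- part_interval(idx, if (!is.null(parts$linker)) "linker" else "m5")[1L]
  rows[[1L]] <- data.frame(label = "5prime", start = five_start,
                           end = part_interval(idx, "m5")[2L],
                           stringsAsFactors = FALSE)
  addp("Ia", "ia"); addp("IC2", "ic2"); addp("ID2", "id2")
  addp("ID2a", "id2a"); addp("IE", "ie"); addp("DIIIa", "diiia")
  addp("EBS2_loop", "ebs2", loop_only = TRUE)
  addp("EBS1_loop", "ebs1", loop_only = TRUE)
  addp("DII_loop", "dII", loop_only = TRUE)
  addp("DIII_loop", "dIII", loop_only = TRUE)
  div_pre <- part_interval(idx, "div_pre")
  div_post <- part_interval(idx, "div_post")
  rows[[length(rows) + 1L]] <- data.frame(label = "DIV_interior",
                                          start = div_pre[1L], end = div_post[2L],
                                          stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Score recovery of generator truth by the annotation pipeline
#'
#' Runs feature annotation and family assignment on a cohort and compares
#' against its ground truth: Rand index of the family partition, and accuracy
#' of subgroup, IEP type, IEP status and EBS presence calls.
#'
#' @param cohort An `intron_cohort`.
#' @param allow_wobble Allow G.U pairs in EBS scoring.
#' @param identity_threshold Family homology threshold (default 0.6).
#' @return List of scores plus the feature table and assignments.
#' @export
evaluate_recovery <- function(cohort, allow_wobble = FALSE,
                              identity_threshold = 0.6) {
  ft <- annotate_cohort(cohort, allow_wobble = allow_wobble)
  truth <- cohort$truth[match(ft$key, cohort$truth$key), ]

  fam <- assign_families(cohort$introns, cohort$reference_genes,
                         identity_threshold = identity_threshold)
  assigned <- setNames(fam$assignments$family, fam$assignments$key)
  lab <- assigned[ft$key]
  lab[is.na(lab)] <- paste0("unassigned_", seq_len(sum(is.na(lab)))) # singletons
  ri <- rand_index(lab, truth$family)

  subgroup_acc <- mean(ft$subgroup == truth$subgroup)
  iep_type_acc <- mean(ft$iep_type == truth$iep_type)
  iep_status_acc <- mean(ft$iep_status == truth$iep_status)
  ebs_status_ok <-
    (ft$ebs1 == "found") &
    (ft$ebs2 == ifelse(truth$ebs2_present, "found", "lost")) &
    (ft$ebs3 == "found")
  # sequence-level agreement for the sites reported found
  ebs_seq_ok <- vapply(seq_len(nrow(ft)), function(i) {
    tr <- cohort$templates[[truth$family[i]]]$truth
    ok1 <- ft$ebs1[i] == "found" && identical(ft$ebs1_seq[i], tr$ebs1$seq)
    ok2 <- if (tr$ebs2$present) {
      ft$ebs2[i] == "found" && identical(ft$ebs2_seq[i], tr$ebs2$seq)
    } else ft$ebs2[i] == "lost"
    ok1 && ok2
  }, logical(1L))
  list(
    rand_index = ri,
    subgroup_accuracy = subgroup_acc,
    iep_type_accuracy = iep_type_acc,
    iep_status_accuracy = iep_status_acc,
    ebs_status_accuracy = mean(ebs_status_ok),
    ebs_sequence_accuracy = mean(ebs_seq_ok),
    features = ft, assignments = fam
  )
}
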
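# Simulation configuration: cohort-level settings and per-family specs.

SUBGROUPS <- c("IIA1", "IIA2", "IIB1", "IIB2", "IIB-like")
DEGENERATIONS <- c("linker", "no_branchpoint_A", "lose_EBS2", "lose_IC2",
                   "lose_ID2", "add_ID2a", "add_IE", "add_DIIIa",
                   "orf_premature_stop", "orf_absent")

#' Specify one synthetic intron family
#'
#' A family is defined by its host gene and insertion site (1-based; the
#' intron sits between reference-gene positions `site` and `site + 1`), its
#' structural subgroup, its IEP type, the per-species presence probability,
#' and a set of lineage-specific degenerations/innovations. Constraints
#' mirroring the observed biology are enforced: IIA subgroups always carry an
#' intact RT/M (unless an orf degeneration flag says otherwise), and the 5'
#' linker -- characteristic of some IIB-LHE lineages -- is only allowed in
#' IIB1/IIB2 and is coupled with loss of the branch-point adenosine.
#'
#' @param host_gene Host gene name.
#' @param site Insertion site on the reference gene (>= 12).
#' @param subgroup One of IIA1, IIA2, IIB1, IIB2, IIB-like.
#' @param iep `"RTM"`, `"LHE"` or `"none"`.
#' @param presence_prob Probability that a species carries the family.
#' @param degenerations Character subset of
#'   `linker, no_branchpoint_A, lose_EBS2, lose_IC2, lose_ID2, add_ID2a,
#'   add_IE, add_DIIIa, orf_premature_stop, orf_absent`.
#' @param invasion_donor Optional family id whose evolved LHE ORF is grafted
#'   into this family's DIV (models an independent LHE invasion).
#' @param id Family id; defaults to `name_intron(host_gene, site)`.
#' @return A `family_spec` list.
#' @export
family_spec <- function(host_gene, site, subgroup, iep = "RTM",
                        presence_prob = 1, degenerations = character(),
                        invasion_donor = NULL,
                        id = name_intron(host_gene, site)) {
  subgroup <- match.arg(subgroup, SUBGROUPS)
  iep <- match.arg(iep, c("RTM", "LHE", "none"))
  stopifnot(presence_prob >= 0, presence_prob <= 1, site >= 12)
  bad <- setdiff(degenerations, DEGENERATIONS)
  if (length(bad)) stop("unknown degeneration flags: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (subgroup %in% c("IIA1", "IIA2") && iep != "RTM") {
    stop("invalid config: IIA introns carry an RT/M IEP", call. = FALSE)
  }
  if ("linker" %in% degenerations) {
    if (!subgroup %in% c("IIB1", "IIB2")) {
      stop("invalid config: the 5' linker is restricted to IIB1/IIB2", call. = FALSE)
    }
    degenerations <- union(degenerations, "no_branchpoint_A") # coupled features
  }
  if (iep == "none" && any(c("orf_premature_stop") %in% degenerations)) {
    stop("invalid config: orf_premature_stop requires an IEP", call. = FALSE)
  }
  if (!is.null(invasion_donor) && iep != "LHE") {
    stop("invalid config: invasion_donor applies to LHE families", call. = FALSE)
  }
  structure(
    list(id = id, host_gene = host_gene, site = as.integer(site),
         subgroup = subgroup, iep = iep, presence_prob = presence_prob,
         degenerations = degenerations, invasion_donor = invasion_donor),
    class = "family_spec"
  )
}

#' Cohort simulation configuration
#'
#' Defaults are the study conditions used throughout: a 20-species compartment
#' cohort, tree-depth scaled substitution rates of 0.05 substitutions/site for
#' RNA scaffolds and ORFs, a family-level scaffold divergence of 0.25, and a
#' 450-nt conserved DI core extension that provides alignable phylogenetic
#' signal shared by every family.
#'
#' @param n_species Number of species (>= 3).
#' @param organelle `"mt"` or `"cp"`.
#' @param seed Integer seed; the same seed and config give byte-identical
#'   cohorts.
#' @param birth_rate Yule birth rate for the species tree.
#' @param subst_rate_rna Expected RNA substitutions/site across the species
#'   tree depth.
#' @param subst_rate_orf Expected ORF substitutions/site across tree depth.
#' @param families List of [family_spec()]s.
#' @param exon_len Length of each annotated exon flank (default 60).
#' @param family_divergence Expected scaffold substitutions/site across the
#'   family-tree depth separating intron families (default 0.25).
#' @param extra_scaffold Extra conserved-core DI scaffold, in nt (default 450),
#'   shared by all families; provides retained columns for RNA phylogenetics.
#' @param translation_table NCBI genetic code for ORFs (default 1,
#'   configurable because organellar codes vary).
#' @param protect_factor Relative substitution rate of constrained sites
#'   (diagnostic motifs, DV, EBS/IBS, branch point); default 0.1.
#' @param min_edge_frac Minimum species-tree internal edge length as a
#'   fraction of tree depth (see [simulate_species_tree()]); default 0.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 20L, organelle = c("mt", "cp"), seed = 1L,
                       birth_rate = 1, subst_rate_rna = 0.05,
                       subst_rate_orf = 0.05, families = default_family_set(),
                       exon_len = 60L, family_divergence = 0.25,
                       extra_scaffold = 450L, translation_table = 1L,
                       protect_factor = 0.1, min_edge_frac = 0) {
  organelle <- match.arg(organelle)
  n_species <- as.integer(n_species)
  if (is.na(n_species) || n_species < 3L) {
    stop("invalid config: n_species must be >= 3", call. = FALSE)
  }
  stopifnot(birth_rate > 0, subst_rate_rna >= 0, subst_rate_orf >= 0,
            exon_len >= 20L, length(families) >= 1L)
  ids <- vapply(families, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate family ids", call. = FALSE)
  for (f in families) {
    if (!is.null(f$invasion_donor) && !f$invasion_donor %in% ids) {
      stop("invasion_donor '", f$invasion_donor, "' is not a configured family",
           call. = FALSE)
    }
    if (f$site < exon_len) {
      stop("family ", f$id, ": site must be >= exon_len so the upstream exon is complete",
           call. = FALSE)
    }
  }
  names(families) <- ids
  structure(
    list(n_species = n_species, organelle = organelle, seed = as.integer(seed),
         birth_rate = birth_rate, subst_rate_rna = subst_rate_rna,
         subst_rate_orf = subst_rate_orf, families = families,
         exon_len = as.integer(exon_len), family_divergence = family_divergence,
         extra_scaffold = as.integer(extra_scaffold),
         translation_table = translation_table, protect_factor = protect_factor,
         min_edge_frac = min_edge_frac),
    class = "sim_config"
  )
}

#' Default family set: the study conditions for the full analysis
#'
#' Twelve families spanning the observed subgroup mix: IIA1 with and without
#' the DIIIa insertion, IIA2, IIB1 and IIB2 with RT/M or LHE, lineage-specific
#' DI degenerations, a 5' linker coupled with branch-point loss in IIB1-LHE,
#' two independent LHE invasions (one within IIB1, one within IIB2, producing
#' the dual-origin signal) and an IEP-lacking, highly degenerated IIB-like
#' family present in every genome. Presence probabilities span the broad
#' (> 0.40) to narrow (< 0.15) occurrence range.
#'
#' @return List of [family_spec()]s.
#' @export
default_family_set <- function() {
  list(
    family_spec("cox1", 199, "IIA1", "RTM", 0.30),
    family_spec("atp1", 990, "IIA1", "RTM", 0.12, c("add_DIIIa", "add_IE")),
    family_spec("nad5", 1057, "IIA1", "RTM", 0.10, "add_DIIIa"),
    family_spec("petD", 87, "IIA2", "RTM", 0.30),
    family_spec("rnl", 1963, "IIB1", "RTM", 0.35),
    family_spec("rns", 780, "IIB1", "RTM", 0.10, c("lose_IC2", "orf_premature_stop")),
    family_spec("rnl", 2698, "IIB1", "LHE", 0.25,
                c("linker", "no_branchpoint_A", "lose_IC2", "lose_ID2", "lose_EBS2")),
    family_spec("rns", 420, "IIB1", "LHE", 0.30,
                c("linker", "no_branchpoint_A", "lose_EBS2"),
                invasion_donor = "rnl-2698"),
    family_spec("nad3", 216, "IIB2", "RTM", 0.52, "add_ID2a"),
    family_spec("cox1", 874, "IIB2", "LHE", 0.48),
    family_spec("rns", 670, "IIB2", "LHE", 0.45, invasion_donor = "cox1-874"),
    family_spec("infA", 62, "IIB-like", "none", 1.00,
                c("lose_EBS2", "no_branchpoint_A", "lose_ID2", "lose_IC2"))
  )
}

#' Degeneration-free family set for label-recovery experiments
#'
#' Twelve families covering the six principal subgroup x IEP lineages with no
#' degenerations, so every feature call has an unambiguous truth.
#'
#' @return List of [family_spec()]s.
#' @export
clean_family_set <- function() {
  list(
    family_spec("cox1", 199, "IIA1", "RTM", 0.9),
    family_spec("atp1", 990, "IIA1", "RTM", 0.7),
    family_spec("petD", 87, "IIA2", "RTM", 0.8),
    family_spec("atp1", 1316, "IIA2", "RTM", 0.6),
    family_spec("rnl", 1963, "IIB1", "RTM", 0.9),
    family_spec("petB", 277, "IIB1", "RTM", 0.7),
    family_spec("rns", 420, "IIB1", "LHE", 0.8),
    family_spec("rnl", 2698, "IIB1", "LHE", 0.6),
    family_spec("nad3", 216, "IIB2", "RTM", 0.9),
    family_spec("petB", 69, "IIB2", "RTM", 0.7),
    family_spec("cox1", 874, "IIB2", "LHE", 0.8),
    family_spec("rns", 670, "IIB2", "LHE", 0.6)
  )
}
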
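# Evolution of part lists along trees, the family-level backbone tree, and
# the full cohort simulator.

stop_codons <- function(translation_table = 1L) {
  code <- rna_code(translation_table)
  names(code)[code == "*"]
}

# One substitution step for a part across an edge. ORF parts undergo
# purifying selection against nonsense changes: substitutions creating a new
# stop codon are reverted (pre-existing stops, e.g. a planted premature stop,
# are kept).
mutate_part <- function(part, p_rna, p_orf, protect_factor = 0.1,
                        stops = c("UAA", "UAG", "UGA")) {
  p <- switch(part$rate,
    normal = p_rna,
    conserved = p_rna * protect_factor,
    orf = p_orf
  )
  if (p <= 0) return(part)
  old <- part$seq
  new <- mutate_rna(old, p, protect = part$protect, protect_factor = protect_factor)
  if (part$rate == "orf") {
    ncod <- nchar(new) %/% 3L
    if (ncod > 0L) {
      at <- 3L * (seq_len(ncod) - 1L) + 1L
      oldc <- substring(old, at, at + 2L)
      newc <- substring(new, at, at + 2L)
      bad <- which(newc %in% stops & !(oldc %in% stops))
      for (b in bad) substr(new, at[b], at[b] + 2L) <- oldc[b]
    }
  }
  part$seq <- new
  part
}

# Evolve a named part list along a tree (preorder); returns the per-tip part
# lists, named by tip label. Rates are per unit branch length.
evolve_parts_tree <- function(parts, tree, rna_rate_unit, orf_rate_unit,
                              protect_factor = 0.1,
                              stops = c("UAA", "UAG", "UGA")) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  store <- vector("list", ntip + tree$Nnode)
  store[[ntip + 1L]] <- parts
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]
    chi <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    store[[chi]] <- lapply(store[[par]], mutate_part,
                           p_rna = rna_rate_unit * len,
                           p_orf = orf_rate_unit * len,
                           protect_factor = protect_factor, stops = stops)
  }
  setNames(store[seq_len(ntip)], tree$tip.label)
}

# Family backbone tree: ultrametric, depth 1. Fixed clade structure
# (IIB-like, (IIA1+IIA2, IIB1+IIB2)) with IEP-type subclades inside each
# subgroup (LHE lineages within a subgroup share a common scaffold ancestor,
# reflecting invasion of a single ancestral lineage); within-group topologies
# are seeded coalescent draws.
build_family_tree <- function(families) {
  ids <- names(families)
  if (length(ids) < 2L) return(NULL)
  sub <- vapply(families, `[[`, character(1L), "subgroup")
  iep <- vapply(families, `[[`, character(1L), "iep")

  render_tips <- function(tips, age) {
    force(tips); force(age)
    function(parent_age) {
      k <- length(tips)
      if (k == 1L) return(paste0(tips, ":", format(parent_age, scientific = FALSE)))
      t <- ape::rcoal(k)
      d <- max(ape::node.depth.edgelength(t)[seq_len(k)])
      t$edge.length <- t$edge.length * (age / d)
      t$tip.label <- sort(tips)
      s <- sub(";$", "", ape::write.tree(t))
      paste0(s, ":", format(parent_age - age, scientific = FALSE))
    }
  }
  mk_node <- function(kids, age) {
    kids <- kids[!vapply(kids, is.null, logical(1L))]
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    force(age)
    function(parent_age) {
      paste0("(", paste(vapply(kids, function(k) k(age), character(1L)),
                        collapse = ","),
             "):", format(parent_age - age, scientific = FALSE))
    }
  }
  subgroup_clade <- function(sg, crown = 0.35) {
    tips <- ids[sub == sg]
    if (!length(tips)) return(NULL)
    if (length(tips) == 1L) return(render_tips(tips, crown))
    by_iep <- split(tips, iep[tips])
    if (length(by_iep) == 1L) return(render_tips(tips, crown))
    mk_node(lapply(by_iep, render_tips, age = 0.2), crown)
  }
  iia <- mk_node(list(subgroup_clade("IIA1"), subgroup_clade("IIA2")), 0.55)
  iib <- mk_node(list(subgroup_clade("IIB1"), subgroup_clade("IIB2")), 0.55)
  core <- mk_node(list(iia, iib), 0.75)
  root <- mk_node(list(subgroup_clade("IIB-like"), core), 1.0)
  s <- root(1.0)
  s <- sub(":0$", "", s)
  ape::read.tree(text = paste0(s, ";"))
}

#' Evolve family templates into per-species intron copies
#'
#' Presence of each family in each species is an independent Bernoulli draw
#' with the family's `presence_prob`; present copies diverge along the species
#' tree under a single-parameter substitution process with independent draws
#' for the RNA scaffold (`subst_rate_rna`) and the ORF (`subst_rate_orf`),
#' both expressed as expected substitutions/site across the tree depth.
#' Because scaffold and ORF share the same tree, their histories are congruent
#' by construction.
#'
#' @param templates Named list of family templates (as in a cohort's
#'   `$templates`: each with `$parts` and `$spec`).
#' @param species_tree Rooted ultrametric species tree.
#' @param config The [sim_config()] (rates, seed, protect factor).
#' @return List with `presence` (family x species logical matrix) and
#'   `copies` (per family: named list of per-species part lists).
#' @export
evolve_cohort <- function(templates, species_tree, config) {
  sp <- species_tree$tip.label
  depth <- tree_depth(species_tree)
  rna_unit <- if (depth > 0) config$subst_rate_rna / depth else 0
  orf_unit <- if (depth > 0) config$subst_rate_orf / depth else 0
  stops <- stop_codons(config$translation_table)
  with_seed(config$seed + 2L, {
    presence <- matrix(FALSE, length(templates), length(sp),
                       dimnames = list(names(templates), sp))
    copies <- list()
    for (id in names(templates)) {
      tpl <- templates[[id]]
      presence[id, ] <- runif(length(sp)) < tpl$spec$presence_prob
      tips <- evolve_parts_tree(tpl$parts, species_tree, rna_unit, orf_unit,
                                config$protect_factor, stops)
      copies[[id]] <- tips[presence[id, ]]
    }
    list(presence = presence, copies = copies)
  })
}

#' Simulate a synthetic organellar intron cohort with full ground truth
#'
#' End-to-end generator: species tree (Yule), family backbone tree, reference
#' host genes, family templates derived from a shared ancestral scaffold
#' (subgroup motifs, degenerations, EBS-IBS interfaces, RT/M or LHE ORFs --
#' with optional LHE invasion grafts copying a donor family's evolved ORF),
#' per-species intron copies, species gene copies, and assembled genomes with
#' gene models. Identical config (including seed) gives byte-identical output.
#'
#' @param config A [sim_config()].
#' @return An `intron_cohort`: list with `config`, `species_tree`,
#'   `family_tree`, `reference_genes`, `templates`, `introns` (data.frame, one
#'   row per intron occurrence), `structures` (named dot-bracket strings),
#'   `genomes` (list per species: `id`, `organelle`, `sequence` (DNA),
#'   `gene_models` data.frame), `presence` (family x genome matrix) and
#'   `truth` (data.frame, one row per intron occurrence).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  species_tree <- simulate_species_tree(config$n_species, config$birth_rate,
                                        config$seed,
                                        min_edge_frac = config$min_edge_frac %||% 0)
  sp <- species_tree$tip.label
  depth <- tree_depth(species_tree)
  stops <- stop_codons(config$translation_table)

  fam_stage <- with_seed(config$seed + 1L, {
    genes <- sort(unique(vapply(config$families, `[[`, character(1L), "host_gene")))
    ref_genes <- list()
    ref_protect <- list()
    for (g in genes) {
      sites <- sort(unique(vapply(
        Filter(function(f) f$host_gene == g, config$families),
        `[[`, integer(1L), "site"
      )))
      ref_genes[[g]] <- rand_rna(max(sites) + config$exon_len + 20L)
      ref_protect[[g]] <- unlist(lapply(sites, function(s) c((s - 11L):s, s + 1L)))
    }
    root_parts <- build_scaffold_parts(config$extra_scaffold)
    ieps <- vapply(config$families, `[[`, character(1L), "iep")
    if (any(ieps == "RTM")) {
      p <- make_orf_part("RTM", config$translation_table)
      p$name <- "rtm_orf"
      root_parts$rtm_orf <- p
    }
    if (any(ieps == "LHE")) {
      p <- make_orf_part("LHE", config$translation_table)
      p$name <- "lhe_orf"
      root_parts$lhe_orf <- p
    }
    family_tree <- build_family_tree(config$families)
    fam_tips <- if (!is.null(family_tree)) {
      evolve_parts_tree(root_parts, family_tree,
                        rna_rate_unit = config$family_divergence,
                        orf_rate_unit = config$family_divergence,
                        protect_factor = config$protect_factor, stops = stops)
    } else {
      setNames(list(root_parts), names(config$families))
    }
    templates <- list()
    for (id in names(config$families)) {
      spec <- config$families[[id]]
      tip <- fam_tips[[id]]
      ref <- ref_genes[[spec$host_gene]]
      ibs_context <- list(
        up12 = substr(ref, spec$site - 11L, spec$site),
        down2 = substr(ref, spec$site + 1L, spec$site + 2L)
      )
      orf_part <- NULL
      if (spec$iep == "RTM") {
        orf_part <- tip$rtm_orf
      } else if (spec$iep == "LHE") {
        orf_part <- if (!is.null(spec$invasion_donor)) {
          fam_tips[[spec$invasion_donor]]$lhe_orf # invasion graft
        } else {
          tip$lhe_orf
        }
      }
      if (!is.null(orf_part)) orf_part$name <- "div_core"
      parts <- tip
      parts$rtm_orf <- NULL
      parts$lhe_orf <- NULL
      parts <- apply_family_spec(parts, spec, ibs_context, orf_part)
      templates[[id]] <- list(spec = spec, parts = parts,
                              ibs_context = ibs_context,
                              truth = template_truth(parts, spec, ibs_context))
    }
    list(ref_genes = ref_genes, ref_protect = ref_protect,
         family_tree = family_tree, templates = templates)
  })

  ev <- evolve_cohort(fam_stage$templates, species_tree, config)

  # Species copies of the reference genes (IBS windows constrained).
  rna_unit <- if (depth > 0) config$subst_rate_rna / depth else 0
  sp_genes <- with_seed(config$seed + 3L, {
    out <- list()
    for (g in names(fam_stage$ref_genes)) {
      part <- new_part(g, "gene", fam_stage$ref_genes[[g]],
                       strrep(".", nchar(fam_stage$ref_genes[[g]])),
                       protect = fam_stage$ref_protect[[g]])
      tips <- evolve_parts_tree(list(part), species_tree, rna_unit, 0,
                                config$protect_factor, stops)
      out[[g]] <- lapply(tips, function(pp) pp[[1L]]$seq)
    }
    out
  })

  # Assemble genomes and intron records.
  build <- with_seed(config$seed + 4L, {
    exon_len <- config$exon_len
    fam_by_gene <- split(names(fam_stage$templates), vapply(
      fam_stage$templates, function(t) t$spec$host_gene, character(1L)
    ))
    introns <- list()
    genomes <- list()
    structures <- character(0)
    for (s in sp) {
      pieces <- character(0)
      pos <- 0L
      gene_rows <- list()
      for (g in sort(names(fam_by_gene))) {
        fams <- fam_by_gene[[g]]
        sites <- vapply(fams, function(id) fam_stage$templates[[id]]$spec$site, integer(1L))
        ord <- order(sites)
        fams <- fams[ord]
        sites <- sites[ord]
        gseq <- sp_genes[[g]][[s]]
        spacer <- rand_rna(50L)
        pieces <- c(pieces, rna_to_dna(spacer))
        pos <- pos + 50L
        a <- min(sites) - exon_len + 1L
        b <- max(sites) + exon_len
        cur <- a
        gene_start <- pos + 1L
        prev_exon_seq <- NULL
        pending <- NULL # intron awaiting its downstream flank
        for (k in seq_along(fams)) {
          id <- fams[k]
          s_k <- sites[k]
          exon_seq <- substr(gseq, cur, s_k)
          pieces <- c(pieces, rna_to_dna(exon_seq))
          exon_iv <- c(pos + 1L, pos + nchar(exon_seq))
          pos <- pos + nchar(exon_seq)
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            genome_id = s, gene = g, type = "exon",
            start = exon_iv[1L], end = exon_iv[2L], family = NA_character_,
            site = NA_integer_, stringsAsFactors = FALSE
          )
          if (!is.null(pending)) {
            introns[[pending]]$downstream_flank <-
              substr(exon_seq, 1L, min(20L, nchar(exon_seq)))
            pending <- NULL
          }
          if (ev$presence[id, s]) {
            asm <- assemble_parts(ev$copies[[id]][[s]])
            key <- paste0(s, ":", id)
            iv <- c(pos + 1L, pos + nchar(asm$sequence))
            pieces <- c(pieces, rna_to_dna(asm$sequence))
            pos <- pos + nchar(asm$sequence)
            introns[[key]] <- list(
              key = key, intron_id = id, genome_id = s, host_gene = g,
              site = s_k, family = id, sequence = asm$sequence,
              dot_bracket = asm$dot_bracket,
              upstream_flank = substr(exon_seq,
                                      max(1L, nchar(exon_seq) - 19L),
                                      nchar(exon_seq)),
              downstream_flank = NA_character_,
              genome_start = iv[1L], genome_end = iv[2L]
            )
            structures[key] <- asm$dot_bracket
            gene_rows[[length(gene_rows) + 1L]] <- data.frame(
              genome_id = s, gene = g, type = "intron",
              start = iv[1L], end = iv[2L], family = id, site = s_k,
              stringsAsFactors = FALSE
            )
            pending <- key
          }
          cur <- s_k + 1L
        }
        exon_seq <- substr(gseq, cur, b)
        pieces <- c(pieces, rna_to_dna(exon_seq))
        exon_iv <- c(pos + 1L, pos + nchar(exon_seq))
        pos <- pos + nchar(exon_seq)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          genome_id = s, gene = g, type = "exon",
          start = exon_iv[1L], end = exon_iv[2L], family = NA_character_,
          site = NA_integer_, stringsAsFactors = FALSE
        )
        if (!is.null(pending)) {
          introns[[pending]]$downstream_flank <-
            substr(exon_seq, 1L, min(20L, nchar(exon_seq)))
        }
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          genome_id = s, gene = g, type = "gene",
          start = gene_start, end = pos, family = NA_character_,
          site = NA_integer_, stringsAsFactors = FALSE
        )
        spacer <- rand_rna(50L)
        pieces <- c(pieces, rna_to_dna(spacer))
        pos <- pos + 50L
      }
      gm <- do.call(rbind, gene_rows)
      gm$strand <- "+"
      genomes[[s]] <- list(id = s, organelle = config$organelle, species = s,
                           sequence = paste(pieces, collapse = ""),
                           gene_models = gm)
    }
    list(introns = introns, genomes = genomes, structures = structures)
  })

  intron_df <- do.call(rbind, lapply(build$introns, function(x) {
    data.frame(key = x$key, intron_id = x$intron_id, genome_id = x$genome_id,
               host_gene = x$host_gene, site = x$site, family = x$family,
               sequence = x$sequence, dot_bracket = x$dot_bracket,
               upstream_flank = x$upstream_flank,
               downstream_flank = x$downstream_flank,
               genome_start = x$genome_start, genome_end = x$genome_end,
               stringsAsFactors = FALSE)
  }))
  rownames(intron_df) <- NULL

  truth <- do.call(rbind, lapply(seq_len(NROW(intron_df)), function(i) {
    tr <- fam_stage$templates[[intron_df$family[i]]]$truth
    data.frame(
      key = intron_df$key[i], family = tr$family, genome_id = intron_df$genome_id[i],
      subgroup = tr$subgroup, iep_type = tr$iep_type, iep_status = tr$iep_status,
      length = tr$length, linker_len = tr$linker_len,
      branchpoint = !is.na(tr$branchpoint_pos),
      branchpoint_pos = tr$branchpoint_pos,
      tetramer = tr$tetramer, dimer = tr$dimer,
      ebs2_present = tr$ebs2$present,
      has_ia = !is.null(tr$accessory$ia), has_ic2 = !is.null(tr$accessory$ic2),
      has_id2 = !is.null(tr$accessory$id2), has_id2a = !is.null(tr$accessory$id2a),
      has_ie = !is.null(tr$accessory$ie), has_diiia = !is.null(tr$accessory$diiia),
      stringsAsFactors = FALSE
    )
  }))
  rownames(truth) <- NULL

  structure(
    list(config = config, species_tree = species_tree,
         family_tree = fam_stage$family_tree,
         reference_genes = fam_stage$ref_genes,
         templates = fam_stage$templates,
         introns = intron_df, structures = build$structures,
         genomes = build$genomes, presence = ev$presence, truth = truth),
    class = "intron_cohort"
  )
}

#' @export
print.intron_cohort <- function(x, ...) {
  cat("intron_cohort:", length(x$genomes), x$config$organelle, "genomes,",
      length(x$templates), "families,", NROW(x$introns), "intron copies\n")
  invisible(x)
}
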
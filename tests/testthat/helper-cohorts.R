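# Shared simulated cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

get_cohort <- function(name) {
  if (!exists(name, envir = .cohort_cache)) {
    coh <- switch(name,
      clean0 = simulate_cohort(sim_config(
        n_species = 8, seed = 42, subst_rate_rna = 0, subst_rate_orf = 0,
        family_divergence = 0, families = clean_family_set()
      )),
      default = simulate_cohort(sim_config(n_species = 6, seed = 7)),
      stop("unknown cohort fixture: ", name)
    )
    assign(name, coh, envir = .cohort_cache)
  }
  get(name, envir = .cohort_cache)
}

# Evolve a single unstructured sequence along a tree; returns a named aligned
# character vector (one row per tip). Rates are expected substitutions/site
# across the whole tree depth.
sim_tree_alignment <- function(tree, len, rate, seed) {
  depth <- max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  unit <- if (depth > 0) rate / depth else 0
  intronscape:::with_seed(seed, {
    part <- intronscape:::new_part("s", "x", intronscape:::rand_rna(len),
                                   strrep(".", len))
    tips <- intronscape:::evolve_parts_tree(list(part), tree, unit, 0)
    vapply(tips, function(p) p[[1L]]$seq, character(1L))
  })
}
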
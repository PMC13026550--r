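#' Simulate an ultrametric species tree under a Yule (pure-birth) process
#'
#' Provides the vertical-inheritance backbone along which intron copies
#' diverge. Leaves are labelled `sp1..spN`; the tree is rooted, fully
#' bifurcating and ultrametric, and deterministic for a fixed seed.
#'
#' @param n_species Number of species (>= 3).
#' @param birth_rate Yule birth rate (> 0).
#' @param seed Integer seed.
#' @param min_edge_frac Optional minimum internal edge length as a fraction of
#'   tree depth (default 0 = unconditioned). Yule trees routinely contain
#'   near-zero internal edges -- bipartitions no finite alignment can resolve;
#'   recovery experiments condition on resolvable trees by rejection sampling
#'   (deterministic for a fixed seed).
#' @return A rooted ultrametric `ape::phylo` tree.
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1, seed = 1L,
                                  min_edge_frac = 0) {
  n_species <- as.integer(n_species)
  if (is.na(n_species) || n_species < 3L) {
    stop("invalid config: n_species must be >= 3", call. = FALSE)
  }
  if (birth_rate <= 0) stop("invalid config: birth_rate must be > 0", call. = FALSE)
  tree <- with_seed(seed, {
    repeat {
      t <- ape::rphylo(n_species, birth = birth_rate, death = 0)
      if (min_edge_frac <= 0) break
      depth <- max(ape::node.depth.edgelength(t)[seq_len(n_species)])
      internal <- t$edge.length[t$edge[, 2L] > n_species]
      if (!length(internal) || min(internal) >= min_edge_frac * depth) break
    }
    t
  })
  tree$tip.label <- paste0("sp", seq_len(n_species))
  tree
}

# Depth (root-to-tip path length) of an ultrametric tree.
tree_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}
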
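# Hotspot masking, distances, neighbor-joining, bootstrap support,
# Robinson-Foulds congruence and monophyly tests.

as_aln_matrix <- function(alignment) {
  if (inherits(alignment, "masked_alignment")) return(alignment$matrix)
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    stopifnot(is.character(alignment))
    if (is.null(names(alignment))) {
      names(alignment) <- paste0("seq", seq_along(alignment))
    }
    if (length(unique(nchar(alignment))) != 1L) {
      stop("alignment rows differ in length", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
    rownames(m) <- names(alignment)
  }
  m[m == "T"] <- "U"
  m
}

#' Mask mutation-hotspot regions out of an alignment
#'
#' Labeled column intervals (e.g. the 5' terminal linker region, loop regions
#' of DI substructures, DIIIa, loops within DII/DIII/DIV) are removed before
#' distance computation, mirroring the exclusion of fast-evolving regions
#' prior to phylogenetic inference. Overlapping regions are merged with a
#' warning; a region outside the alignment is an error, as is masking every
#' column.
#'
#' @param alignment Named character vector of aligned sequences, or a
#'   character matrix (rows = taxa).
#' @param region_spec data.frame with columns `label`, `start`, `end`
#'   (1-based inclusive alignment columns); NULL or zero rows = no masking.
#' @return A `masked_alignment`: list with `matrix` (retained columns),
#'   `mask` (the region spec with per-region column counts), `retained`
#'   (original column indices kept) and `retained_count`.
#' @export
mask_regions <- function(alignment, region_spec = NULL) {
  m <- as_aln_matrix(alignment)
  L <- ncol(m)
  drop <- logical(L)
  if (!is.null(region_spec) && nrow(region_spec)) {
    if (any(region_spec$start < 1L | region_spec$end > L |
              region_spec$start > region_spec$end)) {
      stop("mask region outside alignment (length ", L, ")", call. = FALSE)
    }
    cols <- unlist(Map(seq, region_spec$start, region_spec$end))
    if (anyDuplicated(cols)) warning("overlapping mask regions merged")
    drop[unique(cols)] <- TRUE
    region_spec$columns <- mapply(function(s, e) e - s + 1L,
                                  region_spec$start, region_spec$end)
  } else {
    region_spec <- data.frame(label = character(0), start = integer(0),
                              end = integer(0), columns = integer(0))
  }
  retained <- which(!drop)
  if (!length(retained)) stop("empty alignment after masking", call. = FALSE)
  structure(
    list(matrix = m[, retained, drop = FALSE], mask = region_spec,
         retained = retained, retained_count = length(retained)),
    class = "masked_alignment"
  )
}

#' Pairwise distances from a (masked) alignment
#'
#' p-distance = mismatches / compared sites under pairwise deletion of gaps
#' (`-`) and `N`. The JC69 correction d = -(3/4) ln(1 - 4p/3) is defined only
#' for p < 0.75; saturated pairs are reported as `Inf`.
#'
#' @param alignment A `masked_alignment`, named character vector or matrix.
#' @param model `"p"` or `"JC69"`.
#' @return Symmetric numeric matrix with zero diagonal and a `model`
#'   attribute.
#' @export
compute_distances <- function(alignment, model = c("p", "JC69")) {
  model <- match.arg(model)
  m <- as_aln_matrix(alignment)
  if (nrow(m) < 3L) stop("need at least 3 sequences", call. = FALSE)
  if (!ncol(m)) stop("no retained columns", call. = FALSE)
  n <- nrow(m)
  labels <- rownames(m)
  valid <- m != "-" & m != "N"
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- valid[i, ] & valid[j, ]
      ncomp <- sum(comp)
      if (ncomp == 0L) {
        stop("no comparable sites between '", labels[i], "' and '", labels[j], "'",
             call. = FALSE)
      }
      p <- sum(m[i, comp] != m[j, comp]) / ncomp
      if (model == "JC69") {
        p <- if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else Inf
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  attr(d, "model") <- model
  d
}

# Lexicographically smallest leaf label in each active cluster, used as the
# deterministic NJ tie-break key.
nj_pick_pair <- function(Q, keys) {
  n <- nrow(Q)
  qmin <- min(Q[upper.tri(Q)])
  best <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (Q[i, j] <= qmin + 1e-12) {
        pair_key <- sort(c(keys[i], keys[j]))
        if (is.null(best) || pair_key[1L] < best$key[1L] ||
            (pair_key[1L] == best$key[1L] && pair_key[2L] < best$key[2L])) {
          best <- list(i = i, j = j, key = pair_key)
        }
      }
    }
  }
  best
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining with the Q criterion. Ties in Q are
#' broken deterministically by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest leaf). Negative branch
#' lengths are clamped to zero and noted in the `clamped` attribute.
#'
#' @param dm Symmetric numeric distance matrix with labels (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
build_nj_tree <- function(dm) {
  if (!is.matrix(dm) || !isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(!is.finite(dm))) stop("distance matrix contains non-finite values", call. = FALSE)
  labels <- rownames(dm)
  n0 <- length(labels)
  if (n0 < 3L) stop("need at least 3 taxa", call. = FALSE)
  D <- dm
  nodes <- labels          # newick fragment per active cluster
  keys <- labels           # tie-break key per active cluster
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    format(max(0, x), scientific = FALSE)
  }
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    pick <- nj_pick_pair(Q, keys)
    i <- pick$i; j <- pick$j
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    new_frag <- paste0("(", nodes[i], ":", bl(vi), ",", nodes[j], ":", bl(vj), ")")
    new_key <- min(keys[i], keys[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    nodes <- c(nodes[keep], new_frag)
    keys <- c(keys[keep], new_key)
    rownames(D2) <- colnames(D2) <- keys
    D <- D2
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", nodes[1], ":", bl(v1), ",", nodes[2], ":", bl(v2), ",",
                nodes[3], ":", bl(v3), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# Canonical non-trivial bipartition keys of an unrooted tree: each internal
# edge splits the leaves; the side not containing the alphabetically smallest
# leaf is sorted and joined with '|'.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n <- length(tips)
  ref <- min(tips)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in pp) {
    side <- tips[cl]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= n - 2L) {
      keys <- c(keys, paste(sort(side), collapse = "|"))
    }
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets; 0
#' means identical unrooted topologies.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  s1 <- sort(t1$tip.label); s2 <- sort(t2$tip.label)
  if (!identical(s1, s2)) {
    stop("leaf sets differ: ",
         paste(c(setdiff(s1, s2), setdiff(s2, s1)), collapse = ", "),
         call. = FALSE)
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Classical bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement; support for each internal
#' edge of the point-estimate tree is the percentage of replicate NJ trees
#' containing the same bipartition. Support is mapped only onto bipartitions
#' of the point-estimate tree.
#'
#' @param alignment A `masked_alignment`, named character vector or matrix.
#' @param model Distance model, see [compute_distances()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; fixed seed gives identical supports.
#' @return The point-estimate tree with `node.label` holding per-edge support
#'   (percent) and a `support` attribute (named by bipartition key).
#' @export
bootstrap_support <- function(alignment, model = "p", n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  m <- as_aln_matrix(alignment)
  tree <- build_nj_tree(compute_distances(m, model))
  keys <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(keys)), keys)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      bt <- build_nj_tree(compute_distances(m[, cols, drop = FALSE], model))
      bk <- tree_bipartitions(bt)
      hit <- keys %in% bk
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_reps
  # Map support onto internal nodes of the (unrooted) point-estimate tree.
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  ref <- min(tips)
  nnode <- tree$Nnode
  labs <- rep("", nnode)
  pp <- ape::prop.part(tree)
  for (k in seq_along(pp)) {
    side <- tips[pp[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= length(tips) - 2L) {
      key <- paste(sort(side), collapse = "|")
      if (key %in% names(support)) labs[k] <- format(support[[key]], digits = 4)
    }
  }
  tree$node.label <- labs
  attr(tree, "support") <- support
  tree
}

#' Test whether a set of leaves is monophyletic
#'
#' The tree is rooted on `outgroup_leaf`; the query is monophyletic iff the
#' smallest clade containing all query leaves contains no other leaf.
#'
#' @param tree An `ape::phylo` tree.
#' @param leaves Character vector of query leaf labels (proper subset).
#' @param outgroup_leaf Leaf used to root the tree; must not be in `leaves`.
#' @return Logical.
#' @export
test_monophyly <- function(tree, leaves, outgroup_leaf) {
  tips <- tree$tip.label
  if (!all(leaves %in% tips)) {
    stop("query leaves not in tree: ",
         paste(setdiff(leaves, tips), collapse = ", "), call. = FALSE)
  }
  if (outgroup_leaf %in% leaves) stop("outgroup leaf must not be a query leaf", call. = FALSE)
  if (!outgroup_leaf %in% tips) stop("outgroup leaf not in tree", call. = FALSE)
  if (setequal(leaves, setdiff(tips, outgroup_leaf)) || setequal(leaves, tips)) {
    warning("query covers (almost) all leaves; trivially monophyletic")
    return(TRUE)
  }
  rooted <- ape::root(ape::unroot(tree), outgroup = outgroup_leaf, resolve.root = TRUE)
  ape::is.monophyletic(rooted, leaves)
}
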
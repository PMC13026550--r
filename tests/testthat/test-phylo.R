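test_that("mask_regions removes labeled intervals and validates input", {
  aln <- c(a = "ACGUACGUAC", b = "ACGUACGUAC", c = "UGCAUGCAUG")
  m0 <- mask_regions(aln, NULL)
  expect_equal(m0$retained_count, 10)

  spec <- data.frame(label = c("x", "y"), start = c(2, 7), end = c(4, 8))
  m1 <- mask_regions(aln, spec)
  expect_equal(m1$retained, c(1L, 5L, 6L, 9L, 10L)) # set complement of the mask
  expect_equal(m1$retained_count, 5)

  expect_error(mask_regions(aln, data.frame(label = "x", start = 1, end = 10)),
               "empty alignment")
  expect_error(mask_regions(aln, data.frame(label = "x", start = 5, end = 12)),
               "outside")
  expect_warning(mask_regions(aln, data.frame(label = c("x", "y"),
                                              start = c(1, 2), end = c(3, 4))),
                 "overlapping")
})

test_that("distances follow p and JC69 with pairwise deletion", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "AAAAAAAAAA")
  d <- compute_distances(aln, "p")
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 0.1)

  dj <- compute_distances(aln, "JC69")
  expect_equal(dj["a", "b"], -0.75 * log(1 - 0.4 / 3))

  # pairwise deletion of gaps
  alng <- c(a = "AA-AAAAAAA", b = "AACAAAAAAC", c = "AAAAAAAAAA")
  dg <- compute_distances(alng, "p")
  expect_equal(dg["a", "b"], 1 / 9)

  # saturation: p >= 0.75 is flagged infinite under JC69
  alns <- c(a = "AAAA", b = "CCCC", c = "AAAA")
  expect_true(is.infinite(compute_distances(alns, "JC69")["a", "b"]))

  # no comparable sites is an error naming the pair
  expect_error(compute_distances(c(a = "A---", b = "-CCC", c = "AAAA"), "p"),
               "'a' and 'b'")

  # JC69 is monotone in p on [0, 0.75)
  p <- seq(0, 0.74, by = 0.01)
  jc <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(jc) > 0))
})

test_that("masking invariant columns leaves distances unchanged", {
  set.seed(41)
  const <- strrep("G", 20)
  var1 <- vapply(1:4, function(i) intronscape:::rand_rna(50), character(1))
  aln <- setNames(paste0(substr(var1, 1, 25), const, substr(var1, 26, 50)),
                  paste0("t", 1:4))
  d_full <- compute_distances(mask_regions(aln, NULL), "p")
  d_mask <- compute_distances(
    mask_regions(aln, data.frame(label = "const", start = 26, end = 45)), "p"
  )
  # p-distance denominators change, so compare mismatch counts instead
  expect_equal(d_full * 70, d_mask * 50 + 0) # constant block adds no mismatches
})

test_that("neighbor joining matches the 3-taxon closed form", {
  dm <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
               dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  tr <- build_nj_tree(dm)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["t1"]], 0.05) # (0.2 + 0.3 - 0.4) / 2
  expect_equal(el[["t2"]], 0.15)
  expect_equal(el[["t3"]], 0.25)
  expect_error(build_nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
})

test_that("NJ recovers the topology of additive matrices", {
  # 4-taxon additive matrix from ((A,B),(C,D)) with all edges 0.1
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  dm <- cophenetic(tr)
  nj <- build_nj_tree(dm)
  expect_equal(rf_distance(nj, tr), 0)

  # ultrametric 6-taxon matrix from a known tree
  t6 <- simulate_species_tree(6, 1, seed = 5)
  expect_equal(rf_distance(build_nj_tree(cophenetic(t6)), t6), 0)

  # random 6-10 taxon trees, exact recovery, cross-checked against ape::nj
  set.seed(42)
  for (i in 1:30) {
    t <- ape::rtree(sample(6:10, 1))
    dm <- cophenetic(t)
    mine <- build_nj_tree(dm)
    expect_equal(rf_distance(mine, t), 0)
    expect_equal(rf_distance(mine, ape::nj(as.dist(dm))), 0)
  }
})

test_that("Robinson-Foulds distance counts bipartition differences", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")), "differ")

  # symmetry and agreement with phangorn on random trees
  skip_if_not_installed("phangorn")
  set.seed(43)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    a <- ape::rtree(n)
    b <- ape::rtree(n)
    b$tip.label <- a$tip.label[match(b$tip.label, sort(b$tip.label))]
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_equal(rf_distance(a, b), phangorn::RF.dist(a, b))
  }
})

test_that("bootstrap support is deterministic and finds clear splits", {
  tree <- ape::read.tree(text = paste0(
    "(((A:0.005,B:0.005):0.005,(C:0.005,D:0.005):0.005):0.15,",
    "((E:0.005,F:0.005):0.005,(G:0.005,H:0.005):0.005):0.15);"
  ))
  sup <- vapply(1:5, function(s) {
    aln <- sim_tree_alignment(tree, 2000, rate = 0.31, seed = s)
    bt <- bootstrap_support(aln, "p", n_reps = 100, seed = s)
    attr(bt, "support")[[paste(sort(c("E", "F", "G", "H")), collapse = "|")]]
  }, numeric(1))
  expect_true(all(sup >= 95)) # the deep split between the two clusters

  aln <- sim_tree_alignment(tree, 500, rate = 0.31, seed = 9)
  b1 <- bootstrap_support(aln, "p", 50, seed = 7)
  b2 <- bootstrap_support(aln, "p", 50, seed = 7)
  expect_identical(attr(b1, "support"), attr(b2, "support"))

  # identical sequences: a star-like problem still returns supports
  alnid <- setNames(rep(strrep("ACGU", 25), 4), paste0("t", 1:4))
  bid <- bootstrap_support(alnid, "p", 10, seed = 1)
  expect_true(all(attr(bid, "support") >= 0 & attr(bid, "support") <= 100))
})

test_that("monophyly is assessed on the outgroup-rooted tree", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),E);")
  expect_true(test_monophyly(tr, c("A", "B"), "E"))
  expect_false(test_monophyly(tr, c("A", "C"), "E"))
  expect_true(test_monophyly(tr, c("A", "B", "C", "D"), "E") |> suppressWarnings())
  expect_warning(test_monophyly(tr, c("A", "B", "C", "D"), "E"), "trivially")
  expect_error(test_monophyly(tr, c("A", "E"), "E"), "outgroup")
  expect_error(test_monophyly(tr, c("A", "Z"), "E"), "not in tree")
})
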
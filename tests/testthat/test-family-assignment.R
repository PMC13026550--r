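test_that("insertion sites map onto the reference gene by local alignment", {
  set.seed(21)
  ref <- intronscape:::rand_rna(800)
  # exact flank ending at reference position 686
  flank <- substr(ref, 667, 686)
  expect_equal(map_insertion_site(flank, ref)$site, 686)

  # one mismatch at the flank 5' end: compare against the DP oracle
  v <- intronscape:::seq_chars(flank)
  v[1] <- setdiff(c("A", "C", "G", "U"), v[1])[1]
  flank_mm <- paste(v, collapse = "")
  got <- map_insertion_site(flank_mm, ref)
  oracle <- local_align_oracle(intronscape:::rna_to_dna(flank_mm),
                               intronscape:::rna_to_dna(ref))
  expect_equal(got$site, oracle$subject_end)
  expect_equal(got$site, 686)
  expect_equal(got$score, oracle$score)

  # unrelated flank is unmappable
  expect_error(map_insertion_site(strrep("A", 20), substr(ref, 1, 400)),
               "unmappable")
})

test_that("site mapping agrees with the brute-force oracle on noisy flanks", {
  set.seed(22)
  for (i in 1:10) {
    ref <- intronscape:::rand_rna(400)
    end <- sample(100:390, 1)
    flank <- intronscape:::mutate_rna(substr(ref, end - 19, end), 0.05)
    got <- tryCatch(map_insertion_site(flank, ref), error = function(e) NULL)
    oracle <- local_align_oracle(intronscape:::rna_to_dna(flank),
                                 intronscape:::rna_to_dna(ref))
    if (!is.null(got)) expect_equal(got$score, oracle$score)
  }
})

test_that("families are defined by shared site AND sequence homology", {
  set.seed(23)
  ref <- intronscape:::rand_rna(400)
  flank <- substr(ref, 181, 200) # site 200
  base <- intronscape:::rand_rna(600)
  near <- intronscape:::mutate_rna(base, 0.05)   # ~95% identity
  far <- intronscape:::rand_rna(600)             # ~25% identity
  introns <- data.frame(
    key = c("a", "b", "c"), host_gene = "g",
    sequence = c(base, near, far),
    upstream_flank = flank, stringsAsFactors = FALSE
  )
  fam <- assign_families(introns, c(g = ref))
  asg <- setNames(fam$assignments$family, fam$assignments$key)
  expect_identical(asg[["a"]], asg[["b"]])       # homologous pair: one family
  expect_identical(asg[["a"]], "g-200")
  expect_identical(asg[["c"]], "g-200.2")        # co-sited, non-homologous

  # same sequence at different sites -> two families (site rule dominates)
  introns2 <- data.frame(
    key = c("a", "b"), host_gene = "g",
    sequence = base,
    upstream_flank = c(substr(ref, 181, 200), substr(ref, 281, 300)),
    stringsAsFactors = FALSE
  )
  fam2 <- assign_families(introns2, c(g = ref))
  expect_equal(length(unique(fam2$assignments$family)), 2)

  # unmappable introns land in the unassigned bin
  introns3 <- rbind(introns, data.frame(
    key = "d", host_gene = "g", sequence = base,
    upstream_flank = strrep("A", 20), stringsAsFactors = FALSE
  ))
  fam3 <- assign_families(introns3, c(g = ref))
  expect_true("d" %in% fam3$unassigned$key)
})

test_that("seed-and-extend search finds planted copies and nothing else", {
  set.seed(24)
  genome <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  probe <- substr(genome, 4001, 4500)
  hits <- search_family_members(probe, genome)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pident, 100)
  expect_equal(hits$coverage, 1)
  expect_equal(c(hits$start, hits$end), c(4001, 4500))

  # absent probe: no hits at E <= 1e-5 across 20 seeds
  fp <- vapply(1:20, function(s) {
    intronscape:::with_seed(s, {
      g <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
      p <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
      nrow(search_family_members(p, g))
    })
  }, numeric(1))
  expect_true(all(fp == 0))

  # planted copy with 5% substitutions: recovered, identity 95 +/- 2
  rec <- vapply(1:20, function(s) {
    intronscape:::with_seed(100 + s, {
      g <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
      p <- intronscape:::rna_to_dna(
        intronscape:::mutate_rna(intronscape:::dna_to_rna(substr(g, 2001, 2500)), 0.05))
      h <- search_family_members(p, g)
      if (nrow(h)) h$pident[1] else NA_real_
    })
  }, numeric(1))
  expect_true(all(!is.na(rec))) # recall 1.0 at >= 85% identity
  expect_true(all(abs(rec - 95) <= 2.5))

  expect_error(search_family_members("ACGTACGT", "ACGT"), "word size")
})

test_that("occurrence frequencies and distribution classes match hand values", {
  mk <- function(k, n) {
    m <- matrix(FALSE, 1, n, dimnames = list("fam", paste0("g", 1:n)))
    m[1, seq_len(k)] <- TRUE
    m
  }
  f1 <- occurrence_frequency(mk(23, 44))
  expect_equal(f1$percent, 52.3)
  expect_identical(f1$class, "broad")
  f2 <- occurrence_frequency(mk(23, 47))
  expect_equal(f2$percent, 48.9)
  f3 <- occurrence_frequency(mk(7, 44))
  expect_equal(f3$percent, 15.9)
  expect_identical(f3$class, "intermediate")
  f4 <- occurrence_frequency(mk(0, 44))
  expect_equal(f4$percent, 0)
  expect_identical(f4$class, "narrow")
  expect_error(occurrence_frequency(matrix(logical(0), 0, 0)), "at least one")
})

test_that("occurrence frequency equals brute-force column counts", {
  set.seed(25)
  for (i in 1:20) {
    nf <- sample(2:8, 1); ng <- sample(3:30, 1)
    m <- matrix(runif(nf * ng) < 0.4, nf, ng,
                dimnames = list(paste0("f", 1:nf), paste0("g", 1:ng)))
    of <- occurrence_frequency(m)
    for (r in seq_len(nf)) {
      k <- sum(m[r, ])
      expect_equal(of$count[r], k)
      expect_equal(of$percent[r], round(100 * k / ng, 1))
    }
  }
})

test_that("presence matrix construction matches assignments", {
  coh <- get_cohort("clean0")
  pm <- build_presence_matrix(coh$truth[, c("family", "genome_id")],
                              genome_ids = names(coh$genomes))
  expect_identical(unname(pm[rownames(coh$presence), colnames(coh$presence)]),
                   unname(coh$presence))
})
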
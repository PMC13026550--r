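test_that("GC and AT content are exact and complementary", {
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("AUAU"), 0)
  expect_equal(gc_content("GCAU"), 50)
  expect_equal(gc_content("GCAN"), 100 * 2 / 3) # N excluded from denominator
  expect_warning(expect_true(is.na(gc_content("NNN"))), "undefined")

  set.seed(51)
  for (i in 1:20) {
    s <- intronscape:::rand_rna(sample(10:200, 1))
    expect_equal(gc_content(s) + at_content(s), 100)
  }
})

test_that("two-way ANOVA: zero effects give F = 0, and SS match the oracle", {
  # balanced 2x2 with all cell means equal -> F = 0 for both main effects
  y0 <- rep(c(-1, 1), times = 8)
  A0 <- rep(c("a", "b"), each = 8)
  B0 <- rep(rep(c("m", "c"), each = 4), 2)
  r0 <- two_way_anova_tukey(y0, A0, B0)
  expect_equal(r0$anova$F[r0$anova$effect == "A"], 0)
  expect_equal(r0$anova$F[r0$anova$effect == "B"], 0)

  # balanced 2x2 with additive means: SS equal the hand computation
  set.seed(52)
  mu <- c(a.m = 0, b.m = 2, a.c = 1, b.c = 3) # additive: A effect 2, B effect 1
  A <- rep(c("a", "b"), each = 10)
  B <- rep(rep(c("m", "c"), each = 5), 2)
  y <- mu[paste(A, B, sep = ".")] + rnorm(20, sd = 0.5)
  r <- two_way_anova_tukey(y, A, B)
  o <- ss_oracle(y, A, B)
  expect_equal(r$anova$SS[r$anova$effect == "A"], o$A, tolerance = 1e-8)
  expect_equal(r$anova$SS[r$anova$effect == "B"], o$B, tolerance = 1e-8)
  expect_equal(r$anova$SS[r$anova$effect == "A:B"], o$AB, tolerance = 1e-8)
  expect_equal(r$anova$SS[r$anova$effect == "Residuals"], o$E, tolerance = 1e-8)
  # balanced design: the decomposition is exhaustive
  expect_equal(sum(r$anova$SS), sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("Tukey-Kramer pairs match TukeyHSD on balanced cells", {
  set.seed(53)
  y <- rnorm(40)
  A <- rep(c("a", "b"), each = 20)
  B <- rep(c("m", "c"), 20)
  r <- two_way_anova_tukey(y, A, B)
  tk <- TukeyHSD(aov(y ~ interaction(A, B)))[[1]]
  expect_equal(sort(abs(unname(r$tukey$diff))), sort(abs(unname(tk[, "diff"]))),
               tolerance = 1e-8)
  expect_equal(sort(unname(r$tukey$p_adj)), sort(unname(tk[, "p adj"])),
               tolerance = 1e-6)
})

test_that("ANOVA reduces to one-way when a factor has a single level", {
  set.seed(54)
  y <- rnorm(30)
  A <- rep(c("a", "b", "c"), 10)
  B <- rep("mt", 30)
  expect_warning(r <- two_way_anova_tukey(y, A, B), "one-way")
  ref <- anova(lm(y ~ A))
  expect_equal(r$anova$F[1], ref$`F value`[1], tolerance = 1e-10)
  expect_equal(r$anova$p[1], ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(two_way_anova_tukey(y, rep("a", 30), B), "single level")
})

test_that("insertion-site logos hit the exact information bounds", {
  w <- c("AACG", "AACU", "AAGU")
  lp <- insertion_site_logo(w)
  expect_equal(unname(lp$ic[1]), 2) # invariant column: 2 bits
  expect_equal(unname(lp$freq["A", 1]), 1)
  expect_true(all(abs(colSums(lp$freq) - 1) < 1e-12))
  expect_true(all(lp$ic >= 0 & lp$ic <= 2))

  lp2 <- insertion_site_logo(c("A", "C", "G", "U"))
  expect_equal(unname(lp2$ic[1]), 0) # uniform column: 0 bits

  lp3 <- insertion_site_logo(c("AA", "AC"))
  expect_equal(unname(lp3$ic[2]), 1) # (0.5, 0.5, 0, 0) -> 2 - 1 = 1 bit

  # positions are junction-relative for a 41-nt window
  lp4 <- insertion_site_logo(vapply(1:3, function(i) {
    intronscape:::with_seed(i, intronscape:::rand_rna(41))
  }, character(1)))
  expect_equal(range(lp4$positions), c(-20, 20))

  # the small-sample correction only lowers the content
  lp5 <- insertion_site_logo(w, small_sample_correction = TRUE)
  expect_true(all(lp5$ic <= lp$ic + 1e-12))

  expect_error(insertion_site_logo(c("AA", "AAA")), "length")
})

test_that("bubble matrix percentages equal brute-force counting", {
  ftab <- data.frame(
    intron_id = paste0("i", 1:7),
    family = c("f1", "f1", "f1", "f1", "f2", "f2", "f2"),
    branchpoint_A = c(TRUE, TRUE, TRUE, FALSE, TRUE, NA, FALSE),
    ebs2 = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  bm <- bubble_matrix(ftab)
  expect_equal(bm$percent["f1", "branchpoint_A"], 75.0) # 3 of 4
  expect_equal(bm$percent["f1", "ebs2"], 0.0)
  expect_equal(bm$percent["f2", "branchpoint_A"], 50.0) # 1 of 2 assessable
  expect_equal(bm$not_assessable["f2", "branchpoint_A"], 1)
  expect_equal(unname(bm$family_size), c(4L, 3L))

  # 19 of 25 absent -> 76.0% absent (one-decimal rounding parity)
  ft2 <- data.frame(intron_id = paste0("i", 1:25), family = "nad3-216",
                    ia_absent = rep(c(TRUE, FALSE), c(19, 6)))
  expect_equal(bubble_matrix(ft2)$percent["nad3-216", "ia_absent"], 76.0)

  set.seed(55)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    ft <- data.frame(intron_id = seq_len(n),
                     family = sample(c("x", "y", "z"), n, TRUE),
                     feat = sample(c(TRUE, FALSE, NA), n, TRUE))
    bm <- bubble_matrix(ft)
    for (f in rownames(bm$percent)) {
      v <- ft$feat[ft$family == f]
      denom <- sum(!is.na(v))
      exp_pct <- if (denom) round(100 * sum(v, na.rm = TRUE) / denom, 1) else NA_real_
      expect_equal(bm$percent[f, "feat"], exp_pct)
    }
  }
})
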
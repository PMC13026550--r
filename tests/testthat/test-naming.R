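test_that("introns are named gene-site and names parse back", {
  expect_identical(name_intron("cox1", 686), "cox1-686")
  expect_identical(name_intron("infA", 62), "infA-62")
  expect_identical(name_intron("orf185", 47), "orf185-47")
  expect_error(name_intron("cox1", 0), "positive")

  expect_identical(parse_intron_name("nad5-1057"), list(gene = "nad5", site = 1057L))
  expect_identical(parse_intron_name("atp1-1316"), list(gene = "atp1", site = 1316L))
  expect_error(parse_intron_name("abc"), "malformed")
})

test_that("name/parse round trip holds, including hyphenated gene names", {
  set.seed(1)
  genes <- c("cox1", "rnl", "orf185", "ymf-16", "trnK-uuu")
  for (i in 1:50) {
    g <- sample(genes, 1)
    s <- sample.int(5000, 1)
    p <- parse_intron_name(name_intron(g, s))
    expect_identical(p$gene, g)
    expect_identical(p$site, s)
  }
})
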
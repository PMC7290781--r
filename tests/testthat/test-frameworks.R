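test_that("scaffold strings encode cysteine spacings exactly", {
  # 37-mer with cysteines at 9, 10, 12, 32
  s <- paste0(strrep("A", 8), "CC", "A", "C", strrep("A", 19), "C",
              strrep("A", 5))
  sc <- scaffoldString(s)
  expect_equal(sc$scaffold, "x_8CCx_1Cx_19Cx_5")
  expect_equal(sc$length, 37L)
  expect_equal(sc$cys_positions, c(9L, 10L, 12L, 32L))
  expect_equal(scaffoldString(s, style = "display")$scaffold,
               "x_8_CCx_1_Cx_19_Cx_5_")
  expect_equal(scaffoldString("CCCC")$scaffold, "CCCC")
  expect_equal(scaffoldString("AAAAA")$scaffold, "x_5")
})

test_that("scaffold format/parse round trip is the identity", {
  set.seed(41)
  for (i in 1:500) {
    aa <- randAA(sample(5:90, 1))
    sc <- scaffoldString(aa)
    parsed <- parseScaffold(sc$scaffold)
    expect_equal(unname(parsed["length"]), nchar(aa))
    expect_equal(unname(parsed["n_cys"]), sc$n_cys)
  }
})

test_that("scaffold parser reads printed scaffolds and rejects malformed input", {
  expect_equal(parseScaffold("Cx_6Cx_5CCx_4Cx_6Cx_29"),
               c(length = 56L, n_cys = 6L))
  expect_equal(parseScaffold("x_10Cx_5Cx_4CCx_11Cx_9Cx_28Cx_1Cx_5Cx_6Cx_1"),
               c(length = 90L, n_cys = 10L))
  expect_equal(parseScaffold("x_5"), c(length = 5L, n_cys = 0L))
  # display-style trailing underscores parse too
  expect_equal(parseScaffold("x_8_CCx_1_Cx_19_Cx_5_"),
               c(length = 37L, n_cys = 4L))
  expect_error(parseScaffold("x_8CZx_1"), "position")
})

test_that("every packaged scaffold row satisfies the length identity", {
  tab <- referenceScaffolds()
  for (i in seq_len(nrow(tab))) {
    p <- parseScaffold(tab$scaffold[i])
    expect_equal(unname(p["length"]), tab$length[i], info = tab$scaffold[i])
    expect_equal(unname(p["n_cys"]), tab$n_cys[i], info = tab$scaffold[i])
  }
})

test_that("toxin-like filter keeps even cysteine counts of four or more", {
  mk <- function(n) paste0(strrep("AC", n), "A")  # n cysteines
  peps <- vapply(c(3, 4, 5, 6, 12, 0), mk, character(1))
  peps[6] <- "AAAA"
  kept <- toxinLikeFilter(peps)
  nCys <- vapply(strsplit(kept, ""), function(x) sum(x == "C"), integer(1))
  expect_equal(nCys, c(4L, 6L, 12L))
  set.seed(43)
  rand <- vapply(1:200, function(i) randAA(sample(10:60, 1)), character(1))
  kept2 <- toxinLikeFilter(rand)
  oracle <- rand[vapply(strsplit(rand, ""), function(x) {
    n <- sum(x == "C"); n >= 4 && n %% 2 == 0
  }, logical(1))]
  expect_equal(kept2, oracle)
})

test_that("framework classification follows the CC-C-C and C-C-CC-C-C patterns", {
  fw1 <- paste0(strrep("A", 8), "CCAC", strrep("A", 19), "C", strrep("A", 5))
  expect_equal(classifyFramework(fw1), "framework_I")
  ick <- paste0("C", strrep("A", 6), "C", strrep("A", 5), "CC",
                strrep("A", 4), "C", strrep("A", 6), "C", strrep("A", 29))
  expect_equal(classifyFramework(ick), "ICK_VI_VII")
  eight <- paste0(strrep("GC", 8), "G")
  expect_equal(classifyFramework(eight), "other_even")
  expect_equal(classifyFramework("AAA"), "none")
  expect_equal(classifyFramework("CCC"), "none")
})

test_that("framework classification agrees with a regex oracle", {
  fw1Re <- "^[^C]*CC[^C]+C[^C]+C[^C]*$"
  ickRe <- "^[^C]*C[^C]+C[^C]+CC[^C]+C[^C]+C[^C]*$"
  set.seed(47)
  # bias the alphabet so cysteine-rich patterns actually occur
  alpha <- strsplit("CCCCAGLSTV", "")[[1]]
  for (i in 1:2000) {
    aa <- randAA(sample(8:60, 1), alpha)
    got <- classifyFramework(aa)
    nC <- sum(strsplit(aa, "")[[1]] == "C")
    want <- if (grepl(fw1Re, aa)) "framework_I"
      else if (grepl(ickRe, aa)) "ICK_VI_VII"
      else if (nC >= 4 && nC %% 2 == 0) "other_even"
      else "none"
    expect_equal(got, want, info = aa)
  }
})

test_that("disulfide count is half the cysteine count, odd counts rejected", {
  expect_equal(predictDisulfideCount(12L), 6L)
  expect_equal(predictDisulfideCount(0L), 0L)
  expect_equal(predictDisulfideCount(4L), 2L)
  expect_error(predictDisulfideCount(5L), "free cysteine")
})

test_that("cysteine distribution counts and fractions are exact", {
  mk <- function(n) paste0(strrep("AC", n), "A")
  peps <- c(rep(mk(4), 72), rep(mk(6), 20), rep(mk(8), 8))
  dist <- cysteineDistribution(peps)
  expect_equal(dist$fraction[dist$n_cys == 4], 0.72)
  expect_equal(sum(dist$fraction), 1)
  expect_equal(sum(dist$n_peptides), 100L)
  one <- cysteineDistribution(mk(4))
  expect_equal(one$fraction, 1)
  expect_equal(nrow(cysteineDistribution(character(0))), 0L)
})
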
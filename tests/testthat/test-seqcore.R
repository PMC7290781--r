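test_that("six-frame translation handles canonical and reverse frames", {
  fr <- sixFrameTranslate("ATGAAATAA")
  expect_equal(fr[["+1"]], "MK*")
  fr2 <- sixFrameTranslate("TTACATTTT")
  expect_equal(fr2[["-1"]], "KM*")  # revcomp is AAAATGTAA
  expect_error(sixFrameTranslate("ATGZAA"), "position 4")
  # ambiguous codons translate to X
  expect_equal(sixFrameTranslate("ATGNNN")[["+1"]], "MX")
})

test_that("six-frame translation matches a naive codon-loop oracle", {
  set.seed(11)
  for (i in 1:300) {
    nt <- randNT(sample(9:120, 1))
    expect_identical(sixFrameTranslate(nt), oracleSixFrames(nt))
  }
})

test_that("ORF finding reports maximal stop-free stretches with valid coordinates", {
  set.seed(7)
  # one 60-aa stop-free stretch in frame +1
  aa60 <- randAA(60, setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*"))
  nt <- paste0(vapply(strsplit(aa60, "")[[1]], function(a) {
    # encode via the oracle map inverted
    names(.oracleCodonMap)[base::match(a, .oracleCodonMap)]
  }, character(1)), collapse = "")
  nt <- paste0("TAA", nt, "TAA")
  orfs <- findOrfs(nt, minOrfLen = 50)
  inFrame1 <- orfs[orfs$frame == 1, ]
  expect_equal(nrow(inFrame1), 1L)
  expect_equal(inFrame1$length_aa, 60L)
  expect_equal(inFrame1$aa_seq, aa60)
  # below threshold: empty
  expect_equal(nrow(findOrfs(nt, minOrfLen = 80)), 0L)
  expect_error(findOrfs(nt, minOrfLen = 0), "minOrfLen")
})

test_that("ORF set equals a brute-force scan on random sequences", {
  set.seed(19)
  for (i in 1:40) {
    nt <- randNT(sample(60:400, 1))
    minLen <- sample(5:15, 1)
    got <- findOrfs(nt, minOrfLen = minLen)
    want <- oracleOrfs(nt, minLen)
    key <- function(f, s, e) paste(f, s, e, sep = ":")
    expect_setequal(key(got$frame, got$start_nt, got$end_nt),
                    if (nrow(want)) key(want[, 1], want[, 2], want[, 3])
                    else character(0))
    # coordinate/length invariant
    expect_true(all(got$end_nt - got$start_nt + 1L == 3L * got$length_aa))
    expect_false(any(grepl("*", got$aa_seq, fixed = TRUE)))
  }
})

test_that("global alignment is exact on self and matches exhaustive enumeration", {
  al <- globalAlign("PEPTIDE", "PEPTIDE")
  expect_equal(al$aligned_a, "PEPTIDE")
  expect_equal(al$aligned_b, "PEPTIDE")
  expect_equal(al$score, 7)
  expect_error(globalAlign("", "AA"), "non-empty")
  set.seed(23)
  for (i in 1:40) {
    a <- randAA(sample(1:6, 1)); b <- randAA(sample(1:6, 1))
    expect_equal(globalAlign(a, b)$score, oracleAlignScore(a, b),
                 info = paste(a, b))
  }
})

test_that("identity/similarity percentages behave per definition", {
  s <- identitySimilarity("PEPTIDE", "PEPTIDE")
  expect_equal(s$pct_identity, 100)
  expect_equal(s$pct_similarity, 100)
  s2 <- identitySimilarity("AV", "VA")
  expect_equal(s2$pct_identity, 0)
  expect_equal(s2$pct_similarity, 100)  # A and V share a class
  expect_error(identitySimilarity("AAA", "AA"), "equal length")
  # X columns never identical nor similar
  s3 <- identitySimilarity("XA", "XA")
  expect_equal(s3$n_identical, 1L)
  # identity <= similarity on random aligned pairs
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    a <- randAA(n); b <- randAA(n)
    st <- identitySimilarity(a, b)
    expect_lte(st$pct_identity, st$pct_similarity)
    expect_equal(st$pct_identity, 100 * st$n_identical / st$aligned_length)
  }
})

test_that("mature poneratoxin isoforms align gaplessly over 25 residues", {
  seqs <- poneratoxinSequences()
  trimmed <- substr(matureSeq(pc1ePrecursor()), 1, 25)
  al <- globalAlign(trimmed, seqs[["Pc1d_mature"]])
  expect_equal(nchar(al$aligned_a), 25L)
  expect_false(grepl("-", al$aligned_a, fixed = TRUE))
  expect_false(grepl("-", al$aligned_b, fixed = TRUE))
})

test_that("FASTA round trip preserves sequences with 60-column wrapping", {
  tmp <- tempfile(fileext = ".fasta")
  seqs <- c(a = randNT(150), b = randNT(59))
  set.seed(3)
  writeFasta(seqs, tmp)
  lines <- readLines(tmp)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- readContigs(tmp)
  expect_equal(setNames(back$nt_seq, back$contig_id), seqs)
})
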
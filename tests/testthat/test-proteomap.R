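test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_setequal(digestProtein("AKRGR", maxMissed = 0, minLength = 1),
                  c("AK", "R", "GR"))
  expect_equal(digestProtein("AKPR", maxMissed = 0, minLength = 1), "AKPR")
  # missed cleavages are nested supersets
  set.seed(67)
  for (i in 1:20) {
    prot <- randAA(sample(30:120, 1))
    d0 <- digestProtein(prot, 0, minLength = 1)
    d1 <- digestProtein(prot, 1, minLength = 1)
    d2 <- digestProtein(prot, 2, minLength = 1)
    expect_true(all(d0 %in% d1))
    expect_true(all(d1 %in% d2))
    # 0-missed peptides partition the protein
    expect_equal(paste(d0, collapse = ""), prot)
  }
})

test_that("semi-tryptic mode adds one-sided truncations", {
  semi <- digestProtein("MKTAYIAK", maxMissed = 0, mode = "semi",
                        minLength = 3)
  full <- digestProtein("MKTAYIAK", maxMissed = 0, mode = "full",
                        minLength = 3)
  expect_true(all(full %in% semi))
  expect_true("TAYIA" %in% semi)  # suffix-truncated TAYIAK
  expect_true("AYIAK" %in% semi)  # prefix-truncated
  expect_false("AYIA" %in% semi)  # both termini non-tryptic
})

test_that("FDR threshold equals an exhaustive scan over all cut points", {
  # 98 targets above 2 decoys: everything passes at FDR 0
  ev <- data.frame(peptide_seq = sprintf("P%03d", 1:100),
                   score = c(seq(100, 3, length.out = 98), 2, 1),
                   confidence = 99,
                   is_decoy = c(rep(FALSE, 98), TRUE, TRUE))
  acc <- psmFilter(ev)
  expect_equal(nrow(acc), 98L)
  # interleaved decoys: matches brute force
  set.seed(71)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    isD <- runif(n) < 0.3
    sc <- ifelse(isD, rnorm(n, 15, 5), rnorm(n, 40, 10))
    expect_equal(fdrThreshold(sc, isD), oracleFdrThreshold(sc, isD))
    # optimality: FDR below threshold at cut, >= 2% for any lower cut
    thr <- fdrThreshold(sc, isD)
    if (is.finite(thr)) {
      fdrAt <- function(t) {
        a <- sc >= t
        sum(a & isD) / max(1, sum(a & !isD))
      }
      expect_lt(fdrAt(thr), 0.02)
      lower <- sort(unique(sc[sc < thr]), decreasing = TRUE)
      for (t in lower) expect_gte(fdrAt(t), 0.02)
    }
  }
  # all confidences below 95 -> empty
  ev2 <- transform(ev, confidence = 94)
  expect_equal(nrow(psmFilter(ev2)), 0L)
  expect_error(fdrThreshold(c(1, 2), c(TRUE, TRUE)), "no target")
})

test_that("peptide mapping enforces the two-peptide and score rules", {
  orfs <- data.frame(contig_id = c("c1", "c2", "c3"),
                     aa_seq = c("MAAAKTTTTRGGGGK",
                                "MAAAKWWWWWWWWWW",
                                "MLLLLLLNNNNNNDD"),
                     stringsAsFactors = FALSE)
  ev <- data.frame(peptide_seq = c("MAAAK", "TTTTR", "WWWWW"),
                   score = c(50, 40, 30), confidence = 99,
                   is_decoy = FALSE, stringsAsFactors = FALSE)
  res <- mapAndInfer(ev, orfs, minPeptides = 2, minScore = 15)
  expect_setequal(res$contig_id, c("c1", "c2"))  # c3 has no peptide
  c1 <- res[res$contig_id == "c1", ]
  expect_equal(c1$n_peptides, 2L)
  expect_equal(c1$n_unique_peptides, 1L)  # MAAAK is shared with c2
  expect_equal(c1$coverage_pct, 100 * 10 / 15)
  expect_equal(c1$best_score, 50)
  # a protein with a single matching peptide is rejected
  res1p <- mapAndInfer(ev[3, ], orfs, minPeptides = 2)
  expect_equal(nrow(res1p), 0L)
  # peptide shared by identical proteins stays unique to the group
  orfs2 <- rbind(orfs, data.frame(contig_id = "c1b",
                                  aa_seq = orfs$aa_seq[1]))
  res2 <- mapAndInfer(ev, orfs2, minPeptides = 2)
  expect_setequal(res2$contig_id, c("c1", "c1b", "c2"))
  expect_equal(res2$n_unique_peptides[res2$contig_id %in% c("c1", "c1b")],
               c(1L, 1L))
  # coverage of two disjoint 10-mers on a 100-mer is 20 percent
  prot <- randAA(100)
  ev3 <- data.frame(peptide_seq = c(substr(prot, 1, 10),
                                    substr(prot, 51, 60)),
                    score = 50, confidence = 99, is_decoy = FALSE)
  res3 <- mapAndInfer(ev3, data.frame(contig_id = "p", aa_seq = prot),
                      minPeptides = 2)
  expect_equal(res3$coverage_pct, 20)
})

test_that("secretion filter partitions and conserves matches", {
  matches <- data.frame(contig_id = c("a", "b", "c"),
                        n_peptides = 2L, stringsAsFactors = FALSE)
  sig <- data.frame(contig_id = c("a", "b"),
                    signal_end = c(22L, NA), stringsAsFactors = FALSE)
  part <- secretionFilter(matches, sig)
  expect_equal(part$toxins$contig_id, "a")
  expect_setequal(part$excluded$contig_id, c("b", "c"))
  expect_equal(nrow(part$toxins) + nrow(part$excluded), nrow(matches))
  expect_true(all(nzchar(part$excluded$reason)))
})

test_that("protein categorisation counts match a grouping oracle", {
  ann <- data.frame(query_id = sprintf("m%02d", 1:10),
                    description = c("venom toxin precursor",
                                    rep("actin, cytoplasmic", 3),
                                    rep("unknown protein", 6)),
                    stringsAsFactors = FALSE)
  matches <- data.frame(contig_id = ann$query_id)
  tab <- categorizeProteins(matches, ann)
  expect_equal(attr(tab, "toxin_fraction"), 0.1)
  expect_equal(tab$n[tab$category == "structural/motor"], 3L)
  expect_equal(tab$n[tab$category == "uncharacterised"], 6L)
  expect_equal(sum(tab$n), 10L)
  badMap <- data.frame(keyword = "x", category = "not-a-category")
  expect_error(categorizeProteins(matches, ann, categoryMap = badMap),
               "unknown category")
})

test_that("mass-tolerance predicate flags evidence outside instrument bounds", {
  ev <- data.frame(ppm_error = c(10, -60, 0), fragment_error = c(0.05, 0, 0.2))
  expect_equal(withinMassTolerance(ev), c(TRUE, FALSE, FALSE))
})
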
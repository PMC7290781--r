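test_that("peptide names render per the grammar", {
  expect_equal(buildPeptideName("delta", "paraponeritoxin", "Paraponera",
                                "clavata", 1, "e", 2),
               "δ-paraponeritoxin-Pc1e_2")
  expect_equal(buildPeptideName("U", "paraponeritoxin", "Paraponera",
                                "clavata", 1, "a", prefixIndex = 1),
               "U1-paraponeritoxin-Pc1a")
  expect_error(buildPeptideName("", "x", "G", "s", 1, "a"), "non-empty")
})

test_that("protein names render per the grammar", {
  expect_equal(buildProteinName("phospholipase A2", 1, "a", 1,
                                "Paraponera", "clavata"),
               "Phospholipase-A2-1a_1-P-clavata")
  expect_equal(buildProteinName("serine protease", 5, "a", NA,
                                "Paraponera", "clavata"),
               "Serine-protease-5a-P-clavata")
  expect_equal(buildProteinName("U", 1, "a", NA, "Paraponera", "clavata"),
               "U-1a-P-clavata")
})

test_that("name parsing recovers components from both grammars", {
  n <- parseToxinName("δ-paraponeritoxin-Pc1e_2")
  expect_equal(n@kind, "peptide")
  expect_equal(n@prefix, "δ")
  expect_equal(n@toxin_stem, "paraponeritoxin")
  expect_equal(n@family, 1L)
  expect_equal(n@isoform, "e")
  expect_equal(n@nt_variant, 2L)
  m <- parseToxinName("Hyalyronidase-1a_1-P-clavata")
  expect_equal(m@kind, "protein")
  expect_equal(m@generic_name, "Hyalyronidase")  # printed spelling preserved
  expect_equal(m@family, 1L)
  expect_equal(m@isoform, "a")
  expect_equal(m@nt_variant, 1L)
  u <- parseToxinName("U_1_-Paraponeritoxin-Pc1a")
  expect_equal(u@prefix, "U")
  expect_equal(u@prefix_index, 1L)
  expect_error(parseToxinName("not a name"), "cannot parse")
})

test_that("parse-then-render is the identity on fuzzed component tuples", {
  set.seed(53)
  stems <- c("paraponeritoxin", "myrmeciitoxin", "poneritoxin")
  prefixes <- c("alpha", "delta", "omega", "mu", "kappa")
  for (i in 1:200) {
    if (runif(1) < 0.5) {
      nm <- buildPeptideName(sample(prefixes, 1), sample(stems, 1),
                             "Paraponera", "clavata",
                             sample(1:9, 1), sample(letters, 1),
                             if (runif(1) < 0.5) sample(1:8, 1) else NA)
    } else {
      nm <- buildProteinName(
        paste(sample(c("venom", "serine", "acid", "protease", "lipase",
                       "kinase"), sample(1:3, 1)), collapse = " "),
        sample(1:9, 1), sample(letters, 1),
        if (runif(1) < 0.5) sample(1:8, 1) else NA,
        "Paraponera", "clavata")
    }
    expect_identical(renderName(parseToxinName(nm)), nm, info = nm)
  }
})

test_that("every packaged printed name parses and round-trips verbatim", {
  for (nm in referenceToxinNames()) {
    parsed <- parseToxinName(nm)
    expect_identical(renderName(parsed), nm, info = nm)
  }
})

test_that("name assignment orders families, isoforms and variants by abundance", {
  # six identical-protein transcripts -> variants 1..6 by descending TPM
  df <- data.frame(
    contig_id = c("i11", "i2", "i12", "i5", "i8", "i3"),
    protein_seq = "FLPLLILGSLLMTPPVIQAIHDVQRGK",
    group = "Neurotoxin", kind = "peptide",
    tpm = c(39657, 9279, 2414, 797, 2, 0),
    stringsAsFactors = FALSE)
  res <- assignNames(df, "Paraponera", "clavata", "paraponeritoxin",
                     prefixes = c(Neurotoxin = "delta"))
  expect_equal(res$assigned_name[res$old_id == "i11"],
               "δ-paraponeritoxin-Pc1a_1")
  expect_equal(res$variant[order(-df$tpm)], 1:6)
  # two distinct sequences -> isoforms a and b by TPM
  df2 <- data.frame(contig_id = c("x", "y"),
                    protein_seq = c("AAAA", "CCCC"),
                    group = "Phospholipase",
                    tpm = c(5, 50), stringsAsFactors = FALSE)
  res2 <- assignNames(df2, "Paraponera", "clavata")
  expect_equal(res2$isoform[res2$old_id == "y"], "a")
  expect_equal(res2$isoform[res2$old_id == "x"], "b")
  expect_true(all(is.na(res2$variant)))
  # single sequence -> family 1, isoform a, no variant
  df3 <- df2[1, ]
  res3 <- assignNames(df3, "Paraponera", "clavata")
  expect_equal(res3$family, 1L)
  expect_equal(res3$isoform, "a")
  expect_true(is.na(res3$variant))
  # stable under input reordering
  perm <- df[sample(nrow(df)), ]
  resPerm <- assignNames(perm, "Paraponera", "clavata", "paraponeritoxin",
                         prefixes = c(Neurotoxin = "delta"))
  expect_equal(resPerm[order(resPerm$old_id), c("assigned_name", "variant")],
               res[order(res$old_id), c("assigned_name", "variant")],
               ignore_attr = TRUE)
})

test_that("isoform letters extend beyond z", {
  expect_equal(venomtx:::.isoformLetters(28)[27:28], c("aa", "ab"))
})

test_that("Greek prefixes transliterate both ways", {
  expect_equal(greekPrefix("delta"), "δ")
  expect_equal(asciiPrefix("δ"), "delta")
  expect_equal(asciiPrefix("U"), "U")
})
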
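## Seeded synthetic venom-gland dataset generator with recorded ground
## truth: contigs, read counts, annotation, signal annotations and
## target/decoy peptide evidence.

.CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), K = c("AAA", "AAG"),
  M = "ATG", F = c("TTT", "TTC"), P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG",
  Y = c("TAT", "TAC"), V = c("GTT", "GTC", "GTA", "GTG"))

.reverseTranslate <- function(aaSeq) {
  # uniform synonymous codon choice
  paste(vapply(strsplit(aaSeq, "")[[1]], function(a) {
    cods <- .CODONS[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

.randomAA <- function(n, alphabet = setdiff(names(.CODONS), "C")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.randomNt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Realise random peptides from cysteine-scaffold templates
#'
#' For each scaffold template a random sequence is drawn whose cysteine
#' scaffold equals the template exactly: cysteines at the template
#' positions, cysteine-free random residues in the spacers.
#'
#' @param templates character vector of scaffold strings (defaults to
#'   the packaged reference scaffolds).
#' @param seed RNG seed.
#' @return named character vector of peptides.
#' @export
plantFrameworkPeptides <- function(templates = referenceScaffolds()$scaffold,
                                   seed = 1L) {
  set.seed(seed)
  out <- vapply(templates, function(tp) {
    pos <- 1L
    parts <- character(0)
    while (pos <= nchar(tp)) {
      rest <- substr(tp, pos, nchar(tp))
      if (substr(rest, 1L, 1L) == "C") {
        parts <- c(parts, "C"); pos <- pos + 1L
      } else {
        m <- regexpr("^x_([0-9]+)_?", rest)
        if (m < 0L) stop("malformed scaffold template: ", tp)
        k <- as.integer(sub("^x_([0-9]+)_?$", "\\1", regmatches(rest, m)))
        parts <- c(parts, .randomAA(k))
        pos <- pos + attr(m, "match.length")
      }
    }
    paste(parts, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(out) <- sprintf("fw_pep%02d", seq_along(out))
  out
}

#' Default synthetic-dataset configuration
#'
#' @param nContigs total contigs (default 300).
#' @param nToxins planted toxin precursors (default 20).
#' @param nFrameworkPeptides planted cysteine-framework peptides
#'   (default 15).
#' @param variantGroupFrac fraction of toxins duplicated as
#'   identical-protein / distinct-nucleotide variant groups (default
#'   0.05).
#' @param readDepth total simulated reads (default 1e5).
#' @param exprSigma log-normal sigma of the expression law (default 2,
#'   a long-tailed venom-gland-like distribution).
#' @param dominantShare expression-weight share of the dominant toxin
#'   transcript (default 0.04, i.e. roughly 40,000 TPM -- the scale of
#'   a dominant venom-gland toxin).
#' @param detectableFrac fraction of toxin precursors represented in
#'   the peptide evidence (default 0.6).
#' @param decoysPerTarget decoy records per target record (default 0.5).
#' @return configuration list.
#' @export
venomSimConfig <- function(nContigs = 300L, nToxins = 20L,
                           nFrameworkPeptides = 15L,
                           variantGroupFrac = 0.05,
                           readDepth = 1e5, exprSigma = 2,
                           dominantShare = 0.04,
                           detectableFrac = 0.6,
                           decoysPerTarget = 0.5) {
  cfg <- as.list(environment())
  if (cfg$nContigs < cfg$nToxins + cfg$nFrameworkPeptides + 10L)
    stop("nContigs too small for the requested toxin/framework counts")
  if (cfg$variantGroupFrac < 0 || cfg$variantGroupFrac > 1)
    stop("variantGroupFrac must be in [0, 1]")
  if (cfg$readDepth < 1) stop("readDepth must be positive")
  if (cfg$dominantShare <= 0 || cfg$dominantShare >= 1)
    stop("dominantShare must be in (0, 1)")
  cfg
}

.TOXIN_FAMILIES <- data.frame(
  family = c("Neurotoxin", "Phospholipase", "Hyaluronidase", "Protease",
             "Metalloproteinase", "Arginine kinase", "Allergen", "Defensin"),
  description = c("poneratoxin-like neurotoxin precursor",
                  "PREDICTED: phospholipase A2",
                  "PREDICTED: hyaluronidase-like protein",
                  "serine protease venom isoform",
                  "disintegrin and metalloproteinase domain-containing protein",
                  "PREDICTED: arginine kinase isoform X1",
                  "PREDICTED: venom allergen 3-like",
                  "PREDICTED: defensin-2-like"),
  stringsAsFactors = FALSE)

.HOUSEKEEPING <- c("actin, cytoplasmic", "elongation factor 1-alpha",
                   "60S ribosomal protein L4", "heat shock protein 70",
                   "ATP synthase subunit beta", "hypothetical protein",
                   "uncharacterized protein", "histone H2A",
                   "glyceraldehyde-3-phosphate dehydrogenase",
                   "tubulin alpha chain")

#' Generate a complete synthetic venom-gland dataset
#'
#' Emits, under \code{outDir}: \code{contigs.fasta} (precursor ORFs
#' reverse-translated with uniform codon choice and embedded in UTR
#' padding), \code{counts.tsv} (multinomial reads over a long-tailed
#' expression law with a dominant toxin transcript),
#' \code{annotation.tsv} (keyword-bearing descriptions; toxin e-values
#' 1e-20..1e-6, junk above 1e-4 half the time),
#' \code{signal_annotations.tsv}, \code{evidence.tsv} (tryptic peptides
#' of a detectable precursor subset, target scores ~N(40,10), decoys
#' ~N(15,5), truncated at zero) and \code{ground_truth.json}. The same
#' seed reproduces all files byte-identically.
#'
#' @param outDir output directory (created if needed).
#' @param config configuration from [venomSimConfig()].
#' @param seed RNG seed.
#' @return (invisibly) list with \code{files} and \code{ground_truth}.
#' @export
simulateVenomGland <- function(outDir, config = venomSimConfig(), seed = 1L) {
  if (!is.list(config) || is.null(config$nContigs))
    stop("'config' must come from venomSimConfig()")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  nTox <- config$nToxins
  nFw <- config$nFrameworkPeptides
  nVar <- max(if (config$variantGroupFrac > 0) 1L else 0L,
              round(config$nToxins * config$variantGroupFrac))
  nHouse <- config$nContigs - nTox - nFw - nVar

  # --- toxin precursors: signal + propeptide + mature -------------------
  toxFam <- .TOXIN_FAMILIES$family[
    (seq_len(nTox) - 1L) %% nrow(.TOXIN_FAMILIES) + 1L]
  precursors <- lapply(seq_len(nTox), function(i) {
    sig <- paste0("M", .randomAA(sample(19:23, 1L),
                                 alphabet = strsplit("AVLIFMSTG", "")[[1]]))
    pro <- .randomAA(sample(10:14, 1L), alphabet = strsplit("AEVSKPD", "")[[1]])
    mat <- .randomAA(sample(25:40, 1L))
    if (i %% 3L == 0L) mat <- paste0(mat, "GK")  # amidation signal
    list(id = sprintf("TOX%03d", i), signal = sig, propeptide = pro,
         mature = mat, family = toxFam[i])
  })
  # identical-protein variant groups: re-encode the first nVar precursors
  variants <- lapply(seq_len(nVar), function(i) {
    p <- precursors[[i]]
    p$id <- sprintf("%s_v2", p$id)
    p
  })

  fwPeps <- plantFrameworkPeptides(
    referenceScaffolds()$scaffold[seq_len(nFw)], seed = seed + 1L)

  # --- assemble contig nucleotide sequences -----------------------------
  mkContig <- function(aaSeq) {
    # in-frame stop immediately upstream so the coding stretch starts at
    # the first residue of the planted protein
    orf <- paste0("TAA", .reverseTranslate(aaSeq), "TAA")
    paste0(.randomNt(sample(20:60, 1L)), orf, .randomNt(sample(20:60, 1L)))
  }
  ids <- c(vapply(precursors, `[[`, character(1), "id"),
           vapply(variants, `[[`, character(1), "id"),
           names(fwPeps),
           sprintf("HK%04d", seq_len(nHouse)))
  aaFull <- c(vapply(precursors, function(p)
    paste0(p$signal, p$propeptide, p$mature), character(1)),
    vapply(variants, function(p)
      paste0(p$signal, p$propeptide, p$mature), character(1)),
    unname(vapply(names(fwPeps), function(n)
      paste0("M", .randomAA(20, alphabet = strsplit("AVLIFMSTG", "")[[1]]),
             fwPeps[[n]]), character(1))),
    vapply(seq_len(nHouse), function(i) .randomAA(sample(60:200, 1L)),
           character(1)))
  ntSeqs <- vapply(aaFull, mkContig, character(1), USE.NAMES = FALSE)
  names(ntSeqs) <- ids

  # --- expression weights and read counts -------------------------------
  w <- rlnorm(length(ids), meanlog = 0, sdlog = config$exprSigma)
  # dominant toxin transcript gets a fixed share of the expression weight
  w[1] <- config$dominantShare / (1 - config$dominantShare) * sum(w[-1])
  lens <- nchar(ntSeqs)
  counts <- as.integer(rmultinom(1L, size = config$readDepth,
                                 prob = w * lens))

  # --- annotation table -------------------------------------------------
  famDesc <- setNames(.TOXIN_FAMILIES$description, .TOXIN_FAMILIES$family)
  nToxLike <- nTox + nVar + nFw
  desc <- c(vapply(c(precursors, variants), function(p)
    unname(famDesc[p$family]), character(1)),
    rep("cysteine-rich toxin-like peptide", nFw),
    sample(.HOUSEKEEPING, nHouse, replace = TRUE))
  evalue <- numeric(length(ids))
  evalue[seq_len(nToxLike)] <- 10^runif(nToxLike, -20, -6)
  junkHigh <- runif(nHouse) < 0.5
  evalue[nToxLike + seq_len(nHouse)] <-
    ifelse(junkHigh, 10^runif(nHouse, -3.9, 0), 10^runif(nHouse, -30, -5))
  annot <- data.frame(query_id = ids,
                      accession = sprintf("XP_%06d", seq_along(ids)),
                      species = "Synthetica exemplaris",
                      description = desc, e_value = evalue,
                      stringsAsFactors = FALSE)

  # --- signal annotations ----------------------------------------------
  allPrec <- c(precursors, variants)
  sigAnn <- data.frame(
    contig_id = ids,
    signal_end = NA_integer_, propeptide_end = NA_integer_,
    stringsAsFactors = FALSE)
  for (k in seq_along(allPrec)) {
    p <- allPrec[[k]]
    i <- base::match(p$id, ids)
    sigAnn$signal_end[i] <- nchar(p$signal)
    sigAnn$propeptide_end[i] <- nchar(p$signal) + nchar(p$propeptide)
  }
  # framework-peptide contigs carry a minimal signal annotation
  for (n in names(fwPeps)) {
    i <- base::match(n, ids)
    sigAnn$signal_end[i] <- 21L
    sigAnn$propeptide_end[i] <- 21L
  }

  # --- peptide evidence -------------------------------------------------
  nDetect <- max(1L, round(nTox * config$detectableFrac))
  detectable <- vapply(precursors[seq_len(nDetect)], `[[`, character(1), "id")
  evRows <- list()
  for (k in seq_len(nDetect)) {
    p <- precursors[[k]]
    full <- paste0(p$signal, p$propeptide, p$mature)
    peps <- digestProtein(full, maxMissed = 1L, mode = "full", minLength = 7L)
    peps <- peps[nchar(peps) <= 30L]
    if (length(peps) > 6L) peps <- sample(peps, 6L)
    for (pep in peps) {
      evRows[[length(evRows) + 1L]] <- data.frame(
        peptide_seq = pep,
        score = max(0, rnorm(1, 40, 10)),
        confidence = round(runif(1, 96, 99.9), 1),
        is_decoy = FALSE,
        ppm_error = round(runif(1, -30, 30), 2),
        fragment_error = round(runif(1, -0.05, 0.05), 4),
        stringsAsFactors = FALSE)
    }
  }
  nTargets <- length(evRows)
  nDecoys <- max(1L, round(nTargets * config$decoysPerTarget))
  for (d in seq_len(nDecoys)) {
    evRows[[length(evRows) + 1L]] <- data.frame(
      peptide_seq = .randomAA(sample(7:20, 1L),
                              alphabet = names(.CODONS)),
      score = max(0, rnorm(1, 15, 5)),
      confidence = round(runif(1, 50, 99), 1),
      is_decoy = TRUE,
      ppm_error = round(runif(1, -30, 30), 2),
      fragment_error = round(runif(1, -0.05, 0.05), 4),
      stringsAsFactors = FALSE)
  }
  evidence <- do.call(rbind, evRows)

  # --- write files ------------------------------------------------------
  files <- list(
    fasta = file.path(outDir, "contigs.fasta"),
    counts = file.path(outDir, "counts.tsv"),
    annotation = file.path(outDir, "annotation.tsv"),
    signal = file.path(outDir, "signal_annotations.tsv"),
    evidence = file.path(outDir, "evidence.tsv"),
    ground_truth = file.path(outDir, "ground_truth.json"))
  writeFasta(ntSeqs, files$fasta)
  write.table(data.frame(contig_id = ids, read_count = counts,
                         length = lens),
              files$counts, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(annot, files$annotation, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sigAnn, files$signal, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(evidence, files$evidence, sep = "\t", quote = FALSE,
              row.names = FALSE)

  groundTruth <- list(
    seed = seed,
    config = config,
    toxin_precursors = lapply(allPrec, function(p)
      list(id = p$id, signal = p$signal, propeptide = p$propeptide,
           mature = p$mature, family = p$family)),
    framework_peptides = as.list(fwPeps),
    framework_scaffolds = as.list(
      setNames(referenceScaffolds()$scaffold[seq_len(nFw)], names(fwPeps))),
    housekeeping_ids = ids[nToxLike + seq_len(nHouse)],
    expression_weights = as.list(setNames(w, ids)),
    detectable_toxins = detectable,
    n_decoys = nDecoys)
  jsonlite::write_json(groundTruth, files$ground_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(files = files, ground_truth = groundTruth))
}
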
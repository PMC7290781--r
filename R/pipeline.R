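## Pipeline orchestration: contigs -> TPM -> annotation mining ->
## precursors/masses -> scaffolds -> names -> proteome mapping -> reports.

#' Default pipeline thresholds
#'
#' The centralised set of filter thresholds used across the workflow:
#' minimum ORF length 50 aa, e-value cutoff 1e-4, TPM >= 1, target-decoy
#' FDR < 2 percent, confidence >= 95 percent, at least 2 peptides per
#' protein, best score >= 15, up to 3 missed cleavages (semi-tryptic),
#' mass-match tolerance 0.5 Da, top-20 expression report.
#'
#' @return named list of thresholds.
#' @export
pipelineDefaults <- function() {
  list(min_orf_len = 50L, evalue_cutoff = 1e-4, min_tpm = 1,
       max_fdr = 2, min_confidence = 95, min_peptides = 2L,
       min_score = 15, max_missed = 3L, digest_mode = "semi",
       mass_tolerance = 0.5, top_n = 20L,
       genus = "Synthetica", species = "exemplaris", stem = "exemplaritoxin")
}

.readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defs <- pipelineDefaults()
  thr <- utils::modifyList(defs, config[names(config) %in% names(defs)])
  inputs <- config$inputs
  need <- c("fasta", "counts", "annotation", "signal", "evidence")
  if (is.null(inputs) || !all(need %in% names(inputs)))
    stop("config$inputs must name files: ", paste(need, collapse = ", "))
  missing <- !vapply(unlist(inputs[need]), file.exists, logical(1))
  if (any(missing))
    stop("missing input file(s): ",
         paste(unlist(inputs[need])[missing], collapse = ", "))
  list(inputs = inputs, thresholds = thr,
       out_dir = if (!is.null(config$out_dir)) config$out_dir else ".")
}

.orfTableFromContigs <- function(contigs, minOrfLen) {
  # every ORF of every contig (the search database for peptide mapping)
  rows <- lapply(seq_len(nrow(contigs)), function(i)
    findOrfs(contigs$nt_seq[i], minOrfLen = minOrfLen,
             contigId = contigs$contig_id[i]))
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    out <- data.frame(contig_id = character(), frame = integer(),
                      start_nt = integer(), end_nt = integer(),
                      length_aa = integer(), aa_seq = character())
  rownames(out) <- NULL
  out
}

.precursorOrf <- function(contigs, contigId, minOrfLen) {
  # representative precursor ORF: the longest Met-initiated ORF
  i <- base::match(contigId, contigs$contig_id)
  if (is.na(i)) return(NA_character_)
  o <- findOrfs(contigs$nt_seq[i], minOrfLen = minOrfLen,
                requireStart = TRUE, contigId = contigId)
  if (!nrow(o)) return(NA_character_)
  o$aa_seq[which.max(o$length_aa)]
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow on one set of input files and writes
#' six reports plus a run log to the output directory:
#' \code{family_summary.tsv}, \code{top_expressed.tsv},
#' \code{precursor_report.tsv}, \code{scaffold_table.tsv},
#' \code{naming_report.tsv}, \code{protein_report.tsv},
#' \code{run_log.txt}. The run log records every threshold and the MD5
#' digest of every input, so identical inputs and configuration yield
#' byte-identical outputs.
#'
#' @param config configuration list or path to a YAML file. Must contain
#'   \code{inputs} (named paths \code{fasta}, \code{counts},
#'   \code{annotation}, \code{signal}, \code{evidence}) and may override
#'   any threshold in [pipelineDefaults()] plus \code{out_dir}.
#' @return (invisibly) list of the in-memory report tables.
#' @export
runPipeline <- function(config) {
  cfg <- .readPipelineConfig(config)
  thr <- cfg$thresholds
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  contigs <- readContigs(cfg$inputs$fasta, cfg$inputs$counts)
  expr <- expressionTable(contigs)
  annot <- readAnnotationTsv(cfg$inputs$annotation)
  sigAnn <- read.delim(cfg$inputs$signal, stringsAsFactors = FALSE)
  evidence <- read.delim(cfg$inputs$evidence, stringsAsFactors = FALSE)

  # annotation mining
  hits <- evalueFilter(annot, thr$evalue_cutoff)
  assign <- classifyByKeywords(hits)
  exprKept <- filterMinTPM(expr, thr$min_tpm)
  famSum <- familySummary(assign, exprKept)
  top <- topToxinTable(assign, exprKept, annot, thr$top_n)

  # ORFs and precursors
  orfs <- .orfTableFromContigs(contigs, thr$min_orf_len)
  sigIds <- sigAnn$contig_id[!is.na(sigAnn$signal_end)]
  secreted <- list()
  for (id in intersect(sigIds, contigs$contig_id)) {
    aa <- .precursorOrf(contigs, id, thr$min_orf_len)
    if (is.na(aa)) next
    k <- base::match(id, sigAnn$contig_id)
    if (sigAnn$signal_end[k] >= nchar(aa)) next
    p <- try(parsePrecursor(aa, signalEnd = sigAnn$signal_end[k],
                            propeptideEnd = sigAnn$propeptide_end[k],
                            orfId = id), silent = TRUE)
    if (!inherits(p, "try-error")) secreted[[length(secreted) + 1L]] <- p
  }
  precReport <- if (length(secreted))
    processingReport(secreted, tolerance = thr$mass_tolerance)
  else data.frame()

  # cysteine scaffolds of secreted mature peptides
  matures <- setNames(vapply(secreted, matureSeq, character(1)),
                      vapply(secreted, function(p) p@orf_id, character(1)))
  toxinLike <- toxinLikeFilter(matures)
  scafTab <- if (length(toxinLike))
    scaffoldTable(toxinLike, tpm = setNames(expr$tpm, expr$contig_id))
  else data.frame()

  # naming of mined toxins (representative protein = longest ORF)
  repOrfs <- orfs[order(-orfs$length_aa), , drop = FALSE]
  repOrfs <- repOrfs[!duplicated(repOrfs$contig_id), , drop = FALSE]
  oi <- base::match(assign$query_id, repOrfs$contig_id)
  ei <- base::match(assign$query_id, expr$contig_id)
  nameIn <- data.frame(contig_id = assign$query_id,
                       protein_seq = repOrfs$aa_seq[oi],
                       group = assign$family,
                       tpm = expr$tpm[ei],
                       stringsAsFactors = FALSE)
  nameIn <- nameIn[!is.na(nameIn$protein_seq) & !is.na(nameIn$tpm), ,
                   drop = FALSE]
  naming <- if (nrow(nameIn))
    assignNames(nameIn, thr$genus, thr$species, thr$stem)
  else data.frame()

  # proteome mapping
  accepted <- psmFilter(evidence, thr$min_confidence, thr$max_fdr)
  matches <- mapAndInfer(accepted, orfs, thr$min_peptides, thr$min_score)
  secretion <- secretionFilter(matches, sigAnn)
  categories <- categorizeProteins(matches, annot)
  protReport <- secretion$toxins
  if (nrow(protReport)) {
    ai <- base::match(protReport$contig_id, annot$query_id)
    ei2 <- base::match(protReport$contig_id, expr$contig_id)
    protReport$description <- annot$description[ai]
    protReport$tpm <- expr$tpm[ei2]
  }

  reports <- list(family_summary = famSum, top_expressed = top,
                  precursor_report = precReport, scaffold_table = scafTab,
                  naming_report = naming, protein_report = protReport,
                  excluded_matches = secretion$excluded,
                  category_summary = categories,
                  score_threshold = attr(accepted, "score_threshold"))

  wr <- function(df, name) {
    write.table(df, file.path(cfg$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wr(famSum, "family_summary.tsv")
  wr(top, "top_expressed.tsv")
  wr(precReport, "precursor_report.tsv")
  wr(scafTab, "scaffold_table.tsv")
  wr(naming, "naming_report.tsv")
  wr(protReport, "protein_report.tsv")

  log <- c("venomtx pipeline run",
           "", "[thresholds]",
           sprintf("%s = %s", names(thr), vapply(thr, format, character(1))),
           "", "[input md5]",
           sprintf("%s = %s", unlist(cfg$inputs),
                   vapply(unlist(cfg$inputs),
                          function(f) unname(md5sum(f)), character(1))),
           "", sprintf("psm score threshold = %s",
                       format(reports$score_threshold)))
  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  invisible(reports)
}
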
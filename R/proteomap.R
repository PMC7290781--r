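## Proteome-to-transcriptome evidence mapping: in-silico tryptic
## digestion, PSM/protein-level filtering, secretion filtering and
## category summaries.

#' In-silico tryptic digestion
#'
#' Trypsin rule: cleave after K or R except when the next residue is P.
#' Full mode emits every peptide spanning at most \code{maxMissed}
#' internal cleavage sites; semi mode additionally emits every prefix
#' and suffix truncation of each fully-tryptic peptide (one non-tryptic
#' terminus).
#'
#' @param protein protein string.
#' @param maxMissed maximum missed cleavages (default 3).
#' @param mode \code{"full"} or \code{"semi"}.
#' @param minLength minimum peptide length reported (default 5).
#' @return character vector of peptides in N-to-C order; duplicate
#'   sequences arising from repeated tryptic fragments are retained, so
#'   the zero-missed peptides always concatenate back to the protein.
#' @export
digestProtein <- function(protein, maxMissed = 3L, mode = c("full", "semi"),
                          minLength = 5L) {
  mode <- match.arg(mode)
  if (!nzchar(protein)) stop("'protein' must be non-empty")
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  # cleavage points: after position i
  cut <- which(chars %in% c("K", "R"))
  cut <- cut[cut < n & chars[cut + 1L] != "P"]
  bounds <- c(0L, cut, n)  # peptide i spans bounds[i]+1 .. bounds[i+1]
  nFrag <- length(bounds) - 1L
  peps <- character(0)
  for (i in seq_len(nFrag)) {
    for (j in i:min(nFrag, i + maxMissed)) {
      peps <- c(peps, substr(protein, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  if (mode == "semi") {
    semi <- unlist(lapply(peps, function(p) {
      L <- nchar(p)
      if (L < 2L) return(character(0))
      c(substring(p, 1L, seq_len(L - 1L)),       # prefixes
        substring(p, seq(2L, L), L))             # suffixes
    }))
    peps <- c(peps, semi)
  }
  peps[nchar(peps) >= minLength]
}

#' Target-decoy FDR score threshold
#'
#' Scans all cut points on the score axis (descending) and returns the
#' lowest score threshold at which the estimated FDR among accepted
#' records is below \code{maxFdr} percent. The default estimate is the
#' simple decoy/target count ratio; \code{"double_decoy"} uses
#' 2*decoys/total.
#'
#' @param scores numeric scores (larger = better).
#' @param isDecoy logical decoy flags.
#' @param maxFdr maximum FDR in percent (default 2).
#' @param method \code{"decoy_ratio"} or \code{"double_decoy"}.
#' @return the score threshold, or \code{Inf} when no cut point
#'   satisfies the bound.
#' @export
fdrThreshold <- function(scores, isDecoy, maxFdr = 2,
                         method = c("decoy_ratio", "double_decoy")) {
  method <- match.arg(method)
  if (!any(!isDecoy)) stop("no target records")
  ord <- order(-scores)
  s <- scores[ord]; d <- isDecoy[ord]
  cumD <- cumsum(d); cumT <- cumsum(!d)
  fdr <- if (method == "decoy_ratio") ifelse(cumT == 0, Inf, cumD / cumT)
         else 2 * cumD / (cumD + cumT)
  # candidate thresholds: last record of each tied-score block
  lastOfBlock <- c(s[-1] != s[-length(s)], TRUE)
  ok <- which(lastOfBlock & fdr < maxFdr / 100)
  if (!length(ok)) return(Inf)
  s[max(ok)]
}

#' Filter peptide-spectrum evidence on confidence and target-decoy FDR
#'
#' Applies, conjunctively, a minimum confidence and the score threshold
#' from [fdrThreshold()]. Decoy records are used to set the threshold
#' and then removed.
#'
#' @param evidence data.frame with \code{peptide_seq}, \code{score},
#'   \code{confidence}, \code{is_decoy}.
#' @param minConfidence minimum confidence in percent (default 95).
#' @param maxFdr maximum FDR in percent (default 2).
#' @param method FDR estimate, see [fdrThreshold()].
#' @return accepted target records, with the chosen score threshold in
#'   \code{attr(, "score_threshold")}.
#' @export
psmFilter <- function(evidence, minConfidence = 95, maxFdr = 2,
                      method = c("decoy_ratio", "double_decoy")) {
  need <- c("peptide_seq", "score", "confidence", "is_decoy")
  stopifnot(all(need %in% names(evidence)))
  thr <- fdrThreshold(evidence$score, evidence$is_decoy, maxFdr, method)
  keep <- !evidence$is_decoy & evidence$score >= thr &
    evidence$confidence >= minConfidence
  out <- evidence[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "score_threshold") <- thr
  out
}

#' Map filtered peptide evidence onto translated ORFs
#'
#' Peptides are located by exact substring match in the ORF
#' translations (Ile/Leu kept distinct). Identical protein sequences
#' are collapsed into one group, so variant transcripts of the same
#' protein share peptide counts; a peptide is unique when it matches
#' exactly one such group. Proteins are kept when they have at least
#' \code{minPeptides} matching peptides and a best score of at least
#' \code{minScore}. Coverage is the union of matched residues over the
#' protein length.
#'
#' @param evidence accepted evidence (e.g. from [psmFilter()]).
#' @param orfs data.frame with \code{contig_id}, \code{aa_seq}.
#' @param minPeptides minimum matching peptides (default 2).
#' @param minScore minimum best score (default 15).
#' @return data.frame with one row per contig: \code{contig_id},
#'   \code{n_peptides}, \code{n_unique_peptides}, \code{coverage_pct},
#'   \code{best_score}.
#' @export
mapAndInfer <- function(evidence, orfs, minPeptides = 2L, minScore = 15) {
  stopifnot(all(c("contig_id", "aa_seq") %in% names(orfs)))
  empty <- data.frame(contig_id = character(), n_peptides = integer(),
                      n_unique_peptides = integer(),
                      coverage_pct = numeric(), best_score = numeric())
  if (!nrow(evidence) || !nrow(orfs)) return(empty)
  peps <- unique(evidence$peptide_seq)
  pepScore <- tapply(evidence$score, evidence$peptide_seq, max)
  # collapse identical protein sequences across the ORF database
  uniqSeqs <- unique(orfs$aa_seq)
  grpOf <- base::match(orfs$aa_seq, uniqSeqs)
  hits <- lapply(peps, function(p) {
    which(vapply(uniqSeqs, function(s)
      grepl(p, s, fixed = TRUE), logical(1), USE.NAMES = FALSE))
  })
  nGroups <- lengths(hits)  # distinct proteins matched by each peptide
  coverageOf <- function(g, pIdx) {
    s <- uniqSeqs[g]
    covered <- rep(FALSE, nchar(s))
    for (k in pIdx) {
      p <- peps[k]
      st <- gregexpr(p, s, fixed = TRUE)[[1]]
      for (a in st) covered[a:(a + nchar(p) - 1L)] <- TRUE
    }
    100 * sum(covered) / nchar(s)
  }
  pepsOfGroup <- lapply(seq_along(uniqSeqs), function(g)
    which(vapply(hits, function(h) g %in% h, logical(1))))
  # aggregate per contig over all its ORFs
  rows <- lapply(split(seq_len(nrow(orfs)), orfs$contig_id), function(ridx) {
    gset <- unique(grpOf[ridx])
    pIdx <- unique(unlist(pepsOfGroup[gset]))
    if (!length(pIdx)) return(NULL)
    cov <- max(vapply(gset, function(g) {
      pg <- intersect(pepsOfGroup[[g]], pIdx)
      if (!length(pg)) 0 else coverageOf(g, pg)
    }, numeric(1)))
    data.frame(contig_id = orfs$contig_id[ridx[1]],
               n_peptides = length(pIdx),
               n_unique_peptides = sum(nGroups[pIdx] == 1L),
               coverage_pct = cov,
               best_score = max(pepScore[peps[pIdx]]),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  out <- rows[rows$n_peptides >= minPeptides &
                rows$best_score >= minScore, , drop = FALSE]
  out <- out[order(base::match(out$contig_id, orfs$contig_id)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition protein matches into secreted-toxin candidates and excluded
#'
#' Matches without a predicted signal peptide are excluded from the
#' toxin candidate list (they are presumed non-secreted) but retained
#' with a reason; the two partitions always sum to the input.
#'
#' @param matches data.frame with \code{contig_id}.
#' @param signalAnnotations data.frame with \code{contig_id},
#'   \code{signal_end} (NA when no signal peptide was predicted).
#' @return list with \code{toxins} and \code{excluded} (the latter with
#'   a \code{reason} column).
#' @export
secretionFilter <- function(matches, signalAnnotations) {
  i <- base::match(matches$contig_id, signalAnnotations$contig_id)
  se <- signalAnnotations$signal_end[i]
  hasSig <- !is.na(se) & se > 0
  toxins <- matches[hasSig, , drop = FALSE]
  toxins$has_signal <- rep(TRUE, nrow(toxins))
  excluded <- matches[!hasSig, , drop = FALSE]
  excluded$has_signal <- rep(FALSE, nrow(excluded))
  excluded$reason <- ifelse(is.na(i[!hasSig]), "no signal-peptide annotation",
                            "no predicted signal peptide")
  rownames(toxins) <- rownames(excluded) <- NULL
  list(toxins = toxins, excluded = excluded)
}

#' Default protein functional categories
#'
#' The eleven functional categories used to summarise venom-proteome
#' matches.
#'
#' @return character vector of category names.
#' @export
defaultProteinCategories <- function() {
  c("uncharacterised", "structural/motor", "cellular", "toxin-like",
    "metabolic", "regulation", "chaperone", "oxidoreductase", "kinase",
    "transport", "miscellaneous")
}

# keyword -> functional category, mirroring defaultProteinCategories()
defaultCategoryKeywords <- function() {
  data.frame(
    keyword = c("actin", "myosin", "tubulin", "ribosomal", "histone",
                "toxin", "phospholipase", "hyaluronidase", "protease",
                "peptidase", "allergen", "dehydrogenase", "oxidase",
                "reductase", "kinase", "chaperone", "heat shock",
                "transcription", "regulat", "metabol", "synthase",
                "transport", "carrier"),
    category = c("structural/motor", "structural/motor", "structural/motor",
                 "cellular", "cellular", "toxin-like", "toxin-like",
                 "toxin-like", "toxin-like", "toxin-like", "toxin-like",
                 "oxidoreductase", "oxidoreductase", "oxidoreductase",
                 "kinase", "chaperone", "chaperone", "regulation",
                 "regulation", "metabolic", "metabolic", "transport",
                 "transport"),
    stringsAsFactors = FALSE)
}

#' Categorise protein matches into functional categories
#'
#' Each match is placed into one category by keyword search of its
#' annotation description (longest keyword wins); matches with no
#' annotation or no keyword hit become "uncharacterised". The toxin-like
#' fraction is attached as an attribute.
#'
#' @param matches data.frame with \code{contig_id}.
#' @param annotation annotation data.frame with \code{query_id},
#'   \code{description}.
#' @param categoryMap data.frame with \code{keyword}, \code{category}
#'   (default [defaultCategoryKeywords()]).
#' @param categories allowed category vocabulary.
#' @return data.frame with \code{category}, \code{n}, \code{fraction};
#'   \code{attr(, "toxin_fraction")} gives the toxin-like share, and
#'   \code{attr(, "per_match")} the per-contig category assignment.
#' @export
categorizeProteins <- function(matches, annotation,
                               categoryMap = defaultCategoryKeywords(),
                               categories = defaultProteinCategories()) {
  if (!all(categoryMap$category %in% categories))
    stop("unknown category in 'categoryMap': ",
         paste(setdiff(categoryMap$category, categories), collapse = ", "))
  i <- base::match(matches$contig_id, annotation$query_id)
  desc <- tolower(annotation$description[i])
  km <- categoryMap[order(-nchar(categoryMap$keyword)), , drop = FALSE]
  cat <- rep("uncharacterised", nrow(matches))
  assigned <- rep(FALSE, nrow(matches))
  for (k in seq_len(nrow(km))) {
    hit <- !is.na(desc) & grepl(km$keyword[k], desc, fixed = TRUE) & !assigned
    cat[hit] <- km$category[k]
    assigned[hit] <- TRUE
  }
  tab <- table(factor(cat, levels = categories))
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    fraction = as.numeric(tab) / max(1L, nrow(matches)),
                    stringsAsFactors = FALSE)
  attr(out, "toxin_fraction") <- out$fraction[out$category == "toxin-like"]
  attr(out, "per_match") <- data.frame(contig_id = matches$contig_id,
                                       category = cat,
                                       stringsAsFactors = FALSE)
  out
}

#' Validate evidence mass-error tolerances
#'
#' Predicate flags for the instrument tolerances used when the evidence
#' was generated: parent-ion error within \code{ppmTol} ppm and fragment
#' error within \code{fragTol} Da. These are validity checks on the
#' evidence records, not spectrum matching.
#'
#' @param evidence data.frame with \code{ppm_error},
#'   \code{fragment_error}.
#' @param ppmTol parent tolerance in ppm (default 50).
#' @param fragTol fragment tolerance in Da (default 0.1).
#' @return logical vector, TRUE when the record is within tolerance.
#' @export
withinMassTolerance <- function(evidence, ppmTol = 50, fragTol = 0.1) {
  abs(evidence$ppm_error) <= ppmTol & abs(evidence$fragment_error) <= fragTol
}
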
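## Keyword-driven toxin mining of homology-annotation tables and
## family summarisation.

#' Read a homology-annotation table
#'
#' @param path TSV with columns \code{query_id}, \code{accession},
#'   \code{species}, \code{description}, \code{e_value}.
#' @return data.frame of annotation hits.
#' @export
readAnnotationTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "accession", "species", "description", "e_value")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (any(df$e_value < 0)) stop("e-values must be non-negative")
  df
}

#' Filter annotation hits on an e-value cutoff
#'
#' Keeps hits with \code{e_value} strictly below the cutoff; a hit
#' exactly at the cutoff is excluded.
#'
#' @param hits annotation data.frame with an \code{e_value} column.
#' @param cutoff e-value cutoff (default 1e-4).
#' @return subset of \code{hits}.
#' @export
evalueFilter <- function(hits, cutoff = 1e-4) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("'cutoff' must be > 0")
  out <- hits[hits$e_value < cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default toxin-family keyword map
#'
#' Maps description keywords (case-insensitive substrings) to 17 toxin
#' families commonly mined from venom-gland annotation output. The map
#' is a starting point and fully user-configurable; a production run
#' would extend it to the full keyword list of the study at hand.
#'
#' @return data.frame with \code{keyword}, \code{family}.
#' @export
defaultKeywordMap <- function() {
  kw <- list(
    Protease = c("serine protease", "serine proteinase", "aspartic protease",
                 "cathepsin", "protease", "proteinase"),
    Neurotoxin = c("poneratoxin", "neurotoxin", "paraponeritoxin"),
    Phospholipase = c("phospholipase"),
    Hyaluronidase = c("hyaluronidase"),
    Metalloproteinase = c("metalloproteinase", "metalloprotease",
                          "disintegrin"),
    `Arginine kinase` = c("arginine kinase"),
    Allergen = c("allergen", "icarapin", "pilosulin"),
    Defensin = c("defensin"),
    `Esterase/lipase` = c("lipase", "esterase"),
    Phosphatase = c("acid phosphatase", "alkaline phosphatase",
                    "phosphatase"),
    Peptidase = c("dipeptidyl peptidase", "carboxypeptidase", "neprilysin",
                  "peptidase"),
    `Protease inhibitor` = c("protease inhibitor", "serpin", "alaserpin"),
    Kinase = c("kinase"),
    `Lectin-like` = c("lectin"),
    `Toxin-like` = c("conotoxin", "agatoxin", "latrotoxin", "toxin-like"),
    Antimicrobial = c("antimicrobial", "antibacterial"),
    `Other toxin` = c("toxin", "venom")
  )
  data.frame(keyword = unlist(kw, use.names = FALSE),
             family = rep(names(kw), lengths(kw)),
             stringsAsFactors = FALSE)
}

#' Classify annotation hits into toxin families by keyword
#'
#' Case-insensitive substring search of each keyword in the hit
#' description; the longest matching keyword wins (alphabetical family
#' tie-break), so "serine protease" beats "protease". Hits matching no
#' keyword are left unassigned (dropped from the output).
#'
#' @param hits annotation data.frame with \code{query_id} and
#'   \code{description}.
#' @param keywordMap data.frame with \code{keyword}, \code{family}
#'   (default [defaultKeywordMap()]).
#' @param wordBoundary require keyword matches at word boundaries.
#' @return data.frame with \code{query_id}, \code{family},
#'   \code{matched_keyword}.
#' @export
classifyByKeywords <- function(hits, keywordMap = defaultKeywordMap(),
                               wordBoundary = FALSE) {
  if (!nrow(keywordMap)) stop("'keywordMap' must be non-empty")
  km <- keywordMap[order(-nchar(keywordMap$keyword), keywordMap$family), ,
                   drop = FALSE]
  desc <- tolower(hits$description)
  fam <- character(nrow(hits))
  mk <- character(nrow(hits))
  for (i in seq_len(nrow(km))) {
    k <- tolower(km$keyword[i])
    hit <- if (wordBoundary)
      grepl(paste0("\\b", k, "\\b"), desc)
    else grepl(k, desc, fixed = TRUE)
    take <- hit & fam == ""
    fam[take] <- km$family[i]
    mk[take] <- km$keyword[i]
  }
  keep <- fam != ""
  data.frame(query_id = hits$query_id[keep], family = fam[keep],
             matched_keyword = mk[keep], stringsAsFactors = FALSE)
}

#' Per-family transcript counts and TPM summary
#'
#' One row per family, ordered by transcript count descending (ties by
#' family name). Queries missing from the expression table are counted
#' but excluded from the TPM statistics and reported in
#' \code{n_missing_expression}.
#'
#' @param assignments data.frame from [classifyByKeywords()].
#' @param expression data.frame with \code{contig_id}, \code{tpm}.
#' @return data.frame with \code{family}, \code{n_transcripts},
#'   \code{tpm_min}, \code{tpm_median}, \code{tpm_max},
#'   \code{n_missing_expression}.
#' @export
familySummary <- function(assignments, expression) {
  if (!nrow(assignments))
    return(data.frame(family = character(), n_transcripts = integer(),
                      tpm_min = numeric(), tpm_median = numeric(),
                      tpm_max = numeric(),
                      n_missing_expression = integer()))
  i <- base::match(assignments$query_id, expression$contig_id)
  tpm <- expression$tpm[i]
  rows <- lapply(split(seq_len(nrow(assignments)), assignments$family),
                 function(idx) {
    v <- tpm[idx]
    miss <- sum(is.na(v))
    v <- v[!is.na(v)]
    data.frame(family = assignments$family[idx[1]],
               n_transcripts = length(idx),
               tpm_min = if (length(v)) min(v) else NA_real_,
               tpm_median = if (length(v)) median(v) else NA_real_,
               tpm_max = if (length(v)) max(v) else NA_real_,
               n_missing_expression = miss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_transcripts, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top expressed toxin transcripts with their annotation
#'
#' Joins family assignments with expression and annotation and reports
#' the \code{n} most expressed toxin transcripts.
#'
#' @param assignments data.frame from [classifyByKeywords()].
#' @param expression data.frame with \code{contig_id}, \code{tpm}.
#' @param annotation annotation data.frame (for description/accession).
#' @param n number of rows (default 20).
#' @return data.frame with \code{contig_id}, \code{description},
#'   \code{accession}, \code{species}, \code{tpm}, \code{family}.
#' @export
topToxinTable <- function(assignments, expression, annotation, n = 20L) {
  ie <- base::match(assignments$query_id, expression$contig_id)
  ia <- base::match(assignments$query_id, annotation$query_id)
  df <- data.frame(contig_id = assignments$query_id,
                   description = annotation$description[ia],
                   accession = annotation$accession[ia],
                   species = annotation$species[ia],
                   tpm = expression$tpm[ie],
                   family = assignments$family,
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$tpm), , drop = FALSE]
  topExpressed(df, n)
}
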
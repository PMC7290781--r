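## Sequence primitives: six-frame translation, ORF extraction, pairwise
## global alignment and identity/similarity statistics.

FRAME_LABELS <- c("+1", "+2", "+3", "-1", "-2", "-3")

.checkNucleotides <- function(ntSeq) {
  if (!is.character(ntSeq) || length(ntSeq) != 1L || !nzchar(ntSeq))
    stop("'ntSeq' must be a single non-empty string")
  bad <- regexpr("[^ACGTUNRYSWKMBDHV]", toupper(ntSeq))
  if (bad > 0L)
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 substr(ntSeq, bad, bad), bad))
  invisible(toupper(ntSeq))
}

# standard genetic code (table 1) as a codon lookup; any codon with a
# non-ACGT letter translates to X
.codonTable <- local({
  tab <- NULL
  function() {
    if (is.null(tab))
      tab <<- setNames(as.character(Biostrings::GENETIC_CODE),
                       names(Biostrings::GENETIC_CODE))
    tab
  }
})

.translateFrame <- function(ntChars, offset) {
  n <- length(ntChars) - offset
  n <- n - n %% 3L
  if (n < 3L) return("")
  idx <- offset + seq_len(n)
  m <- matrix(ntChars[idx], nrow = 3L)
  codons <- paste0(m[1, ], m[2, ], m[3, ])
  aa <- .codonTable()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.revcompChars <- function(ntChars) {
  rev(chartr("ACGTUNRYSWKMBDHV", "TGCAANYRSWMKVHDB",
             ntChars))
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames \code{+1..+3} translate the forward strand at offsets 0..2;
#' frames \code{-1..-3} translate the reverse complement at offsets 0..2.
#' Stop codons are rendered as \code{*}, ambiguous codons (any codon
#' containing a non-ACGT letter, including N) as \code{X}, and trailing
#' partial codons are dropped. The standard codon table is used.
#'
#' @param ntSeq single nucleotide string (IUPAC letters; T or U).
#' @return named character vector of six protein strings, names
#'   \code{"+1".."-3"}.
#' @examples
#' sixFrameTranslate("ATGAAATAA")[["+1"]]  # "MK*"
#' @export
sixFrameTranslate <- function(ntSeq) {
  ntSeq <- .checkNucleotides(ntSeq)
  fwd <- strsplit(chartr("U", "T", ntSeq), "")[[1]]
  rev <- .revcompChars(fwd)
  out <- c(vapply(0:2, function(o) .translateFrame(fwd, o), character(1)),
           vapply(0:2, function(o) .translateFrame(rev, o), character(1)))
  setNames(out, FRAME_LABELS)
}

#' Find open reading frames in all six frames
#'
#' Reports every maximal stop-free stretch of at least \code{minOrfLen}
#' residues in any frame. Coordinates are 1-based inclusive on the
#' forward strand regardless of frame. ORFs are not required to start
#' with Met unless \code{requireStart = TRUE}, in which case each stretch
#' is trimmed to its first Met before the length test.
#'
#' @param ntSeq nucleotide string.
#' @param minOrfLen minimum ORF length in amino acids (default 50).
#' @param requireStart require a leading methionine (default FALSE).
#' @param contigId id recorded in the output (default "seq").
#' @return data.frame with columns \code{contig_id}, \code{frame},
#'   \code{start_nt}, \code{end_nt}, \code{length_aa}, \code{aa_seq}.
#' @export
findOrfs <- function(ntSeq, minOrfLen = 50L, requireStart = FALSE,
                     contigId = "seq") {
  if (!is.numeric(minOrfLen) || minOrfLen < 1L)
    stop("'minOrfLen' must be >= 1")
  ntSeq <- .checkNucleotides(ntSeq)
  L <- nchar(ntSeq)
  trans <- sixFrameTranslate(ntSeq)
  res <- list()
  for (k in seq_along(trans)) {
    aa <- trans[[k]]
    if (!nzchar(aa)) next
    frame <- c(1L, 2L, 3L, -1L, -2L, -3L)[k]
    offset <- abs(frame) - 1L
    # maximal stop-free runs
    runs <- gregexpr("[^*]+", aa)[[1]]
    if (runs[1] == -1L) next
    for (i in seq_along(runs)) {
      p <- runs[i]
      len <- attr(runs, "match.length")[i]
      seg <- substr(aa, p, p + len - 1L)
      if (requireStart) {
        m <- regexpr("M", seg, fixed = TRUE)
        if (m < 0L) next
        p <- p + m - 1L
        len <- len - m + 1L
        seg <- substr(seg, m, nchar(seg))
      }
      if (len < minOrfLen) next
      # frame-local nt coordinates (on strand translated)
      sLoc <- offset + 3L * (p - 1L) + 1L
      eLoc <- offset + 3L * (p + len - 1L)
      if (frame > 0L) {
        startNt <- sLoc; endNt <- eLoc
      } else {
        startNt <- L - eLoc + 1L; endNt <- L - sLoc + 1L
      }
      res[[length(res) + 1L]] <- data.frame(
        contig_id = contigId, frame = frame, start_nt = startNt,
        end_nt = endNt, length_aa = len, aa_seq = seg,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(contig_id = character(), frame = integer(),
                      start_nt = integer(), end_nt = integer(),
                      length_aa = integer(), aa_seq = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Default conservative-substitution classes
#'
#' Residue groups counted as conservative substitutions when computing
#' percentage similarity: aliphatic/hydrophobic (AVLIM), aromatic (FWY),
#' hydroxyl (ST), basic (KR), acidic (DE), amide (NQ), and H, C, G, P as
#' singletons. A and V share a class, so an A-to-V substitution is
#' conservative.
#'
#' @return character vector of residue classes.
#' @export
defaultSimilarityClasses <- function() {
  c("AVLIM", "FWY", "ST", "KR", "DE", "NQ", "H", "C", "G", "P")
}

.classIndex <- function(classes) {
  idx <- integer(0)
  for (i in seq_along(classes)) {
    letters <- strsplit(classes[i], "")[[1]]
    idx[letters] <- i
  }
  idx
}

#' Deterministic Needleman-Wunsch global alignment
#'
#' Global alignment of two protein strings with linear gap penalty.
#' Default scoring: match +1; mismatch 0 when the two residues share a
#' similarity class, -1 otherwise; gap -2. Traceback ties are broken by
#' preferring the diagonal move, then the vertical (gap in \code{b}),
#' then the horizontal, making the alignment deterministic.
#'
#' @param a,b protein strings.
#' @param match,mismatchClass,mismatch,gap scoring parameters.
#' @param classes similarity classes (see [defaultSimilarityClasses()]).
#' @return list with \code{aligned_a}, \code{aligned_b} (equal-length,
#'   gap symbol \code{-}) and \code{score}.
#' @export
globalAlign <- function(a, b, match = 1, mismatchClass = 0, mismatch = -1,
                        gap = -2, classes = defaultSimilarityClasses()) {
  if (!nzchar(a) || !nzchar(b)) stop("alignment inputs must be non-empty")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  cls <- .classIndex(classes)
  subScore <- function(x, y) {
    if (x == y && x != "X") return(match)
    cx <- cls[x]; cy <- cls[y]
    if (!is.na(cx) && !is.na(cy) && cx == cy && x != "X" && y != "X")
      return(mismatchClass)
    mismatch
  }
  S <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 up, 3 left
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + subScore(av[i], bv[j])
      u <- S[i, j + 1L] + gap
      l <- S[i + 1L, j] + gap
      best <- max(d, u, l)
      S[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  # traceback
  i <- n + 1L; j <- m + 1L
  ra <- character(0); rb <- character(0)
  while (i > 1L || j > 1L) {
    mv <- P[i, j]
    if (mv == 1L) {
      ra <- c(av[i - 1L], ra); rb <- c(bv[j - 1L], rb); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      ra <- c(av[i - 1L], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j - 1L], rb); j <- j - 1L
    }
  }
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       score = S[n + 1L, m + 1L])
}

#' Percentage identity and similarity of an aligned pair
#'
#' Identity counts columns with identical non-gap residues; similarity
#' additionally counts columns whose residues share a conservative
#' substitution class. Percentages are relative to the full aligned
#' length (gap columns included in the denominator). \code{X} never
#' counts as identical or similar.
#'
#' @param alignedA,alignedB equal-length aligned strings (gap \code{-}).
#' @param classes similarity classes.
#' @return data.frame with \code{pct_identity}, \code{pct_similarity},
#'   \code{aligned_length}, \code{n_identical}, \code{n_similar}.
#' @export
identitySimilarity <- function(alignedA, alignedB,
                               classes = defaultSimilarityClasses()) {
  if (nchar(alignedA) != nchar(alignedB))
    stop("aligned strings must have equal length")
  av <- strsplit(alignedA, "")[[1]]; bv <- strsplit(alignedB, "")[[1]]
  cls <- .classIndex(classes)
  valid <- av != "-" & bv != "-" & av != "X" & bv != "X"
  ident <- valid & av == bv
  ca <- cls[av]; cb <- cls[bv]
  simil <- ident | (valid & !is.na(ca) & !is.na(cb) & ca == cb)
  L <- length(av)
  data.frame(pct_identity = 100 * sum(ident) / L,
             pct_similarity = 100 * sum(simil) / L,
             aligned_length = L,
             n_identical = sum(ident),
             n_similar = sum(simil))
}

#' Read a FASTA file of contigs with a read-count table
#'
#' @param fastaPath nucleotide FASTA file.
#' @param countsPath optional TSV with columns \code{contig_id},
#'   \code{read_count} (and optionally \code{length}); when absent,
#'   counts default to 0.
#' @return data.frame with \code{contig_id}, \code{nt_seq},
#'   \code{read_count}, \code{length}.
#' @export
readContigs <- function(fastaPath, countsPath = NULL) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  ids <- sub("\\s.*$", "", names(seqs))
  df <- data.frame(contig_id = ids, nt_seq = as.character(seqs),
                   read_count = 0, length = Biostrings::width(seqs),
                   stringsAsFactors = FALSE)
  if (!is.null(countsPath)) {
    cnt <- read.delim(countsPath, stringsAsFactors = FALSE)
    i <- base::match(df$contig_id, cnt$contig_id)
    df$read_count <- ifelse(is.na(i), 0, cnt$read_count[i])
  }
  if (any(df$read_count < 0)) stop("read counts must be non-negative")
  rownames(df) <- NULL
  df
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
writeFasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}
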
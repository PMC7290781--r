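# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with R/.

# standard genetic code entered independently (codon -> amino acid)
.oracleCodonMap <- local({
  aa <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  setNames(strsplit(aa, "")[[1]], codons)
})

oracleTranslate <- function(nt, offset = 0L) {
  nt <- toupper(chartr("u", "t", nt))
  out <- character(0)
  i <- offset + 1L
  while (i + 2L <= nchar(nt)) {
    cod <- substr(nt, i, i + 2L)
    aa <- if (grepl("^[ACGT]{3}$", cod)) .oracleCodonMap[[cod]] else "X"
    out <- c(out, aa)
    i <- i + 3L
  }
  paste(out, collapse = "")
}

oracleRevComp <- function(nt) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(nt)), "")[[1]]),
        collapse = "")
}

oracleSixFrames <- function(nt) {
  rc <- oracleRevComp(nt)
  setNames(c(vapply(0:2, function(o) oracleTranslate(nt, o), character(1)),
             vapply(0:2, function(o) oracleTranslate(rc, o), character(1))),
           c("+1", "+2", "+3", "-1", "-2", "-3"))
}

# brute-force ORF scan over all six frame translations
oracleOrfs <- function(nt, minLen) {
  frames <- oracleSixFrames(nt)
  L <- nchar(nt)
  res <- list()
  for (k in seq_along(frames)) {
    aa <- frames[[k]]
    frame <- c(1L, 2L, 3L, -1L, -2L, -3L)[k]
    off <- abs(frame) - 1L
    runs <- gregexpr("[^*]+", aa)[[1]]
    if (runs[1] == -1) next
    for (i in seq_along(runs)) {
      p <- runs[i]; len <- attr(runs, "match.length")[i]
      if (len < minLen) next
      sL <- off + 3 * (p - 1) + 1; eL <- off + 3 * (p + len - 1)
      if (frame > 0) { s <- sL; e <- eL } else { s <- L - eL + 1; e <- L - sL + 1 }
      res[[length(res) + 1]] <- c(frame = frame, start = s, end = e, len = len)
    }
  }
  if (!length(res)) return(matrix(numeric(0), ncol = 4))
  do.call(rbind, res)
}

# exhaustive global-alignment score by recursion (tiny sequences only)
oracleAlignScore <- function(a, b, match = 1, mismatchClass = 0,
                             mismatch = -1, gap = -2,
                             classes = c("AVLIM", "FWY", "ST", "KR", "DE",
                                         "NQ", "H", "C", "G", "P")) {
  classOf <- function(x) {
    hit <- which(vapply(classes, function(cl)
      grepl(x, cl, fixed = TRUE), logical(1)))
    if (length(hit)) hit[1] else NA_integer_
  }
  sub <- function(x, y) {
    if (x == y && x != "X") return(match)
    cx <- classOf(x); cy <- classOf(y)
    if (!is.na(cx) && !is.na(cy) && cx == cy && x != "X") return(mismatchClass)
    mismatch
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, sub(av[i], bv[j]) + rec(i + 1, j + 1))
    if (i <= length(av)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# exhaustive FDR threshold scan over every cut point
oracleFdrThreshold <- function(scores, isDecoy, maxFdr = 2) {
  cand <- sort(unique(scores))
  feasible <- c()
  for (t in cand) {
    acc <- scores >= t
    nT <- sum(acc & !isDecoy); nD <- sum(acc & isDecoy)
    fdr <- if (nT == 0) Inf else nD / nT
    if (fdr < maxFdr / 100) feasible <- c(feasible, t)
  }
  if (!length(feasible)) Inf else min(feasible)
}

randAA <- function(n, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

randNT <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
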
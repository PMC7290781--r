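## Toxin precursor architecture, peptide masses and mass-based inference
## of C-terminal amidation-signal processing.

# standard amino-acid residue masses (Da)
.MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
.AVG_RESIDUE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594,
  N = 114.1038, D = 115.0886, Q = 128.1307, K = 128.1741,
  E = 129.1155, M = 131.1926, H = 137.1411, F = 147.1766,
  R = 156.1875, Y = 163.1760, W = 186.2132)
.WATER_MONO <- 18.010565
.WATER_AVG <- 18.01528
# acid -> amide at the C terminus: replace OH with NH2
.AMIDE_SHIFT <- -0.98402

#' Peptide mass from residue composition
#'
#' Sum of standard residue masses plus one water, in either the
#' monoisotopic or the average convention.
#'
#' @param seq peptide string (standard 20 amino-acid letters).
#' @param mode \code{"mono"} (default) or \code{"average"}.
#' @return mass in Da.
#' @examples
#' peptideMass("G")  # 75.032
#' @export
peptideMass <- function(seq, mode = c("mono", "average")) {
  mode <- match.arg(mode)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("'seq' must be a single non-empty peptide string")
  res <- strsplit(seq, "")[[1]]
  tab <- if (mode == "mono") .MONO_RESIDUE else .AVG_RESIDUE
  m <- tab[res]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("non-standard amino acid '%s' at position %d",
                 res[bad], bad))
  }
  sum(m) + if (mode == "mono") .WATER_MONO else .WATER_AVG
}

#' ToxinPrecursor: signal/propeptide/mature partition of a translated ORF
#'
#' @slot orf_id identifier of the source ORF.
#' @slot signal signal-peptide segment ("" when absent).
#' @slot propeptide propeptide segment ("" when absent).
#' @slot mature mature-peptide segment.
#' @exportClass ToxinPrecursor
setClass("ToxinPrecursor",
         representation(orf_id = "character", signal = "character",
                        propeptide = "character", mature = "character"),
         validity = function(object) {
           if (!nzchar(object@mature)) return("mature segment is empty")
           TRUE
         })

#' @describeIn parsePrecursor signal-peptide segment accessor
#' @param x a \code{ToxinPrecursor}.
#' @export
signalPeptide <- function(x) x@signal

#' @describeIn parsePrecursor propeptide segment accessor
#' @export
propeptideSeq <- function(x) x@propeptide

#' @describeIn parsePrecursor mature segment accessor
#' @export
matureSeq <- function(x) x@mature

#' @describeIn parsePrecursor full precursor sequence
#' @export
precursorSeq <- function(x) paste0(x@signal, x@propeptide, x@mature)

#' @describeIn parsePrecursor TRUE when a signal peptide is annotated
#' @export
hasSignal <- function(x) nzchar(x@signal)

setMethod("show", "ToxinPrecursor", function(object) {
  cat("ToxinPrecursor ", object@orf_id, "\n",
      " signal     (", nchar(object@signal), " aa): ", object@signal, "\n",
      " propeptide (", nchar(object@propeptide), " aa): ",
      object@propeptide, "\n",
      " mature     (", nchar(object@mature), " aa): ", object@mature, "\n",
      sep = "")
})

#' Partition a translated precursor into signal, propeptide and mature
#'
#' Cleavage positions come from an external annotation (e.g. a SignalP
#' run and proteomic evidence); they are consumed, not predicted. With
#' \code{signalEnd = NA} the whole sequence is the mature peptide; with
#' \code{propeptideEnd = NA} the propeptide is empty.
#'
#' @param aaSeq full translated precursor.
#' @param signalEnd 1-based last residue of the signal peptide, or NA.
#' @param propeptideEnd 1-based last residue of the propeptide, or NA.
#' @param orfId identifier stored in the object.
#' @return a \code{ToxinPrecursor}.
#' @export
parsePrecursor <- function(aaSeq, signalEnd = NA, propeptideEnd = NA,
                           orfId = "orf") {
  n <- nchar(aaSeq)
  if (n == 0L) stop("'aaSeq' must be non-empty")
  se <- if (is.na(signalEnd)) 0L else as.integer(signalEnd)
  pe <- if (is.na(propeptideEnd)) se else as.integer(propeptideEnd)
  if (se < 0L || pe < se || pe >= n)
    stop("cleavage positions must satisfy 0 <= signalEnd <= propeptideEnd < length")
  new("ToxinPrecursor", orf_id = orfId,
      signal = substr(aaSeq, 1L, se),
      propeptide = if (pe > se) substr(aaSeq, se + 1L, pe) else "",
      mature = substr(aaSeq, pe + 1L, n))
}

.bothMasses <- function(seq, amide = FALSE) {
  shift <- if (amide) .AMIDE_SHIFT else 0
  c(mono = peptideMass(seq, "mono") + shift,
    avg = peptideMass(seq, "average") + shift)
}

#' Enumerate C-terminal processing candidates of a mature peptide
#'
#' Always emits the intact peptide. When the C-terminus carries an
#' amidation-signal motif -- a glycine followed by zero, one or two
#' basic residues (K/R), i.e. \code{G}, \code{GK}, \code{GR},
#' \code{GKK}, \code{GRR}, ... -- the des-basic intermediates (trailing
#' K/R stripped one at a time), the fully processed peptide with the
#' glycine also removed, and its C-terminally amidated form
#' (acid-to-amide, mass shift -0.98402 Da) are emitted too. Both mass
#' conventions are reported for every candidate.
#'
#' @param mature mature peptide string.
#' @return data.frame with \code{variant}, \code{processed_seq},
#'   \code{mass_mono}, \code{mass_avg}, ordered from least to most
#'   processed (strictly decreasing mass).
#' @export
processingCandidates <- function(mature) {
  if (!nzchar(mature)) stop("'mature' must be non-empty")
  rows <- list()
  add <- function(label, seq, amide = FALSE) {
    m <- .bothMasses(seq, amide)
    rows[[length(rows) + 1L]] <<- data.frame(
      variant = label, processed_seq = seq,
      mass_mono = unname(m["mono"]), mass_avg = unname(m["avg"]),
      stringsAsFactors = FALSE)
  }
  add("intact", mature)
  m <- regexpr("G[KR]{0,2}$", mature)
  if (m > 0L) {
    motif <- substr(mature, m, nchar(mature))
    basics <- substr(motif, 2L, nchar(motif))
    # strip trailing basic residues one at a time
    removed <- ""
    seq <- mature
    if (nzchar(basics)) {
      for (i in rev(seq_len(nchar(basics)))) {
        removed <- paste0(substr(basics, i, i), removed)
        seq <- substr(seq, 1L, nchar(seq) - 1L)
        add(paste0("des-", removed), seq)
      }
    }
    core <- substr(mature, 1L, m - 1L)
    if (!nzchar(core)) stop("amidation motif spans the whole peptide")
    lab <- paste0("des-G", basics)
    add(lab, core)
    add(paste0(lab, "-amidated"), core, amide = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match an observed mass against processing candidates
#'
#' Selects the candidate minimising \code{|observed - mass_mono|}; ties
#' prefer the less-processed variant (earlier candidate row).
#'
#' @param observed observed mass in Da (> 0).
#' @param candidates data.frame from [processingCandidates()].
#' @param tolerance match tolerance in Da (default 0.5, MALDI scale).
#' @return one-row data.frame: \code{observed_mass}, \code{best_variant},
#'   \code{delta} (observed minus calculated), \code{within_tolerance}.
#' @export
matchObservedMass <- function(observed, candidates, tolerance = 0.5) {
  if (!is.numeric(observed) || observed <= 0)
    stop("'observed' must be a positive mass in Da")
  if (!nrow(candidates)) stop("'candidates' must be non-empty")
  if (tolerance <= 0) stop("'tolerance' must be > 0")
  dev <- abs(observed - candidates$mass_mono)
  best <- which(dev == min(dev))[1]  # earlier row = less processed
  data.frame(observed_mass = observed,
             best_variant = candidates$variant[best],
             delta = observed - candidates$mass_mono[best],
             within_tolerance = dev[best] <= tolerance,
             stringsAsFactors = FALSE)
}

#' Processing report for a set of precursors
#'
#' Convenience wrapper producing the TSV-ready report of processing
#' candidates and (optional) observed-mass matches.
#'
#' @param precursors list of \code{ToxinPrecursor} objects.
#' @param observed optional named numeric vector of observed masses,
#'   names matching ORF ids.
#' @param tolerance match tolerance in Da.
#' @return data.frame with one row per candidate.
#' @export
processingReport <- function(precursors, observed = NULL, tolerance = 0.5) {
  out <- lapply(precursors, function(p) {
    cand <- processingCandidates(matureSeq(p))
    cand <- cbind(orf_id = p@orf_id, cand, stringsAsFactors = FALSE)
    obs <- if (!is.null(observed)) observed[p@orf_id] else NA_real_
    if (!is.null(observed) && !is.na(obs)) {
      mm <- matchObservedMass(obs, cand[, -1], tolerance)
      cand$observed <- obs
      cand$delta <- obs - cand$mass_mono
      cand$best_match <- cand$variant == mm$best_variant
      cand$within_tolerance <- abs(cand$delta) <= tolerance
    } else {
      cand$observed <- NA_real_
      cand$delta <- NA_real_
      cand$best_match <- NA
      cand$within_tolerance <- NA
    }
    cand
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
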
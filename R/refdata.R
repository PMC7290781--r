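## Accessors for the packaged reference sequences.

#' Reference poneratoxin sequences
#'
#' The packaged poneratoxin (delta-paraponeritoxin) reference set: the
#' Pc1e precursor (24-residue signal peptide, 14-residue propeptide,
#' 27-residue mature peptide carrying the C-terminal GK amidation
#' signal) and the published mature isoform sequences used for
#' comparison.
#'
#' @return named character vector of protein sequences.
#' @export
poneratoxinSequences <- function() {
  seqs <- Biostrings::readAAStringSet(
    system.file("extdata", "poneratoxin.fasta", package = "venomtx"))
  setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' The Pc1e precursor as a ToxinPrecursor
#'
#' Parses the packaged Pc1e precursor with its annotated cleavage sites
#' (signal residues 1-24, propeptide 25-38, mature 39-65).
#'
#' @return a \code{ToxinPrecursor}.
#' @export
pc1ePrecursor <- function() {
  seqs <- poneratoxinSequences()
  parsePrecursor(seqs[["Pc1e_precursor"]], signalEnd = 24,
                 propeptideEnd = 38, orfId = "Pc1e")
}
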
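## Cysteine scaffolds: extraction, parsing, toxin-like filtering,
## conotoxin-framework / ICK classification and disulfide counts.

#' Extract the cysteine scaffold of a peptide
#'
#' Encodes inter-cysteine spacings as \code{x_n} segments and adjacent
#' cysteines as \code{CC}; zero-length spacers are omitted. With
#' \code{style = "display"} each subscript carries a trailing underscore
#' (\code{x_8_CCx_1_...}), the table-facing variant of the notation.
#'
#' @param aaSeq peptide string.
#' @param peptideId identifier stored in the result.
#' @param style \code{"plain"} (default) or \code{"display"}.
#' @return list of class \code{CysteineScaffold}: \code{peptide_id},
#'   \code{length}, \code{cys_positions}, \code{n_cys}, \code{scaffold},
#'   \code{framework}.
#' @examples
#' scaffoldString(paste0(strrep("A", 8), "CCACAAAAAAAAAAAAAAAAAAACAAAAA"))
#' @export
scaffoldString <- function(aaSeq, peptideId = "pep",
                           style = c("plain", "display")) {
  style <- match.arg(style)
  if (!nzchar(aaSeq)) stop("'aaSeq' must be non-empty")
  chars <- strsplit(aaSeq, "")[[1]]
  pos <- which(chars == "C")
  L <- length(chars)
  spacer <- function(n) {
    if (n == 0L) return("")
    if (style == "display") sprintf("x_%d_", n) else sprintf("x_%d", n)
  }
  if (!length(pos)) {
    sc <- spacer(L)
  } else {
    parts <- spacer(pos[1] - 1L)
    for (i in seq_along(pos)) {
      parts <- c(parts, "C")
      nxt <- if (i < length(pos)) pos[i + 1L] else L + 1L
      parts <- c(parts, spacer(nxt - pos[i] - 1L))
    }
    sc <- paste(parts, collapse = "")
  }
  structure(list(peptide_id = peptideId, length = L,
                 cys_positions = pos, n_cys = length(pos),
                 scaffold = sc, framework = classifyFramework(aaSeq)),
            class = "CysteineScaffold")
}

#' @export
print.CysteineScaffold <- function(x, ...) {
  cat("CysteineScaffold ", x$peptide_id, ": ", x$scaffold,
      " (", x$length, " aa, ", x$n_cys, " Cys, ", x$framework, ")\n",
      sep = "")
  invisible(x)
}

#' Parse a cysteine-scaffold string
#'
#' Accepts both the plain (\code{x_8CCx_1Cx_19Cx_5}) and the display
#' (\code{x_8_CCx_1_Cx_19_Cx_5_}) notation.
#'
#' @param scaffold scaffold string.
#' @return named integer vector with \code{length} (sum of spacer
#'   subscripts plus number of C symbols) and \code{n_cys}.
#' @examples
#' parseScaffold("Cx_6Cx_5CCx_4Cx_6Cx_29")  # length 56, n_cys 6
#' @export
parseScaffold <- function(scaffold) {
  if (!is.character(scaffold) || length(scaffold) != 1L || !nzchar(scaffold))
    stop("'scaffold' must be a single non-empty string")
  s <- scaffold
  pos <- 1L
  len <- 0L
  ncys <- 0L
  while (pos <= nchar(s)) {
    rest <- substr(s, pos, nchar(s))
    if (substr(rest, 1L, 1L) == "C") {
      ncys <- ncys + 1L
      len <- len + 1L
      pos <- pos + 1L
    } else {
      m <- regexpr("^x_([0-9]+)_?", rest)
      if (m < 0L)
        stop(sprintf("malformed scaffold string at position %d: '%s'",
                     pos, substr(rest, 1L, 1L)))
      tok <- regmatches(rest, m)
      len <- len + as.integer(sub("^x_([0-9]+)_?$", "\\1", tok))
      pos <- pos + attr(m, "match.length")
    }
  }
  c(length = len, n_cys = ncys)
}

.cysCount <- function(seqs) {
  vapply(strsplit(seqs, ""), function(x) sum(x == "C"), integer(1))
}

#' Filter peptides with a toxin-like cysteine complement
#'
#' Keeps peptides with an even number of at least four cysteines (the
#' threshold is inclusive, matching the four-cysteine peptides reported
#' alongside the six-plus ones).
#'
#' @param peptides character vector of peptide sequences, or data.frame
#'   with an \code{aa_seq} column.
#' @return subset of the input, in order.
#' @export
toxinLikeFilter <- function(peptides) {
  seqs <- if (is.data.frame(peptides)) peptides$aa_seq else peptides
  nc <- .cysCount(seqs)
  keep <- nc >= 4L & nc %% 2L == 0L
  if (is.data.frame(peptides)) {
    out <- peptides[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else peptides[keep]
}

#' Classify the cysteine framework of a peptide
#'
#' \code{framework_I}: exactly four cysteines with the first pair
#' adjacent and the others isolated (\code{CC-C-C}, conotoxin framework
#' I). \code{ICK_VI_VII}: exactly six cysteines with the third and
#' fourth adjacent and the others isolated (\code{C-C-CC-C-C}, the
#' pattern-level inhibitor-cystine-knot / conotoxin VI/VII framework).
#' Other even counts of four or more give \code{other_even}; anything
#' else \code{none}. Only the cysteine pattern is tested; disulfide
#' topology is not verified.
#'
#' @param aaSeq peptide string.
#' @return one of \code{"framework_I"}, \code{"ICK_VI_VII"},
#'   \code{"other_even"}, \code{"none"}.
#' @export
classifyFramework <- function(aaSeq) {
  pos <- which(strsplit(aaSeq, "")[[1]] == "C")
  n <- length(pos)
  if (n == 4L) {
    gaps <- diff(pos)
    if (gaps[1] == 1L && gaps[2] > 1L && gaps[3] > 1L) return("framework_I")
  }
  if (n == 6L) {
    gaps <- diff(pos)
    if (all(gaps[c(1, 2, 4, 5)] > 1L) && gaps[3] == 1L) return("ICK_VI_VII")
  }
  if (n >= 4L && n %% 2L == 0L) return("other_even")
  "none"
}

#' Predicted number of disulfide bonds from the cysteine count
#'
#' Assumes all cysteines are paired: \code{n_cys / 2}. An odd count
#' implies a free cysteine and is rejected rather than rounded.
#'
#' @param nCys even, non-negative cysteine count.
#' @return predicted disulfide-bond count.
#' @export
predictDisulfideCount <- function(nCys) {
  if (any(nCys < 0) || any(nCys %% 2L != 0L))
    stop("odd cysteine count: free cysteine, cannot pair all residues")
  as.integer(nCys / 2L)
}

# canonical framework connectivity, as labels only
.FRAMEWORK_CONNECTIVITY <- c(framework_I = "1-3/2-4",
                             ICK_VI_VII = "1-4/2-5/3-6")

#' Cysteine-count distribution of a toxin-like peptide set
#'
#' @param peptides character vector or data.frame with \code{aa_seq}.
#' @return data.frame with \code{n_cys}, \code{n_peptides},
#'   \code{fraction} (fractions sum to 1; empty input gives an empty
#'   table).
#' @export
cysteineDistribution <- function(peptides) {
  seqs <- if (is.data.frame(peptides)) peptides$aa_seq else peptides
  if (!length(seqs))
    return(data.frame(n_cys = integer(), n_peptides = integer(),
                      fraction = numeric()))
  nc <- .cysCount(seqs)
  tab <- table(nc)
  data.frame(n_cys = as.integer(names(tab)),
             n_peptides = as.integer(tab),
             fraction = as.numeric(tab) / length(nc))
}

#' Scaffold table for a set of peptides
#'
#' One row per peptide with its length, cysteine count, scaffold string,
#' framework class, predicted disulfide count (NA for odd counts) and
#' canonical connectivity label. Column order is fixed for the TSV
#' interface.
#'
#' @param seqs named character vector of peptide sequences.
#' @param tpm optional named TPM vector.
#' @return data.frame with columns \code{peptide_id}, \code{length},
#'   \code{n_cys}, \code{scaffold}, \code{framework},
#'   \code{predicted_disulfides}, \code{connectivity}, \code{tpm}.
#' @export
scaffoldTable <- function(seqs, tpm = NULL) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("pep", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    sc <- scaffoldString(seqs[[i]], ids[i])
    data.frame(peptide_id = ids[i], length = sc$length, n_cys = sc$n_cys,
               scaffold = sc$scaffold, framework = sc$framework,
               predicted_disulfides = if (sc$n_cys %% 2L == 0L)
                 predictDisulfideCount(sc$n_cys) else NA_integer_,
               connectivity = if (sc$framework %in%
                                  names(.FRAMEWORK_CONNECTIVITY))
                 .FRAMEWORK_CONNECTIVITY[[sc$framework]] else NA_character_,
               tpm = if (!is.null(tpm)) unname(tpm[ids[i]]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cysteine-rich scaffold reference table
#'
#' The packaged reference of printed cysteine scaffolds (scaffold string,
#' mature length, TPM) used by tests and the acceptance script.
#'
#' @return data.frame with \code{n_cys}, \code{scaffold}, \code{length},
#'   \code{tpm}.
#' @export
referenceScaffolds <- function() {
  read.delim(system.file("extdata", "reference_scaffolds.tsv",
                         package = "venomtx"),
             comment.char = "#", stringsAsFactors = FALSE)
}
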
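## Rational toxin nomenclature: build, parse and assign peptide-toxin
## (King-style) and protein-toxin names.

# Greek activity prefixes with ASCII transliterations
.GREEK <- c(alpha = "α", beta = "β", gamma = "γ",
            delta = "δ", epsilon = "ε", zeta = "ζ",
            eta = "η", theta = "θ", iota = "ι",
            kappa = "κ", lambda = "λ", mu = "μ",
            nu = "ν", xi = "ξ", omicron = "ο",
            pi = "π", rho = "ρ", sigma = "σ",
            tau = "τ", upsilon = "υ", phi = "φ",
            chi = "χ", psi = "ψ", omega = "ω")
.SUBSCRIPT_DIGITS <- c("₀", "₁", "₂", "₃", "₄",
                       "₅", "₆", "₇", "₈", "₉")

#' Transliterate an activity prefix between ASCII and Greek
#'
#' \code{greekPrefix("delta")} gives the Greek letter;
#' \code{asciiPrefix} maps it back, yielding file-system-safe names.
#'
#' @param x prefix string.
#' @return transliterated prefix (unchanged if not mapped).
#' @export
greekPrefix <- function(x) {
  if (x %in% names(.GREEK)) unname(.GREEK[x]) else x
}

#' @rdname greekPrefix
#' @export
asciiPrefix <- function(x) {
  i <- base::match(x, .GREEK)
  if (!is.na(i)) names(.GREEK)[i] else x
}

.speciesCode <- function(genus, species) {
  paste0(toupper(substr(genus, 1L, 1L)), tolower(substr(species, 1L, 1L)))
}

#' ToxinName: structured components of a rational toxin name
#'
#' @slot kind \code{"peptide"} or \code{"protein"}.
#' @slot prefix activity prefix (Greek letter, or \code{"U"} for unknown
#'   activity; peptide names only).
#' @slot prefix_index numeric index on a \code{U} prefix (NA when absent).
#' @slot prefix_text verbatim prefix as printed (preserves subscript
#'   markup on parse).
#' @slot generic_name generic protein name (protein names only).
#' @slot toxin_stem genus-derived toxin stem (peptide names only).
#' @slot family paralog-family number.
#' @slot isoform isoform letter(s).
#' @slot nt_variant nucleotide-variant numeral (NA when absent).
#' @slot genus genus (or its initial, when parsed from a name).
#' @slot species species epithet (or its initial).
#' @exportClass ToxinName
setClass("ToxinName",
         representation(kind = "character", prefix = "character",
                        prefix_index = "integer", prefix_text = "character",
                        generic_name = "character", toxin_stem = "character",
                        family = "integer", isoform = "character",
                        nt_variant = "integer", genus = "character",
                        species = "character"),
         prototype(prefix = "", prefix_index = NA_integer_,
                   prefix_text = "", generic_name = "", toxin_stem = "",
                   nt_variant = NA_integer_),
         validity = function(object) {
           if (!object@kind %in% c("peptide", "protein"))
             return("kind must be 'peptide' or 'protein'")
           if (is.na(object@family) || object@family < 1L)
             return("family must be a positive integer")
           if (!grepl("^[a-z]+$", object@isoform))
             return("isoform must be lowercase letters")
           TRUE
         })

setMethod("show", "ToxinName", function(object) {
  cat("ToxinName <", renderName(object), "> (", object@kind, ")\n", sep = "")
})

#' Render a ToxinName back to its string form
#'
#' @param x a \code{ToxinName}.
#' @return the name string.
#' @export
renderName <- function(x) {
  var <- if (!is.na(x@nt_variant)) paste0("_", x@nt_variant) else ""
  if (x@kind == "peptide") {
    pre <- if (nzchar(x@prefix_text)) x@prefix_text else x@prefix
    paste0(pre, "-", x@toxin_stem, "-",
           .speciesCode(x@genus, x@species), x@family, x@isoform, var)
  } else {
    paste0(x@generic_name, "-", x@family, x@isoform, var, "-",
           toupper(substr(x@genus, 1L, 1L)), "-", tolower(x@species))
  }
}

#' Build a peptide-toxin name
#'
#' Grammar: \code{<prefix>-<stem>-<Gs><family><isoform>[_<variant>]}
#' where \code{<Gs>} is the genus initial (uppercase) followed by the
#' species initial (lowercase). The activity prefix is a Greek letter
#' (ASCII spellings are transliterated) or \code{U} with an index for
#' toxins of unknown activity.
#'
#' @param prefix activity prefix ("delta", Greek letter, or "U").
#' @param stem genus-derived toxin stem (e.g. "paraponeritoxin";
#'   configuration, not derived).
#' @param genus,species source organism.
#' @param family paralog-family number.
#' @param isoform isoform letter(s).
#' @param variant nucleotide-variant numeral, or NA.
#' @param prefixIndex index for a "U" prefix, or NA.
#' @return name string.
#' @examples
#' buildPeptideName("delta", "paraponeritoxin", "Paraponera", "clavata",
#'                  1, "e", 2)  # "δ-paraponeritoxin-Pc1e_2"
#' @export
buildPeptideName <- function(prefix, stem, genus, species, family, isoform,
                             variant = NA, prefixIndex = NA) {
  for (arg in list(prefix, stem, genus, species, isoform))
    if (!is.character(arg) || !nzchar(arg))
      stop("all peptide-name components must be non-empty strings")
  if (is.na(family)) stop("'family' is required")
  pre <- greekPrefix(prefix)
  if (toupper(pre) == "U")
    pre <- paste0("U", if (!is.na(prefixIndex)) prefixIndex else "")
  renderName(new("ToxinName", kind = "peptide", prefix = pre,
                 prefix_index = as.integer(prefixIndex), prefix_text = pre,
                 toxin_stem = stem, family = as.integer(family),
                 isoform = isoform,
                 nt_variant = as.integer(variant),
                 genus = genus, species = species))
}

#' Build a protein-toxin name
#'
#' Grammar:
#' \code{<GenericName>-<family><isoform>[_<variant>]-<G>-<species>}.
#' The generic name is hyphen-joined with its first letter capitalised;
#' uncharacterised proteins use the generic name \code{U}.
#'
#' @param generic generic protein name (e.g. "phospholipase A2"); use
#'   "U" or "Uncharacterised" when unknown.
#' @param family paralog-family number.
#' @param isoform isoform letter(s).
#' @param variant nucleotide-variant numeral, or NA.
#' @param genus,species source organism.
#' @return name string.
#' @examples
#' buildProteinName("phospholipase A2", 1, "a", 1, "Paraponera", "clavata")
#' @export
buildProteinName <- function(generic, family, isoform, variant = NA,
                             genus, species) {
  for (arg in list(generic, genus, species, isoform))
    if (!is.character(arg) || !nzchar(arg))
      stop("all protein-name components must be non-empty strings")
  if (is.na(family)) stop("'family' is required")
  gen <- gsub("\\s+", "-", trimws(generic))
  substr(gen, 1L, 1L) <- toupper(substr(gen, 1L, 1L))
  renderName(new("ToxinName", kind = "protein", generic_name = gen,
                 family = as.integer(family), isoform = isoform,
                 nt_variant = as.integer(variant),
                 genus = genus, species = species))
}

.GREEK_CLASS <- paste0("[", paste(.GREEK, collapse = ""), "]")

#' Parse a toxin name in either grammar
#'
#' Protein names are recognised by their \code{-<G>-<species>} tail;
#' everything else is parsed under the peptide grammar. The verbatim
#' prefix and generic-name tokens are preserved so that
#' \code{renderName(parseToxinName(x)) == x} for any valid name,
#' including printed names with subscript markup such as \code{U_1_}.
#'
#' @param name name string.
#' @return a \code{ToxinName}.
#' @export
parseToxinName <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string")
  protRe <- "^(.*)-([0-9]+)([a-z]+)(?:_([0-9]+))?-([A-Z])-([a-z]+)$"
  if (grepl("-[A-Z]-[a-z]+$", name)) {
    m <- regmatches(name, regexec(protRe, name))[[1]]
    if (!length(m))
      stop(sprintf("cannot parse protein name '%s': no <family><isoform> token before the species tail", name))
    return(new("ToxinName", kind = "protein", generic_name = m[2],
               family = as.integer(m[3]), isoform = m[4],
               nt_variant = if (nzchar(m[5])) as.integer(m[5]) else NA_integer_,
               genus = m[6], species = m[7]))
  }
  prefixRe <- paste0("(", .GREEK_CLASS,
                     "|U(?:_[0-9]+_|[0-9]+|[₀-₉]+)?)")
  pepRe <- paste0("^", prefixRe,
                  "-([A-Za-z][A-Za-z0-9-]*)-([A-Z])([a-z])",
                  "([0-9]+)([a-z]+)(?:_([0-9]+))?$")
  m <- regmatches(name, regexec(pepRe, name))[[1]]
  if (!length(m))
    stop(sprintf("cannot parse '%s': leading token is neither a Greek/U activity prefix nor a generic protein name with a species tail", name))
  pre <- m[2]
  idx <- NA_integer_
  if (substr(pre, 1L, 1L) == "U" && nchar(pre) > 1L) {
    digits <- gsub("[^0-9₀-₉]", "", pre)
    digits <- chartr(paste(.SUBSCRIPT_DIGITS, collapse = ""), "0123456789",
                     digits)
    if (nzchar(digits)) idx <- as.integer(digits)
  }
  new("ToxinName", kind = "peptide",
      prefix = if (substr(pre, 1L, 1L) == "U") "U" else pre,
      prefix_index = idx, prefix_text = pre,
      toxin_stem = m[3], family = as.integer(m[6]), isoform = m[7],
      nt_variant = if (nzchar(m[8])) as.integer(m[8]) else NA_integer_,
      genus = m[4], species = m[5])
}

.isoformLetters <- function(k) {
  # a..z, then aa, ab, ... (spreadsheet-style) beyond 26
  vapply(seq_len(k), function(i) {
    s <- ""
    while (i > 0L) {
      r <- (i - 1L) %% 26L
      s <- paste0(letters[r + 1L], s)
      i <- (i - 1L) %/% 26L
    }
    s
  }, character(1))
}

#' Assign rational names to grouped toxin sequences
#'
#' Within each generic-name group, paralog families (given by
#' \code{family_key}) are numbered by descending maximum TPM (ties by
#' key), making the assignment deterministic and stable under input
#' reordering. Within a family, distinct protein sequences receive
#' isoform letters a, b, c, ... by descending maximum TPM; transcripts
#' with identical protein sequence but distinct nucleotide sequence
#' receive nucleotide-variant numerals 1, 2, ... by descending TPM (ties
#' by transcript id). A variant numeral is only attached when a family's
#' isoform has more than one transcript.
#'
#' @param df data.frame with columns \code{contig_id},
#'   \code{protein_seq}, \code{group} (generic name or peptide family
#'   target), \code{tpm}, and optionally \code{kind} ("peptide" or
#'   "protein", default "protein") and \code{family_key} (defaults to
#'   \code{group}).
#' @param genus,species source organism.
#' @param stem toxin stem used for peptide names.
#' @param prefixes named character vector mapping peptide group names to
#'   activity prefixes (default "U").
#' @return data.frame: \code{old_id}, \code{assigned_name},
#'   \code{group}, \code{family}, \code{isoform}, \code{variant},
#'   \code{basis}.
#' @export
assignNames <- function(df, genus, species, stem = "toxin",
                        prefixes = character()) {
  stopifnot(all(c("contig_id", "protein_seq", "group", "tpm") %in% names(df)))
  if (!"kind" %in% names(df)) df$kind <- "protein"
  if (!"family_key" %in% names(df)) df$family_key <- df$group
  out <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, , drop = FALSE]
    famTpm <- tapply(sub$tpm, sub$family_key, max)
    famKeys <- names(sort(famTpm, decreasing = TRUE))
    # stable tie-break by key
    famKeys <- famKeys[order(-famTpm[famKeys], famKeys)]
    for (fi in seq_along(famKeys)) {
      fam <- sub[sub$family_key == famKeys[fi], , drop = FALSE]
      isoTpm <- tapply(fam$tpm, fam$protein_seq, max)
      isoSeqs <- names(isoTpm)[order(-isoTpm, names(isoTpm))]
      isoLetters <- .isoformLetters(length(isoSeqs))
      for (si in seq_along(isoSeqs)) {
        grp <- fam[fam$protein_seq == isoSeqs[si], , drop = FALSE]
        grp <- grp[order(-grp$tpm, grp$contig_id), , drop = FALSE]
        multi <- nrow(grp) > 1L
        for (vi in seq_len(nrow(grp))) {
          kind <- grp$kind[vi]
          var <- if (multi) vi else NA
          nm <- if (kind == "peptide") {
            pre <- if (g %in% names(prefixes)) prefixes[[g]] else "U"
            buildPeptideName(pre, stem, genus, species, fi,
                             isoLetters[si], var,
                             prefixIndex = if (toupper(pre) == "U") fi else NA)
          } else {
            buildProteinName(g, fi, isoLetters[si], var, genus, species)
          }
          out[[length(out) + 1L]] <- data.frame(
            old_id = grp$contig_id[vi], assigned_name = nm, group = g,
            family = fi, isoform = isoLetters[si], variant = var,
            basis = if (multi) "identical protein, distinct transcript"
                    else "distinct protein sequence",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(base::match(res$old_id, df$contig_id)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Printed reference toxin names
#'
#' The packaged list of published rational toxin names used by the
#' round-trip tests.
#'
#' @return character vector of names.
#' @export
referenceToxinNames <- function() {
  readLines(system.file("extdata", "reference_toxin_names.txt",
                        package = "venomtx"), encoding = "UTF-8")
}
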
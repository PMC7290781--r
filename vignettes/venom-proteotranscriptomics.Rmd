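---
title: "Methods: venom-gland proteo-transcriptomic toxin analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: venom-gland proteo-transcriptomic toxin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomtx)
```

# Scope and model

`venomtx` operationalises the analysis layer of an integrated
venom-gland study: a transcriptome assembly provides candidate toxin
transcripts and their abundances, homology annotation provides putative
identities, and shotgun proteomic peptide evidence confirms which
transcripts are actually secreted as venom proteins. The package treats
all upstream tools (assembler, aligner, homology search, signal-peptide
predictor, spectrum search engine) as producers of tabular inputs; what
it implements itself is everything downstream of those tables:
filtering, quantification, precursor parsing, mass arithmetic, scaffold
classification, naming and evidence reconciliation.

# Sequence layer

Translation uses the standard genetic code; any codon containing a
non-ACGT letter (including N) yields `X`, and `X` never counts as an
identical or similar residue in alignment statistics. ORFs are maximal
stop-free stretches of at least 50 amino acids in any of the six frames
— the biologist-facing default for short secreted peptides, where
requiring a leading Met would discard genuine partial ORFs (a
`requireStart` flag is available). All coordinates are serialised
1-based inclusive on the forward strand regardless of frame.

Pairwise comparison uses a deterministic Needleman–Wunsch alignment:
match +1, mismatch 0 between residues sharing a conservative class and
−1 otherwise, gap −2, with traceback ties resolved diagonal-first, then
vertical, then horizontal. The conservative classes default to
`{AVLIM, FWY, ST, KR, DE, NQ, H, C, G, P}`; notably A and V share a
class, which is what makes an Ala→Val substitution conservative and
yields 100% similarity alongside 96% identity for the mature
poneratoxin isoform pair. The published comparisons this reproduces are
gapless, so the gap-penalty choice does not affect them; it matters
only for diverged pairs, where users can supply their own scheme.
Percentages are taken over the full aligned length, gap columns
included in the denominator.

# Abundance

TPM is computed directly from its definition,
$\mathrm{TPM}_i = 10^6 (c_i/\ell_i) / \sum_j (c_j/\ell_j)$, which makes
the output sum to $10^6$ exactly and makes the measure invariant to
global count scaling. Effective length defaults to the contig length;
an optional mean-fragment-length correction
($\ell_{\mathrm{eff}} = \ell - \mu_{\mathrm{frag}} + 1$, floored at 1)
is provided because production quantifiers apply one internally but its
fragment-length parameter is study-specific. The reporting filter keeps
transcripts with TPM ≥ 1 (boundary inclusive) and the expression report
ranks descending by TPM with a lexicographic id tie-break, so reports
are reproducible to the byte.

# Precursor processing and mass arithmetic

A toxin precursor is partitioned into signal peptide, propeptide and
mature peptide from externally supplied cleavage positions — signal
sites come from a dedicated predictor and propeptide boundaries only
from proteomic evidence or explicit annotation; the package never
guesses them. Peptide masses are sums of standard residue masses plus
one water, in both the monoisotopic and the average convention. The
monoisotopic convention is the verification surface: the published
poneratoxin mass pair (2968.7/2783.6 Da and the 185.1 Da gap) is
reproduced exactly by monoisotopic arithmetic, so that is what
mass-matching uses, with both conventions always reported.

C-terminal processing candidates follow the amidation-signal grammar: a
trailing glycine followed by zero to two basic residues (G, GK, GR,
GKK, GRR). Candidates are the intact peptide, the des-basic
intermediates, the fully processed (des-G…) peptide and its amidated
form (acid→amide, −0.98402 Da). Matching an observed mass minimises the
absolute monoisotopic deviation, prefers the less-processed variant on
ties, and flags matches within a 0.5 Da tolerance — a MALDI-scale
default, configurable for higher-resolution instruments. Broader
processing motifs (longer basic runs, other convertases) and all other
PTMs are deliberately out of scope.

# Cysteine scaffolds

Scaffold strings encode inter-cysteine spacings (`x_n`) and adjacent
cysteine doublets (`CC`); zero-length spacers are omitted. The
serialised notation drops the trailing underscore after subscripts
(`x_8CCx_1Cx_19Cx_5`); a display variant with trailing underscores
matches the table-facing notation, and the parser accepts both. The
toxin-like filter keeps peptides with an even number of at least four
cysteines — the inclusive reading, since published tables include
four-cysteine peptides. Classification is pattern-level only:
framework I is exactly four cysteines as `CC-C-C`, the ICK/VI-VII
pattern exactly six as `C-C-CC-C-C`; other even counts of four or more
are reported as `other_even` (putatively novel cysteine-rich
scaffolds). Knottedness is not verified, and disulfide connectivity
beyond the count n/2 is emitted only as the canonical framework label
(I: 1-3/2-4; VI/VII: 1-4/2-5/3-6).

# Nomenclature

Peptide names follow the rational peptide-toxin grammar
(`<prefix>-<stem>-<Gs><family><isoform>[_<variant>]`) and protein names
its protein adaptation
(`<GenericName>-<family><isoform>[_<variant>]-<G>-<species>`). The
genus-derived stem is configuration, not derived — there is no reliable
morphological rule. Greek prefixes are stored as Unicode with an ASCII
transliteration map for file-system-safe output. The parser preserves
verbatim tokens (including subscript markup such as `U_1_` and
historical spellings in generic names) so that parse∘render is the
identity on published names; the builder itself always emits canonical
forms.

Automatic assignment orders everything by abundance: paralog families
within a generic-name group, isoform letters within a family, and
nucleotide-variant numerals within an identical-protein set are all
numbered by descending maximum TPM with deterministic tie-breaks (key,
then transcript id). Published usage does not state whether isoform
letters were assigned by discovery date or abundance; abundance is used
here because it is reproducible from the data alone and makes the
assignment stable under input reordering. Isoform letters extend
spreadsheet-style (`aa`, `ab`, …) beyond 26.

# Annotation mining

Hits are kept when their e-value is strictly below 1e-4 (a hit exactly
at the cutoff is excluded). Family classification is case-insensitive
substring matching of a configurable keyword map, longest keyword
first with an alphabetical family tie-break, so "serine protease"
always beats "protease" and every query receives at most one family.
The shipped map covers 17 families with a compact keyword set; a real
study would extend it to its full curated keyword list, which is why
the map is ordinary data, not code.

# Proteome mapping

In-silico digestion applies the trypsin rule (cleave after K/R, not
before P) with up to three missed cleavages; semi-tryptic mode adds
every one-sided truncation of each fully tryptic peptide. Duplicate
fragments are retained so the zero-missed digest always partitions the
protein. The spectrum engine's scoring is not reimplemented: scores,
confidences and decoy flags are inputs, and the instrument tolerances
(50 ppm parent, 0.1 Da fragment) are validity predicates on evidence
records rather than spectrum matching.

The FDR threshold is the lowest score cut at which the decoy/target
ratio among accepted records is below 2% (a `2·decoys/total` estimate
is selectable); the confidence filter (≥ 95%) is conjunctive. Peptides
are located in ORF translations by exact substring match with Ile/Leu
kept distinct (this is sequence-database matching, not spectral
matching). Identical protein sequences are collapsed so variant
transcripts share peptide counts; a peptide is unique when it matches
exactly one distinct protein. Proteins require at least two matching
peptides and a best score of at least 15; coverage is the union of
matched residues over the protein length, taken over the contig's best
ORF. Matches without a predicted signal peptide are excluded from the
toxin candidate list but retained with a reason, since a protein
detected in venom without a signal peptide may be non-secreted
contamination or an incomplete ORF.

# Synthetic data: what it emulates, and what it does not

The generator plants, under a single seed: toxin precursors with
signal+propeptide+mature architecture (every third carrying a GK
amidation signal), identical-protein variant groups re-encoded with
different codons, cysteine-framework peptides realising published
scaffold patterns exactly, housekeeping contigs, keyword-bearing
annotation descriptions with e-values straddling the 1e-4 cutoff, and
target/decoy peptide evidence from tryptic digestion of a detectable
precursor subset. Defaults are 300 contigs, 20 toxin precursors, 15
framework peptides, a 5% variant-group fraction, 100,000 reads, a
log-normal(0, σ=2) expression law with the dominant toxin at a 4%
weight share (the scale of a dominant venom toxin, ~40,000 TPM), and
target/decoy score distributions N(40,10)/N(15,5) truncated at zero —
chosen so the 2% FDR threshold lands mid-distribution and the filter is
exercised non-trivially rather than passed vacuously.

What passing on this generator shows: the plumbing and the filter
mathematics are correct end to end, including exact ground-truth
recovery. What it does not show: robustness to assembly artefacts
(chimeras, fragmented ORFs), codon bias, shared peptides between
homologous toxin families, post-translational modifications beyond
C-terminal processing, or real spectral score distributions. Claims
about real data should rest on the per-operation contracts, which are
tested against independent brute-force oracles, not on the simulation.

# Numerical and engineering choices

Report tables are written with TPM at two decimals while full precision
is kept internally. The pipeline writes an audit log of every threshold
and the MD5 of every input; no timestamps enter any output, so
identical inputs and configuration reproduce every report byte for
byte. Degenerate inputs fail fast with informative errors (all-zero
counts, empty alignment inputs, odd cysteine counts for disulfide
prediction, missing input files before any stage runs). Test problem
sizes (hundreds of random sequences per property, a 10,000-sequence
classifier/oracle comparison, one 300-contig simulated dataset) were
chosen as the smallest sizes at which the properties are convincingly
exercised.

# Known limitations

Signal peptides are consumed, never predicted; nomenclature activity
prefixes require pharmacology and default to `U`; the keyword map is a
starting vocabulary; alignment is pairwise only (no MSA); and the FDR
estimate is the simple target-decoy ratio, which is optimistic for very
small evidence sets.
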
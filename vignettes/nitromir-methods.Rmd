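---
title: "Methods: small RNA profiling and miRNA discovery under nitrogen deprivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling and miRNA discovery under nitrogen deprivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitromir)
```

`nitromir` re-implements, as a tested and reusable pipeline, the
computational analysis applied to two pooled small-RNA libraries of
*Chlamydomonas reinhardtii* grown in nitrogen-replete (TAP) and
nitrogen-free (TAP-N) medium: raw-read cleaning, unique-tag collapsing,
classification against noncoding-RNA and mature-miRNA references, novel
miRNA discovery from genomic hairpins, an exact Poisson test for
two-library differential expression, rule-based miRNA target prediction,
and KOG functional summarization. Every stage runs on synthetic data with
planted ground truth, so the whole pipeline is verifiable without any
external download.

## Tag processing

Reads are 3'-adaptor trimmed with a deterministic rule: the first 8 bases
of the adaptor are searched verbatim anywhere in the read; failing that, a
7- then 6-base adaptor prefix is matched flush with the read end. Inserts
of 18-30 nt are kept; discards are tallied as `no_adaptor`, `too_short`,
`too_long`, `ambiguous` (any N) or `low_quality` (mean Phred < 20). The
source material specifies only that adaptors were removed and low-quality
tags filtered, so both the search rule and the quality criterion are
documented package defaults, not inferences about the original software.
Collapsing to unique tags conserves counts exactly: the per-library column
sums equal the clean-read totals, an identity asserted on every pipeline
run together with `specific = unique - common` for the library overlap.

## Annotation

Classification against the reference sets (rRNA, tRNA, snRNA, snoRNA, then
mature miRNAs) is exact, full-length, strand-as-given string identity; the
first set containing the tag wins. This mirrors the original analysis,
where only perfectly matched sequences were accepted as known miRNAs, and
makes the partition property (every tag exactly one class) trivially
testable. IsomiR aggregation is deliberately not performed; whether the
original study summed near-variants of a mature sequence is unstated, so
the strictest reading is the default. The precedence order is
configurable through the order of the reference list.

## Folding engine and energy model

Novel-miRNA calling and duplex energies share one nearest-neighbour model:
stacking energies for the 36 ordered combinations of the six admissible
pair types (AU, UA, GC, CG, GU, UG; values loosely Turner-like, G:U stacks
kept moderately strong), one helix-initiation penalty of +3.5 kcal/mol per
helix, and a minimum hairpin loop of 3 nt. The table ships as an explicit
constant (`rna_energy_params()`). Folding minimizes this energy over all
nested (pseudoknot-free) structures by dynamic programming in compiled
code; because stacking terms are negative and initiation positive, lone
pairs never pay off and the MFE is bounded above by 0. The test suite
proves the DP equal to exhaustive enumeration of all nested structures for
every test sequence up to 18 nt — the energy model is simple enough to be
oracle-checkable, which we value over kcal-level fidelity to experimental
parameters. Full Turner rules, dangles, coaxial stacking and suboptimal
ensembles are out of scope.

## Novel miRNA discovery

Unannotated tags with a combined count of at least 3 (singletons are
background by construction and dominate runtime otherwise) are mapped to
the genome on both strands with at most one substitution. Around every
locus, candidate precursor windows sweep lengths 62-96 nt with the mature
placed 0-8 nt from either window edge. A candidate is accepted when the
best window folds below the -18 kcal/mol ceiling into a single stem-loop,
the mature (20-23 nt) avoids the loop, and the mature/star duplex carries
at most 4 weighted mismatches. The ceiling leaves margin below the weakest
hairpin the study reported (-22.3 kcal/mol) and is configurable. The
duplex mismatch count is read off the folded structure (unpaired mature
position = 1, G:U pair = 0.5) rather than from a fixed antiparallel
alignment: bulges shift the pairing register, and a register-blind
sequence alignment misscores structurally near-perfect duplexes.
Multi-locus candidates are reported once with their locus count; counts
are never multiplied across loci.

## Differential expression

Expression is normalized to transcripts per million of clean reads;
features below 1 TPM in both libraries are removed before testing. The
fold change is `log2(TAP-N / TAP)` with zeros replaced by 0.01 first; the
substitution applies to the fold change only, while the test always uses
raw counts. The test is the exact Poisson (Audic–Claverie) comparison: the
conditional

$$p(y \mid x) = \left(\tfrac{N_2}{N_1}\right)^{\!y}
  \frac{(x+y)!}{x!\,y!\,\bigl(1 + N_2/N_1\bigr)^{x+y+1}}$$

is evaluated in log space via log-gamma, with the lower tail C summed
directly and the upper tail D summed directly whenever it is the smaller
tail (the complement `1 - C + p(y|x)` would lose it to cancellation). The
reported p-value is `min(1, 2 min(C, D))`, capped at 1; the source
material never states how C and D combine, so the doubling convention is
ours and a one-sided option exists. Significance labels are `**` for
p < 0.01 and `*` for 0.01 <= p < 0.05, both requiring |log2FC| > 1;
library-specific features are flagged, never starred. No multiple-testing
correction is applied by default (matching the raw-p reporting
convention), with Benjamini–Hochberg behind a flag.

Two numerical notes. First, the conditional is exactly a negative binomial
(`size = x + 1`, `prob = N1/(N1+N2)`), which the tests exploit as an
independent cross-check. Second, the statistic is *not* exactly symmetric
under swapping the libraries: it conditions on one library's count, and
conditioning on x versus y gives different two-sided tails (differences of
tens of percent are possible at extreme depth ratios). The tests therefore
assert the exact identity `C + D = 1 + p(y|x)` and modest swap agreement
in the realistic regime, not exact symmetry.

## Target prediction

Target search is an ungapped antiparallel scan of each mature miRNA over
every transcript window, with miRNA positions numbered 1-based from the
5' end. Per-position states are Watson-Crick match, G:U wobble (weight
0.5) or mismatch (weight 1). The six acceptance rules: (1) total weight
<= 4; (2) no run of three or more consecutive mismatches; (3) no adjacent
mismatches within positions 2-12; (4) no mismatch at positions 10-11;
(5) weight over positions 1-12 at most 2.5; (6) duplex energy at least
75% of the perfect-complement energy, compared on magnitudes — the
sign-ambiguous "greater than 75%" phrasing only rejects weak duplexes
under the magnitude reading. Wobbles are weighted in rules 1 and 5 but do
not count as mismatches for rules 2-4. Rule 2 is read as forbidding runs
longer than two ("no more than two adjacent mismatches"); the alternative
reading (no two adjacent anywhere) would make rule 3 redundant within the
seed. Gapped duplexes (bulges) are a documented limitation: all six rules
are positional over miRNA coordinates, which a gap would make ill-defined.
Duplicate gene hits deduplicate to a unique gene list for KOG counting.

## KOG summarization and concordance

KOG assignment consumes a precomputed gene-to-letter table (the database
lookup behind it is not reproducible offline and is not the computational
contribution); the 25-letter-to-4-class table ships with the package.
Genes absent from the map are reported, never dropped; genes with several
letters count once per letter, since the published percentages leave the
denominator unstated — pair counting is the documented default.
miRNA/target concordance is sign-based on log2 fold changes: opposite
signs are consistent with cleavage, shared signs with translational
repression; a zero fold change has no direction and errors.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions at desk scale:

* **Hairpins.** 30 precursors of 62-96 nt (matching the reported range),
  matures 20-23 nt placed within 8 nt of a precursor end, the 3' arm a
  reverse complement of the 5' arm carrying 2-3 substitutions opposite the
  mature (wobble-creating where possible, so the stem stays paired) plus
  at most one elsewhere. 30% of miRNAs are planted at 2-5 loci and one at
  9 loci, matching the reported multi-locus composition. Substitutions
  opposite the mature also guarantee the mature cannot cross-map onto the
  star arm within the one-mismatch mapping tolerance.
* **Libraries.** 200,000 clean reads per library — the two ~14M-read
  libraries scaled down ~70-fold. Planted log2 fold changes come from
  {-3,...,3}; the less-expressed side of each feature draws its TPM
  log-uniform from [100, 500], so both counts of every planted feature
  stay near or above 20 at the default depth (the detectable regime; at
  the study's full depth a 100-TPM feature has ~1400 counts). Counts are
  Poisson(tpm x depth / 1e6) — the model the test itself assumes; no
  overdispersion is simulated because the study pooled replicates into
  one library per condition, and replicate-aware simulation is
  deliberately out of scope. Reads are insert + 3' adaptor padded to 40 nt
  with substitution errors at rate 0.005. Background fills each library to
  its exact depth: half from generated ncRNA *fragment* pools (18-30 nt,
  since annotation is exact-identity), half uniform random 18-30-mers
  emulating the ~60% unannotated fraction the study observed. Insert
  lengths are drawn from a 21-nt-centred distribution, reproducing the
  Dicer-product length mode of real libraries.
* **Target truth.** For each rule, sites violating exactly that rule are
  constructed from the perfect complement by placing mismatches or
  wobbles at rule-specific positions and *validated with the package's own
  scorer* before being emitted; a violation unrealizable for every miRNA
  is a construction error naming the rule. Clean sites are perfect
  complements. Transcripts embed one site each among decoys; a KOG map
  with ~10% deliberately unannotated genes accompanies them.

What passing on this generator does **not** show: robustness to isomiR
heterogeneity, sequencing-instrument error profiles, biological replicate
variance, RNA editing, or genome assembly artefacts — real libraries have
all of these and the generator none.

## Problem sizes and determinism

The default test fixture uses 10 hairpins at 30,000 reads per library; the
acceptance suite and `scripts/acceptance.R` run the full study-scale
fixture (30 hairpins, 200,000 reads per library). All sampling flows from
explicit integer seeds through one RNG stream per generator call, and the
pipeline itself is deterministic: identical config and inputs give
byte-identical outputs, which the tests assert file by file.

## Known limitations

Ungapped target duplexes; a simplified, oracle-checkable energy model
rather than full Turner parameters; exact-match annotation without isomiR
handling; no replicate-aware dispersion (single pooled library per
condition, as in the source design); single-hairpin precursor topology
only (no multibranched precursors); and the slight, intrinsic asymmetry
of the two-sided exact Poisson test discussed above.
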
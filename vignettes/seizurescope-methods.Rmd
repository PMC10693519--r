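---
title: "Methods: disproportionality signals and anchored conservation profiles"
author: "seizurescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and anchored conservation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizurescope)
```

This vignette is the package's account of what it computes, the assumptions
behind each step, the parameters that matter, and what the synthetic-data
tests do and do not demonstrate about real data.

## 1. Pharmacovigilance disproportionality

### Model

Spontaneous-report systems (FAERS-style) collect reports that each mention a
set of drugs and a set of adverse-event (AE) terms. For a drug–AE pair the
package forms the 2×2 table

|            | term     | not term |
|------------|----------|----------|
| drug       | a        | b        |
| not drug   | c        | d        |

where the **report** is the counting unit: in record mode, a report listing
several drugs and several terms contributes each unique (drug, term)
combination once, because drugs and terms are report-level sets, not paired
mentions. In count mode the table arrives pre-aggregated.

Two disproportionality statistics are computed:

* the proportional reporting ratio, `PRR = (a/(a+b)) / (c/(c+d))` — the
  term's reporting proportion for the drug against all other drugs. It is a
  ratio of proportions and therefore scale-invariant; it is undefined when
  the drug has no reports or no other drug reports the term (`c = 0`), and
  such pairs are flagged missing rather than assigned an infinite value,
  which keeps downstream summaries finite and conservative;
* the shrinkage information component, `IC = log2((a+0.5)/(E+0.5))` with
  independence expectation `E = (a+b)(a+c)/N`, and the standard credibility
  approximation for its 95% lower bound,
  `IC025 = IC − 3.3 (a+0.5)^(−1/2) − 2 (a+0.5)^(−3/2)`. The +0.5 shrinkage
  stabilizes small counts; the bound is strictly below IC for every a ≥ 0.
  This estimator is the de-facto standard in modern disproportionality work;
  a full Bayesian confidence-propagation (BCPNN) variant would give slightly
  different bounds, which is a known, accepted difference.

### Retention criteria

A pair is retained when all three hold: `PRR ≥ 2` (inclusive), `IC025 > 0`
(strictly positive), and `a ≥ 5` reports for the pair (inclusive). The report
threshold is interpreted per drug–AE pair, because the other two criteria are
pair-level. Retention is monotone in `a` at fixed margins, which the test
suite asserts.

### Term group and burden summaries

Seizure-related AEs enter as a flat term list (one term per line, `#`
comments), matched case-insensitively after trimming by default — the package
deliberately performs no MedDRA hierarchy traversal. All burden percentages
are computed over **retained** records only:

* per pair, `drug_ae_pct = a / (drug total reports) × 100`;
* per drug, the cumulative seizure-AE fraction of its reports (burden) and
  its share of the retained seizure-record pool;
* per AE, its pie share of the pool; pool and pie shares each sum to 100;
* `top_coverage_terms`: the smallest prefix of AEs, sorted by descending
  total count with lexicographic tie-break, whose cumulative share reaches
  the `coverage` parameter (default 0.98);
* the two top-10 drug rankings (by burden and by pool share) and their
  intersection. All ranking ties break deterministically by descending value
  then name, so repeated runs agree exactly.

## 2. Conservation profiling

### The scoring matrix

The raw BLOSUM90 table (integer half-bit log-odds, bundled in NCBI format) is
restricted to the 20 standard residues — the ambiguity and stop rows B/Z/X/*
of published files are dropped **before** the extremes are taken — and then
rescaled linearly so the 20×20 table spans exactly [0, 1]. For the bundled
table the raw extremes are −6 and +11 (the W–W diagonal), so a perfectly
conserved tryptophan scores 1. Restricting to the 20×20 core before
normalization is a deliberate choice that makes the rescaling reproducible
across matrix file dialects. Two fixed scores sit outside the table: a gap
aligned against a residue (an insertion or deletion in either sequence)
scores −0.5, and a gap aligned against a gap scores 0. Terminal gaps are not
treated specially. The linear rescale is affine, hence order-preserving,
which the suite checks on random symmetric matrices.

### Track scoring and the domain split

Alignments are consumed, never computed: the package reads aligned FASTA with
`SUBUNIT|SPECIES|ACCESSION` headers, one file per subunit, each with exactly
one human reference row. Every non-human row is compared column-by-column to
the same-subunit human reference (never cross-subunit), producing a score
track of length equal to the alignment width where each value is a table
entry, −0.5 or 0.

Columns are split into ECD and non-ECD parts on the **human** sequence: a
column is ECD when the human residue at or before it has position
≤ `ecd_end` (the residue before TM1, taken from the annotation file). Gap
columns inherit the label of the nearest preceding human residue and leading
gaps count as ECD, since the split is defined on the human sequence only.

### Anchored coordinates

Because subunit alignments have different lengths, ECD positions are made
comparable by anchoring: ECD columns of the reference subunit (GABRR1 by
convention, as the longest subunit; if absent, the longest supplied human
sequence is used and reported) are numbered 1..n, and every other alignment
is shifted by the integer offset that places its cys-loop second cysteine —
a residue conserved across the whole receptor superfamily — at the
reference's anchor number. Non-ECD columns are renumbered from 1 in every
alignment independently. Columns where the human row is gapped (insertions in
the non-human sequence) keep their alignment-column numbering within the
part; they are plotted, not skipped. Annotation coordinates are human
1-based inclusive sequence positions throughout, matching biologists' segment
tables; alignment columns are 1-based.

### Segment summaries

Segments (loops A–G, TM1–TM4) are converted to alignment column ranges via
the human row, including interleaved gap columns; the per-segment mean and
minimum are taken over columns where at least one of the two rows has a
residue (dual-gap columns carry no signal for the pair). Output rows follow
the canonical order A..G, TM1..TM4.

## 3. Synthetic data: what it emulates and what it does not

`simulate_reports()` draws one multinomial of size N over the drug × term
grid with cell probabilities proportional to `p_i q_j λ_ij`: independence
background (λ = 1) with multiplicatively spiked pairs. `simulate_orthologs()`
copies a human reference and applies, per position, a segment-specific
substitution probability (replacements drawn from a softmax over the raw
BLOSUM90 row, identity excluded — cheap, biochemically plausible, and
sufficient for recovery tests, in place of a full Markov substitution model)
and an indel probability (equal odds of deleting the residue or inserting one
uniform-random residue after it). The simulation knows the true homology, so
the emitted alignment is exact. Generators are pure functions of
(config, seed); the caller's RNG stream is saved and restored.

What passing the recovery tests therefore shows: the pipeline detects
multiplicative reporting signals of the designed strength on an independence
background, and the score tracks rank segment divergence correctly. What it
does **not** show: behaviour under real FAERS features deliberately not
modelled — duplicated and incomplete reports, drug-name synonymy,
co-reporting correlations between drugs or between terms, secular reporting
trends — nor under real phylogeny (correlated substitutions, alignment
errors from the external aligner, segment-length variation).

### Study conditions used by the tests and the acceptance script

* Signal recovery: N = 100,000 reports, 50 drugs × 40 terms with uniform
  margins, 10 pairs spiked at λ = 8. Expected spiked pair counts are ≈ 390,
  so recovery of ≥ 9/10 with ≤ 1% null retention is robust; repeated-seed
  checks during design gave 10/10 and 0% across all seeds tried.
* Independence calibration: a 10 × 8 grid at N = 200,000 gives pair counts
  ≈ 2,500, so |PRR − 1| < 0.2 holds with a wide margin for pairs with
  a ≥ 50; on tables built with exact product margins PRR equals 1 to machine
  precision.
* Conservation recovery: a 1,800-residue reference split into 12 equal
  segments with substitution rates 0 to 0.55; 150 positions per segment keep
  the binomial noise on per-segment means small enough that the Spearman
  correlation between mean score and true rate is below −0.9 for every seed
  tried during design. (Twelve generic segments are used here because the
  recovery property needs more rate levels than the eleven named segments
  provide.)
* The fixture bundle: one 120-residue subunit with loops A–G and TM1–TM4
  annotated, three species with loop-graded substitution rates, and a
  5,000-report 10 × 8 table with two pairs spiked at λ = 8 (expected
  a ≈ 425), calibrated so the spiked pairs are retained with large margin.

These sizes run in seconds and are stated here as the package's chosen,
fixed study conditions.

## 4. Numerical and design choices

* Degenerate inputs are hard errors with named context: asymmetric or
  incomplete matrices, constant matrices (normalization undefined), unknown
  residues (with the offending column), `ecd_end` outside the human
  sequence, anchors that are not cysteines, empty term groups, empty
  retained sets, duplicate (drug, model) hit rows.
* Undefined PRR (c = 0 or an empty drug margin) is `NA`, never infinity, and
  never retained.
* Drug-name matching across evidence sources in the red-flag report is exact
  after case-folding and whitespace trimming; fuzzy joins are avoided because
  silent mismatches corrupt pharmacovigilance output. A drug is dual-source
  flagged iff it has a PV alert and at least one in-silico model hit — the
  hit table is consumed as data (the profiler that produces it is out of
  scope).
* `run_all()` writes every output table as TSV and a JSON manifest listing
  each file with its MD5 hash, the seed and all parameters; re-running with
  the same config and seed reproduces every hash, with the timestamp as the
  only varying manifest field. Figures are opt-in (`make_plots = TRUE`); the
  hashed tabular outputs are the primary artifact. A failing stage aborts
  with a stage-named error and leaves a `FAILED` marker naming the stage.
* One YAML config file with per-stage sections is the single source of truth
  for a run; the fixture bundle writes one that refers to its own files by
  relative path.

## 5. Known limitations

* The IC025 approximation is the standard two-term credibility expansion; it
  is accurate for moderate counts but not identical to a full posterior
  interval at a ≤ 2.
* The burden denominators assume the drug margin (a + b) of the input table
  is the drug's complete report total; restricting the input to a term group
  before tabulation would change that meaning.
* The anchoring requires the cys-loop second cysteine to be present and
  alignable in every subunit's human row; a subunit whose anchor falls in a
  human gap column is rejected rather than guessed.
* No MedDRA traversal, drug-name normalization, case deduplication or
  external-database retrieval: inputs are taken as curated.
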
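# seizurescope

Desk-scale R implementation of the two computational procedures behind a
GABA<sub>A</sub>-receptor seizure-liability screen:

1. **Pharmacovigilance signal detection.** From spontaneous-report tables
   (record-level or pre-aggregated drug × adverse-event counts) it builds the
   2×2 contingency table for every drug–AE pair, computes the proportional
   reporting ratio and the shrinkage information component with its 95%
   credibility lower bound,

   PRR = (a/(a+b)) / (c/(c+d)),
   IC = log₂((a+0.5)/(E+0.5)) with E = (a+b)(a+c)/N,
   IC025 = IC − 3.3 (a+0.5)^(−1/2) − 2 (a+0.5)^(−3/2),

   retains pairs with PRR ≥ 2, IC025 > 0 and a ≥ 5 reports, restricts them to
   a seizure term group, and summarizes the burden: per-drug seizure-AE
   fraction (a / drug total reports × 100), per-drug share of the retained
   seizure-record pool, the smallest AE set covering ≥98% of records, and the
   intersection of the two top-10 drug rankings.

2. **Cross-species subunit conservation profiling.** It normalizes BLOSUM90
   linearly to [0, 1] (gap-vs-residue scored −0.5, gap-vs-gap 0), scores every
   alignment column of each non-human ortholog against the same-subunit human
   reference, splits columns into extracellular (ECD) and non-ECD parts on the
   human sequence, anchors the ECD coordinates of all subunit alignments at
   the cys-loop second cysteine of a reference subunit (GABRR1 by convention,
   the longest sequence), renumbers non-ECD columns from 1, and summarizes
   conservation per annotated segment (binding-site loops A–G, TM1–TM4).

A synthetic-data module generates both kinds of input with known ground truth
(spiked drug–AE pairs; per-segment substitution/indel rates), and `run_all()`
drives simulate → conservation → signals → burden → red-flag integration with
a hashed run manifest.

It is aimed at drug-safety and molecular-pharmacology researchers who want a
tested, reproducible re-implementation of these steps on their own FAERS-style
extracts and ortholog alignments.

## Worked example

```r
library(seizurescope)

tbl <- report_table(data.frame(
  drug    = c("amoxapine", "amoxapine", "diazepam", "diazepam"),
  ae_term = c("Seizure", "Nausea", "Seizure", "Nausea"),
  count   = c(30L, 170L, 25L, 4775L)))
sig <- pv_signals(tbl, group = term_group("seizures", "Seizure"))
sig
#> Disproportionality signals: 2 drug-AE pairs, 1 retained (PRR >= 2, IC025 > 0, a >= 5)
#>       drug ae_term  a  prr    ic ic025
#>  amoxapine Seizure 30 28.8 3.498 2.888
```

Amoxapine reports seizures in 15% of its 200 reports versus 0.52% for the
rest of the table, giving PRR = 28.8; the IC credibility bound stays positive,
so with 30 ≥ 5 reports the pair is retained. Diazepam's seizure pair fails the
criteria and is kept only as an unretained row.

```r
sm <- build_scoring_matrix(read_raw_matrix(blosum90_path()))
sm
#> Normalized substitution scoring matrix (BLOSUM90)
#>   20x20 table rescaled from [-6, 11] to [0, 1]
#>   gap vs residue: -0.5;  gap vs gap: 0

aln <- subunit_alignment("GABRA1",
  c("GABRA1|Homo_sapiens|h" = "MKCDE-FG",
    "GABRA1|Mus_musculus|m" = "MKCDEAFG"),
  species = c("Homo_sapiens", "Mus_musculus"),
  human_reference_id = "GABRA1|Homo_sapiens|h")
round(score_track(aln, "GABRA1|Mus_musculus|m", sm)$scores, 3)
#> [1]  0.765  0.706  0.882  0.765  0.706 -0.500  0.765  0.706
```

Matched residues score their normalized substitution value (identities here:
M 0.765, K 0.706, C 0.882, D 0.765, E 0.706, F 0.765, G 0.706); the mouse
insertion opposite the human gap scores −0.5.

The full simulated pipeline:

```r
res <- run_all("out", simulate = TRUE, seed = 1)
res$red_flags   # drugs sorted by flag level; the two spiked drugs carry PV alerts
```

## Command line

A thin wrapper over the package functions ships at
`inst/cli/seizurescope.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","seizurescope.R",package="seizurescope"))')" \
  run-all --simulate --seed 1 --out out
```

Subcommands: `simulate`, `conservation`, `signals`, `burden`, `integrate`,
`run-all`, plus `--version`.
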
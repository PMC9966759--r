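---
title: "Methods: separating mutation pressure from translational selection in codon usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating mutation pressure from translational selection in codon usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cricketcub)
```

## The question

Synonymous codon usage in a genome can be shaped by directional mutation
pressure (and GC-biased gene conversion), by selection for translational
efficiency, or by drift. The analysis implemented here takes a set of
in-frame coding sequences — typically the CDS calls from a de novo
transcriptome assembly of a non-model organism — plus per-gene expression
(FPKM), and asks which force dominates. The logic is the classic one: if
mutation pressure alone acts on third codon positions, per-gene bias should
be a function of GC3 and sit on Wright's expected-ENC curve, and the leading
axis of RSCU variation should be GC3; if translational selection acts, bias
should strengthen with expression, and — decisively — the relative usage of
*GC-conservative* synonymous codon pairs should correlate with expression,
because those pairs are invisible to AT/GC mutation bias.

## The statistics

**RSCU.** For codon $j$ of amino acid $i$ with degeneracy $n_i$,
$\mathrm{RSCU}_{ij} = x_{ij} \big/ \big(\tfrac{1}{n_i}\sum_j x_{ij}\big)$.
Values within an observed family sum to $n_i$; 1 is the no-bias value.
Families absent from a gene are *undefined* (never 0); the 1-fold codons
ATG and TGG are reported as 1 when present and excluded from multivariate
summaries. Pooled genome-level RSCU is computed on summed counts, not by
averaging per-gene values — the two differ whenever gene lengths vary.

**ENC.** Wright's estimator. Per amino acid with $n \ge 2$ counted codons,
the homozygosity $F = (n\sum_j p_j^2 - 1)/(n-1)$; the class means
$\bar F_k$ over the 2-, 3-, 4- and 6-fold families (only defined, positive
$F$ enter a mean — $F \le 0$ occurs at small $n$ and would make the
reciprocal meaningless) give
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
capped at 61. Serine, leucine and arginine are treated as single 6-fold
families (the convention of CodonW's standard table). When isoleucine is
absent, $\bar F_3$ is replaced by $(\bar F_2 + \bar F_4)/2$, Wright's own
fallback; if any other class mean is missing the gene's ENC is undefined
and the gene is excluded from downstream fits, with the count logged in the
run manifest. The mutation-only expectation is
$\mathrm{ENC}_{\exp}(s) = 2 + s + 29/(s^2 + (1-s)^2)$, evaluated on the
standard grid of 1000 GC3 values equally spaced from 0.001 to 1.000. Note
the curve *peaks* at 60.5 near $s = 0.5$ and falls to 31/32 at the
composition extremes. The deviation ratio is
$(\mathrm{ENC}_{\exp} - \mathrm{ENC}_{obs})/\mathrm{ENC}_{\exp}$.

**GC-conservative pairs.** Two synonymous codons differing only at the
third position by A$\leftrightarrow$T or C$\leftrightarrow$G. A brute-force
scan of the standard code yields exactly 17 such pairs (one per A/T and C/G
ending pair in the five 4-fold families and in the CTN, CGN and TCN blocks
of the 6-fold families, plus ATA/ATT of isoleucine). Per pair and gene, the
relative usage $a/(a+b)$ is defined only when the pair occurs; across genes
it is correlated with log expression and a preferred codon is called when
$|r| > 0.05$ and $p < 0.001$ (thresholds configurable).

**Multivariate screens.** PCA on the genes × 59 RSCU matrix, centred but
not variance-scaled (RSCU values already share a scale); undefined entries
are imputed at the neutral value 1, which adds no spurious variance
direction (dropping incomplete genes is available instead). The PC1 sign is
fixed so that PC1 correlates non-negatively with GC3, making score plots
deterministic. The correlation screen tests ENC, PC1 and PC2 against GC3,
$\log_2(\mathrm{FPKM}+1)$, GRAVY (Kyte–Doolittle grand average of
hydropathy), aromaticity, and the first three PCs of the 20-column
amino-acid composition matrix; correlations are Pearson by default
(Spearman via config), pairwise-deleted, with per-pair n and
Benjamini–Hochberg adjusted p-values reported alongside raw ones. Gene
subsets (e.g. chemosensory families) are compared with the unlabelled
background by two-sided Mann–Whitney tests on ENC and GC3 — a rank test
because ENC distributions are left-skewed and bounded.

## Quality filter

Records shorter than 200 bp, with more than 10% N, or with more than one
internal stop codon are removed. Three readings required a decision:

- the N fraction is taken over the whole sequence (the internal/terminal
  distinction is not testable on single records and the simplest reading is
  used);
- an "internal" stop is an in-frame stop strictly before the last complete
  codon — a terminal stop is expected in a complete CDS and never counts;
- sequences whose length is not a multiple of 3 are retained (with a
  warning) and their trailing bases ignored by all codon counting; frame
  truncation is common in transcriptome CDS calls and silent discard would
  bias composition.

Each failing record is tallied once under its first failing rule in the
fixed order short → N → stops, so reports are deterministic.

## The synthetic generator

`generate_dataset()` emulates the data a transcriptome study of this kind
feeds into the analysis. Defaults, chosen once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 1000 | clean CDS count (tests use 200–3000) |
| length law | lognormal, sdlog 0.45, mean 163 codons | mean CDS ≈ 489 bp, matching the target transcriptome's mean of 488.7 bp; minimum 66 residues so clean genes pass the 200 bp filter |
| `gc3_law` | Beta(2, 2) | wide per-gene third-position GC preference, the GC3 gradient real CDS sets show |
| expression | lognormal(1, 1.5) | right-skewed FPKM spanning ~4 orders of magnitude |
| `selection_strength` | 0 | mutation-only regime |
| `preferred_set` | GCC, GGC, ACC, GTG, CTG | one member from each of five GC-conservative pairs (a mix of a- and b-side codons, so sign handling is exercised) |

Codon choice is residue-independent given the gene's parameters: within a
family, third-position G/C codons share probability $s$ and A/T codons
$1-s$; under selection the preferred codons are additionally multiplied by
$e^{\beta z}$, where $z \in [0,1]$ is the gene's *empirical quantile* of
log FPKM. The quantile (rank) definition was chosen over min–max scaling
because the lognormal tails dominate a min–max range and saturate the
usage–expression correlation; with ranks, `selection_strength = 2.5` gives
planted-pair correlations around $|r| \approx 0.4$ at 2000 genes, a clearly
detectable but not caricatured signal. Corrupted records (150 bp clean,
300 bp with 15% N, 300 bp with three internal stops) are appended per
config, each failing exactly one filter rule.

What the generator does *not* emulate: amino-acid composition linked to
GC (positions 1–2 are fixed by the uniform amino-acid profile),
autocorrelated codon choice along a gene, isoform redundancy, assembly
chimeras, or any coupling between expression and GC3. Passing tests
therefore show that the statistics behave correctly when their assumptions
hold and that the null is calibrated — not that real transcriptomes are
this clean. A real-data caveat to keep in mind: because amino-acid usage is
uniform here, realised GC3 regresses on the true preference with slope
slightly below 1 (ATG and TGG contribute fixed G-ending codons).

## Numerical choices and degenerate inputs

- Codon counting skips codons containing N; a gene with no countable codon
  is an error.
- Dinucleotide expected frequencies use the marginals at the junction's own
  positions; junction 3–1 never pairs across gene boundaries; a zero
  expected frequency yields an NA ratio with a warning, never an infinity.
- ENC values above 61 (sampling noise) are capped at 61.
- PCA of rank-deficient matrices is fine: components beyond the rank get
  variance fraction 0.
- Correlations with fewer than 3 complete pairs, or against a constant
  vector, are reported as undefined rather than dropped silently.
- All tables are written as TSV with deterministic row order; re-running a
  pipeline config on the same inputs reproduces every TSV byte-for-byte.

## Validation problem sizes

The test-suite simulations use 200–2000 genes per dataset: 500 genes for
the RSCU/ENC oracle-equivalence check (against independent from-definition
implementations, agreement to 1e−9), 1000 genes for the expected-ENC curve
geometry and PC1–GC3 coupling ($R^2 > 0.9$), 50 replicates of 2000 genes
for the null false-call rate of the preferred-codon screen, and 20
replicates of 2000 genes for planted-signal recovery. These sizes put the
Monte-Carlo error of each checked quantity well inside its assertion band
while keeping a full run in tens of seconds.

## Known limitations

- No codon adaptation index, tRNA adaptation index, or tRNA-abundance
  modelling; the expression screen is the only selection probe.
- The pooled composition convention weighs genes by length; per-gene tables
  are exposed for the alternative convention.
- Display thresholds for "preferred"/"avoided" codons in the pooled RSCU
  table (1.5/0.5, and the milder 1.25/0.75) are conventions from the
  literature, exposed as configuration and not used for inference.
- The subset comparison treats genes as independent; paralogous family
  members violate this mildly.
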
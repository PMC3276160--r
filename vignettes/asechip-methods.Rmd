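---
title: "aseChip: models, design rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aseChip: models, design rules and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseChip)
```

This vignette is the package's own account of the science it
implements: the probe-design rules, the signal model, the statistical
tests and their assumptions, the choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The measurement problem

In an F1 heterozygote of two inbred strains, both alleles of a gene are
exposed to the same trans-acting environment, so unequal allelic
expression (allelic imbalance, AI) is evidence for cis-regulatory
variation. An allele-discriminating array measures this with SNP probe
sets, but two biases stand in the way:

* **probe-affinity bias** — the PM1 and PM2 probes are different
  25-mers and hybridize with different efficiency even at a 1:1 target
  ratio;
* **nonspecific background** — signal a probe would show with no
  matching target at all, which depends strongly on the probe's G+C
  content.

The workflow counters the first with a genomic-DNA hybridization of the
same heterozygote (a known 1:1 allele ratio, so its PM1−PM2 difference
is pure affinity bias) and the second with GC-bin background controls.

## Probe design

Coordinates are 0-based and half-open throughout. A SNP at reference
position $p$ owns the design window $[p-17,\,p+18)$: 35 reference-strand
bases with the SNP at the center.

SNP candidates come from a per-column scan of a multiple sequence
alignment; a column qualifies when it shows at least two distinct
non-gap bases. Rows with a gap at the column contribute neither an
allele nor support. Candidates are then discarded (with recorded flags,
never silently) when:

* support < 5 sequences (`low_support`);
* more than two alleles (`multiallelic`) — only biallelic SNPs proceed;
* another candidate lies within 17 bases (`multi_snp_window`) — the
  window would contain a second SNP and the local alignment is suspect;
* the window maps to more than one genomic location (`multi_map`).

Genome-wide uniqueness cannot be decided from an alignment alone, so
the multi-map rule delegates to a caller-supplied *uniqueness oracle*
mapping a 35-mer to its genome hit count; the default assumes
uniqueness, and a BLAST-backed oracle can be plugged in without
changing the interface. A gapped reference at the SNP column
(`unresolvable`) and windows truncated by the region edge
(`window_truncated`) are likewise flagged and failed.

Each passing candidate yields **24 probes**: 25-mers with the SNP base
at offsets −4, 0 and +4 from the probe center, on both strands, with
each of A/C/G/T substituted at the SNP site. A probe whose SNP base
(mapped to the forward strand) equals the first or second design allele
is a perfect-match probe (PM1 or PM2, 6 each); the other 12 are
mismatch (MM) probes, which carry no allele information but serve the
models below as error-degree-of-freedom carriers and
cross-hybridization sentinels.

### Probe quality heuristic

The original platform scored probes with a proprietary hybridization
model. The package's scorer is a documented, reproducible stand-in with
the same discard semantics: a weighted penalty sum (weights 0.5 / 0.25 /
0.25 by default) of

1. deviation of the Wallace-rule melting temperature
   $T_m = 2(A{+}T) + 4(G{+}C)$ (°C) from the probe-set median, scaled
   by 16 °C;
2. the longest substring shared with the probe's own reverse complement
   (hairpin/self-dimer proxy), scaled by 12 bases;
3. the longest homopolymer run, scaled by 6 bases;

subtracted from 1, so quality lives in $[0, 1]$ with higher = better. A
probe set is eliminated when any probe has a homopolymer run ≥ 6
(configurable; no threshold is standard in array design, and 6 is the
shortest run that is clearly synthesis- and hybridization-hostile for
25-mers), when any probe carries a non-ACGT character (the proxy for
"cannot be synthesized"), or when $\lceil 24/3 \rceil = 8$ or more
probes score below the poor-hybridization threshold (0.5) — the
"one third or more" rule, applied inclusively at the boundary.

### Per-gene selection

Genes with seven or fewer surviving probe sets contribute all of them;
genes with more contribute a uniform random seven, and leftover array
capacity is filled by a uniform random draw from the remainder. Both
draws are seeded, so selection is reproducible; the guarantee is
applied *after* quality filtering (the alternative order is not
implied by anything in the design and would let guaranteed slots be
consumed by probe sets that are then discarded).

## Signal model

Probes are assigned to GC bins by their G+C count clamped to the
control range $[3, 24]$. All background statistics are computed per
sample: hybridization efficiency varies chip to chip, and a pooled
background would leak between-array variation into every downstream
test.

* **Detection above background (DABG):** a probe is detected when its
  intensity is *strictly* greater than the median of its GC bin's
  control probes in that sample. Fractions are reported per sample,
  overall and per module.
* **Summarization:** per probe set $i$ and sample,
  $$Y_i = \ln\!\Big(\tfrac{1}{N_i}\sum_j (X_{ij} - GC_j) + 100\Big),$$
  with $X_{ij}$ the raw probe intensity, $GC_j$ the background value of
  probe $j$'s bin, and $N_i$ the number of probes. The natural log and
  the +100 offset are used exactly as stated; no further variance
  stabilization is applied. Grouping is per probe set, or per allele
  class (PM1/PM2/MM within each SNP probe set) — the allele-class form
  feeds the AI model's six treatment levels.

Two places where the upstream description is ambiguous, resolved here
as configuration rather than hidden choices:

* the background value $GC_j$ is the per-bin control **mean** by
  default (matching the formula's definition) with a **percentile**
  option (e.g. the 5th percentile, matching the narrative description
  of the correction); both are exposed because the source material
  states both;
* a nonpositive log argument (possible when background exceeds signal
  by more than the offset) is clamped to a configurable epsilon
  (default $10^{-6}$) and counted; the count is carried on the result
  object as a data-quality signal.

## Statistical tests

All per-unit tests produce F statistics with their degrees of freedom
and Benjamini–Hochberg q-values (`stats::p.adjust`; the step-up
procedure is also verified against a hand implementation in the test
suite). Degenerate zero-residual-variance fits — legitimate for
noiseless synthetic input — are flagged rather than erroring, with
p = 0 when the effect is nonzero and p = 1 otherwise.

**Sex bias.** Per probe set over the RNA arrays of one genotype:
$Y = \mu + \text{sex} + \varepsilon$, classical one-way ANOVA F. With a
single genotype, probe–target polymorphism affects both sexes equally
and cancels from the comparison. Counts and percentages are reported at
FDR 0.05/0.1/0.2 with the male-/female-higher split.

**Cross-module agreement.** Gene-level significance calls from two
modules are cross-tabulated; Cohen's kappa and McNemar's test quantify
agreement and asymmetry. McNemar is computed *without* continuity
correction, $\chi^2 = (b-c)^2/(b+c)$ — the only variant consistent with
the reference worked value reproduced in the tests. A gene's
exon-module call aggregates its constitutive probe sets by an "any
significant" rule (default) or a majority rule; the comparison
threshold defaults to FDR 0.1.

**Isoform usage.** Per gene over its exon probe sets:
$Y = \mu + x + s + xs + \varepsilon$ with $x$ the exon type
(constitutive exons pooled as one type, each alternative exon its own
type) and $s$ sex. The interaction is the signature of sex-specific
isoform usage. The residual variance is estimated separately for each
sex from within-cell replicates; the interaction is tested by a
weighted Wald F on the cell means with inverse-variance weights and a
Satterthwaite denominator df (per-contrast dfs averaged across the
interaction contrasts). No specific heteroscedastic estimator is
canonical here, so this documented choice was selected for two
verifiable properties, both asserted in the tests: it reduces
*exactly* to the ordinary two-way ANOVA interaction F when the per-sex
variance estimates coincide, and it holds the type-I error near nominal
under strongly unequal sex variances, where the pooled test would not.
A plain two-way ANOVA mode is provided for comparison.

**Allelic imbalance.** Per SNP probe set over the F1 arrays, on
allele-class signals: $Y = \mu + s + t + \varepsilon$ with six
treatment levels $t$ (DNA/RNA × PM1/PM2/MM) and the single-df contrast
$$(\text{RNA.PM1} - \text{RNA.PM2}) - (\text{DNA.PM1} - \text{DNA.PM2}).$$
The contrast estimate is the log-scale AI effect with probe-affinity
bias removed. MM cells carry zero contrast weight but stay in the model
as error df — the model is fit over all six levels. The residual
variance is pooled across cells and sexes (nothing in the design
suggests otherwise for the combined analysis). Because the gDNA arrays
are female-only in the reference design, the sex effect is estimable
from the RNA rows alone; the fit performs a rank check and names
aliased cells on failure. Sex-stratified analyses use each sex's RNA
arrays plus the shared gDNA baseline, with the sex term dropped; a
sex × AI interaction test is deliberately not part of the headline path
(at n = 3 replicates per cell its power is poor) but the per-sex tables
make sex differences visible.

**Genotype calling.** Within a SNP probe set, each base's signal is the
mean over the probes representing that base — both strands and all
offsets, with reverse-strand probes counted toward the complement of
their own-strand base, since alleles are defined on the forward strand.
Averaging happens on the normalized log scale by default (a raw-scale
option exists; the choice is not decidable from the source material and
the log scale matches the rest of the pipeline). Bases are ranked by
signal; ties are broken by the fixed order A < C < G < T and flagged.
Concordance reports compare top-1 calls to a homozygous truth or top-2
calls to a heterozygous allele pair, overall and per base. Fisher LDA
(with an optional ridge on the within-class scatter for singular cases)
checks that genotype classes separate; the implementation is
cross-checked against an established LDA in the test suite.

## The synthetic-data generator

The generator exists so that every pipeline stage can be tested against
known truth. It is additive on the natural-log scale — the scale of the
summarization formula — so planted effects are directly recoverable:

$$\log X = \underbrace{b_0 + b_1 \cdot GC}_{\text{background curve}}
 + \underbrace{a_p}_{\text{probe affinity}}
 + \underbrace{\mu_g + \beta_{\text{sex}}}_{\text{expression}}
 + \underbrace{\log f_{\text{allele}}}_{\text{allele fraction}}
 + \underbrace{m}_{\text{match}}
 + \varepsilon$$

with intensities exponentiated and GC-bin controls drawn from the same
background curve. The allele fraction $f$ is 1 for a homozygous target,
½ each for heterozygous DNA, and logistic-shifted by the planted AI
effect $\delta$ in heterozygous RNA
($f_{\text{PM1}}/f_{\text{PM2}} = e^{\delta}$), so the AI contrast's
estimand equals $\delta$ by construction. Probes for a base the sample
does not carry (including all MM probes) are damped by a
cross-hybridization factor (default 2 log units). Probe affinities are
drawn once and shared across samples — exactly the bias the gDNA
control cancels, and the generator's noiseless DNA arrays verify that
cancellation property directly in the tests.

Default study conditions mirror the reference verification design:
3 RNA replicates per sex of the F1 (6 RNA arrays) and 3 female gDNA
replicates each of the two parents and the F1 (9 gDNA arrays); noise SD
0.2 on the log scale, affinity SD 0.3, expression well above background
(mean log level 8.5 against a background intercept of 3) as in a
successful hybridization.

Two deliberate simplifications, and their consequences:

* **No hybridization thermodynamics or scanner artifacts.** Signals are
  log-normal around the structural model. Passing tests therefore show
  the *statistical machinery* behaves as designed (bias cancellation,
  calibration, power, recovery), not that the heuristics would survive
  every physical artifact of real chips.
* **Class-size heteroscedasticity in round trips.** Allele-class
  signals average 6 (PM) or 12 (MM) probes, so probe-level noise leaves
  PM cells with higher variance than MM cells, and the pooled-variance
  F of the AI model becomes slightly anticonservative in full
  probe-level round trips. The type-I calibration checks are therefore
  run at the signal level, where the model's own error assumptions
  hold; probe-level round trips are held to estimate-recovery criteria
  (mean contrast within 0.05 of a planted δ = 0.8), which are robust to
  this. The same caveat applies to real arrays, where it is one of many
  departures from the homoscedastic ideal absorbed by the FDR-level
  interpretation of the results.

The generator also offers signal-level shortcuts
(`simulate_expression_signal`, `simulate_isoform_gene`,
`simulate_ai_signal`) that skip the probe layer and plant effects
directly in probe-set signals — the right granularity for calibration
studies of the statistical tests themselves.

## Numerical choices and problem sizes

* Tolerances: oracle agreement for ANOVA/contrast is asserted to
  1e−10; the homoscedastic limit of the interaction test to 1e−6;
  exact algebraic identities (signal recombination, shift invariance)
  to near machine precision.
* Noiseless AI round trips through the full probe pipeline are asserted
  to 1e−3, not machine precision: the +100 offset inside the log leaves
  a level-dependent remainder of order $100/\text{signal}$.
* Degenerate inputs: zero-variance fits are flagged, not errors; empty
  GC bins and missing DNA baselines are errors naming the bin/issue;
  B = C = 0 makes McNemar undefined and it is reported as `NA`.
* Seeds: every stochastic routine takes an explicit seed and restores
  the caller's RNG state.
* Simulation sizes used by the test suite and the acceptance script —
  500 probe sets for power/recovery studies, 1000 for genotype
  concordance, 2000 for type-I calibration — were chosen to put
  Monte-Carlo error comfortably inside the asserted bands
  (binomial SE ≈ 0.005 at rate 0.05, n = 2000).

## Known limitations

* The probe-quality scorer is a stand-in: it reproduces the discard
  *semantics* (homopolymers, unsynthesizable probes, the one-third
  rule) but not any particular proprietary score, so probe sets kept or
  discarded near the quality threshold can differ from any specific
  commercial design.
* The multi-map filter is only as good as the supplied uniqueness
  oracle; the default (assume unique) is correct for the synthetic
  round trips but permissive for real genomes.
* Exon classification derives each gene's isoform universe from the
  union of its probe sets' memberships; exons absent from every probe
  set cannot be seen, so a truly constitutive exon can be classified
  alternative if the annotation table is incomplete.
* The AI model treats allele-class signals as homoscedastic
  observations (see above); and with DNA arrays from one sex only, the
  pooled sex effect rests on the RNA rows — both are properties of the
  reference design, not removable by the implementation.
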
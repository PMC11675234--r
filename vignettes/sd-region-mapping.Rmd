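---
title: "Mapping a sex-determination region and building PCR sex markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a sex-determination region and building PCR sex markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdscan)
```

## The problem

A species with genetic sex determination but no visibly differentiated
sex chromosomes can still be sexed molecularly: in the heterogametic
sex, sites inside the non-recombining neighbourhood of the
sex-determination (SD) locus are systematically heterozygous, while
the homogametic sex is homozygous there. Given a panel of resequenced
individuals of known gonadal sex, three questions follow in order:

* which heterogamety system operates (XX/XY male-heterogametic or
  ZZ/ZW female-heterogametic),
* what genomic interval co-segregates with sex,
* whether the interval contains an indel large enough to type cheaply
  by PCR band size on an agarose gel.

`sdscan` answers all three from a VCF and a phenotype table, and adds
the k-mer genome-size arithmetic used when the reference assembly for
such a study is built.

## Statistical machinery

### Concordance scores

For a biallelic site with genotype $g_i \in \{\text{hom-ref},
\text{het}, \text{hom-alt}\}$ in individual $i$, the XY concordance is

$$C_{XY} = \frac{\#\{\text{males het}\} + \#\{\text{females hom}\}}
{n_{\text{used}}},$$

where "hom" accepts either homozygote — a deliberate choice, since
restricting to hom-ref would make the score depend on which allele the
reference assembly happens to carry — and missing genotypes leave both
numerator and denominator. $C_{ZW}$ is the mirror with sexes swapped,
and the identity $C_{ZW}(\text{data}) =
C_{XY}(\text{sex-swapped data})$ is enforced by a property test.

A site "supports" a system when its score strictly exceeds the
`threshold` of `scan_config()` (default 0.90: *over* 90% consistency,
so at the default panel size of 38 this requires at least 35 of 38
matches — asserted combinatorially in the tests). The system is called
when the winning side has at least `min_snps` (default 5) supporters
*and* more than `majority_factor` (default 2) times the other side's
count; the 2× majority prevents a coin-flip call on noisy panels and
is exposed in the configuration. The region is the min–max envelope of
supporting SNPs on their majority chromosome after merging runs
separated by at most `max_gap` (default 1 Mb) and keeping the run with
the most supporters; supporters elsewhere are reported as outliers,
never silently dropped. The envelope rule is intentionally the
simplest one consistent with reporting an interval "between its first
and last concordant SNP"; density-based refinements are out of scope.

### Allelic association

The association scan is the basic case/control allelic test: each
non-missing diploid genotype contributes two allele observations to
its sex's row of a 2×2 table, and the uncorrected Pearson statistic

$$\chi^2 = \frac{N (ad - bc)^2}{r_1 r_2 c_1 c_2}$$

is referred to the 1-df upper tail. No covariates, no continuity
correction, no mixed model — the allelic test is what a default PLINK
association run computes, and with a phenotype as discrete as sex and
a fully penetrant sex-linked region, anything fancier only costs
power at n = 38. Degenerate tables (any zero margin — monomorphic
sites are routine) return $\chi^2 = 0$, $p = 1$ rather than erroring,
so a genome scan never halts. Multiple testing is handled with a
Bonferroni line $\alpha/m$ only; no FDR machinery is provided because
the regionally clustered, fully linked signal this scan targets does
not call for it.

The test statistic is verified two ways: against the expected-count
form $\sum (O-E)^2/E$ on an exhaustive sweep of small tables, and
against a label-permutation oracle on simulated genotypes (Spearman
rank agreement of p-values).

### Hard filtering

Filtering follows GATK hard-filter semantics exactly: a site passes
when every *present* annotation satisfies its strict inequality
(QD > 2.0, MQ > 40.0, FS < 60.0, ReadPosRankSum > −8.0,
MQRankSum > −12.5). Two conventions matter and are fixed
deliberately:

* equality fails — the kept set is defined by strict inequalities, and
  a deterministic boundary rule is required for reproducibility;
* an absent annotation passes that sub-filter — rank-sum annotations
  are undefined at sites without heterozygotes, and treating absence
  as failure would systematically remove exactly the homozygous-only
  sites a concordance scan needs to see. Absent is therefore `NA`,
  never 0.

### In-silico PCR and marker assays

A PCR product is declared where the forward primer matches the
template exactly and the reverse complement of the reverse primer
matches exactly downstream on the same strand; both strands are
searched and all occurrences reported. Product length is counted
inclusively from 5' end to 5' end, i.e. primers are part of the
amplicon — the convention under which gel sizes are reported and under
which the Y product exceeds the X product by exactly the insertion
length. Matching is exact (0 mismatches) so the operation is
deterministic; a mismatch allowance would need a thermodynamic model
(melting temperature, dimers) that is explicitly out of scope.

Band patterns map to sex calls as on a gel: under XY, both products =
male, X product only = female, anything else (no bands, Y-only,
unexpected sizes) = `no_call`. Accuracy is `correct / scorable`;
no-calls are excluded from the denominator but always reported, and
the full confusion matrix is emitted so either accounting can be
recomputed.

### k-mer genome size

Genome size is estimated as total k-mer instances divided by the
homozygous coverage peak, rounded half away from zero (half-up
reproduces the printed values of the reference arithmetic in every
rounding direction; base R's round-half-even does not in general).
Peak detection uses a first-local-minimum rule: scanning depths in
ascending order, the first rise in counts marks the error/signal
valley and the peak is the maximal count above it. Dedicated k-mer
tools fit full mixture models (heterozygous and repeat components);
that modelling is deliberately not reproduced — only the size
arithmetic is, with the valley rule sufficient at desk scale. A
monotonically non-increasing histogram has no diploid peak and is an
error, not a guess. Single-copy integration bounds are not modelled at
all: the single-copy size is an input, and only the ratio (rounded
half-up to 3 decimals) is computed.

## The synthetic panel

`sim_config()` defines a desk-scale replica of a real resequencing
study at 1/100 physical scale: 18 males and 20 females, 24
chromosomes of 300 kb, an SD region at `chr9:197400-226000` (the
19.74–22.60 Mb interval scaled down) centred on an SD locus at
211.7 kb, with the `ZW` option mirroring all sex roles.

The generative model, per site:

* **sex-linked SNPs** (uniformly placed in the SD region): a
  heterogametic individual is het with probability
  $f(d)\,(1 - e_m)$, where $f(d) = e^{-d/\lambda}$ is the linkage
  fidelity at distance $d$ from the SD locus, else hom-ref; a
  homogametic individual is hom-ref with probability $1 - e_f$, else
  het. The expected concordance
  $[n_m f(d)(1-e_m) + n_f(1-e_f)]/(n_m+n_f)$ is checked against
  simulation in the tests.
* **marker indels**: two Y-linked insertions (18 bp and 14 bp) inside
  amplicons whose primer pairs are the published MFS-1/MFS-2
  sequences; they are fully sex-linked ($f = 1$) but still subject to
  genotyping error and missingness.
* **autosomal SNPs**: Hardy–Weinberg draws at a minor-allele
  frequency uniform on `maf_range`.
* every call is independently missing with probability `missing_rate`;
* site annotations come from a two-component model: a well-behaved
  draw comfortably inside each filter threshold, or (with probability
  `annotation_fail_rate` per field) a draw beyond it, so filtering has
  real work to do on every criterion.

Parameter defaults and their rationale:

| parameter | default | why |
|---|---|---|
| `n_males`, `n_females` | 18, 20 | the study panel composition |
| `sd_region` | 197.4–226.0 kb on chr9 | 19.74–22.60 Mb at 1/100 scale |
| `decay_length` λ | 200 kb | keeps $f \ge 0.93$ across the region, matching the observed pattern of >90%-concordance SNPs tiling the whole mapped interval (recombination suppression around SD loci), while still decaying measurably |
| `male_error`, `female_error` | 0.02 | typical genotype-call error at ~9× short-read coverage |
| `missing_rate` | 0.03 | typical post-calling missingness at that depth |
| `maf_range` | (0.05, 0.5) | post-filter variant sets exclude rare variants; keeps allele-count cells large enough for the asymptotic chi-square null at 2N = 76 |
| `n_sex_linked_snps`, `n_autosomal_snps` | 60, 500 | sparser than a literal 1/100 SNP-density scaling; per-site statistics are unaffected by density and runs stay instant |
| `annotation_fail_rate` | 0.03 | ≈14% of sites fail at least one of five criteria — visible attrition without starving downstream stages |

All randomness flows from the mandatory `seed`: `build_reference()`
consumes the stream seeded with `seed` and `simulate_genotypes()` the
stream seeded with `seed + 1`, so one reference layout can be reused
across many genotype draws (this is how the repeated-panel tests
define "100 seeds of the default panel"). Identical seeds give
byte-identical output files.

### What the generator does and does not emulate

It reproduces the statistical structure the scans consume: concordance
decaying with distance, HWE background, error/missingness, filterable
annotation values, sex-linked amplicon indels. It does **not** emulate
reads or alignment (no FASTQ, no mapping bias), linkage disequilibrium
between sites (sites are conditionally independent given sex),
coalescent population structure, allele-frequency spectra, or
annotation values correlated with genotype quality. Passing tests on
this panel therefore demonstrate that the *computations* are correct
and calibrated under the study's sample sizes — not that the pipeline
is robust to alignment artefacts or population stratification in real
data.

## Numerical choices and degenerate inputs

* Intervals are 1-based inclusive everywhere; BED export is the only
  0-based half-open surface.
* Genotypes are alt-allele doses 0/1/2 with `NA` for missing;
  heterozygote parsing is phase- and order-insensitive, and genotypes
  touching alt alleles beyond the first are set missing (biallelic
  first-alt policy; such sites are flagged `multiallelic`).
* Concordance at a site with no non-missing genotype is `NA` and the
  site is skipped, not scored 0.
* Region calling with fewer than `min_snps` supporters is an error —
  a region from 1–2 SNPs would be an envelope of noise.
* Rounding: genome sizes half-up to 1 bp, proportions half-up to
  3 decimals.
* Peak detection ties (equal counts above the valley) resolve to the
  smaller depth via `which.max`.
* Chi-square on tables with any zero margin: 0 with p = 1.
* Test problem sizes were chosen so the whole suite runs in about two
  minutes: repeated-panel checks use 100 genotype seeds over one
  reference, the null calibration uses 10 panels of 10,000 autosomal
  sites (1e5 site-tests), and oracle sweeps use exhaustive small
  tables plus 100 random sequences.

## Limitations

* The concordance scan assumes full penetrance of genetic sex; sex
  reversal or mis-sexed gonads appear as score depression, not as a
  modelled term.
* The allelic test is asymptotic; at very low minor-allele counts its
  null is discrete and conservative. The simulator's MAF floor keeps
  it calibrated, but real rare variants should be interpreted with
  that in mind.
* In-silico PCR with exact matching will miss primers that anneal
  with mismatches in vivo; product-size prediction is exact only under
  the inclusive-of-primers length convention.
* The region envelope depends on the outermost supporting SNPs; with
  sparse high-fidelity SNPs near the region edges the called interval
  shrinks toward the centre.
* Gene-level interpretation (which candidate gene sits at the centre
  of the region) requires an external annotation and is outside the
  package's scope.
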
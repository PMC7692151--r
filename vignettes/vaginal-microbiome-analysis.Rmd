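---
title: "Compositional and quantitative analysis of AV/BV/reference vaginal microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional and quantitative analysis of AV/BV/reference vaginal microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagcomp)
```

## The problem

Aerobic vaginitis (AV) is an inflammatory vaginal condition that is easily
confused with bacterial vaginosis (BV) although the two differ sharply in
their microbiology: BV is a high-load anaerobic overgrowth, while AV
combines inflammation and epithelial thinning with a *depleted* bacterial
community of heterogeneous composition. Characterising AV therefore needs
two complementary measurements: *relative* community composition from 16S
rRNA amplicon sequencing (ASV-level count tables), and *absolute* bacterial
and human-cell concentrations from qPCR. vagcomp implements the analysis
layer for such three-group cohorts — an ANCOM-style compositional
differential-abundance test, standard-curve qPCR quantification with
non-detect handling and bacteria-to-human load ratios, and the cohort-level
summaries used to describe such data — together with a synthetic-cohort
generator that provides full ground truth, so every stage of the pipeline
can be validated by parameter recovery rather than by eye.

## The differential-abundance model

Relative abundances are compositional: an increase of one taxon forces
apparent decreases elsewhere, so taxon-wise tests on proportions are
confounded. The ANCOM strategy avoids this by working on log ratios. For
every ordered pair of taxa $(t, r)$ and sample $s$ we form

$$\ell_{s,t,r} = \log\frac{c_{s,t} + \delta}{c_{s,r} + \delta},$$

with counts $c$ aggregated to the tested rank (genus by default) and a
pseudocount $\delta = 1$ added *after* aggregation to avoid division by
zero. Library size cancels in the ratio, so up to the pseudocount the
statistic is identical on counts and on relative abundances. For each taxon
pair the per-sample log ratios are compared between the two groups with a
two-sided Wilcoxon rank-sum test (exact when both groups have at most 25
samples and the pooled values are tie-free; normal approximation with tie
and continuity correction otherwise). The pairwise p-values are adjusted in
one family across all unordered taxon pairs with the Benjamini–Yekutieli
step-up procedure, which controls the false discovery rate under the
arbitrary dependence that shared-reference log ratios create, at a cap of
10%. Each mirrored pair $(t,r)/(r,t)$ carries the same p-value, so the
family counts each unordered pair once; counting both orders would merely
duplicate every p-value and make the harmonic-number inflation factor
$c(m)=\sum_{k\le m}1/k$ needlessly larger.

Per taxon, the W statistic counts the reference taxa against which its log
ratio shifts significantly; we flag a taxon when its W fraction
$W/(T-1)$ reaches 0.7, the conventional ANCOM cutoff. The cutoff is
exposed in `vag_thresholds()` and the full W table is returned, so users
can re-threshold without re-fitting; whether a W rule or a per-pair
reading is preferable is genuinely open, and both summaries are available
in the fitted object. Effects are quantified with the two-sample
Hodges–Lehmann estimator — the median of all between-group pairwise
differences of the log ratio — and a taxon's reported effect is the median
over all reference taxa, in natural log with a log10 column alongside.

Two further design points were open and decided as follows. First, the BY
family is per tested rank: genus-level and ASV-level analyses each form
their own family, since they answer different questions and mixing ranks
would couple their thresholds. Second, all taxa with non-zero total count
enter the grid; a prevalence filter is available but off by default.

### Pseudocount placement and library-size invariance

With a fixed $\delta = 1$, multiplying one sample's counts by an integer
changes its log ratios slightly (the pseudocount does not scale with the
sample), so invariance to library size is only approximate. The deviation
is tiny at realistic depths: for counts $(9, 4)$ scaled tenfold,
$\log(10/5) = 0.693$ becomes $\log(91/41) = 0.797$ at $\delta = 1$ — the
difference vanishes as counts grow, and at the default depth of roughly
20,000 reads it is negligible except for taxa observed a handful of times.
`da_test(..., scaled_pseudocount = TRUE, reference_depth = D)` replaces
$\delta$ by $\delta \cdot d_s / D$ for a sample of depth $d_s$, which makes
each sample's ratios depend on its counts only through proportions and
restores exact invariance for any fixed $D$; with the default
(data-derived) median-depth reference, exactness holds whenever the
rescaled sample does not move the median. The fixed pseudocount remains
the default because it is the conventional choice for this procedure.

## qPCR quantification

Each assay (total bacteria via the 16S V4 region; *Lactobacillus*,
*Streptococcus*, Enterobacteriaceae and *Staphylococcus* via genus- or
family-specific primers; human cells via the cytochrome *c1* gene) is
calibrated by a standard curve: ordinary least squares of Ct on
$\log_{10}$ concentration over a 10-fold serial dilution of a reference of
known concentration, measured in duplicate. The slope gives the
amplification efficiency $10^{-1/\text{slope}} - 1$; values outside
[0.8, 1.2] warn but do not fail, since a usable if imperfect curve is
better surfaced than hidden. Samples are measured in duplicate after a
20-fold dilution; replicates with Ct above 38 cycles are non-detects, a
sample with both replicates censored is "not detected", and otherwise the
detected replicates are averaged and inverted through the curve,

$$\hat{C} = 10^{(\bar{\mathrm{Ct}} - b)/a} \times \text{dilution},$$

reported as CFU/mL for bacterial assays (genome equivalents conflated with
CFU, as is conventional for qPCR-derived counts) and cells/mL for the
human assay. Duplicate discordance above 1 cycle is flagged, not dropped.
The bacteria-to-human ratio divides the two concentrations per sample; it
is the load estimator most robust to sampling-volume variation. Group
medians are reported under a detected-only policy by default — group
medians in this field are conventionally quoted alongside detection counts
— with zero-imputation available, since published summaries are often
ambiguous about which was used; both are one argument apart.

## The synthetic-cohort generator

The generator emulates the study design the pipeline targets, with default
group sizes AV = 20, BV = 20, NL = 18:

* **Composition.** Per group, a Dirichlet template over 12 genera. The NL
  template concentrates weight on *Lactobacillus* with a low total
  concentration, so most samples are heavily dominated while a minority
  are not; the BV template mixes *Gardnerella*, *Atopobium*, *Prevotella*,
  *Sneathia*, *Megasphaera* and *Dialister*; AV samples first draw a
  dominance category from {*Lactobacillus*, *Prevotella*,
  *Streptococcus*, *Gardnerella*, none} with weights 5:5:2:1:7, and the
  drawn taxon (if any) receives a large template weight — reproducing the
  per-sample single-taxon dominance that makes AV communities
  heterogeneous. *Lactobacillus* and *Prevotella* are each split over two
  ASVs (70/30 and 80/20) so genus aggregation is exercised end to end.
* **Counts.** Depth is negative binomial (mean 20,000 reads, dispersion 5 —
  generator conventions, chosen as typical for MiSeq amplicon libraries
  since per-sample depths are rarely reported) and counts are multinomial
  given depth and composition.
* **Spikes.** `spike_effects` multiplies a taxon's template weight by
  $e^{\text{effect}}$ in one group. Note that a weight-scale spike of
  $\log 8$ induces a log-ratio shift slightly above $\log 8$ (for a unit
  base weight, roughly $\psi(8) - \psi(1) \approx 2.59$ versus
  $2.08$, with $\psi$ the digamma function), because the spike acts on the
  Dirichlet concentration rather than directly on the composition; effect
  recovery is therefore asserted within ±30% rather than exactly.
* **Loads.** Per group and assay, absolute concentrations are
  $10^{\mathcal{N}(\log_{10} m_g,\ 0.6)}$ around the group median $m_g$
  of `default_load_model()` — total bacteria 2.2×10⁹ / 9.6×10⁷ / 1.1×10⁷
  CFU/mL for BV/NL/AV, human cells 1.4×10⁶ / 7.4×10⁵ / 2.7×10⁶ cells/mL,
  lactobacilli highest in NL (1.5×10⁷), streptococci highest in AV
  (2.7×10⁵, versus 254 in NL), and so on. The 0.6-decade spread is a
  generator convention consistent with the order-of-magnitude within-group
  variability such cohorts show. Loads are drawn independently of the
  composition and of each other; this is a simplification — in real data
  the genus-specific loads are coupled to the composition and to total
  load, so the implied ratio-of-medians here equals the ratio of the
  configured medians rather than being free.
* **qPCR measurement.** Every assay shares a log-linear response with
  slope −3.3219 (perfect doubling) and intercept 38, so the detection
  limit at 20-fold dilution is 20 units/mL. Standards (10-fold series,
  10² to 10⁸, duplicate) and sample duplicates receive Gaussian Ct noise
  of 0.15 cycles, a typical duplicate variability for SYBR-green assays.
  Replicates above Ct 38 are censored, producing the partial non-detects
  seen for low-load assays.
* **AV scores.** For AV samples, the composite score (0–10) is a clamped,
  rounded linear function of the standardized log10 relative *Prevotella*
  abundance plus Gaussian noise, calibrated (slope 2.2, noise sd 2.0)
  so that score and *Prevotella* abundance correlate at about
  $r = 0.6$ at the defaults. Clamping and rounding attenuate the latent
  correlation, which the calibration accounts for.

What passing recovery tests on these cohorts shows is that the pipeline's
statistics behave as designed under the generative model; it does not show
robustness to features the generator omits — compositional coupling of
loads, PCR primer bias, contamination, overdispersion beyond
Dirichlet-multinomial, or batch structure across plates.

## Cohort summaries

Dominance/presence profiling uses strict inequalities (relative abundance
above 50% and above 1% respectively). Display tables keep the 11 most
abundant genera (ranked by total relative abundance over all samples) and
pool the rest into a residual, so rows still sum to one. Sample ordering
for stacked-bar displays minimises total Bray–Curtis distance
($1 - 2\sum\min(x,y)/(\sum x + \sum y)$) between neighbours: an open-path
travelling-salesman problem solved exactly by exhaustive search up to 9
samples and by best-of-all-starts nearest-neighbour with 2-opt refinement
above, with ties broken by sample identifier and orientation fixed by the
lexicographically smaller endpoint, so the ordering is fully
deterministic. An AV panel can alternatively be ordered by AV score, the
display convention for that group. The score–abundance association is
plain Pearson correlation on relative abundance (no transform — an
assumption worth noting, since a log transform would weight dominance
differently). Group endpoints (qPCR concentrations, reporter-assay
absorbances) are compared with pairwise Wilcoxon rank-sum tests under Holm
step-down correction, with the tie-corrected Kruskal–Wallis test for
global differences; reporter absorbances are compared raw, with the blank
mean reported alongside rather than subtracted (blank subtraction is an
option).

## Numerical and degenerate-input choices

* All-zero samples are rejected with the offending identifier, never
  dropped silently; the same for samples without metadata or ASVs without
  taxonomy.
* Unclassified ASVs aggregate into `unclassified_<deepest known rank>`
  buckets so unknowns from different lineages never merge.
* `by_adjust` and Holm adjustments are monotone and clipped to 1;
  identical values across all groups make the tie-corrected
  Kruskal–Wallis statistic undefined and raise an explicit error.
* Bray–Curtis on two all-zero vectors is undefined and errors (rather
  than returning the NaN a generic implementation would).
* Exhaustive seriation compares path lengths with a 10⁻¹² slack before
  tie-breaking, so floating-point noise cannot flip the chosen optimum.
* Zero concentrations simulate as censored pairs; quantification of a
  fully censored pair is a valid "not detected" result, not an error.

## Problem sizes used in the shipped checks

The package's own validation uses 200 random instances per statistical
primitive against brute-force oracles, 50 replicate cohorts (two groups of
20, 12 taxa) for the null false-discovery behaviour and for the 8-fold
spike power/recovery check, three default cohorts (58 samples, 6 assays)
for quantification recovery, and exhaustive-versus-heuristic seriation
checks up to 7 samples against an independent permutation oracle (the
package's own search is exhaustive to 9). These sizes make the full suite
run in well under a minute while keeping Monte-Carlo standard errors small
enough for the stated tolerances.

## A worked run

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(seed = 1))

# compositional differential abundance, AV vs NL at genus level
fit <- da_test(cohort$counts, cohort$metadata, "AV", "NL",
               rank = "genus", taxonomy = cohort$taxonomy)
summary(fit)

# absolute quantification and load ratios
quant <- lapply(cohort$qpcr_plates, quantify_plate)
group_median_summary(quant$total_16S, cohort$metadata)
ratios <- load_ratio_table(quant$total_16S, quant$human_cyc1)
group_median_summary(ratios, cohort$metadata, value_col = "ratio")

# cohort summaries
relab <- relative_abundance(aggregate_taxa(cohort$counts, cohort$taxonomy,
                                           "genus"))
dominance_profile(relab, cohort$metadata)
seriate_samples(relab[cohort$metadata$group == "BV", ])
```

## Limitations

The differential-abundance test is two-group and unadjusted: no
covariates, no longitudinal structure, no zero-inflation model, and no
directional sub-tests. qPCR quantification assumes the log-linear
single-efficiency model and identical processing of samples and standards
apart from the explicit dilution; multi-plate batch calibration and
copy-number correction are out of scope. The generator's independence
assumptions (loads vs composition) mean ratio-based quantities are tested
against their implied, not free, targets.
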
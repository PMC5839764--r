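---
title: "Methods: mutation-frequency estimation, hotspot analysis and target prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-frequency estimation, hotspot analysis and target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmatlas)
library(dplyr)
```

## Scope and model

`shmatlas` analyzes off-target mutagenesis by activation-induced deaminase
(AID) in germinal-center B cells from targeted deep-sequencing base counts.
AID deaminates deoxycytidine to deoxyuridine on both DNA strands; in
repair-deficient genotypes (most cleanly *Ung−/−Msh2−/−*, where neither
base-excision nor mismatch repair can process the U:G lesion) the uracil is
replicated over and leaves C→T and G→A transitions that mark the raw
deamination footprint. The pipeline starts from per-base base-call tallies
over a panel of captured regions (TSS-anchored 500-bp windows in the study
design the package emulates) and proceeds in five stages:

1. **Region and motif handling** — regions come in as BED + FASTA; the
   canonical hotspot WRC/WRCY (W = A/T, R = A/G, Y = C/T) and the extended
   AGCTNT hotspot are scanned on both strands in the *deaminated-cytosine
   frame*: a minus-strand hotspot appears on the plus strand as the
   reverse complement of the motif, and its deaminated base is a plus-strand
   G. Reported positions always refer to the plus strand, 0-based.
2. **Mutation profiling** — germline SNPs are masked, substitutions
   tallied per (position, alternate base), and region summaries computed
   with the three frequency formulas: total mutations over total sequenced
   length; mutated C+G over sequenced C+G; and the same restricted to
   hotspot cytosines/guanines. Numerators are read-level call counts and
   denominators depth sums, so every frequency is per sequenced base.
3. **Target discovery** — per region, C→T/G→A events versus the AID-null
   (*Aicda−/−*) control in a one-tailed Fisher exact test, with
   Benjamini–Hochberg correction across regions; a region is an AID target
   at q ≤ 0.05.
4. **Sequence-context analysis** — flanking windows around mutated
   cytosines (control-adjusted C→T frequency ≥ 4×10⁻³), logo composition,
   per-position one-tailed Fisher enrichment against the contexts of all
   cytosines in the panel (Bonferroni over the 4 × 2w tests, significance
   at adjusted p ≤ 10⁻³), per-motif mutability ranking and a two-tailed
   Mann–Whitney contrast of AGCTNT against its AGCTNV control.
5. **Mutability prediction** — a conditional-inference classification tree
   over gene-level transcriptional features, plus the convergent
   transcription (ConvT) rule: a gene is ConvT-positive when strictly more
   than 100 bp of sense and antisense transcription overlap inside its
   body.

## Coordinates and conventions

All coordinates are 0-based half-open, in BED convention, both internally
and in every table the package writes. Substitutions are labelled `C>T`
style; transitions are C>T, T>C, G>A, A>G. Sequence `N` positions are
excluded from every denominator, and an `N` in a region sequence matches
only the motif letter `N`, never an ambiguity code — an unknown base is not
allowed to complete a hotspot. A cytosine covered by several overlapping
hotspot instances is counted once in hotspot denominators, since the
frequency formulas are per nucleotide, not per motif instance.

## Contingency construction for target calling

The published pipeline does not state whether Fisher counts were read-level
events or distinct mutated positions. The default here is read-level:
events are all C→T calls at cytosines plus G→A calls at guanines, and the
exposure is the depth-summed sequenced C/G length. This uses all the
information deep coverage provides; a positions mode (distinct mutated C/G
sites against C/G position counts) is available via
`call_targets(mode = "positions")` for sensitivity analysis. Sequencing
error is deliberately not filtered by a caller threshold
(`min_alt_count = 1`): the genotype contrast against the AID-null control
absorbs it, because error strikes both genotypes at the same rate.

## The synthetic study

Because the deposited sequencing data are not part of the package, a
generator produces data with the statistical structure the analysis
assumes, and everything is tested against it.

* **Sequences and SNPs** — random sequences at a configurable GC content
  (default 0.5); heterozygous SNPs at 10⁻³ per bp with allele fraction 0.5,
  a realistic density for inbred-strain panels after known-SNP masking is
  deliberately stressed.
* **Deamination landscape** — the expected mutant-allele fraction at a
  non-hotspot cytosine is `base_deamination` = 2×10⁻⁴; hotspot sites take
  the largest applicable motif multiplier, WRCY ×10 and AGCTNT ×25 by
  default, planting the mutability ordering AGCTNT > WRCY > background. A
  `hotspot_only` switch restricts deamination entirely to the listed
  motifs, the condition used for the context-recovery analyses.
* **Genotypes** — each genotype is an escape fraction (deaminations not
  faithfully repaired), a substitution spectrum at the deaminated C, and a
  collateral A/T-mutation scale. The AID-null control is identically zero;
  the double knockout escapes fully as pure C→T/G→A with no A/T phase
  (mismatch repair, which recruits error-prone polymerase η to A/T sites,
  is absent); the single knockouts and double heterozygote keep small
  escape fractions (0.10, 0.10, 0.04) because the remaining pathway backs
  up the lost one. The published work gives no quantitative escape
  fractions; these defaults were chosen once to reproduce the qualitative
  ordering — the double knockout several-fold above all others, and the
  three repair-competent genotypes mutually similar — and are not fitted
  to data.
* **Sequencing** — depth is Poisson (default mean 500×), base calls
  multinomial with per-base substitution error 10⁻⁴ (consensus-quality
  targeted sequencing), SNP positions pulled to allele fraction 0.5.
  Mutant-allele fractions are modelled directly as expected frequencies of
  a polyclonal cell population; no per-cell lineages are simulated, so the
  only stochasticity is Poisson depth and multinomial sampling.
* **Feature tables** — continuous features (expression, transcription
  rate, PolII and Spt5 densities) are lognormal around a shared latent
  activity; binary marks are Bernoulli with activity-linked probabilities;
  the target label is Bernoulli with
  P(target) = logistic(−3 + 4.2·[PolII and Spt5 both above their 75th
  percentile]), so the high-PolII∧Spt5 stratum has target probability
  logistic(1.2) ≈ 0.77 — the planted analogue of the reported
  high-PolII/Spt5 rule.

All randomness flows from one master seed through fixed per-region and
per-genotype substreams, so any fragment of a simulation is reproducible
in isolation.

What the generator does **not** emulate: alignment artifacts, PCR
duplicates, capture-efficiency bias, strand-specific error, clonal
phylogenies and linkage between mutations. Passing tests therefore
demonstrate that the statistics recover the structure they assume, not
that the pipeline is robust to every artifact of real libraries.

## Numerical choices

* The one-tailed Fisher p-value is the exact hypergeometric upper tail;
  Benjamini–Hochberg and Bonferroni adjustments are the standard step-up
  and product corrections.
* The Mann–Whitney test enumerates all group assignments exactly (with
  midranks for ties) up to pooled n = 12 and otherwise uses the normal
  approximation with tie and continuity corrections.
* Region summaries report a frequency of 0 with a flag when a denominator
  is zero rather than propagating NaN.
* Control subtraction floors at zero: a site more mutated in the AID-null
  control than in the case carries no evidence of AID activity.
* The context window default is 5 nucleotides per side. The source
  description ("a window of 10 nucleotides") is ambiguous between total
  width and per-side width; positions out to ±5 are displayed in the
  corresponding figures, so 5 per side was chosen and is configurable.
* Context enrichment uses the one-tailed Fisher test with Bonferroni
  correction. The originating description is internally inconsistent (the
  methods text names a t test, the figure legend a Fisher test for the
  same analysis); the Fisher test is the one consistent with count data
  and was adopted.
* Windows truncated by a region edge are dropped (and counted) rather than
  padded.
* Welch's unequal-variance t test is used for per-gene genotype contrasts;
  the original analysis names only a "two-tailed Student's t test", and
  the unequal-variance form is the safer default for two-replicate
  frequency comparisons.
* Genotype contrasts subtract the AID-null region-level frequency before
  any comparison, flooring at zero, mirroring the figure-level subtraction
  convention.

## The conditional-inference tree

No conditional-inference implementation is wrapped; the recursive
procedure is implemented directly, with parameter defaults mirroring the
conventional ones (split criterion 0.95, `minsplit` 20, `minbucket` 7):

1. At each node, every covariate's association with the class label gets a
   p-value: continuous covariates via the rank-based two-sample test (or
   Kruskal–Wallis for ≥3 classes), binary covariates via the exact
   two-sided Fisher test (chi-square for ≥3 classes). Exact Fisher rather
   than asymptotic chi-square keeps small leaves valid.
2. P-values are Bonferroni-adjusted across covariates; the node becomes a
   leaf when the minimum adjusted p exceeds α = 0.05 or the node is
   smaller than `minsplit`.
3. Otherwise the winning covariate is split: binary by level, continuous
   at the midpoint between adjacent sorted unique values maximizing the
   chi-square statistic of the left/right-by-class table, subject to
   `minbucket` on both children.

This is a rank-based approximation of the conditional-inference framework;
bit-exact agreement with the original `party::ctree` algorithm is a
non-goal. The fitted object is deterministic in its inputs, carries
broom-style `tidy()`/`glance()` methods, serializes through
`describe_tree()`/`ctree_from_description()`, and refuses missing values
(no surrogate splits). The response may be the binary target/nontarget
flag from target discovery or the three mutability classes (highly
mutated: targets in the top 20% by C→T frequency with frequency above
3×10⁻⁴; mutated: remaining targets; nonmutated: the rest) — the original
outcome coding is not stated, so both are supported, with binary the
default in examples. Genes with AID-null background mutation frequency
strictly above 5×10⁻⁴ are excluded before fitting.

## Worked example

A compact end-to-end run on a simulated study:

```{r example, eval = FALSE}
cfg <- simulation_config(n_regions = 60, seed = 1)
sim <- simulate_shm_experiment(cfg, target_fraction = 0.1)

wrcy <- annotate_hotspots(sim$regions, preset_motifs("WRCY"))
summaries <- lapply(sim$counts, function(cts) {
  masked <- mask_snps(cts, sim$snps)
  summarize_region(tally_mutations(masked), masked, wrcy)
})

calls <- call_targets(summaries$UngMsh2_DKO, summaries$Aicda_KO)
dplyr::filter(calls, is_target)

adj <- subtract_control(
  site_frequencies(sim$counts$UngMsh2_DKO, "ct"),
  dplyr::select(site_frequencies(sim$counts$Aicda_KO, "ct"),
                region_id, pos, freq))
ranking <- motif_mutability(adj, sim$regions,
                            preset_motifs(c("AGCTNT", "AGCTNV", "WRCY")))
plot_motif_mutability(ranking)
```

## Problem sizes used in the test suite

The packaged tests exercise the pipeline at desk scale, chosen once as
representative: 100 simulated studies of 200 regions × 500 bp at depth
500× with 5% planted targets (plus 100 null studies) for the
target-calling operating characteristics; 50 studies for the motif
ranking; 200 independence runs at n = 200 and 100 planted-interaction
runs at n = 2,000 for the tree, with the leaf-probability check at
n = 5,000. The headline gene counts of the original study (291 target
regions, 275 target genes) derive from the deposited sequencing data and
are not reproduced here; the one directly checkable published quantity —
21 of 275 target genes (7.6%) annotated in the DLBCL mutation set — is
recomputed by `gene_set_enrichment()` in the acceptance script.

## Known limitations

* Substitutions only; indels are not called.
* No base-quality or strand-bias modelling; the AID-null contrast is the
  sole error control.
* The per-motif mutability ranking weights every site equally rather than
  by depth (the original weighting is unstated).
* The collateral A/T-mutation model is uniform within a region; no
  positional model of the repair-patch footprint is attempted.
* The tree has no surrogate splits and requires complete feature tables.
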
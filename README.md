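# shmatlas

Analysis of off-target somatic hypermutation by activation-induced
deaminase (AID) from targeted deep-sequencing base counts.

AID initiates antibody diversification in germinal-center B cells by
deaminating deoxycytidine on both DNA strands, but it also strikes many
non-immunoglobulin loci, and those off-target mutations contribute to
B-cell lymphomagenesis. In repair-deficient *Ung−/−Msh2−/−* cells the
resulting U:G lesions replicate into pure C→T/G→A transitions, exposing
the raw deamination footprint. `shmatlas` is for researchers who have (or
simulate) per-base base-call tallies over a capture panel and want to:

- scan regions for AID hotspot motifs — WRC/WRCY (W = A/T, R = A/G,
  Y = C/T) and the extended AGCTNT hotspot — on both strands in the
  deaminated-cytosine frame;
- mask germline SNPs and compute the standard mutation frequencies per
  region, with depth-weighted denominators:

  - total frequency = total mutations / total sequenced length,
  - C/G frequency = (mutated C + mutated G) / (sequenced C + G bases),
  - hotspot frequency = the same restricted to hotspot cytosines and
    guanines;

- call AID target regions by a one-tailed Fisher exact test of C→T/G→A
  events against the AID-null (*Aicda−/−*) control with
  Benjamini–Hochberg FDR control (targets at q ≤ 0.05);
- analyze the sequence context of mutated cytosines (logo composition,
  per-position Fisher enrichment with Bonferroni correction, per-motif
  mutability ranking, Mann–Whitney contrasts such as AGCTNT vs AGCTNV);
- compare DNA-repair genotypes after subtracting the AID-null background;
- predict gene mutability from transcriptional features (expression,
  transcription rate, PolII/Spt5 densities, chromatin marks,
  superenhancer and convergent-transcription flags) with a
  conditional-inference classification tree.

A synthetic-data module generates regions, genotype-specific mutation
landscapes, count tables, SNP masks and feature tables with the
statistical structure the analysis assumes, so the whole pipeline is
testable without sequencing data. All functions take data frames first
and return tibbles, so stages chain with the pipe; coordinates are
0-based half-open throughout (BED convention).

## Worked example

Simulate a 60-region study with 10% planted AID targets, call targets
against the AID-null control, and rank hotspot motifs:

```r
library(shmatlas)
library(dplyr)

cfg <- simulation_config(n_regions = 60, seed = 1)
sim <- simulate_shm_experiment(cfg, target_fraction = 0.1)

wrcy <- annotate_hotspots(sim$regions, preset_motifs("WRCY"))
summaries <- lapply(sim$counts, function(cts) {
  masked <- mask_snps(cts, sim$snps)
  summarize_region(tally_mutations(masked), masked, wrcy)
})

calls <- call_targets(summaries$UngMsh2_DKO, summaries$Aicda_KO)
filter(calls, is_target)
#> # A tibble: 6 × 8
#>   region_id m_case n_case m_ctrl n_ctrl  p_value  q_value is_target
#>   <chr>      <int>  <int>  <int>  <int>    <dbl>    <dbl> <lgl>
#> 1 r0006         47 123269      5 123530 6.12e-10 6.12e- 9 TRUE
#> 2 r0010         60 137001      6 137625 1.20e-12 1.44e-11 TRUE
#> 3 r0031         68 126074      4 126076 2.29e-16 6.87e-15 TRUE
#> 4 r0033         66 126866      3 127237 8.40e-17 5.04e-15 TRUE
#> 5 r0045         62 119680      3 119521 1.28e-15 2.57e-14 TRUE
#> 6 r0048         54 135900      1 134988 1.85e-15 2.77e-14 TRUE
```

All six called regions are exactly the six planted targets: `m_case` is
the number of C→T/G→A transition calls in the double knockout, `n_case`
the depth-summed sequenced C/G length, and the q-values are the
BH-adjusted one-tailed Fisher p-values against the AID-null counts.

Motif mutability on control-adjusted per-site transition frequencies:

```r
adj <- subtract_control(
  site_frequencies(sim$counts$UngMsh2_DKO, "ct"),
  select(site_frequencies(sim$counts$Aicda_KO, "ct"), region_id, pos, freq))
motif_mutability(adj, sim$regions,
                 preset_motifs(c("AGCTNT", "AGCTNV", "WRCY"))) |>
  select(-freqs)
#> # A tibble: 3 × 3
#>   motif_name n_sites mean_freq
#>   <chr>        <int>     <dbl>
#> 1 AGCTNT          43  0.00132
#> 2 AGCTNV         161  0.000337
#> 3 WRCY          1785  0.000288
```

AGCTNT cytosines are the most mutated, ahead of the AGCTNV control and
the WRCY family — the planted hotspot hierarchy, recovered from counts.
`plot_motif_mutability()`, `plot_genotype_comparison()`,
`plot_per_base_profile()` and `plot_position_composition()` render the
corresponding figures; the fitted tree from `ctree_fit()` has
`tidy()`/`glance()` methods.

See the methods vignette (`vignettes/shm-atlas-methods.Rmd`) for the
models, parameter defaults and design decisions.

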
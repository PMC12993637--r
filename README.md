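# vertmicro

Is the vaginal microbiota vertically transmitted — seeded from mother to
daughter at birth and persisting into adolescence? `vertmicro` implements a
reusable, tested version of the two analyses that address this question at
community and strain resolution:

1. **Community similarity.** From a mothur-style shared OTU table and sample
   metadata, compute Yue–Clayton θ (θ_YC) distances between all samples,

   θ = Σᵢ pᵢqᵢ / (Σᵢ pᵢ² + Σᵢ qᵢ² − Σᵢ pᵢqᵢ),  d = 1 − θ,

   over the relative abundances p, q of shared and non-shared OTUs; group
   the distances *within subject* (weekly stability), *within
   mother/daughter pair*, and *between pairs*; test the three-group contrast
   with Kruskal–Wallis + Dunn's posttest and the birth-mode contrast
   (vaginal delivery vs C-section) with a Wilcoxon rank-sum test; and
   ordinate samples by principal coordinates analysis.

2. **Strain transmission plausibility.** From per-isolate variant calls
   against a shared *Lactobacillus crispatus* reference, apply the
   filter cascade — hard quality filters (QUAL > 100, MQ > 50, supporting
   depth ≥ 10, FQ < 0.025), SNVs < 5 bp from indels, phage/repeat regions,
   the core genome, recombinant tracts — count recombination-filtered
   pairwise SNPs s, and convert them to an in vivo doubling-time estimate
   under a shared-ancestor molecular clock:

   doubling time = μ · T · L / m,  m = s/2,  mutations/year = s / (2 · age),

   with μ the per-bp per-generation mutation rate, T the daughter's age in
   hours (365 × 24 h years) and L the recombination-filtered core genome
   length.

Because the underlying study data are sequencing archives, the package ships
two statistically explicit simulators — a Dirichlet-multinomial
paired-community generator whose within-pair similarity is controlled by a
birth-mode-dependent transmission weight, and a Poisson clonal-divergence
genome generator with injected recombination tracts — so every stage of both
pipelines is testable end to end from code alone.

Intended users: microbiome researchers who want the θ_YC grouping analysis or
a recombination-aware SNP-distance/molecular-clock estimate on their own
shared files and VCFs, with every threshold explicit and overridable.

## Worked example

```r
library(vertmicro)
library(dplyr)

# a 13-pair cohort, 5 weekly samples per subject, 3 C-section daughters
sim  <- simulate_pair_cohort(community_sim_config(seed = 7))
kept <- exclude_low_depth(sim$otu_table)          # drops 9 samples < 1000 reads
dm   <- theta_yc_distances(relative_abundance(kept))
gd   <- group_distances(dm, sim$metadata)

as_tibble(gd) |> group_by(group) |> summarise(median = median(value), n = n())
#>   group          median     n
#> 1 between_pair    0.886    26
#> 2 within_pair     0.267    13
#> 3 within_subject  0.118    26

kruskal_dunn(gd, value, group)
#> Kruskal-Wallis with Dunn posttest
#> H = 51.42, df = 2, p = 6.814e-12
#> # A tibble: 3 × 5
#>   group1       group2             z  p_value p_value_holm
#> 1 between_pair within_pair     2.67 7.57e- 3     7.57e- 3
#> 2 between_pair within_subject  7.17 7.74e-13     2.32e-12
#> 3 within_pair  within_subject  3.18 1.47e- 3     2.95e- 3

wp <- within_pair_table(gd, sim$metadata)
wilcoxon_rank_sum(wp$value[wp$birth_mode_of_daughter == "vaginal"],
                  wp$value[wp$birth_mode_of_daughter == "c_section"])
#> Wilcoxon rank-sum (normal approximation, tie-corrected): W = 55, p = 0.01123 (n = 10, 3)
```

Communities are most similar week-to-week within a subject (median θ_YC
0.118), intermediate between a mother and her own daughter (0.267), and most
distant between unrelated subjects (0.886); within-pair distances are lower
for vaginally delivered daughters (the rank-sum rejects at α = 0.05).

The strain-level estimate from published inputs — 25 recombination-filtered
SNPs between a mother's and her 20-year-old daughter's isolates across a
940,943 bp core genome, μ = 1.0 × 10⁻⁹/bp/generation:

```r
transmission_estimate(snp_count = 25, age_years = 20, genome_length = 940943)
#> Molecular-clock estimate (s = 25 SNPs, age = 20 y, L = 940943 bp, mu = 1e-09)
#>   doubling time:      13.2 hours
#>   mutations per year: 0.6
```

A doubling time of ~13 hours is biologically plausible for a vaginal
*Lactobacillus*, i.e. the observed SNP count is consistent with a strain
transmitted at birth and diverging clonally ever since.

File-based orchestration (`run_community_pipeline()`,
`run_transmission_pipeline()` with a `run_config()` or YAML equivalent)
writes the exclusion report, distance matrices (tidy CSV and PHYLIP),
grouped distances, test results, PCoA coordinates, per-isolate filter
reports and estimates under an output directory, each file stamped with the
seed and configuration hash.

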
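---
title: "Models and methods: community similarity and strain-clock estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: community similarity and strain-clock estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertmicro)
```

`vertmicro` asks, with two independent lines of evidence, whether members of
the vaginal microbiota pass from mother to daughter at birth and persist:
a community-level similarity analysis of paired 16S OTU profiles, and a
strain-level molecular-clock analysis of *Lactobacillus crispatus* isolate
genomes. This vignette explains the models, the parameters that matter, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## 1. Community similarity

### The θ_YC distance

For two samples with OTU relative abundances $p$ and $q$ over the union of
observed OTUs (absent OTUs imputed as 0), the Yue–Clayton similarity is

$$\theta = \frac{\sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2 - \sum_i p_i q_i},$$

and the distance used throughout is $d = 1 - \theta$. The measure weights
both shared and non-shared taxa: $d = 0$ iff the compositions are identical
and $d = 1$ exactly when supports are disjoint. `theta_yc()` computes one
pair; `theta_yc_distances()` computes the full matrix by the algebraically
identical cross-product form. The test suite holds them to a brute-force
double-loop oracle at `1e-12`.

### Depth handling

Samples with fewer than 1000 sequences are excluded (`exclude_low_depth()`,
inclusive at the boundary: a 1000-read sample stays). No rarefaction is
performed anywhere — the depth exclusion is the only depth handling, and
θ_YC operates on relative abundances. The display-OTU filter
(`select_display_otus()`) keeps OTUs with ≥ 200 reads dataset-wide *and*
> 2% relative abundance in at least one sample; it affects only the emitted
long-format abundance table, never the distances.

### Grouping and units of analysis

Distances are summarised at three levels (`group_distances()`):

- **within subject** — per subject, the mean over all pairs of that
  subject's weekly samples (subjects with one usable sample are omitted);
- **within pair** — per mother/daughter pair, the subject-level distance
  between its two members;
- **between pairs** — per subject, the mean subject-level distance to all
  subjects outside its pair.

The subject-level distance between two subjects is the arithmetic mean of
all their cross-sample distances (`aggregate_subject_distances()`). Using
per-entity means as the unit of analysis matches a "mean distances per
subject/pair" reading of the design; pooled subject-pair distances remain
available from the `subject_distances` attribute for sensitivity analyses
(the λ = 0 exchangeability test in the suite uses exactly that pooling,
because per-entity means of different group sizes are not exchangeable even
under the null).

### Tests

The three-group contrast uses Kruskal–Wallis (tie-corrected, via
`stats::kruskal.test`) followed by Dunn's posttest on the joint midranks
with tie-corrected variance; because no particular multiplicity adjustment
is canonical here, pairwise p-values are reported both unadjusted and
Holm-adjusted. The two-group contrasts (birth mode; mother's reproductive
stage, both at pair level) use the Wilcoxon rank-sum test: exact by complete
enumeration of group assignments when the combined n is ≤ 12 and tie-free,
otherwise the normal approximation with midranks and tie-corrected variance
(no continuity correction, so the statistic matches the tie-corrected z
exactly). The method actually used is recorded in the result. The
menstruation flag is carried through the metadata but never used for
exclusion.

### Ordination

`pcoa_ordination()` is classical (Torgerson) scaling via `stats::cmdscale`:
eigendecomposition of the double-centred squared-distance matrix.
θ_YC matrices are generally non-Euclidean, so negative eigenvalues occur;
they are retained and reported, with variance proportions taken relative to
the sum of positive eigenvalues. For Euclidean-embeddable input the
full-rank coordinates reproduce the distances to 1e-6 (tested).

## 2. Variant filtering and SNP distances

Per isolate, SNVs pass through five stages in fixed order, and each removed
record is attributed to its *first* failing stage so the report satisfies
`input = surviving + Σ removals` exactly:

1. **hard filters** — pass iff QUAL > 100 and MQ > 50 and supporting depth
   ≥ 10 and FQ < 0.025. The boundary operators are deliberate: quality
   thresholds strict, depth inclusive. A record missing any of these fields
   is *unscorable* and fails here rather than being dropped silently.
   Some callers emit FQ with an inverted sign convention, so the comparison
   direction is configurable (`hard_filter_config(fq_direction=)`);
2. **indel proximity** — SNVs strictly closer than 5 bp to an indel's
   reference start are removed. The indels used for this mask are taken
   from the raw record set (not the hard-filter survivors): an indel of
   marginal quality still marks a locally unreliable alignment;
3. **phage/repeat mask**, 4. **core genome** (intersection of per-isolate
   callable intervals), 5. **recombinant tracts** — positional masks on the
   0-based coordinate `pos − 1`. Records on chromosomes a mask does not
   cover are kept with a warning.

Coordinates are uniformly 0-based half-open internally; BED enters
verbatim and GFF (1-based inclusive) is converted at the boundary, both via
`rtracklayer`. The interval set algebra itself (merge, intersect, subtract,
membership) runs on sorted endpoints; tests cross-check every operation
against point-membership oracles.

The SNP distance between isolates (`snp_distances()`) counts positions where
the implied alleles differ, each isolate carrying its ALT at its surviving
variant positions and the reference allele elsewhere. A shared position with
different ALT alleles counts 1 — one site, one SNP. Indels never enter the
distance.

## 3. The molecular-clock estimator

Two isolates are assumed to descend from a common ancestor at the daughter's
birth, accumulating non-convergent mutations independently and
symmetrically, so each lineage carries $m = s/2$ of the $s$ observed
recombination-filtered SNPs. With mutation rate $\mu$ (substitutions per bp
per generation), host age $T$ in hours, and core genome length $L$:

$$\text{doubling time} = \frac{\mu \, T \, L}{m}, \qquad
  \text{mutations/year} = \frac{s}{2 \cdot \text{age}}.$$

Defaults: $\mu = 10^{-9}$ (a published in vitro *Lactobacillus* rate — the
species' own in vivo rate is unknown, which is the dominant source of
systematic uncertainty), years of exactly 365 × 24 hours. Zero observed
mutations is an explicit error ("doubling time unbounded"), never a silent
infinity, and the pipeline surfaces it as an error status with a nonzero
failure flag. Reported values carry full precision; the human-readable
report rounds half-up to one decimal. Asymmetric lineage models and
confidence intervals are out of scope: the estimator reproduces point
values, and its honest uncertainty is Poisson counting noise plus the
unknown true $\mu$.

When the pipeline computes $L$ itself it uses the *masked* core length —
core genome minus phage/repeat minus recombinant tracts — because that is
the territory on which surviving SNPs can actually occur; an explicit
`genome_length` override is available.

## 4. What the simulators emulate

### Paired communities (`simulate_pair_cohort()`)

Per pair: the mother's latent composition is a draw from a sparse symmetric
Dirichlet (concentration 0.2 per OTU over 40 OTUs — dominance-prone,
*Lactobacillus*-like profiles); the daughter's is the convex mixture
$\lambda \cdot \text{mother} + (1-\lambda) \cdot \text{independent draw}$.
Transmission is thus modelled as compositional mixing, not strain-level
colonisation — the minimal structure that produces a within-subject <
within-pair < between-pair distance gradient. Weekly samples re-draw each
subject's composition from a Dirichlet with concentration κ = 100 (stable
but not frozen communities), and counts are multinomial at a
negative-binomial depth (mean 23,000, size 5 ≈ SD 10,000) with 5% of
samples forced under 1000 reads to exercise the exclusion stage.

Cohort structure defaults: 13 pairs, 3 C-section daughters, 5 weekly
samples, mother reproductive-stage frequencies matching the study cohort.
The transmission weights default to $\lambda_{vaginal} = 0.7$,
$\lambda_{csection} = 0.15$: chosen a priori, before any test was run, such
that the pair-level birth-mode rank-sum comparison at n = 10 + 3 is well
powered (the design target was ~80%; the one prescribed calibration run
measured 100% over 200 replicates, with the group ordering holding in every
replicate) — a deliberately clear effect, since the generator's job is to
make the pipeline's behaviour observable, not to estimate the real-world
effect size, which the source cohort is far too small to pin down.

What passing these tests does *not* show about real data: real vaginal
communities share dominant taxa across unrelated women (the simulator's
independent Dirichlet draws rarely do, inflating between-pair distances
toward 1); reproductive stage has no compositional effect in the generator
(the flag exists, the biology does not); and OTU identities carry no
taxonomy.

### Genome divergence (`simulate_genome_divergence()`)

One trunk splits at the daughter's birth into a mother branch and a
daughter branch, each running $G = T/g$ generations (defaults: $g$ = 13.2 h,
$T$ = 20 years → ≈ 13,300 generations). The mother's two isolates share 75%
of her branch. Each branch accumulates Poisson($\mu L G_{branch}$) mutations
at uniform positions, redrawn on collision (non-convergence; at these
densities collisions are ~0 anyway). The expected mother–daughter clonal
count is $2\mu L G$ ≈ 25 at defaults. Overlaid on this: 3 recombinant
tracts of 5 kb at SNP density 0.005 (≫ the clonal density of ~3 × 10⁻⁵)
assigned to random recipient isolates; 5% of the genome masked as
phage/repeat; 2% per isolate uncallable; and per-variant quality fields that
independently violate each hard filter with probability 0.01. The model
errors out if expected mutations exceed L/10, where the sparse-SNP
assumptions break. Truth records every position, tract and injected failure,
so tests can compute expected filtered distances exactly.

The emitted VCFs are a minimal bcftools-flavoured dialect (QUAL, DP4, MQ,
FQ) sufficient for the reader; the simulator does not model read-level
error, coverage variation along the genome, or gene gain/loss.

## 5. Numerical and design choices

- **Determinism**: each simulator consumes a single integer seed; pipelines
  set it once at entry. Identical seed + inputs → byte-identical outputs
  (tested).
- **Ties in rank tests**: midranks with tie-corrected variance everywhere;
  the exact rank-sum branch refuses ties (falls back to the approximation).
- **Degenerate inputs**: empty OTU tables and empty filter results are
  valid; all-zero abundance vectors, zero-total samples, two mothers in a
  pair, inverted intervals, conflicting duplicate variant records and zero
  SNP counts are errors with named offenders.
- **Symmetry enforcement**: the vectorised θ_YC matrix is symmetrised
  against floating-point jitter `(d + t(d))/2` and clamped to [0, 1].
- **Problem sizes in the test suite** (chosen to keep the full suite at
  ~2–3 minutes on one CPU while leaving the Monte-Carlo checks
  well-resolved): 200 cohort replicates for ordering/power, 500 genome
  replicates for the mean-SNP calibration, 200 for estimator recovery,
  100 random variant sets for cascade conservation/monotonicity.

## 6. Known limitations

The estimator inherits every assumption of the clock: borrowed mutation
rate, symmetric divergence, no selection, no within-host recombination
beyond the masked tracts, divergence starting exactly at birth. The
community analysis treats OTUs as exchangeable and the aggregation to
subject level as a plain mean over weeks. None of these can be validated on
synthetic data that builds the same assumptions in; the simulators test the
*implementation*, not the biology.
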
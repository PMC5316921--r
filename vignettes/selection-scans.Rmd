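---
title: "Selection scans between diverged crop populations: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans between diverged crop populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sweepscan)
```

# The problem

Weedy relatives of cultivated crops — weedy rice infesting paddies is the
motivating case — are recently derived from cultivated populations and carry
genomic regions shaped by strong, recent selection for ferality (shattering,
dormancy, stress tolerance). Given resequencing data for a weedy ("test")
population and the landrace ("reference") population it descends from,
sweepscan locates those regions with five complementary statistics, calls
empirical outliers, and intersects the genes they implicate. Because no two
statistics see the same footprint (diversity loss, frequency differentiation,
extended haplotypes, multilocus frequency distortion), a gene supported by at
least two of them is a far stronger candidate than any single outlier.

# Models and estimators

## Windowed diversity and ROD

Per window of length $L$, nucleotide diversity is the unbiased pairwise
estimator $\pi = \sum_j \frac{n_j}{n_j-1} 2\hat p_j(1-\hat p_j)/L$ over
variant sites $j$, with $n_j$ called haplotypes and $\hat p_j$ the alt
frequency; this equals the mean pairwise Hamming distance between sampled
haplotypes divided by $L$ (the identity is enforced by an enumeration oracle
in the tests). ROD $= 1-\pi_\text{test}/\pi_\text{ref}$; windows with
$\pi_\text{ref}=0$ or fewer than `min_snps` (default 10; chosen because
ratio noise explodes in near-empty windows) are flagged invalid and excluded
from ranking but kept in the output.

ROD is oriented with the weedy-like population in the numerator and ranked
on the upper tail (diversity *loss* in the test population). The source
literature on weedy–landrace scans does not state an orientation; this is
the one under which a sweep in the weedy population raises the score.

## Weir–Cockerham F~ST~

Per site, the r = 2 variance components $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals) are computed
exactly as published, from diploid sample sizes, alt frequencies and
observed heterozygote proportions; $\theta = a/(a+b+c)$. Negative per-site
$\theta$ is retained (standard estimator behaviour — clamping would bias
window sums). Windows are summarized as the ratio of averages
$\sum a / \sum(a+b+c)$, never the average of per-site ratios, which is both
the published recommendation and less noisy at low per-site information.

## EHH, iHS and XP-EHH

EHH from a core SNP is the probability that two random carrier haplotypes
are identical over all sites from the core out to a given position,
$\mathrm{EHH}(x) = \sum_g \binom{n_g}{2}/\binom{n}{2}$, computed by
incremental partition refinement (compiled code; verified against a
brute-force substring-grouping oracle). Two semantic choices:

- EHH at the core is **1 by definition**, and refinement uses sites strictly
  beyond the core. For iHS carrier sets (one core allele) this is the usual
  definition; for XP-EHH's all-haplotype sets it means the core's own
  alleles never split the partition, which keeps the profile's
  starts-at-one invariant for both uses.
- Gaps carry no scaling penalty: the max-gap heuristic of common scan
  software is deliberately omitted (documented divergence), because the
  simulator produces no assembly gaps and the heuristic adds a tuning
  parameter with no principled default.

iHH integrates EHH over genetic distance (cM) by trapezoids, truncated at
the first site where EHH < 0.05 (final trapezoid included). A profile that
never falls below the cutoff before the chromosome end — or within the
1-Mb physical extension cap — is invalid; cores with any invalid walk are
dropped. Note that trapezoidal integration is not invariant to inserting a
no-change site inside a sloping segment (a new knot changes the
interpolation); invariance holds exactly in flat stretches, and the tests
pin that case.

iHS = $\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$, standardized to mean 0, sd 1
within 50 equal-width derived-allele-frequency bins; bins with fewer than
20 scores merge with their right neighbour (trailing remainder folds back
left), and the merged bin id is reported per score. Ancestral alleles
default to the REF allele (`ref_is_ancestral`); an annotation table of
ancestral bases — the situation where a wild-rice outgroup is available —
overrides per site. Outliers use |iHS| (two-sided): without an outgroup the
sign is not reliably polarized. XP-EHH = $\ln(\mathrm{iHH}_A/\mathrm{iHH}_B)$
with A = test population, standardized genome-wide, upper tail (long
undecayed haplotypes in the weedy population); swapping populations negates
unstandardized scores exactly.

## Simplified XP-CLR

The test-population frequency at a neutral site is modelled as the
reference frequency plus Gaussian drift noise with variance
$\omega\, p_\text{ref}(1-p_\text{ref})$, truncated to (0,1) with the
truncated tail masses placed as point masses at 0 and 1 (observed boundary
frequencies are evaluated as those masses; the density plus masses
integrates to 1, enforced by quadrature in the tests). Near a selected site
a lineage escapes the sweep with probability $c = 1-e^{-d/s_\text{eff}}$
($d$ = genetic distance in Morgans), giving the mixture
$f = p_\text{ref}\, g(x;\, 1-c+c\,p_\text{ref}) +
(1-p_\text{ref})\, g(x;\, c\,p_\text{ref})$. At $c = 1$ this reduces
exactly to the neutral density, so the sweep model nests the neutral one at
the small-$s$ grid edge and $\mathrm{CLR} = 2(\hat\ell_\text{sweep} -
\ell_\text{neutral}) \ge 0$ (clamped at 0 against floating-point noise).

This is a deliberate simplification of the published XP-CLR: Gaussian drift
replaces the full diffusion transition and there is no LD-based SNP
down-weighting; instead, at most 200 SNPs (nearest first) enter each
window, capping correlated-SNP inflation. $\omega$ is estimated genome-wide
as $\mathrm{mean}[(p_\text{test}-p_\text{ref})^2 /
(p_\text{ref}(1-p_\text{ref}))]$ over sites polymorphic in the reference;
under pure drift of the test branch for $T$ generations its expectation is
$1-(1-\tfrac{1}{2N})^T \approx T/2N$. Per-site densities are floored at
1e-300 before taking logs so that fixed differences — astronomically
unlikely under neutrality when $\omega$ is small — yield large finite CLRs
rather than infinities. The scan maximizes the composite log-likelihood
over a 12-point logarithmic $s$ grid in $[10^{-5}, 10^{-1}]$ Morgans at
grid points every 10 kb; the outlier pipeline ranks the per-window maximum
CLR. The SNP window half-width (`window_cM`, default 0.5 cM) should match
the map scale: about half the expected hitchhiking extent in genetic units.
On the simulator's scaled map (100 cM/Mb) the equivalent value is 10 cM
(±100 kb).

## Outliers, genes, candidates

Each metric's valid records are ranked by the tail-appropriate score and
exactly $\lceil q M \rceil$ of $M$ are flagged ($q = 0.025$), ties broken
deterministically by genomic order; thresholds are applied genome-wide, not
per chromosome (the study-scale question is genome-wide ranking). Window
outliers map to genes by ≥1-bp interval overlap; site outliers by
containment within the gene extended by a configurable flank (default 0).
Genes in the top 2.5% of at least two metrics are the candidate selection
genes; a 600-kb flank query (`flank_genes`) supports inspecting the
neighbourhood of known loci such as the red-pericarp domestication gene.

## Co-expression clustering

Candidate genes are clustered across tissues (default: 11 rice tissues) by
k-means on log2(x+1), per-gene z-scored profiles (constant genes become
zero vectors and are retained), best of 10 restarts, deterministic under a
seed. A cluster is tissue-specific when its centroid deviates from its own
mean by more than twofold the centroid's across-tissue standard deviation —
the rule is applied at the **centroid** level (in log-expression space,
before z-scoring) and propagated to member genes, because a per-gene rule
on z-scored values flags noise in flat profiles; strict inequality means a
flat centroid (sd 0) is never flagged. Clusters whose mean log expression
falls below the bottom decile of gene-level means are flagged
low-expression and excluded from tissue-specific gene lists (threshold
configurable; the literature removes such a cluster without stating its
cutoff).

# The synthetic-data generator

`simulate_populations()` is a discrete-generation diploid Wright–Fisher
forward simulator: parents sampled proportional to fitness (additive at the
sweep site: 1, 1+s/2, 1+s), gametes recombining with per-adjacent-bp
probability $r$, Poisson($\mu L$) new mutations per gamete at uniform
positions with repeat hits redrawn (sites stay biallelic), a burn-in, a
split into two daughters of size $N$, and an optional sweep seeded at count
1 in the test population, with `condition_on_fixation` restarting the
test-population trajectory (RNG running on) until the allele fixes. Forward
simulation — rather than coalescent — keeps sweeps, conditioning and LD
exact by construction; the desk-scale guard ($N \le 1000$, $L \le 1$ Mb)
keeps runs in seconds. Lost sites are pruned; fixed sites are retained so
fixed differences survive the merge of the two daughters' site lists.

Default study conditions, chosen once: $N = 200$ diploids, $L = 500$ kb,
$\mu = 10^{-6}$ and $r = 10^{-6}$ per bp per generation, burn-in $2N$
generations, neutral split $T = 40$ generations, 30 sampled individuals per
population (mirroring a 30 weedy + 30 landrace resequencing design). These
are scaled-population values: $\rho/\theta = 1$ makes haplotype blocks span
tens of kb, so EHH profiles decay inside the simulated region while a hard
sweep's hitchhiking extent $\approx s/(r \ln 2Ns) \approx 90$ kb matches
one 100-kb analysis window. (At $\rho/\theta \ll 1$, recently coalesced
carrier clades are identical across every common SNP and EHH never reaches
its cutoff — the statistic is then uncomputable at this scale, which is why
the recombination rate is part of the study conditions.) The simulator
writes its own uniform genetic map, $10^8 r$ cM/Mb = 100 cM/Mb, used
consistently by all scans on simulated data; `uniform_map()`'s 4 cM/Mb
default is a rice genome-wide average for real data. The standard sweep
scenario is a 1-Mb chromosome with the sweep at 550 kb (a window center, so
the truth window is unambiguous), $s = 0.5$, seeded at the split and
conditioned on fixation with $T_\text{split} = 60$, so fixation completes
just before sampling — the "recent selection" regime the five statistics
target; with longer post-fixation time, drift and new mutation erode the
local signal into a high genome-wide background.

Scenario sizes used by the test suite and the acceptance script: the
standardization null uses $L = 1$ Mb with $\mu = 10^{-5}$ so that over
10,000 valid iHS scores exist genome-wide; drift calibration uses 50
replicates at the default conditions; power experiments use 20 (test
suite) or 10 (acceptance script) sweep replicates.

`drift_only()` is the fast frequency-only null: ancestral frequencies from
a 1/x-shaped grid, then binomial(2N) resampling. The test branch drifts `T`
generations and the reference branch `t_ref` (default 0, i.e. the reference
tracks the ancestral frequency). The default is asymmetric *by design*:
$\omega$ in the XP-CLR model is the variance of the test frequency around
the observed reference frequency, and the calibration
$E[\hat\omega] = 1-(1-\tfrac{1}{2N})^T$ holds exactly for drift along the
test branch alone; with both branches drifting `T` steps the variance
doubles. Set `t_ref = T` for a symmetric split.

What the generator does **not** emulate: selfing and inbreeding (rice is
largely selfing; genotypes here are HWE by construction), missing data and
genotyping error, gene conversion, soft sweeps and standing-variation
sweeps, migration after the split, and realistic gene annotation (genes are
tiled deterministically every 20 kb, length 5 kb, so gene-mapping tests are
reproducible). Passing tests therefore demonstrate correctness of the
statistics and power under idealized hard-sweep conditions, not expected
power on real resequencing data.

# Numerical choices and degenerate inputs

- MAF filter boundary: a site at exactly MAF 0.05 is **kept** (the
  published rule removes MAF < 0.05).
- Window step defaults to the window size (non-overlapping); internal
  coordinates are 0-based half-open, VCF/GFF native 1-based, BED output
  0-based half-open.
- $\lceil qM\rceil$ outliers with genomic-order tie-breaking makes outlier
  sets reproducible byte-for-byte.
- `estimate_omega` floors an exactly-zero estimate at 1e-6 with a warning
  (the degenerate identical-population case).
- LD: phased input uses haplotype $r^2 = D^2/(p_Aq_Ap_Bq_B)$; unphased uses
  squared dosage correlation (composite LD). Monomorphic sites never pair.
- PCA: dosages mean-imputed per site, centred by $2\hat p$, scaled by
  $\sqrt{2\hat p(1-\hat p)}$; monomorphic sites dropped; coordinates are
  left singular vectors scaled by singular values.
- All randomness flows through R's RNG (including compiled code), so a
  single `set.seed()` reproduces any run exactly.

# Known limitations

The simplified XP-CLR ranks sweeps well but its CLR magnitudes are not
comparable to the published diffusion-based implementation; within the
swept region the composite-likelihood surface is nearly flat, so
sub-window localization of the argmax is not meaningful — the windowed
maximum is the intended summary. iHS drops cores whose EHH never reaches
the cutoff (chromosome edges, very recent carrier clades), which on short
simulated chromosomes discards an appreciable fraction of low-frequency
cores; this mirrors the behaviour of standard scan software on real
contigs. The co-expression module clusters whatever expression matrix it is
given; it does not fetch or bundle any expression database.
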
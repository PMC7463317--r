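---
title: "Methods: population-structure analysis of biallelic SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-structure analysis of biallelic SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one defensible option
existed. The workflow mirrors the standard population-genetics analysis
chain for SNP panels in fisheries stock identification: data filters →
diversity and equilibrium tests → pairwise differentiation → outlier
scans → Bayesian clustering and K selection → admixture-zone diagnosis →
individual assignment → isolation by distance.

## Data model and filters

`SnpGenotypes` stores biallelic genotypes as allele dosages (0/1/2, `NA`
missing) with a collection (sampling-site) factor and per-locus /
per-collection metadata. Genepop files are read with both 2- and 3-digit
allele codes accepted and always written with 3-digit codes; an all-zero
allele code means missing, and a call with any missing allele is treated
as wholly missing. Allele codes map to first/second allele by ascending
numeric code, which makes write∘read the identity on the dosage matrix.

Two filters reproduce common panel-construction practice:

* **Individual purge.** Individuals with a missing-call fraction
  *strictly above* 0.30 are removed; a tie at exactly 30% is retained.
  The strict inequality is deliberate: the rule is stated as ">30%
  missing" and ties belong to the kept side.
* **Panel-design filter.** Candidate RAD loci are retained when they
  carry exactly one diallelic SNP, the SNP sits between read positions 41
  and 95 *inclusive* (the bounds leave flanking sequence for primer
  design; "between" is read inclusively and documented here), and the
  minor allele occurs at least twice among the discovery haplotypes (two
  per discovery individual).

Monomorphic loci are retained in the matrix but flagged; each statistic
decides its own handling (they contribute zero variance components to
θ, are untestable for HWE/LD, and have uHe = 0).

## Diversity, Hardy–Weinberg and linkage disequilibrium

Per collection and locus: Hₒ is the heterozygote fraction among
non-missing calls; uHe = [2n/(2n−1)]·2p(1−p) with n the non-missing
individual count (the small-sample-corrected gene diversity); and
FIS = (uHe − Hₒ)/uHe, the convention used by the GenAlEx lineage of
tools, computed per locus and averaged. Summaries are reported as
mean ± SE with SE = sd over loci / √L, matching the usual sample-summary
table layout.

The Hardy–Weinberg test conditions on the observed allele counts
(Levene): for two alleles the distribution of the heterozygote count is
one-dimensional with fixed parity, so we enumerate it *completely*
instead of running the customary Markov chain — the result is the exact
probability test (sum of outcomes no more probable than observed) with
deterministic output. The classic chain configuration (dememorization,
batches, iterations per batch) is retained as the configuration of a
Monte-Carlo cross-check mode that samples from the same conditional
distribution; it exists to validate the enumeration, not to replace it.
One-sided deficit/excess p-values are lower/upper tail sums and the
reported direction is the smaller side. Exact tests are conservative at
small n because of discreteness; the acceptance suite documents the
realized type-I rate band ([0.03, 0.07] at α = 0.05, n = 100).

Genotypic LD uses the log-likelihood-ratio G statistic on the 3×3
genotype table of a locus pair within one collection, with significance
from permutations of one locus' genotypes across individuals and the
unbiased (1 + k)/(1 + N) estimator; seeds are recorded. For ≤8
individuals an exhaustive mode enumerates all n! permutations and
returns the exact permutation p (used as the test oracle).

Family-wise correction is Holm's sequential Bonferroni, implemented via
`p.adjust(..., "holm")` — the identical step-down rule — and exposed as
`holmSequentialBonferroni()` returning rejection flags in input order.

## Weir–Cockerham θ and its permutation test

θ is estimated from the 1984 variance components a (among populations),
b (among individuals within populations) and c (within individuals),
computed per locus from per-group sample sizes, allele frequencies and
observed heterozygote frequencies; the multilocus estimate is the
ratio of sums Σa / Σ(a+b+c). Per-locus sample sizes account for missing
data; loci observed in fewer than two groups drop out of the sums;
negative estimates are reported as computed (no truncation), which keeps
the downstream FST/(1−FST) regression unbiased. Significance permutes
individuals between the two groups preserving sizes, again with the
(1 + k)/(1 + N) estimator, and Holm correction is applied *jointly*
across all pairwise tests of the matrix. The test suite cross-checks the
estimator against an independently coded allele-indicator ANOVA
formulation (sums of squares → mean squares → components), and the
permutation p against exhaustive relabeling on small groups.

Waterway distances are an input; a haversine great-circle helper exists
as a clearly labelled fallback only. Isolation by distance regresses
θ/(1−θ) on distance by OLS, reporting slope, R² and the two-sided slope
test.

## Outlier scans and the consensus rule

**FDist-style envelope.** The neutral joint distribution of (pooled
expected heterozygosity, per-locus FST) is simulated under a symmetric
island model: ancestral frequency uniform on (0.02, 0.98), per-group
frequencies Balding–Nichols around it with drift equal to the target
FST, genotypes multinomial Hardy–Weinberg at the observed group sizes.
The target ("forced") mean FST is estimated from the data by iterative
trimming: loci outside a provisional envelope are excluded and the
neutral mean re-estimated, with two refinement passes (the refinement
count is a package choice; more passes changed nothing in calibration
runs). Simulating Balding–Nichols frequencies directly, rather than
explicit island-model genealogies, matches the F-model that both the
Bayesian scan and the clustering model assume, and for biallelic SNPs
the joint (He, FST) null is the island-model target by construction; an
"infinite allele" null is honored only in spirit for diallelic data. The
nominal deme count (default 100) is carried in the settings for
interface parity but does not enter the Balding–Nichols calibration.
Empirical quantiles at the configured confidence (default 0.95, i.e.
0.025/0.975, a 0.05 two-sided significance) are computed in 20
equal-count heterozygosity bins and smoothed to be monotone in He by
isotonic regression. Loci above the upper (below the lower) quantile are
directional (balancing) candidates.

**Bayesian F-model.** The locus-by-population FST is decomposed on the
logistic scale as αᵢ (locus) + βⱼ (population); allele counts are
beta-binomial (the Balding–Nichols frequency integrated out); a
per-locus indicator switches αᵢ by reversible jump with prior odds 10
for neutrality (the tool-of-record default; configurable), prior
αᵢ ~ N(0,1), βⱼ ~ N(−1,1.8). The posterior probability of selection is
the indicator's inclusion frequency; loci above 0.99 are flagged and the
log10 Bayes factor is reported alongside (the 0.99 threshold corresponds
to "decisive" evidence at these prior odds). A q-value per locus is the
mean posterior error probability among loci at least as extreme.

**Consensus and the balanced pairwise-region design.** Only loci flagged
by both procedures are retained. The global all-collections consensus is
available, but with many collections nested inside few strongly drifted
clusters the F-model's independence assumption is violated and its
false-positive rate inflates (a known hierarchical-structure artifact we
reproduce on synthetic data). The balanced pairwise-region design —
pool each region, draw equal-size random subsets per side, scan each
region pair, intersect per pair, union across pairs — removes the
hierarchy from each scan and is the calibrated procedure the acceptance
suite exercises. The subset size defaults to the smallest region size.

## Admixture clustering

The Gibbs sampler implements the admixture model with correlated allele
frequencies and no location prior: per-locus ancestral frequencies
(uniform prior), per-cluster frequencies Beta-distributed around them
with drift Fₖ (prior Beta(1, 99), mean 0.01), individual ancestries
Dirichlet(α) with α uniform on (0, 10) updated by a random-walk of sd
0.025, and latent per-allele-copy origins. The compiled core updates
copies, Q rows and cluster frequencies by Gibbs and the remaining
parameters by Metropolis. The evidence estimate for K selection is
L = mean(lnL) − var(lnL)/2 over post-burn-in sweeps; ancestry
coefficients carry equal-tailed 90% credible intervals from thinned
retained sweeps (default thin 50 at full chain lengths).

Replicate runs are aligned by maximizing the average pairwise G′
similarity 1 − ‖Q_a − Q_bΠ‖_F/√(2n) over cluster-label permutations:
exhaustively over the joint permutation space when it is small (run 1
fixed), otherwise sequentially against the running mean with iterative
refinement until stable (also the K > 8 fallback). The alignment argmax
is invariant to any monotone normalization of the similarity, so the
exact constant in G′ is immaterial (tested).

ΔK is the mean over replicates of |L(K+1) − 2L(K) + L(K−1)| divided by
the replicate sd of L(K), defined for interior K and reported as NA when
the sd vanishes; replicate sd values are exported rather than
reinterpreted when they differ wildly across K. The four
collection-based statistics (MedMed, MedMean, MaxMed, MaxMean) count
clusters in which at least one collection's median/mean membership
exceeds 0.5 per run, then take the median/max across runs; the chosen K
per statistic is the plateau height — the maximum of the statistic over
the K grid — since the statistics count supported clusters.

Chain lengths: the heavy profile carries full-scale survey settings
(100,000 burn-in + 1,000,000 sweeps × 10 replicates for K = 1..10); the
test profile scales this down about 100-fold. The scaled problem sizes
used by the acceptance suite are stated below.

DAPC centres dosages (locus-mean imputation of missing calls), reduces
by PCA — retaining by default the smallest PC count explaining ≥90% of
variance, capped at n/3 (the original method leaves this choice open) —
and runs LDA on the retained scores. When groups are internally
(near-)constant and the within-group scatter is singular, the PC count
is reduced and, at the degenerate limit, a ridge-regularized
discriminant eigenanalysis substitutes for the standard LDA solver.
Per-axis percentages are shares of discriminant variance; per-locus
contributions rotate the discriminant coefficients back through the PCA
rotation and are normalized per axis.

## Admixture-zone diagnosis and assignment

F1 hybrids are simulated by the gamete rule: parental allele frequencies
estimated from randomly selected pool subsets, each hybrid drawing one
allele per locus from each pool, independently across loci. An
individual is classified *admixed* when its 90% credible intervals for
the two focal clusters' ancestries overlap, otherwise pure toward the
higher posterior mean. This operationalizes "overlapping confidence
intervals" as focal-pair interval overlap — the alternative (interval
containing 0.5) is computable from the same output but is not used for
headline numbers. The definition is monotone: widening intervals can
only move individuals toward admixed.

Assignment uses the posterior-predictive genotype probability under each
baseline with a symmetric Dirichlet prior (λ = 1/2 per allele for
biallelic data, the Rannala–Mountain convention), the compound
(sequential-sampling) form for the two alleles of a genotype, and
leave-one-out removal of a query's own alleles from its baseline.
Log-probabilities are summed over typed loci and normalized across
baselines; alleles unseen in a baseline get nonzero probability through
the prior.

## The synthetic-data generator

`simConfig()` describes a Balding–Nichols hierarchy: ancestral
frequencies uniform on a configurable range (default (0.05, 0.95), which
reproduces the moderate mean diversities typical of ascertained assay
panels), cluster frequencies drifted with per-cluster F, collection
frequencies drifted around their cluster with a small within-cluster F
(default 0.005, matching the near-zero within-region differentiation of
the study system). Pure individuals draw two binomial gene copies from
their collection's frequencies; F1 individuals one copy from each
parental cluster; missing calls are masked uniformly at random.

**Outlier loci.** Loci under divergent selection are emulated by pulling
one randomly chosen cluster toward the opposite allele-frequency extreme
(target 0.9 if the ancestral frequency is below 0.5, else 0.1) with the
Balding–Nichols variance inflated by the configured multiplier (capped
at F = 0.95). A pure variance-inflation model — simply multiplying F at
outlier loci — was evaluated first and rejected: with strong drift all
clusters co-fix the *same* allele in a large fraction of draws, so a
sizeable share of nominal "outliers" realize near-zero divergence and
near-monomorphism, which no scan can detect and which does not resemble
empirically observed outlier loci (strongly divergent yet polymorphic).
The directional mechanism preserves the multiplied-drift magnitude while
guaranteeing that outlier status means divergence.

**The "sprat-like" preset** encodes the study geometry the acceptance
suite exercises: three clusters with drift 0.05/0.12/0.25 (fjord-like,
Atlantic-like, Baltic-like; pairwise FST roughly 0.09–0.19), 15/14/8
collections per cluster plus three transition-zone collections holding
73% F1-like admixed and 27% pure individuals (between clusters 2 and 3),
91 loci with 9 (~10%) outliers at multiplier 5, 60 individuals per
collection (~2,580 total), and a 5% per-call missing rate — chosen so
that about 98% of individuals have <10% missing calls, the missingness
profile of a clean assay run.

What the generator does *not* emulate: linkage between loci (loci are
independent, so LD tests on generated data measure pure type-I
behavior), demographic history (bottlenecks, migration-drift
disequilibrium, isolation-by-distance gradients within clusters),
genotyping artifacts (allelic dropout, clustering errors), and
ascertainment beyond the ancestral-frequency range. Passing recovery
tests on these data therefore demonstrates correctness of the estimators
under the F-model's own assumptions — not robustness to demographic or
technical violations of them.

## Numerical choices and problem sizes

* Permutation p-values always use (1 + k)/(1 + N); exhaustive modes
  return exact proportions including the identity relabeling.
* The FDist envelope drops simulated loci with pooled He below 1e−4;
  frequencies are clamped to [1e−6, 1 − 1e−6] throughout the samplers.
* The admixture sampler records the sweep ln-likelihood after burn-in
  at every sweep and thins only the stored Q samples; Q rows are
  re-normalized draws of Gamma variates with a 1e−9 floor.
* Ties in the HWE probability test are included with a 1 + 1e−9
  relative tolerance, so equal-probability outcomes count as "no more
  probable".
* The acceptance suite runs desk-scale versions of every study: type-I
  calibration at 1,000 permutation tests and 2,500 exact tests; outlier
  calibration/power at 20 preset replicates with 20,000 null iterations
  and short (600 × 2 + 1,000) F-model chains per region pair; clustering
  recovery at 150 individuals × 91 loci with 3,000 + 8,000-sweep chains
  (ancestry RMSE) and 10 repetitions of K = 1..5 grids with 5 replicates
  of 500 + 1,200-sweep chains (K selection; collections are pure sampling
  units of their cluster there, since the stated condition is three
  clusters — with within-cluster drift the Max-family statistics
  correctly resolve the collections as extra clusters once chains
  converge); the hybrid diagnostic at
  450 individuals × 91 loci with 1,500 + 4,000-sweep chains. These sizes
  are the package's chosen scaled study conditions; the "paper" profile
  in `runPipeline()` carries the full-scale settings.
* The clustering-recovery conditions include the panel's ~10%
  elevated-divergence loci. On an all-neutral FST-0.10 panel of 91 SNPs
  the posterior itself is diffuse — fully converged chains leave ~0.9
  posterior-mean own-cluster ancestry for pure individuals — so ancestry
  recovered to RMSE ≤ 0.06 is a property of the realistic panel
  composition (background 0.10 plus outliers), not of longer chains.

## Known limitations

* The F-model outlier scan inherits the hierarchical-structure
  false-positive inflation of its model family when collections are
  nested in strongly drifted clusters; use the balanced pairwise-region
  design in that setting (the package reproduces this artifact on
  synthetic data, and the global scan remains available for comparison).
* ΔK is undefined at boundary K and unstable when replicate sds are
  tiny; with few replicates it occasionally prefers K = 2 on genuinely
  three-cluster data (the acceptance criterion tolerates this at the
  observed rate). The Puechmaille statistics are more stable under the
  package's conditions.
* The exhaustive CLUMPP-style alignment is limited to small joint
  permutation spaces; the greedy refinement fallback can in principle
  return a local optimum.
* No LOCPRIOR or uncorrelated-frequencies clustering variants, no
  linkage model, no F2/backcross classes in the headline workflow (the
  generator can produce them for power studies), no AMOVA, and no VCF
  input in this version.
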
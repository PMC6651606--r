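---
title: "Methods: comparative evolution of UPS gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative evolution of UPS gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`upsdiverge` implements a comparative pipeline for studying how the gene
families of the ubiquitin–26S proteasome system (UPS) diverge between two
plant lineages (a Brassicaceae-like and a Poaceae-like clade). The pipeline
has five analysis stages — family annotation from protein-domain hits,
orthologous-group construction with age ranking, recent-duplication
classification, pairwise selection analysis with a neutrality test, and
between-lineage comparative statistics — plus a synthetic-genome generator
that plants known ground truth so that every stage is recovery-testable.
This vignette records the models, the parameter choices, and the design
decisions behind each stage.

# Family annotation

Each protein is assigned to one of 11 UPS families (E1, E2, FBX, RING, BTB,
HECT, APC, Cullin, Skp1, and the proteasome RP and CP subunit families) from
its table of protein-domain hits. A hit table is filtered at an E-value
cutoff of 1 — deliberately permissive, because family membership is decided
by domain *combinations*, not by a single strong hit. A locus matches a
family when all domains of any one of the family's combinations are present;
for example, a Cullin assignment requires both the Cullin and the
Cullin_Nedd8 domain, and the RP family is defined by a list of eleven
combinations such as RPN7 + PCI or VWA_2 + UIM. Two of the shipped RP
combinations (YfdX + PCI; MitMem_reg + Peptidase_M13_N) are unusual pairings
retained verbatim from the curated rule set rather than reinterpreted. The
prokaryotic Prok-RING_4 domain never counts toward a RING assignment.

Rules live in an editable YAML file (`inst/extdata/family_rules.yaml`)
because the RING subfamily list in particular tracks the release-dependent
composition of the RING clan. When a locus matches several families it is
resolved by a fixed priority order (Cullin, APC, RP, CP, E1, HECT, E2, Skp1,
FBX, RING, BTB) — multi-domain-defined and rarer families first, so that an
F-box protein that also carries a BTB domain is counted once, as FBX. Domain
coordinates are not used; membership is presence/absence only. Pseudogene
status is an input flag supplied by the caller, not computed here.

The accessory domains of a locus — every hit domain that is not part of the
assigned family's defining combinations — form its *subfamily signature*.
Signatures drive both the tandem-duplication rule ("same subfamily") and the
domain-enrichment comparison.

# Orthologous groups and age ranks

All-vs-all protein similarity rows are converted into a weighted undirected
graph: the default weight is −log10(E-value), capped (default 200) so that
zero E-values stay finite, with reciprocal asymmetric rows averaged; a
raw-score mode is available. The graph is clustered with a native
implementation of the Markov Cluster (MCL) algorithm: self-loops equal to
each node's maximum incident weight, column normalization to a stochastic
matrix, then alternating expansion (matrix squaring), inflation (entrywise
power, default 1.5, then renormalization) and pruning of entries below 1e-5,
iterated until the maximum entrywise change falls below 1e-6 (at most 200
iterations; non-convergence is an error, not a silent truncation). Clusters
are read off as connected components of the converged matrix's non-zero
structure, so the output is always a partition of all loci. The inflation
default of 1.5 is the standard granularity used for orthologous-group
construction in this family of analyses; prune threshold, tolerance and
iteration cap are ordinary MCL practice. Full OrthoMCL-style normalization
(inter-species weight rescaling, reciprocal-best-hit weighting) is
deliberately simplified to symmetric transformed scores: the downstream
analyses depend only on group membership, and the recovery tests (adjusted
Rand index ≥ 0.95 on planted graphs; exact recovery on the synthetic
genomes) validate the simplification.

Age ranks stratify the focal species' orthogroups by the nested
species-presence ladder: rank 0 when the focal species is alone; rank 6 when
the non-focal within-family presence is exactly {Aha}; 7 for {Aha, Ath}; 8
for {Aha, Ath, Cru}; 9 adding Bst; 10 adding Bra; and A (ancient) when the
full within-family set is present *and* the outgroup (Atr) or any species of
the other plant family is too. The A rule is our operational definition of
"conserved in flowering plants": presence across the whole family plus at
least one lineage that split before the family radiated. Everything else —
presence patterns that skip a rung, or outgroup hits without the full family
set — is `non_ranked` under the default strict mode. A lenient mode (rank =
deepest ladder split represented) is available behind a flag for sensitivity
analyses. Groups without a focal-species locus get an explicit
`not_applicable` label rather than an error, since second-family groups are
a normal part of a joint clustering. Whether the two plant families are
clustered jointly or separately is left to the caller (both work; the ladder
configuration carries the second family's species names either way).

# Recent duplications

Two genes are called tandem when they belong to the same subfamily (family +
accessory signature by default; family-only mode available), lie on the same
chromosome, are separated by at most 10 intervening gene loci, and their
spans are at most 300 kb apart. "Separated by 10 or fewer genes" is read as
at most 10 intervening annotated loci of any family (order-index difference
≤ 11), counted against the full gene complement; the distance is the
end-of-upstream to start-of-downstream gap, the most permissive reading of
"located within 300 kb". Both thresholds are configurable, and the relation
is symmetric by construction.

A locus is intronless — the retrotransposition proxy — when its
representative transcript consists of a single exon. Intron counts are
defined per locus, which leaves the choice of representative open when a
locus has several isoforms; we adopt the transcript with the longest total
CDS (a locus with a 1-exon minor isoform but a 3-exon longest isoform is
*not* intronless).

Enrichment of tandem or intronless status between two genomes is tested per
family with Fisher's exact test (two-sided) on the 2×2 genome × status
table.

# Pairwise selection analysis

## The codon model

Selection on an orthologous pair is estimated under a GY94-style codon
model: the state space is the 61 sense codons of the standard genetic code;
instantaneous rates allow single-nucleotide changes only, proportional to
the target codon frequency, multiplied by κ for transitions and by ω for
nonsynonymous changes; the matrix is scaled so one unit of divergence t is
one expected substitution per codon. Codon frequencies default to uniform;
an F3x4 mode (positional nucleotide frequencies estimated from the pair,
Laplace-smoothed) is available by flag for sensitivity analyses. Transition probabilities come from one
symmetric eigendecomposition of the similarity-transformed generator, reused
across all divergence values during optimization.

The pair log-likelihood is Σ log(π_i P(t)_{ij}) over codon columns, which by
time-reversibility does not depend on which sequence is called ancestral.
Maximization is deterministic: a fixed 3×3 grid over (κ, ω) with t profiled
out by one-dimensional search, then bounded L-BFGS-B refinement from the two
best starts on the log scale (bounds t ∈ [1e-6, 50], κ ∈ [1e-3, 100],
ω ∈ [1e-4, 20]), finished by an exact one-dimensional re-profiling of t at
the refined (κ, ω). Identical sequences sit on the t lower bound by design.
The converged flag reports the optimizer's own exit status, and pairs whose
fits did not converge cleanly are flagged and excluded from downstream
summaries (the neutral fraction, age trends, lineage comparisons).

## Ka, Ks, and the neutrality test

The fitted divergence is partitioned into per-site rates using expected
flux fractions: with ρS(ω) the synonymous share of substitutions under the
fitted matrix and ρS1 the synonymous share of *sites* (the same matrix at
ω = 1), Ks = t·ρS(ω̂)/(3·ρS1) and Ka analogously, so Ka/Ks equals the
fitted ω̂ exactly. The classical Nei–Gojobori (1986) counting estimate is
computed alongside: per-position synonymous site fractions by one-step
neighbor enumeration (changes to stop codons excluded from numerator and
denominator, so each codon still contributes three sites), differences
averaged over all minimal mutational pathways (stop-transiting pathways
discarded unless all are blocked), and Jukes–Cantor correction
d = −(3/4)·ln(1 − 4p/3), flagged undefined when the argument saturates.
Saturated pairs are retained for ML fitting but flagged.

The neutrality test compares the free-ω fit against ω fixed at 1:
LR = 2(lnL_free − lnL_fixed). The free fit is additionally seeded with the
fixed fit's solution, so the nested likelihoods can never invert beyond
numerical noise; small negative LR values (within 0.05) are clamped to zero
and anything worse is treated as an optimizer failure, not silently
accepted. A pair is called neutrally evolving when LR < 2.71, the 5%
critical value of χ²(1) — used one-sided because the null ω = 1 lies on the
boundary of the alternative, making 2.71 the 90th percentile of χ²(1). The
source prints the likelihood ratio as 2(lnML1 − lnML2) without fixing which
run is ML1; we implement free-minus-fixed, the only ordering consistent
with the stated χ² usage.

## Summary statistics

The age trend of Ka, Ks, ω, or the per-rank neutral fraction is a Spearman
rank correlation against the numeric age rank, with midranks for ties and an
exact p-value when up to nine untied values are correlated (the per-rank
neutral-fraction case), otherwise the t approximation. The ancient rank A is
excluded by default — it is not part of the within-family ladder. A constant
series is an error rather than a silent rho of NA, and the correlation and
its p-value are always reported as an explicit (rho, p) pair.
Between-lineage comparisons use the
two-sided Wilcoxon rank-sum test, exact for small untied samples and
normal-approximated with tie correction otherwise, reporting the direction
of the median difference.

# Comparative statistics

Per-family sizes between the two species groups are compared with two-sided
Wilcoxon rank-sum tests at α = 0.05; accessory-domain counts per genome with
two-sample Student's t-tests (pooled variance, matching the stated test; not
Welch) at α = 0.01. No multiple-testing correction is applied by default — results are
reported at nominal thresholds, as is conventional for this style of
descriptive family-size comparison; a Benjamini–Hochberg option exists
behind the `p_adjust` argument. A
zero-variance category with equal means is reported as non-significant
rather than raising an error. Count profiles are clustered on both axes
with Manhattan distance and Ward linkage ("ward.D") — classical Ward applied
to unsquared distances, even though Ward's criterion formally assumes
squared Euclidean; this pairing is the one conventionally used for
heatmap-style two-way clustering of count profiles. Orphan
(singleton-group) loci can be excluded from the profiles by the caller;
"orphan" is taken to mean a locus whose orthogroup contains only itself.

One caveat the synthetic fixtures make visible: the rank-sum comparison
treats the species of a group as independent samples, but related species
share most of their gene complement by descent, so a single ancestral
expansion shifts a whole clade and can produce clade-level size differences
without any planted bias (phylogenetic pseudoreplication). This is a
property of the comparative method itself, faithfully reproduced here —
nominal significance on family-size comparisons between clades should be
read as descriptive, not as evidence of independent repeated expansion.

# The synthetic genome generator

## What it emulates

The generator plants a two-family, 13-species study design: a focal species
(Aly) with five nested relatives (Aha, Ath, Cru, Bst, Bra), an
ancestral-angiosperm outgroup (Atr), and a second family of six species
(Osa, Obr, Opu, Lpe, Bdi, Sbi). Orthologous groups are born along the
speciation ladder: ancestral groups (age A) are present in every species;
a group born on the branch leading to a nested set is inherited by exactly
the species that diverged later, so the species-presence pattern of every
group encodes its planted age. Births are Poisson per family per branch with
rate birth_rate × branch weight: internal ladder branches have weight 1, the
clade-root branch carries `root_weight` (default 3, reflecting that most UPS
family expansion predates the within-family radiation, which is why most
members sit in the old age ranks), and each species' terminal branch is
weighted by the number of ladder steps it has evolved alone — making
expected root-to-tip birth counts clock-consistent across species, so
family sizes are comparable within a clade rather than piling up on the
focal lineage. Per-clade, per-family bias multipliers (`family_bias`) plant
deliberate family-size shifts between the two clades for the comparative
recovery experiments.

Each birth duplicates an existing family member: with probability
`tandem_fraction` (default 0.3) the copy is tandem — placed at the end of
its template's array in every descendant genome, so arrays stay contiguous
and every copy is adjacent to a same-subfamily sibling; with probability
`retro_fraction` (default 0.15) it is a retrotransposition, intronless in
every descendant; otherwise dispersed. Tandem copies inherit the template's
accessory domain (hence its subfamily signature); other births get a fresh
accessory domain, unique per lineage by default so that subfamily identity
exactly traces duplication history (a shared `accessory_pool` can be
supplied instead). Gene losses are per-lineage Bernoulli with probability
1 − (1 − death_rate)^(steps present); a death rate that wipes out an entire
family is an error naming the family. A configurable fraction (default 5%)
of loci in the two youngest age classes is flagged pseudogene; downstream
stages treat the flag as given.

Genes are laid on one chromosome per species at uniform 30 kb
start-to-start spacing (configurable), so adjacent genes sit well inside
the 300 kb tandem window while a handful of intervening genes can push a
pair outside the 10-gene window — both sides of the rule are exercised. The 300 kb window implies a
gene-density assumption with no single canonical value, hence the spacing
is a parameter rather than a constant.

Coding sequences evolve from a per-group random ancestral sequence (uniform
over sense codons, default 300 codons) down each species' branch under the
GY94 model with κ = 2 and a class-specific ω (`omega_by_class`, default
declining 0.7 → 0.1 from the youngest class to age A, so the planted age
trend of selection strength is recoverable). Branch lengths grow with age
class (t_min + t_step × (depth − 1), defaults 0.02 and 0.05 substitutions
per codon). Substitution is sampled exactly from the matrix-exponential
transition probabilities — per-codon draws from P(t), not a Gillespie
simulation — for speed and determinism; because the state space is the
sense codons, internal stops cannot arise. Each orthogroup's ancestor is
drawn independently, so sequence similarity encodes group membership; the
all-vs-all similarity table reports percent identity × length on ungapped
comparison of equal-length family members, with cross-family and
below-threshold (default 30% identity) pairs omitted, the simplest signal
sufficient for clustering recovery.

## What it does not emulate

No intergenic sequence, no indels, no whole-genome duplications, no
among-site rate variation, no real domain-coordinate structure, and
star-shaped within-group divergence (every member evolves independently from
the group ancestor at equal depth) instead of the true species tree inside
each group. Passing recovery tests on these fixtures therefore demonstrates
that the pipeline's rules and estimators are implemented correctly and are
mutually consistent — not that they are robust to alignment error,
annotation noise, or rate heterogeneity in real genomes.

# Problem sizes and numerical choices

The packaged analyses and tests run at desk scale, chosen to exercise every
code path with comfortable statistical margins: LRT calibration uses 200
simulated pairs of 500 codons at t = 0.5 for each of ω = 1 (expected neutral
call rate 90% at the 2.71 cutoff) and ω = 0.05 (near-total rejection); ω
recovery uses 100 replicates at each of ω ∈ {0.1, 0.5, 1, 2}; NG86/ML
concordance uses 30 low-divergence pairs (t ≤ 0.2), where the two methods
agree within 20% despite NG86's equal-rate site counting (at κ = 2 NG86
overestimates Ks modestly; the generator's ω = 1 sanity check is run at
κ = 1 where the NG86 assumptions hold exactly); clustering recovery uses 20
planted groups across 6 species; and the comparative recovery experiment
uses 20 simulated 13-genome studies with 2× planted biases (FBX in the
Brassicaceae-like clade, BTB in the Poaceae-like clade).

Numerical details worth recording: likelihood optimization is wholly
deterministic (fixed grid + bounded quasi-Newton), so identical inputs give
identical fits on any platform; transition-probability entries are floored
at zero after the eigendecomposition round-trip; pattern probabilities are
floored at 1e-300 inside logs; the MCL stochastic matrix renormalizes
columns that pruning has emptied to an absorbing self-loop; and every
randomized package function takes an explicit seed and restores the
caller's RNG state.
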
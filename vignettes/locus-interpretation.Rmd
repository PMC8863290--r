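---
title: "Interpreting GWAS loci with regulatory evidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting GWAS loci with regulatory evidence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relociate)
```

# The problem

Most disease-associated GWAS variants fall outside coding sequence and are
presumed to act through gene regulation. For any one locus three questions
follow: which gene(s) does the marker variant actually implicate; is the
marker tagging a genuine cis-regulatory variant; and how many independent
functional variants does the locus contain? `relociate` implements a
desk-scale pipeline for all three, together with a deterministic synthetic
data generator so that every stage can be validated against planted truth
without controlled-access genotype or expression data.

# Candidate-gene expansion and tier classification

A locus is a set of marker variants plus the gene set `G` annotated by the
GWAS. Evidence genes `Q` are collected by three routes, in this order of
attribution: exact-identity matches of the marker against cis-eQTL
catalogues (a gene counts once per tissue), the same for cis-sQTLs, and
strand-agnostic transcript overlap — any gene with a transcript whose span
(introns included) covers the marker position. Exact matching is a
deliberate choice over probabilistic colocalization: it assumes nothing
about the number of causal variants per locus, at the cost of missing
overlap when GWAS and QTL analyses tag the same signal with different
markers.

The tier label compares `Q` with `G`:

| condition | tier |
|---|---|
| `Q` empty | 3 |
| `Q` non-empty, `Q ⊆ G` | 1 |
| new genes, `G ⊆ Q` | 2A |
| new genes, partial overlap | 2B |
| new genes, no overlap | 2C |

An empty `G` with non-empty `Q` has no analogue among real catalogued loci;
we label it 2C (all genes are new) and cover it in tests. Evidence is
unioned across a locus's markers before classification, so adding a marker
can only move a locus out of Tier 3, never into it.

Loci left without any annotation (Tier 3) can be rescued by proxy
expansion: all panel variants within a 1 Mb window (interpreted as ±500 kb
around the query, configurable) with `r² > 0.8` (strict) join the marker
set and the QTL match is repeated.

`cad_tier1_catalog()` ships a transcription of the published worked
example — seven coronary-artery-disease loci whose QTL and positional
support points exclusively at the GWAS-annotated genes, including one
two-marker locus and one locus where only one of two annotated genes is
supported. `cad_tier1_assignments()` reproduces the Tier-1 count of 7.

# Linkage disequilibrium

Phased statistics use the textbook closed forms: `D = p_AB − p_A p_B`,
`r² = D² / (p_A(1−p_A) p_B(1−p_B))`, and `D′ = |D|/D_max`. Unphased
dosages are handled either by EM over the double-heterozygote phase
ambiguity (the default, matching standard genetics practice) followed by
the phased formula, or by the composite squared Pearson correlation of
dosages. The EM equals the phased computation exactly when no sample is
doubly heterozygous; when *every* informative pair is doubly heterozygous
the likelihood is symmetric in the two phase resolutions and the boundary
solution is returned with an `ambiguous` attribute. Missing genotypes are
pairwise-deleted with a floor (default 20 informative pairs) below which
the computation refuses to run. All published-style thresholds
(`r² > 0.8`, `> 0.9`, `< 0.1`) are strict inequalities.

# Allelic expression imbalance

At a heterozygous site the reference-allele read fraction `REF_RATIO` is
compared with `NULL_RATIO`, the expected fraction under equal allelic
expression *including* mapping/reference bias, so bias absorbed by the
null produces zero expected deviation. The per-sample call is a two-sided
exact binomial test of the reference count against `NULL_RATIO` at
α = 0.05 with a minimum informative depth of 8 reads; all three settings
are parameters because no published rule defines "exhibits AEI" — this is
the central documented gap. Calls are deliberately not multiplicity-
corrected within a variant-tissue cell (counts of raw per-sample calls are
the quantity of interest); Bonferroni across variants is available where a
family-wise statement is needed.

Two calibration facts matter when interpreting call rates. First, the
exact binomial test is conservative at realistic depths: at negative-
binomial depth with mean 50 its average true size is ≈0.035, not the
nominal 0.05, so null call rates sit below nominal — our calibration tests
check the rate against the enumerated exact size, plus the nominal upper
envelope. Second, per-sample power is modest: against an allelic
fold-change of 2 (expected ratio 2/3) the exact test's power is 0.43 at
depth 30 and only reaches 0.9 near depth 100. Counts of samples
"exhibiting AEI" should therefore be read as lower bounds at moderate
coverage.

The LD-stratified control separates cis-regulation from systematic count
bias by looking at co-located sites: a true cis effect travels with the
haplotype and should enrich imbalance at partners in strong LD
(`r² > 0.9`) but not at partners in weak LD (`r² < 0.1`), while
amplification or mapping artefacts hit all sites in the region. A partner
is "imbalance-enriched" when its imbalanced fraction reaches θ = 0.5
(configurable); enrichment in the weak stratum yields `suspected_bias`,
enrichment confined to the strong stratum yields `true_aei`, and empty or
mixed strata are `inconclusive`. This control is only informative at
robust coverage (dozens to hundreds of reads per allele); our simulated
control loci use negative-binomial depth with mean 100 for that reason —
at mean depth 50 the imbalanced fraction of a fold-change-2 site straddles
θ and the control correctly declines to decide. A marker at which even one
well-covered heterozygote shows no imbalance is flagged
(`all_imbalanced = FALSE`) as likely non-functional-but-linked; this is an
annotation, never a filter.

# Enumerating independent cis-eQTL signals

The scan regresses expression on each variant's dosage (covariates
projected out once; dosages standardized so that effect sizes are
comparable across allele frequencies), with Bonferroni significance over
all tested pairs. Under a single causal variant and standardized dosages,
the population slope at a proxy equals `r` times the causal slope, so a
proxy's effect magnitude should track `sqrt(r²)·|β_lead|`. Variants lying
well above that curve are "more significant than their LD predicts" — the
qualitative criterion we formalize as an excess margin
`|β| − sqrt(r²)·|β_lead| > τ·|β_first_lead|` with τ = 0.25, applied only to
variants with `r² < 0.5` to every current lead (0.5 being the observed
linkage level at which secondary clusters were originally noticed).
Signals are seeded iteratively: the lead eQTL's tight-LD cluster
(`r² > 0.9` and `D′ > 0.9`, graph components) forms a signal, then the
best remaining excess variant seeds the next, until no excess variant
remains. τ and the independence threshold are exposed parameters; at these
defaults, simulations with 500 samples recover one signal for single
planted causals in ≥95% of replicates and two signals for unlinked causal
pairs of comparable effect in ≥80%, with no tendency to over-split. Leads
are deterministic under ties (smaller p, then larger |slope|, then smaller
position).

# Nested model comparison

Expression responses are Gaussian GLMs, disease responses additive
logistic GLMs; model pairs are compared by likelihood-ratio test with the
χ² reference on the difference in estimated parameters, echoing both AICs
(`2k − 2·logLik`, dispersion counted for Gaussian fits). A candidate
marker in perfect LD with one already in the model is dropped as aliased;
the comparison then has zero degrees of freedom and is reported as
uninformative with p = 1 rather than failing — reproducing the
characteristic "p = 1.0" row a redundant proxy produces in sequential
tables. The sequential analysis first tests each marker alone against the
covariate-only base, then grows a context set greedily, testing each
subsequent marker against the accepted set and admitting it when the LRT
is informative and significant at 0.05; the acceptance rule for the
context set is our choice, since none is published. Bonferroni family
size is the number of emitted comparisons, logged in the output. The
genotype-stratified comparison runs a two-sided Wilcoxon rank-sum test of
expression between disease classes within each dosage group; fully tied
groups carry no evidence and report p = 1, groups lacking two observations
per class are marked untestable.

# eQTL power

Detection power is computed for a one-way ANOVA across genotype classes
weighted by Hardy–Weinberg frequencies `((1−p)², 2p(1−p), p²)`, genotype
means `μ(1−δ), μ, μ(1+δ)` (δ = 0.2 is the conventional "40% effect": 20%
below and above the median between homozygotes), noncentrality
`λ = n Σ wᵢ(μᵢ−μ̄)²/σ²`, and a central-F critical value at the
Bonferroni-corrected per-test level (default 0.05 over 5 million tests).
The residual σ is a free parameter defaulting to `cv·μ` with cv = 0.3,
since published power figures in this style do not print their variance
model; power comparisons across tissues are therefore driven by sample
size and the μ/σ ratio. At δ = 0 the formula returns the per-test α
exactly, and it matches a distributionally exact Monte-Carlo of the ANOVA
(simulated through its sufficient statistics, including replicates with an
empty genotype class) within 0.02.

# The synthetic-data generator

`simulate_haplotypes()` uses a founder-mosaic model: each LD block carries
`k` derived founder haplotypes plus the ancestral all-reference
haplotype, and every chromosome independently copies one of the `k + 1`
classes per block. Modelling the ancestral haplotype explicitly (rather
than having chromosomes copy exactly `k` founders) is what makes the
single-founder block well-defined: with `k = 1` a block has two haplotype
classes and every polymorphic pair is in perfect LD, while across blocks
class draws are independent and r² sits at its chance level (≈1/(2N)).
Founder alleles are resampled per variant until the empirical minor-allele
frequency lands in the requested range; an unsatisfiable constraint is an
error naming the variant. This produces the three LD regimes the analysis
consumes (>0.9, ≈0.5, <0.1) deterministically; it is not a coalescent
model and makes no claim about recombination-distance decay, mutation
spectra, or population history.

Expression is Gaussian around genotype-class means
`μ(1 + Σ δ(g − 1))`; allelic counts are binomial with success probability
`ρx/(ρx + (1−ρ)(1−x))`, `x = a/(1+a)`, depth negative-binomial (default
mean 50, dispersion 5, reflecting the coverage needed for usable allelic
ratios); `simulate_locus_catalog()` lays out one locus per requested tier
with the QTL tables, transcript models (GTF) and planted-truth record the
classifier needs. Identical seeds give byte-identical outputs, including
written files. Deliberate simplifications: one tissue is one independent
sample set (no shared donors across tissues), no read-level RNA-seq
simulation, and binary phenotypes use a plain logistic model. Passing
tests on these data demonstrate correctness of the statistical machinery
under the stated generative model, not robustness to the full complexity
of population cohorts.

# Problem sizes used in the test suite

Simulation-backed checks run at: 500 samples and 200 replicates per
scenario for signal enumeration; 1000 sites for imbalance calibration and
100 simulated loci per LD-control scenario; 500 null and 200 alternative
replicates for model comparison; 10⁵ Monte-Carlo replicates per power
triple (at a relaxed per-test α of 10⁻³ so that rejection rates are
estimable). These sizes give the stated acceptance margins comfortable
sampling error while keeping the full suite to a few minutes on one core.

# Known limitations

* Exact-identity QTL matching misses signals tagged by different markers
  in GWAS and QTL analyses; that trade-off is intrinsic to the design.
* The AEI caller's "exhibits imbalance" rule is one defensible choice;
  published sample counts produced by other rules will not be reproduced
  exactly, and per-sample power is the binding constraint at depth below
  ≈100 reads.
* Signal enumeration is a diagnostic, not fine-mapping: it bounds the
  number of independent signals under an additive single-causal null per
  cluster and does not output posterior probabilities.
* The founder-mosaic panel is a stand-in for population haplotypes; LD
  summaries are realistic by construction, haplotype diversity is not.
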
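---
title: "Methods: integrative expression–methylation pathway discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative expression–methylation pathway discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model behind `pathchemo`, the
choices made where the design was genuinely open, and what the synthetic
cohorts do and do not demonstrate.

## The extreme-responder contrast

The pipeline assumes a cohort treated with one regimen, with molecular
profiles taken before therapy and clinical follow-up afterwards. Poor
responders are patients with a new tumor event within `poor_window` days
(default 365) of therapy start; favorable responders are event-free with
follow-up beyond `favorable_min` days (default 730). Patients with an
event inside the gap, or censored early, carry ambiguous labels and are
excluded. The contrast deliberately trades sample size for effect size:
differential signals between the extremes are larger than between
adjacent response categories, which matters at the n = 4 + 4 scale the
design targets. `balance_check()` reports Welch-t/Fisher-exact balance
p-values for age, gender, stage and the like, so the analyst can exclude
samples until the groups are comparable (stratified sub-sampling is
caller-driven; no automated search is attempted because any greedy
exclusion rule embeds arbitrary priorities better left explicit).

Signatures are oriented **poor minus favorable** throughout, so a
positive score means higher in resistant patients and NES signs inherit
that meaning. Welch's t is the default score (unequal variances are the
rule in small extreme groups); the fold-change alternative exists to
confirm rank stability rather than as a serious competitor. Methylation
enters as beta values; parametric scoring happens on
M = log2(β/(1−β)), whose variance is closer to constant across the
(0,1) range. Betas are clipped to [ε, 1−ε] with ε = 1e−6 before the
logit — the transform is strictly monotone on that interval, so ordering
is preserved and boundary values stay finite. Per-gene site selection
maximizes the coefficient of variation of beta across *all* cohort
samples (CV on M-values is unstable because M can have near-zero mean);
ties break to the lexicographically smallest site id so runs are
reproducible. The all-sites mode keeps every CpG and, at enrichment time,
represents each gene by its largest-|score| site, preserving the
strongest differential signal when sites disagree.

## Enrichment engine

The enrichment statistic is the weighted Kolmogorov–Smirnov running sum:
walking down the ranked signature, a pathway member at rank *i* adds
|s_i|^w normalized by the sum over members, a non-member subtracts
1/(N − N_hit); the enrichment score (ES) is the extremum of larger
magnitude, and the leading edge is the members at or before a positive
peak (at or after a negative one). The weight exponent defaults to
w = 1, the classic weighted setting. When the two extrema tie in
magnitude — a measure-zero event for continuous scores — the positive one
is taken; ES also depends on the order among exactly tied scores, so
ranking uses a stable sort of the input order and the tie rule is
documented rather than hidden.

The null distribution permutes **gene labels** (equivalently: the member
positions are re-drawn uniformly), 1000 permutations by default.
NES = ES / mean(null ES of matching sign), the standard sign-conditioned
normalization; the empirical p-value is (r+1)/(m+1) over the
matching-sign permutations, which can never return 0. Two consequences
are worth knowing. First, the attainable p floor is roughly 2/n_perm
(only about half of the permutations match sign), so with 1000
permutations the 0.001 end of the downstream threshold grid is usually
empty — the scan marks such thresholds unavailable rather than failing.
Second, if no permutation matches the observed sign, p is reported at
1/(n_perm+1) with a degeneracy warning.

The **absolute-valued mode** re-ranks the signature by |score|, which
collapses both tails: pathways whose genes move coherently in *both*
directions enrich at the top. A negative NES in this mode means
enrichment among unchanged genes and is never eligible. The **composite**
per pathway takes whichever eligible result (signed, or positive-NES
absolute) has the smaller p; an exact p tie resolves toward signed mode,
because a direction is more informative than its absence.

## Pathway-of-pathways integration

To find pathways altered on both omics levels, the expression composite
is ranked by |NES| (direction deliberately discarded: an over-expressed /
under-methylated pathway should match an under-expressed /
over-methylated one) and treated as the reference signature of a second
GSEA whose items are pathways. The query set is the methylation-composite
pathways with p ≤ θ. Because the enrichment is permutation-based, each θ
in the grid 0.001–0.046 (step 0.005) is run repeatedly (default 100
runs) under derived seeds and the mean NES recorded; the optimal θ is the
argmax, ties resolving to the smallest threshold (the most stringent
query). Candidates are the leading-edge pathways at the optimal θ, each
annotated with its expression and methylation leading-edge genes tagged
`expression-only` / `methylation-only` / `both`. If the pathway-level
enrichment itself is not significant (p > 0.05) the candidate set is
flagged as carrying no dual-level signal; downstream use is then at the
analyst's risk.

Curated collections contain parent–child pathways sharing most of their
genes. All candidate pairs are tested by two-sided Fisher exact tests on
leading-edge overlaps; the universe defaults to the union of all
candidate leading edges and the signature genes (the collection does not
define a background, so the package makes its own explicit and
configurable). Pairs with BH-adjusted q < 0.05 are linked, connected
components merged, and each component keeps the pathway whose expression
composite p is smallest (configurable to the minimum over both omics).

## Single-sample activity and validation

Activity scoring z-scores the matrix per feature (sample sd, n−1),
ranks each sample's z-profile as its own signature, and computes each
candidate pathway's composite NES exactly as at cohort level — the same
code path serves expression and methylation, so cross-level comparisons
are like for like. Permutation seeds are derived per pathway and mode but
shared across samples, so identical profiles receive identical
activities. One numerical caveat: the permutation normalization makes NES
saturate as a pathway approaches the very top of a profile, so activity
is monotone in planted signal up to that plateau; the enrichment score
itself is strictly monotone.

Stratification embeds the pathway × sample activity matrix with t-SNE
(exact, non-Barnes-Hut — implemented in the package because no R t-SNE
implementation was available as a dependency; adequate for tens of
samples) and cuts the embedding with 2-means (10 restarts under derived
seeds; the two-group cut is the package's choice, as is the perplexity
default min(10, ⌊(n−1)/3⌋) appropriate for validation cohorts of 23–40
patients). Raw NES values are embedded by default; a `scale_activity`
switch exists because either convention is defensible. Groups are
labeled high/low by mean activity so the hazard-ratio orientation is
deterministic. Survival separation uses the standard log-rank test and a
Cox proportional-hazards model, reporting the likelihood-ratio p (more
reliable than Wald at these sample sizes) and a univariable group-only
hazard ratio as the headline number.

Two null models calibrate non-randomness: drawing the same number of
random pathways and recomputing activity/stratification/log-rank
(model 1), and drawing random patient groups of the observed sizes
(model 2), both with empirical p = (r+1)/(n+1) over 10,000 draws by
default. LOOCV fits a multivariable logistic regression of outcome on
pathway activities, leaving one patient out at a time; folds with
complete separation fall back to a ridge-penalized fit and are flagged.
The LOOCV outcome is the event indicator within the study window — under
heavy or uninformative censoring that label is noisy and the achievable
AUROC is bounded well below 1 even for a perfect activity predictor,
which is why the response-group ROC (logistic regression of the known
extreme-responder labels on activities) is also reported where labels
exist. Read-out genes per pathway combine the Pearson correlation p
(gene vs pathway activity) with the single-gene Cox likelihood-ratio p
via Fisher's method, picking the smallest combined p per pathway (ties to
larger |r|, then name) — one gene per pathway, a rule chosen because no
formal selection criterion is standard. Correlations use expression
values for expression-edge genes and M-values for methylation-only ones.

## Synthetic cohorts

`generate_cohort()` emulates the statistical structure the pipeline
assumes: Gaussian expression noise (σ = 1) with planted pathways shifted
by Δ·σ (default Δ = 2) in the poor group; methylation drawn from
Beta(2, 2) with planted sites mean-shifted by Δβ = 0.2 at fixed
precision (mean-shift reparameterization keeps betas in [0,1] without
clipping artifacts); 1–3 CpG sites per gene; and exponential survival
whose log-hazard is proportional to the sample's planted-gene mean
expression, with the coefficient parameterized as log(hazard_ratio)/(Δσ)
so the group-level hazard ratio is directly configurable. Censoring is
independent exponential, its rate calibrated by root-finding so the
expected censored fraction matches the configuration — independence from
the event process is required for the log-rank/Cox assumptions the
validation layer relies on. The defaults (100 pathways × 30 genes,
4 + 4 discovery samples, Δ = 2, Δβ = 0.2, hazard ratio 4, 30%
censoring) are the study conditions under which the pipeline is
routinely exercised.

What the synthetic world does **not** contain: correlated co-expression
within pathways, probe-level 450K covariance, batch effects,
cell-composition confounding, overlapping gene sets (planted pathways
are disjoint), or any coupling between methylation and expression beyond
joint planting. Passing tests on these cohorts therefore demonstrates
that the machinery recovers the signals it is specified to recover — not
that real cohorts will behave as cleanly. One synthetic-specific
artifact deserves mention: because single-sample ranking is relative, a
large planted fraction of the genome displaces the ranks of *all* genes,
coupling even random pathways' activities to the response groups; the
random-pathway null model is therefore demonstrated at low planted
density (5 of 200 pathways), closer to a genome-scale collection.

## Problem sizes

The test suite and the acceptance script scale the study conditions to
desk size as the package's own choices: enrichment-oracle checks on 200
random instances (N ≤ 50, |set| ≤ 10); null calibration with 500
replicate signatures at 200 permutations; planted-recovery over 10 seeds
at the default discovery conditions with 500 permutations and a 10-run
threshold scan; validation-recovery over 10 seeds at n = 40 with 200
permutations; random models at 30 pathway draws / 1000 group draws. The
10,000-draw defaults remain available for full-scale runs.

## Known limitations

Gene-label (not sample-label) permutation is the only null; it tests
ranking structure, not inter-gene correlation, and will be anti-
conservative when pathway genes are strongly co-expressed. The p floor
of ~2/n_perm means very small thresholds in the scan grid require
correspondingly large permutation counts. The Fisher-exact pruning
universe is a pragmatic choice, not a genome annotation. t-SNE + 2-means
assumes two activity regimes; cohorts with more structure need a
different cutter. The package does not normalize raw RNA-seq counts
(inputs are assumed normalized; log2(CPM+1) upstream is an acceptable
fallback) and does not process raw 450K IDATs.
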
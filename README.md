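# pathchemo

Integrative transcriptomic–epigenomic discovery of chemotherapy-response
pathways, with survival-based validation.

## The problem

Resistance to a chemotherapy regimen (the motivating case is adjuvant
carboplatin–paclitaxel in lung adenocarcinoma) is rarely explained by one
molecular layer. This package implements an extreme-responder,
pathway-level integration of bulk mRNA expression and DNA methylation:
patients who relapse within one year of therapy start ("poor response")
are contrasted with patients event-free beyond two years ("favorable
response"), and the pathways altered on *both* molecular levels between
those groups are identified and then validated as predictors of treatment
resistance in independent cohorts. It is aimed at computational biologists
working with matched expression/methylation cohorts plus clinical
follow-up (TCGA-style), and it ships a synthetic multi-omics cohort
generator so the entire pipeline is exercisable without any downloads.

## The method

1. **Signatures.** Per-gene differential scores between the responder
   groups: two-sample two-tailed Welch *t* (or log2 fold change), computed
   on expression values and on methylation M-values
   (M = log2(β/(1−β))), with either one CpG site per gene (highest
   coefficient of variation) or all sites.
2. **Signed + absolute-valued enrichment.** Each ranked signature is
   subjected to weighted Kolmogorov–Smirnov running-sum gene set
   enrichment over a pathway collection (GMT). Normalized enrichment
   scores (NES) and empirical p-values come from gene permutations
   (default 1000). The *signed* mode detects pathways changed in one
   direction; the *absolute-valued* mode (scores replaced by |t|)
   detects pathways whose genes move in both directions; negative NES in
   absolute mode reflects enrichment in the unchanged part of the
   signature and is discarded. Per pathway, the **composite** NES is the
   one with the lower p-value of the two eligible modes.
3. **Pathway-of-pathways integration.** The expression composite,
   ranked by |NES|, is the reference "signature" whose items are
   pathways; the query set is the pathways significant in the methylation
   composite at threshold θ. The same running-sum statistic with pathway
   permutations scores the enrichment; θ is scanned over 0.001–0.05
   (step 0.005), each threshold re-run repeatedly (default 100 runs), and
   the θ with the highest mean NES wins. The leading-edge pathways at the
   optimal θ are the dual-level candidates; pairwise Fisher exact tests
   on their leading-edge genes (BH-corrected) prune redundant
   parent–child pathways, keeping the lowest-p representative per
   overlap group.
4. **Validation.** Single-sample activity: z-score the validation matrix
   on features, rank each sample's profile, and compute each candidate
   pathway's composite NES per sample. t-SNE embeds the
   pathway × sample activity matrix in 2D; 2-means splits patients into
   high/low-activity groups, compared by Kaplan–Meier/log-rank and Cox
   proportional hazards (likelihood-ratio test). Null models re-run the
   stratification with randomly drawn pathway sets and with random
   patient groups (empirical p = (r+1)/(n+1)). Leave-one-out
   cross-validated logistic regression assigns per-patient risk;
   read-out genes per pathway combine Pearson correlation with pathway
   activity and single-gene Cox p-values via Fisher's method.

## Worked example

```r
library(pathchemo)

## a discovery cohort with 3 of 30 pathways planted on both omics levels
cfg <- synthetic_config(n_genes = 700, n_pathways = 30, genes_per_pathway = 20,
                        n_planted = 3, seed = 7)
cohort <- generate_cohort(cfg)

fit <- pathchemo(cohort$expression, cohort$methylation, cohort$map,
                 cohort$collection, cohort$groups,
                 n_perm = 200, scan_runs = 5, seed = 3)
fit
#> Integrative expression-methylation pathway model
#>   signatures: welch_t on 700 genes / 700 methylation features
#>   optimal query threshold: 0.011
#>   pathway-level enrichment: NES 1.97, p 0.008264
#>   candidate pathways: 3 before / 3 after pruning
#>   pathway expr_nes  expr_p meth_nes  meth_p
#> 1   PW002     2.07 0.00498     2.15 0.00943
#> 2   PW001     2.00 0.00505     1.70 0.00500
#> 3   PW003     1.82 0.00503     1.63 0.00498
```

All three planted pathways (PW001–PW003) are recovered, each with positive
NES and small permutation p on both omics levels; the threshold scan
found the strongest pathway-level enrichment at a query cutoff of 0.011.
Validation on an independent synthetic cohort in which high pathway
activity quadruples the relapse hazard:

```r
val <- generate_cohort(synthetic_config(n_genes = 700, n_pathways = 30,
                                        genes_per_pathway = 20, n_planted = 3,
                                        n_poor = 20, n_favorable = 20,
                                        hazard_ratio = 4, seed = 8))
activity <- predict(fit, val$expression, n_perm = 200, seed = 4)
strata <- stratify(activity, seed = 4)
surv <- cox_model(data.frame(sample_id = names(strata$group),
                             group = strata$group), val$clinical)
surv
#> survival_comparison: n = 40, LR p = 0.0001253
#>   headline group HR = 5.085 [2.115, 12.228]
#>        term   hr hr_lo hr_hi       p
#> 1 grouphigh 5.09  2.11  12.2 0.00028
```

The high-activity group carries a hazard ratio of ~5 (true planted value
4, well inside the confidence interval), and the corresponding log-rank
test gives chi-square 15.55, p = 8e-05: the discovered pathways stratify
unseen patients by time to relapse.

A thin command-line front end is installed under `inst/cli/pathchemo`
(`simulate`, `discover`, `validate` subcommands) for shell use.

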
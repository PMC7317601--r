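# coexhub

Hub-gene discovery from multi-study gene expression data, as a tested,
reusable R pipeline.

A recurring analysis pattern in cancer transcriptomics asks: given a
set of candidate genes (for instance, the predicted targets of a
microRNA that are also differentially expressed in tumours), which of
them sit at the centre of a trait-associated co-expression module *and*
at a highly connected position in the protein-interaction network?
Genes passing both filters — "hub genes" — are the ones nominated for
diagnostic and prognostic follow-up. `coexhub` implements every stage
of that workflow as plain R functions, plus a synthetic-data module
that plants known structure so the whole pipeline can be validated
end-to-end without downloading anything.

## The methods in brief

**Co-expression modules.** From a genes × samples matrix, the unsigned
similarity S = |cor(X, Y)| is soft-thresholded to an adjacency
A = S^β (β chosen by the signed scale-free fit R² × sign(−slope)),
converted to the topological overlap

    ω_XY = (l_XY + a_XY) / (min{k_X, k_Y} + 1 − a_XY),
    l_XY = Σ_u a_Xu a_uY,   k_X = Σ_u a_Xu,

and clustered on dissTOM = 1 − ω with average linkage. Branches are cut
at a data-adaptive height (the widest usable gap in the merge-height
distribution), small branches fall to the grey label 0, stray genes are
reattached by eigengene correlation, and modules with correlated
eigengenes are merged. Genes are scored by module membership
MM = cor(x, ME) and gene significance GS = cor(x, trait); key genes
pass |MM| > 0.8 and |GS| > 0.2.

**Meta-analysis.** Per-study Hedges' g with inverse-variance fixed and
DerSimonian–Laird random-effects pooling, Cochran's Q,
I² = (Q − df)/Q, the conventional model-selection rule (random when
p < 0.05 or I² > 50%), and Egger's regression test for funnel
asymmetry.

**Network filtering.** Interaction edges below a confidence score of
0.4 are deleted (0.4 itself survives), the network is restricted to its
main connected component, and genes with degree ≥ 8 are kept. Hub
genes are the intersection of the WGCNA key genes with that
high-degree set.

**Marker evaluation.** ROC/AUC (trapezoid = tie-corrected rank
statistic), median-dichotomized Kaplan–Meier curves with the log-rank
test and an O/E hazard ratio, and hypergeometric over-representation
analysis against GMT gene sets with BH-FDR.

See `vignettes/coexpression-hub-discovery.Rmd` for the full model
description, parameter defaults, and design rationale.

## Worked example

The demo generates every input with planted ground truth (four
co-expression modules, the first driving the trait; eight case/control
studies sharing a true SMD of 0.3 with between-study heterogeneity; a
scored interaction network; survival times with a hazard ratio of 1.77
for high expression of a module gene) and runs the full pipeline:

```r
library(coexhub)
res <- run_demo(seed = 1, outdir = "demo_out")
```

which logs, stage by stage:

```
overlap     188 DEGs x 433 targets -> 186 overlapping genes
wgcna       beta=9, 4 modules over 186 genes; trait module 1; 52 key genes
meta        8 studies; random model; pooled SMD = 0.408 [-0.081, 0.897]; I2 = 70.9%
ppi         4079 -> 2865 edges after score >= 0.40 + main component; 443 genes with degree >= 8
hub         52 key genes x 443 high-connectivity genes -> 44 hub genes
diagnostics ROC on 44 gene(s); AUC range [0.639, 0.765]
diagnostics log-rank chi2 = 1.461, p = 0.2267, HR = 1.249
diagnostics ORA over 21 sets; top set by p: planted
```

Reading the numbers: the overlap stage recovered the 180 planted module
genes (plus a handful of false positives) from the simulated
differential-expression and target-prediction tables; all four planted
modules were found and the trait-driving module ranked first by
module–trait correlation; the 44 nominated hub genes are all members of
the planted trait module (`res$truth` carries the ground truth for
checking exactly this); the meta-analysis correctly switched to the
random-effects model under the simulated heterogeneity, and its pooled
SMD of 0.408 brackets the true 0.3; the planted gene set is the top
over-representation hit for the key genes. Each run directory contains
the per-stage TSV/JSON outputs, the resolved configuration, a log, and
`run_report.json` with MD5 hashes of every file.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/coexhub.R demo --seed 1 --outdir demo_out
Rscript inst/cli/coexhub.R run-all --config my_run.yaml --outdir out
```

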
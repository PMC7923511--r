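# cytopattern

Unsupervised pattern recognition for sparse binary cytogenetic matrices.

A patient karyotype can be written as a 0/1 vector over cytogenetic
bands under the Loss/Gain/Fusion (LGF) model: three indicator features
per band record whether that band is lost, gained, or involved in a
fusion. A cohort is then a samples x features binary matrix — very
sparse, and heavily column-redundant because whole-arm and
whole-chromosome events switch many adjacent bands together.
`cytopattern` is for researchers in cancer cytogenomics (and anyone
else with large sparse binary feature matrices) who want to find the
recurrent patterns in such data and characterize them.

The pipeline, in the order the stages run:

1. **Distances.** Ten binary metrics on the 2x2 contingency counts
   (N11, N10, N01, N00) of each pair of profiles. The primary metric is
   the Jaccard distance *d* = 1 − N11/(N11 + N10 + N01), which ignores
   0–0 matches and is therefore suited to sparse aberration profiles.
2. **Feature reduction.** Empty features are dropped; features with
   identical columns are collapsed to one representative with a
   provenance map; features with short loading vectors on the top
   principal components (length below δ = 0.3 on the
   correlation-scaled matrix) are removed as uninformative outliers.
3. **Dimension.** The number of significant principal components,
   estimated with the Auer–Gervini Bayesian step function (the MAP
   component count as a function of the exponential prior rate θ,
   computed exactly via the convex hull of the profile log-likelihood)
   with the broken-stick model as a frequentist reference. "Long" steps
   mark stable candidate dimensions; the cluster count K is tied to the
   chosen dimension.
4. **Clustering.** Deterministic BUILD+SWAP partitioning around medoids
   (PAM) at K, with Hungarian label alignment and a shared color
   palette so the same cluster keeps its color across views and
   methods.
5. **Views.** Thresholded adjacency graph (default τ = 0.6 on Jaccard),
   density-dependent down-sampling that preserves rare clusters,
   classical MDS, Ward (D2) dendrogram; pluggable non-linear embedding.
6. **Characterization.** Features are clustered into elementary event
   groups (loss-only / gain-only / fusion-only / fusion+loss /
   fusion+gain / mixed); per sample cluster, the fraction of patients
   exhibiting each event group drives coverage summaries
   (99/95/90/80/70/60% ladder), top-event reports at a 60% cutoff,
   disease-prevalence cross-tabs, and a two-way
   correlation/Ward-ordered heatmap.

A synthetic cohort generator with planted clusters, block-structured
events, penetrance, one-way noise, and outlier features (with full
ground truth) makes every stage testable without any external data.

## Worked example

```r
library(cytopattern)

sim <- simulateCohort(defaultSimSpec())   # 600 karyotypes, 5 planted clusters
sim$matrix
#> BinaryMatrix: 600 samples x 136 LGF features
#>   1-density: 14.0%; disease labels: yes

res <- runPipeline(pipelineConfig(input = sim$matrix, dimension = 5))
res$dimension
res$partition
#> Partition: 600 objects in 5 clusters
#>   sizes: 124 116 120 105 135
#>   total cost: 79.7733
head(res$report, 5)
#>   cluster size topFrequency                     events                  diseases
#> 1      C1  124    0.9758065                    G8:0.98 C4:0.98; C3:0.02; C5:0.01
#> 2      C3  120    0.9250000 G5:0.92; G10:0.92; G1:0.88                   C1:1.00
#> 3      C4  105    0.9238095           G4:0.92; G9:0.90          C5:0.99; C4:0.01
#> 4      C2  116    0.9224138           G7:0.92; G3:0.88                   C3:1.00
#> 5      C5  135    0.9111111 G6:0.91; G2:0.90; G11:0.85                   C2:1.00
res$coverage
#> 99% 95% 90% 80% 70% 60%
#>   0   1   5   5   5   5
```

Reading the report: each recovered cluster of ~120 karyotypes is
characterized by its planted signature events at frequencies near the
planted penetrance of 0.9 (e.g. cluster C1 carries event group G8 in
98% of its members), and each maps essentially one-to-one onto a
planted pseudo-disease label. The coverage line says that all 5
clusters have at least one event above the 90% bar. Against the
generator's ground truth this run scores an adjusted Rand index of
0.98.

The pipeline stages are equally usable à la carte — see
`binaryDistance()`, `collapseDuplicates()`, `thresherFilter()`,
`estimateDimension()`, `pamCluster()`, `adjacencyGraph()`,
`eventFrequency()` — and a thin command-line front end ships in
`inst/cli/cytopattern.R` (subcommands `simulate`, `dist`, `reduce`,
`dim`, `cluster`, `characterize`, `view`, `run`, `compare-metrics`).

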
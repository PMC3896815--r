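# reponet

Network-based drug repositioning: predicting new drug–disease associations
by representing every drug and every disease as a prioritized gene set and
asking which drug gene sets best explain which disease gene sets.

`reponet` is aimed at computational biologists who have (or can emulate)
three kinds of evidence:

* **literature co-occurrence** — counts of abstracts co-mentioning an
  entity (drug or disease) and a gene, with marginals and corpus size;
* **expression signatures** — replicate ranked gene lists for drugs
  (rank 1 = most up-regulated) and case/control expression matrices for
  diseases;
* **gene–gene interaction networks** — one undirected reference network
  per evidence source.

## The method

For each entity and each evidence source the pipeline builds a gene set in
three steps, then links drugs to diseases with a sparse regression:

1. **Initial list.** Literature: co-mention counts below 5 are zeroed and
   the rest scored with a regularized log-odds connectivity measure,

   `Connect_DG = ln(ABS_DG * max(ABS_D, ABS_G) + λ) − ln(ABS_D + ABS_G + λ)`,

   keeping genes with strictly positive score (λ = 1). Expression: drug
   replicate rank lists are Borda-merged, disease case/control matrices are
   scored with a moderated two-sample statistic
   `d = (mean_case − mean_control)/(s + s0)`; the 25 most up- plus the 25
   most down-regulated genes form the signature.
2. **Subnetwork.** Signature genes plus their direct neighbors in the
   reference network, with the full induced edge set.
3. **Centrality prioritization.** Genes with degree, betweenness or
   closeness centrality strictly above the subnetwork average become the
   entity's row of a Boolean entity × gene membership matrix (one matrix
   per source × measure, plus element-wise-OR combined matrices).
4. **Association.** Per disease, an L1-penalized logistic regression writes
   the disease's Boolean gene vector as a sparse combination of all drug
   vectors (genes are the observations). Positive coefficients are
   predicted drug–disease associations; the model is evaluated by ROC/AUC
   against a gold standard with sampled zero-co-occurrence negatives.

A synthetic-world generator (`generate_world()`) emulates every input with
planted drug–disease gene modules, so the whole pipeline is testable
without any database access. See `vignette("reponet-methods")` for the
model details and design choices.

## Worked example

```r
library(reponet)
options(reponet.verbose = FALSE)

world  <- generate_world(world_config(seed = 42))
world_report(world)
#>           quantity value
#> 1            genes  2343
#> 2            drugs    50
#> 3         diseases     8
#> 4       text_edges  7023
#> 5       expr_edges  7023
#> 6    planted_pairs    10
#> 7 mean_module_size    30

result <- run_pipeline(world, pipeline_config(seed = 42), measures = "degree")
result
#> Pipeline run: 3 configuration(s)
#>              label auc
#>    combined_degree   1
#>  expression_degree   1
#>        text_degree   1
```

All ten planted drug–disease pairs are ranked above every sampled negative
pair (AUC 1) by each evidence source. The fitted coefficients identify the
planted drugs for a given disease directly:

```r
assoc <- result$associations$combined_degree
sort(assoc$scores[, "disease01"], decreasing = TRUE)[1:3]
#> drug021 drug033 drug031
#>   2.144   1.905   0.086

subset(world$truth, disease == "disease01")
#>     disease    drug source
#> 1 disease01 drug021   both
#> 9 disease01 drug033   both
```

The two drugs planted on `disease01` receive the two largest positive
coefficients; the third-ranked drug's coefficient is an order of magnitude
smaller.

A thin command-line front end over the same functions is installed at
`inst/cli/reponet.R` with subcommands `expand`, `score-text`, `score-expr`,
`subnet`, `centrality`, `associate`, `evaluate` and `simulate`, each
reading and writing the package's TSV formats.

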
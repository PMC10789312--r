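# mkbmc

Multi-kernel classification of case–control status from microbiome
profiles, with association-boosted distance metrics.

## What problem this solves

Case–control microbiome studies ask whether community composition — the
relative abundances `P_i = (p_i1, …, p_iq)` of `q` OTUs plus a rooted
phylogenetic tree over them — predicts a binary health outcome `y_i`.
Different outcomes leave different footprints: abundance shifts of a clade,
presence/absence changes of rare taxa, phylogenetically clustered or
scattered signal OTUs. Any single community distance metric captures one of
these forms and misses the others.

`mkbmc` is for statisticians and bioinformaticians who want a prediction
model that uses several forms of microbiome–outcome association at once and
reports *which* form carries the signal. It:

1. **boosts** four classical distances — weighted/unweighted UniFrac,
   Bray–Curtis, Hamming — with per-feature weights
   `a_r = normalized −log10(p_r)` from association tests against the
   training labels (Welch *t* for abundance features, Fisher/χ² for
   presence features), e.g.

   `d_w(i,j) = Σ_r b_r a_r |p_ir − p_jr| / Σ_r b_r a_r (p_ir + p_jr)`;

2. turns each boosted distance into a Gaussian kernel
   `K(i,j) = exp(−d(i,j)² / 2σ²)` with `σ` = mean pairwise training
   distance (plus one kernel per numeric covariate);

3. learns kernel weights `w_l` in closed form under the
   entropy-regularized alignment objective

   `min_w −Σ_ij Σ_l w_l K_l(i,j) CC(i,j) + ρ Σ_l w_l log w_l`,
   `Σ w_l = 1, w_l ≥ 0`,

   whose solution is a softmax of the kernel-alignment scores; `ρ` is tuned
   on an 11-point grid by stratified 5-fold cross-validation;

4. classifies with a per-sample **similarity t-score** (Welch *t* comparing
   a sample's combined-kernel similarities to training cases vs controls)
   fed into a logistic model `logit P(y=1) = β0 + β1 t`.

A Dirichlet-multinomial simulation engine (negative-binomial totals,
tree-clustered signal OTUs, abundance- and presence-driven logistic outcome
models) generates realistic synthetic datasets so the whole pipeline is
testable end to end.

## Worked example

```r
library(mkbmc)

params <- default_parameters(q = 200, seed = 42)   # synthetic tree + DM parameters
train <- simulate_dataset(n = 300, q = 200, scenario = "I", model = "A",
                          beta = 2, seed = 1, params = params)
test  <- simulate_dataset(n = 300, q = 200, scenario = "I", model = "A",
                          beta = 2, seed = 2, params = params)

fit <- mkbmc_fit(train$counts, train$tree, train$meta, seed = 3)
print(fit)
#> Multi-kernel boosted microbiome classifier
#>   300 training samples (150 cases / 150 controls), 200 OTUs
#>   rho = 3277; logistic beta0 = 0.114, beta1 = 0.235
#>   kernel weights:
#>     weighted_unifrac     0.4262
#>     unweighted_unifrac   0.1425
#>     bray_curtis          0.2802
#>     hamming              0.1511

pred <- predict(fit, test$counts)
head(pred, 3)
#>   sample_id    tscore      prob
#> 1        S1 10.617535 0.9315514
#> 2        S2  9.985556 0.9214470
#> 3        S3 10.705466 0.9328580

evaluate_predictions(pred$prob, test$meta$label)[c("auc", "sensitivity", "specificity")]
#> $auc
#> [1] 0.8601778
#> $sensitivity
#> [1] 0.8066667
#> $specificity
#> [1] 0.76
```

The simulated outcome depends on the summed abundance of one
phylogenetically clustered signal group (scenario I, model A), and the
fitted kernel weights point at the right signal form: the boosted weighted
UniFrac kernel — the abundance-sensitive, tree-aware one — gets the largest
weight. Test-set AUC 0.86 approaches the oracle (the true simulated case
probability scores about 0.86 at this effect size).

Under a presence/absence outcome (model B) the largest weights move to the
unweighted-UniFrac and Hamming kernels; the weights are an interpretable
readout of the contributing signal form.

## Command line

A thin CLI over the same functions (see `inst/scripts/mkbmc`):

```sh
mkbmc simulate --scenario I --model A --beta 2 --n 500 --seed 7 --out data/
mkbmc fit      --counts data/counts.tsv --tree data/tree.nwk --meta data/metadata.tsv --out model.json
mkbmc predict  --model model.json --counts test/counts.tsv --out probs.tsv
mkbmc evaluate --probs probs.tsv --meta test/metadata.tsv --out report.json
mkbmc replicate --scenario I --model A --beta 2 --n 200 --reps 10 --seed 1 --out replicate.tsv
```

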
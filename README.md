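# cdd — causal network inference with diffusion models and do-calculus

`cdd` infers a **directed** causal network from a cross-sectional
samples × variables matrix (gene expression is the motivating use case),
for researchers who need more than a correlation network but have no
time-series or perturbation data.

For every ordered pair (x, y) the method contrasts two additive-noise
hypotheses —

* **H0** (no edge): `y = f_H0(Z) + ε̂`
* **H1** (edge): `y = f_H1(x, Z) + ε`

— but instead of fitting two regressions it trains **one denoising
diffusion model** on the joint data and realizes the hypotheses as two
**do-calculus interventions** on the hidden (noised) layer
`H = (h_x, h_Z, h_y)`:

* under H1 the cause coordinate is intervened with each held-out
  sample's *observed* value;
* under H0 it is intervened with standard Gaussian noise, severing the
  dependence on the factual cause.

The interventional outcome `P(y | do(h_x)) = Σ_x P(y | h_x, x) P(x)` is
estimated by Monte-Carlo generation through the learned reverse process,
and the edge is accepted (H1) iff the generation error with the observed
cause is strictly smaller than with noise:
`distance(ŷ_H1, y) < distance(ŷ_H0, y)`, pooled over K cross-validation
folds. A continuous score `(d_H0 − d_H1)/(d_H0 + d_H1)` ranks edges for
AUROC/AUPR evaluation against a gold standard.

The package includes TSV readers/writers in the standard benchmark
dialects, an additive-noise synthetic network generator with known
ground truth, a discrete oracle network for validating the do-estimator
exactly, and a command-line interface.

## Worked example

```r
library(cdd)

# a 10-gene additive-noise network, 100 samples, known true edges
sim <- simulate_grn(n_genes = 10, edge_probability = 0.2,
                    n_samples = 100, seed = 1)
net <- infer_network(sim$expression, cdd_config(list(seed = 1)))
net
#> Causal network: 10 nodes, 90 evaluated pairs, 61 accepted edges
evaluate_network(net, sim$gold)
#> AUC  0.9432
#> AUPR 0.6166
#> TP 7  FP 54  FN 0  TN 29  (of 90 ordered pairs)
```

All 7 true edges rank near the top (AUC 0.94; AUPR 0.62 against an
edge-density baseline of 0.08 for this draw). The binary H1 decisions
are deliberately liberal — correlated-but-indirect pairs are often
accepted, hence the 54 false positives — so use the continuous score
when a ranking is wanted and the decisions when a hard edge set is
wanted.

Single edges can be tested directly:

```r
pair <- simulate_pair(effect = 0.9, n = 200, seed = 42)
test_edge(pair, "x", "y")
#> x -> y: H1 (score 0.5656; d_H1 0.1816, d_H0 0.6545, 5 folds)
```

## Command line

```sh
cdd simulate --genes 10 --samples 100 --density 0.2 --seed 1 --out data/
cdd infer    --expression data/expression.tsv --out edges.tsv --seed 1
cdd evaluate --edges edges.tsv --gold data/gold_standard.tsv --out report.tsv
```

Every flag can also live in a YAML config (`--config cdd.yaml`); flags
override the file. Runs with the same seed and config are byte-identical.

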
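# hypergcn

Transductive hypergraph-convolutional classification of multimodal cohort
data, aimed at health-risk prediction in small cohorts where each subject is
described by several feature *modalities* (physiological, behavioral,
environmental). Pairwise graphs can only relate two subjects at a time;
`hypergcn` instead joins whole neighbourhoods of similar subjects through
hyperedges, one KNN hypergraph per modality, fused into a single incidence
structure.

## The model

A hypergraph with incidence matrix $B$, hyperedge weights $M$ (unit), and
node/edge degree matrices $D_q$, $D_e$ has the normalized Laplacian
$L = I - D_q^{-1/2} B M D_e^{-1} B^\top D_q^{-1/2}$. Both hypergraph
convolution styles reduce to a dense node aggregator $G$:

* spectral: $G = D_q^{-1/2} B M D_e^{-1} B^\top D_q^{-1/2} = I - L$
* spatial: $G = D_q^{-1} B M D_e^{-1} B^\top$ (row-stochastic averaging)

The classifier decouples propagation from transformation and counters
oversmoothing with a learnable per-node retention gate:

$$X^{\mathrm{final}} = G^L X^{(0)} + \sigma(R)\,X^{(0)}$$

followed by a two-layer fully connected head (fused width → 128 → classes),
trained full-batch with Adam (cross-entropy on the training mask, 600
epochs, lr 0.001 decayed by 0.7 every 200 epochs, weight decay 5e-4,
dropout 0.5). The gate vector $R$ lets each node keep a learned fraction of
its raw low-level features — the detail that repeated propagation would
otherwise erase. See the methods vignette
(`vignettes/hypergcn-methods.Rmd`) for derivations, defaults and design
choices.

The package also ships a seeded generator of synthetic multimodal elderly
cohorts (Gaussian class-conditional features, wearable-style gappy sensor
streams, degradable raw tables), repeated stratified cross-validation,
modality / static-gate ablations, a hyperedge-size grid search, a
clique-expansion GCN baseline, and a thin CLI (`exec/hypergcn`).

## Worked example

```r
library(hypergcn)

spec <- cohort_spec(n_subjects = 50, seed = 7)   # 3 modalities, 3 risk classes
sim  <- simulate_cohort(spec)
sim$dataset
#> Multimodal dataset: 50 subjects, 3 classes
#>   physiological  8 features
#>   behavioral     6 features
#>   environmental  4 features
#>   split: 40 train / 10 test / 0 unlabeled

fit <- hgcn(sim$dataset, Z = 5, seed = 1)        # K = 5 nearest neighbours
fit
#> Hypergraph convolutional classifier (transductive)
#>   50 nodes, 3 classes, fused width 18
#>   propagation: spectral, L = 2, Z = 5, gate: adaptive
#>   final loss 0.2615, training accuracy 1.000

summary(fit)
#> Hypergraph convolutional classifier
#>   epochs 600, final cross-entropy 0.2615, train accuracy 1.000
#>   retention gates sigma(R):
#>    0%   25%   50%   75%  100%
#> 0.471 0.500 0.517 0.530 0.566

pred  <- predict(fit, subset = "test")
truth <- sim$dataset$labels[sim$dataset$split == "test"]
accuracy(truth, pred)                            # 1.00 on this seed
macro_f1(truth, pred)                            # 1.000

cross_validate(sim$dataset, Z = 5, folds = 10, repeats = 2, seed = 1)
#> 2 x 10-fold cross-validation (seed 1)
#>   accuracy: 0.9000 +/- 0.1214
#>   macro-F1: 0.8972 +/- 0.1347
```

The fitted object supports `print`, `summary`, `coef` (parameters plus the
sigmoid gates), `predict`, `fitted`, `plot` (training loss curve), and JSON
checkpointing via `write_hgcn()` / `read_hgcn()`. The retention gates start
at the neutral 0.5 and drift apart as training learns which subjects' raw
features matter; training accuracy 1.0 on 40 labeled subjects is expected
for the default well-separated cohort.

## Command line

```sh
hypergcn simulate --seed 3 --out data
hypergcn evaluate --seed 3 --out report --config config.json
hypergcn ablate   --seed 3 --out report --config config.json
```

where `config.json` points at the modality tables and labels file and may
override `Z`, `folds`, `repeats` and any training hyperparameter.

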
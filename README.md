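# cgrnn — reaction barrier heights from condensed reaction graphs

`cgrnn` predicts reaction barrier heights (activation energies, kcal/mol)
from atom-mapped reaction SMILES with a directed message-passing neural
network (D-MPNN) over the condensed graph of reaction (CGR), and quantifies
what 3D transition-state information adds to the prediction. It is aimed at
computational chemists who have balanced, explicit-hydrogen, atom-mapped
reaction tables (RDB7/RGD1-style) and, optionally, reactant /
transition-state / product conformers, and who want a reproducible,
dependency-light R pipeline for barrier regression, leakage-aware data
splitting and feature-importance analysis.

## The model

A reaction `reactants>>products` is superimposed into a single graph: atoms
matched by map index, edge set = union of both sides' bonds, and every
feature vector the concatenation of a reactant half and a product half (a
bond missing on one side has an all-zero half), so bond formation, cleavage
and order change are explicit. With `e_vw = cat(x_v, bond_vw)`, directed
edge states evolve as

    h0_vw   = W_i e_vw + b_i
    h(t+1)  = ReLU( h0_vw + W_h * sum_{k in N(v)\{w}} ht_kv + b_h )
    h_v     = ReLU( W_0 cat(x_v, sum_k hT_kv) + b_0 )
    h_m     = mean_v h_v        ->  FFN  ->  barrier (kcal/mol)

Per-atom extras — tabulated quantum-chemical descriptors (the 37 = 13 atom +
4 bond + 20 molecular schema) or per-atom 3D descriptors (AEV symmetry
functions, SOAP power spectra) computed from conformers for any subset of
the roles r/ts/p — enter either by direct concatenation or through a learned
linear+ReLU embedding (optionally with a residual self-attention pass),
before or after message passing. Training follows AdamW (β1 = 0.9,
β2 = 0.999, ε = 1e-8), batch size 50, cosine annealing with 10 warmup
steps, MSE on z-scored targets, best-validation-MAE checkpointing, and is
bit-reproducible per seed. Splitters: random 90/5/5, reaction-core-clustered
(no core shared across partitions), and barrier-height extremes (lower 5% →
validation, upper 5% → test). See the methods vignette
(`vignettes/barrier-height-dmpnn.Rmd`) for the full account.

The network is implemented in base R matrix code (forward, analytic
backprop, AdamW); a naive per-edge reference evaluator serves as an
independent correctness oracle, and analytic gradients are tested against
finite differences for every parameter tensor.

## Worked example

The built-in generator emits atom-mapped hydrogen-transfer reactions with
r/ts/p conformers and barriers from a known formula in which a γ-weighted
transition-state bond length carries signal no 2D model can reach:

```r
library(cgrnn)

recs <- generate_fixtures(fixture_config(n_reactions = 2000, seed = 7))
ids  <- vapply(recs, function(r) r$id, character(1))
sp   <- random_split(ids, seed = 7)                     # 1800 / 100 / 100

mc <- model_config(hidden_dim = 64, depth = 3, ffn_layers = 2, ffn_hidden = 64)
tc <- train_config(epochs = 30, batch_size = 50, lr = 1e-3, seed = 7)

fit  <- train_dmpnn(recs, sp, mc, tc)                   # ~40 s on one CPU
test <- recs[ids %in% sp$test]
str(evaluate_model(fit$state, test))
#> List of 3
#>  $ mae : num 1.92
#>  $ rmse: num 2.22
#>  $ n   : int 100

geometry_mae_floor(fixture_config(n_reactions = 2000, seed = 7))
#> 1.834722

# add transition-state AEV descriptors and retrain
ac <- aev_config(elements = c("H", "C", "N", "O"))
for (i in seq_along(recs)) {
  pos <- positional_features(recs[[i]]$conformers, roles_used = "ts",
                             config = ac, maps = recs[[i]]$cgr$map_index)
  recs[[i]]$cgr <- attach_positional(recs[[i]]$cgr, pos)
}
mc3d <- model_config(hidden_dim = 64, depth = 3, ffn_layers = 2,
                     ffn_hidden = 64, extra_route = "route1_linear_relu",
                     extra_placement = "before_mpnn", extra_embed_dim = 64)
fit3d <- train_dmpnn(recs, sp, mc3d, tc)
str(evaluate_model(fit3d$state, recs[ids %in% sp$test]))
#> List of 3
#>  $ mae : num 0.423
#>  $ rmse: num 0.521
#>  $ n   : int 100
```

Reading: the coordinate-blind model's test MAE (1.92 kcal/mol) sits at the
analytic floor imposed by the geometry term (1.83 kcal/mol) — it has learned
everything the 2D graph contains. Supplying TS coordinates through AEV
features cuts the MAE by 78%, to 0.42 kcal/mol, approaching the 0.5
kcal/mol noise level of the generator. That ordering (no-coord ≥ floor ≫
with-coord) is the desk-scale analogue of the benefit of ground-truth TS
coordinates on real barrier datasets.

A command-line surface wraps the same functions
(`exec/cgrnn generate|featurize|split|train|evaluate|importance|predict`),
reading reaction CSVs and XYZ conformers and writing JSON splits, metrics
and provenance.

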
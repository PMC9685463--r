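# egmatch

Self-supervised pre-training of an E(3)-equivariant graph matching
encoder on molecular-dynamics trajectories of protein–ligand complexes,
with downstream binding-affinity and ligand-efficacy prediction and a
per-complex motion statistic.

## What it does, for whom

Predicting how strongly a drug binds its target usually starts from one
static complex structure. This package is for computational chemists and
method developers who want to exploit *dynamics*: it learns complex
representations from MD-like trajectories without labels, using two
self-supervised tasks, and transfers them to supervised tasks with linear
probing or fine-tuning. A bundled Langevin toy simulator generates
ligand–pocket trajectories with a known binding-strength parameter, so
every part of the pipeline is exercisable end to end on a laptop-scale
CPU budget.

## The model

Complexes are atom graphs: ligand and pocket atoms carry invariant
features (element one-hot + electronegativity), intra edges connect atoms
within 4 Å, the pocket is receptor atoms strictly within 6 Å of the
ligand, and cross edges link ligand–receptor pairs within a cutoff. An
L-layer equivariant graph matching network transforms features h and
coordinates x jointly:

    m_{j→i} = φ_e(h_i, h_j, ‖x_i − x_j‖²)                    intra edges
    a_{j→i} = softmax_j ⟨φ^q(h_i), φ^k(h_j)⟩                 cross attention
    μ_{j→i} = a_{j→i} · h_j ⊙ φ_d(‖x_i − x_j‖²)              cross edges
    x_i'    = x_i + (1/deg i) Σ_j (x_i − x_j) · w_ij          w from φ_m / φ_μ
    h_i'    = h_i + φ_h(h_i, Σ_j m_{j→i}, Σ_{j'} μ_{j'→i})

Feature outputs are rigid-motion invariant and coordinate outputs
equivariant by construction. Pre-training mixes two objectives:
(1) *prompt-based denoising generation* — from a noise-corrupted frame t,
predict the clean coordinates of frame t + Δt, with a learnable prompt
embedding per interval Δt; (2) *snapshot ordering* — recover the temporal
order of n shuffled frames from antisymmetric pairwise precedence
probabilities, decoded by topological sort. Downstream, mean-pooled
features feed a pK regression head (RMSE loss) or an efficacy classifier
(BCE loss, 5.5 Å interface region), with the encoder frozen (probing) or
trainable (fine-tuning). The motion statistic
Δx_LR = ‖x_out − x_in‖² / (N + M) summarizes how much motion the encoder
predicts for a complex; less predicted motion accompanies stronger
binding.

Because this R stack has no neural-network library, the package includes
a small reverse-mode autodiff tape and Adam optimizer in base R,
gradient-checked against finite differences in the test suite.

## Worked example

Simulate ten toy binding events, pre-train briefly, inspect one complex:

```r
library(egmatch)
set.seed(7)
trajs <- lapply(1:10, function(i) {
  simulate_trajectory(
    egm_synthetic_config(frames = 12, kappa = c(0.1, 1, 10)[1 + (i %% 3)],
                         start_offset = 8, eta = 0.05, cross_cutoff = 8,
                         seed = 100 + i),
    complex_id = sprintf("cpx%02d", i))
})
model <- egm_pretrain(
  trajs,
  egm_pretrain_config(steps = 150, n_layers = 2, hidden = 16,
                      psi_prompt = 4, interval_set = c(1, 2, 5)),
  seed = 7)
model
#> <egm_model> pre-trained equivariant graph matching model
#> <egm_encoder> 2 layers, psi_h=9, psi_prompt=4, hidden=16 (4994 parameters)
#>   tasks: generation=TRUE (sigma=0.1, prompt=TRUE), ordering=TRUE (n=4), lambda=0.50
#>   150 steps; final loss 0.5526
```

The combined loss is the λ-weighted sum of the generation loss (mean
squared per-atom displacement, Å²) and the ordering BCE. Encode the final
frame of the first complex and compute its motion statistic:

```r
snap <- trajs[[1]]$snapshots[[12]]
enc  <- predict(model, snap, type = "encoding")
enc
#> <encoded_complex> 30 atoms, feature width 9
delta_x_LR(rbind(snap$ligand$coords, snap$receptor$coords), enc$coords)
#> [1] 0.2433
```

0.24 Å² of predicted mean squared per-atom motion: this weak binder
(kappa = 0.1) is still settling into the pocket. Across the ten
complexes, `egm_motion()` returns one Δx_LR per complex; larger values
track weaker binders, which is the association the acceptance script
quantifies with a Spearman correlation on 120 complexes.

The same pipeline is scriptable from a shell via `exec/egmatch`
(`simulate`, `pretrain`, `probe`, `finetune`, `predict`,
`analyze-motion`) with a YAML config and a `--seed`.

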
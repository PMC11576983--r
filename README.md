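# gdadapt

Unsupervised **g**raph **d**omain **adapt**ation in R: train a graph
classifier on a labeled source collection and transfer it to an unlabeled
target collection whose distribution has shifted — denser molecules,
noisier drawings, a rewired network.

The package implements a three-stage pipeline:

1. **Joint contrastive pre-training** — a shared GCN encoder is
   initialized on the pooled unlabeled union of both domains with the
   NT-Xent objective over paired stochastic views (edge dropping +
   feature masking).
2. **Information-bottleneck adversarial adaptation** — the encoder
   samples per-edge Bernoulli retention masks with learned keep
   probabilities `alpha_e = sigmoid(score(z_u + z_v))`, propagates
   through the normalized masked adjacency
   `D^{-1/2}(A_mask + I) D^{-1/2}`, and is trained with

   `L = L_cla - L_adv + beta * (I_up_source + I_up_target)`

   where `L_adv` is a Donsker–Varadhan bound
   `E_joint[T] - log E_marg[e^T]` maintained by an adversarial critic
   `T`, and `I_up` is the variational Gaussian-KL upper bound on
   `I(X; Z)` of a reparameterized posterior.
3. **Meta pseudo-label distillation** — a teacher labels the target, a
   student learns from those labels, and the student's measured
   improvement on truly labeled source data (the scalar `h`) scales the
   teacher's reinforcement of its own pseudo-labels:
   `L_teacher = L_adapt(y_s) + h * L_adapt(soft pseudo-labels)`.

Everything runs on a package-local reverse-mode differentiation tape
(plain R + Matrix); gradients are finite-difference-verified in the test
suite. Readers and writers for TUDataset flat files and edge-list
networks are included, along with a seeded synthetic benchmark with
planted class motifs under controlled domain shift, so the whole pipeline
is exercisable end-to-end without downloads.

## Worked example

Generate a paired benchmark whose labels depend only on a planted motif
(ring vs. chord-enriched wirings on six nodes) while the target's
background density is 1.5x the source's, then train the source-only
baseline and the full pipeline:

```r
library(gdadapt)

spec <- shift_spec(n_per_domain = 300, shift_kind = "edge_density",
                   shift_magnitude = 0.5, seed = 11)
pair <- make_graph_shift_pair(spec)

cfg  <- gda_config(epochs = 60)
base <- train_source_gcn(pair$source, pair$target, cfg, seed = 1)

pt  <- pretrain_encoder(c(pair$source$graphs, pair$target$graphs),
                        encoder_config(8, 64),
                        augmentation_config(epochs = 10), seed = 501)
fit <- gda_train(pair$source, pair$target, cfg, seed = 1,
                 enc_params = pt$params)

round(c(baseline = base$final_acc_teacher,
        teacher  = fit$final_acc_teacher,
        student  = fit$final_acc_student), 3)
#> baseline  teacher  student
#>    0.623    0.690    0.623
```

The baseline GCN reaches ~0.88 accuracy on the source but only 0.62 on
the density-shifted target. In this run the adapted teacher recovers
about 7 points over the baseline while the distilled student — the
target-oriented final predictor — matches the baseline; across seeds the
teacher hovers at or a few points above the baseline and the student lags
its teacher, so at this desk scale the pipeline's component mechanisms
are all exercised but the end-to-end headline gain is modest and noisy.
`fit$metrics` holds per-epoch loss components (`l_cla`, `l_adv`,
`i_up_source`, `i_up_target`), the distill-coefficient statistics
(`h_mean`, `h_pos_frac`) and per-epoch target accuracies; run-to-run
spread across seeds is a few points, so paired multi-seed comparisons
(`run_experiment()`, `ablation_suite()`, `beta_sweep()`) are the
supported way to compare variants.

Because the generator records the planted motif edges, the learned keep
probabilities can be scored against ground truth:

```r
alpha_motif_auc(fit$student, pair$target, seed = 5)
#> [1] 0.54     # 0.5 = chance
```

## Command-line wrappers

Thin Rscript wrappers over the exported functions live in `inst/cli/`:

```sh
Rscript inst/cli/simulate.R --task graph --shift edge_density --magnitude 0.5 --n 300 --seed 1 --out sim/
Rscript inst/cli/pretrain.R --source sim/source --target sim/target --epochs 30 --seed 1 --out ckpt/
Rscript inst/cli/train.R    --source sim/source --target sim/target --beta 0.01 --epochs 60 --seed 1 --pretrain-ckpt ckpt/ --out run/
```

See `vignettes/methods.Rmd` for the model details, every tunable
parameter with its default and rationale, and the package's known
limitations.
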
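# ddapred

Drug–disease association prediction with contrastive embedding enhancement.

## The problem

Drug repositioning asks which approved drugs might treat which diseases.
Framed computationally, it is sparse bipartite link prediction: given a small
set of experimentally confirmed drug–disease associations, rank the vast
majority of untested pairs. `ddapred` implements a lightweight dual-encoder
pipeline for this task, aimed at data-sparse and cold-start settings where
graph-based models struggle: it needs only a SMILES string per drug and free
text per disease, with no knowledge-graph construction and no encoder
fine-tuning.

## The model

For a drug *d*, an encoder emits token-level embeddings
**M**<sub>seq</sub> ∈ ℝ<sup>L×384</sup> for its (truncated, L ≤ 512) SMILES
string. A two-layer scorer with tanh activation assigns each token an
attention score *e*<sub>j</sub> = **W**₂ tanh(**W**₁ **m**<sub>j</sub> + **b**₁) + **b**₂,
and a max-stabilized softmax α = softmax(*e*) pools the sequence into
**M**<sub>d</sub> = Σ<sub>j</sub> α<sub>j</sub> **m**<sub>j</sub>, a convex
combination emphasizing informative substructures.

For a disease *i*, each available text field *f* ∈ {Name, Synonymous,
Definition} is encoded to a 768-dimensional aggregate vector
**D**<sub>cls,f</sub>; the fields are fused by the normalized weighted mean
**D**<sub>fused</sub> = Σ w<sub>f</sub> **D**<sub>cls,f</sub> / Σ w<sub>f</sub>
and projected linearly to **D**<sub>i</sub> ∈ ℝ<sup>128</sup>.

Two projection heads (linear → ReLU → linear → layer norm) map
**M**<sub>d</sub> and **D**<sub>i</sub> into a shared space. They are trained
with a temperature-scaled InfoNCE loss over batches of known positives,

ℒ = −mean<sub>(d,i)</sub> log [ exp(S<sub>di</sub>) / Σ<sub>j</sub> exp(S<sub>dj</sub>) ],  S<sub>ij</sub> = **Z**<sub>drug,i</sub>·**Z**<sub>disease,j</sub> / τ,

so matched pairs score above in-batch negatives. The enhanced feature
**X** = [**M**<sub>d</sub>; **D**<sub>i</sub>; **Z**<sub>drug</sub>;
**Z**<sub>disease</sub>; **Z**<sub>interact</sub>] feeds a Random Forest whose
score is the mean per-tree vote ŷ = (1/T) Σ<sub>t</sub> h<sub>t</sub>(**X**);
binary calls use the Youden-optimal threshold θ\* maximizing
J(θ) = TPR(θ) − FPR(θ), selected on training folds only.

The package ships the full evaluation protocol — balanced negative sampling,
stratified 5-fold cross-validation, C1/C2/C3 cold-start splits (new drugs,
new diseases, both), Top-K ranking metrics (P@K, R@K, MRR, NDCG@10),
Gaussian-noise robustness sweeps, cosine-separability diagnostics (Cohen's
d), and KMeans clustering agreement (NMI/ARI) — plus a synthetic benchmark
generator with planted low-rank signal and oracle/mock encoder adapters, so
every stage runs and is tested fully offline. Pretrained molecular and
biomedical text encoders plug in through the same adapter contract.

## Worked example

```r
library(ddapred)

# 1. Simulate a benchmark-shaped dataset with planted signal
ds <- generate_benchmark(synth_config(n_drugs = 60, n_diseases = 40,
                                      latent_dim = 6, target_density = 0.08,
                                      noise_sd = 0.3, seed = 0))
print(ds)

# 2. Configure the pipeline with the oracle encoder adapter
adapter <- adapter_oracle(ds, seed = 1, token_dim = 48, text_dim = 96)
config <- pipeline_config(adapter,
                          enhancer = enhancer_config(proj_dim = 32, epochs = 15,
                                                     batch_size = 128),
                          forest = forest_config(n_estimators = 80),
                          disease_proj_dim = 24, ranking = TRUE, seed = 0)

# 3. Balanced negatives + stratified 5-fold cross-validation
pairs <- build_labeled_pairs(ds, seed = 3)
report <- run_cv_experiment(list(drugs = ds$drugs, diseases = ds$diseases,
                                 pairs = pairs), config)
print(report)
```

```
<synth_dataset: 60 drugs x 40 diseases, 191 positives (density 0.0796)>
<metrics_report: cv5, 5 fold(s)>
  mean AUROC 0.8585 | AUPR 0.8551 | F1 0.7914 | accuracy 0.7909
  ranking: MRR 0.9611 | NDCG@10 0.9697 | P@1=0.9222 P@3=0.5071 | R@1=0.6942 R@3=0.9734
```

The mean AUROC of 0.86 says a random known association outranks a random
unknown pair 86% of the time under cross-validation on this small planted
benchmark; MRR 0.96 says the top-ranked candidate disease for a test drug is
almost always a true association. Cold-start evaluation replaces the CV
split:

```r
cs <- make_coldstart_split(pairs, mode = "C1", seed = 9)   # held-out drugs
run_cv_experiment(list(drugs = ds$drugs, diseases = ds$diseases,
                       pairs = pairs), config, cs)
```

A command-line interface wraps the same functions
(`inst/cli/ddapred simulate|encode|train|evaluate|coldstart|quality|attn-export`);
every run writes a manifest (seed, config echo, version) beside its outputs
and is bit-for-bit reproducible under a fixed `--seed`.

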
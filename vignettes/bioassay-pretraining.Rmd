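---
title: "Multi-task bioassay pre-training for binding-affinity models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task bioassay pre-training for binding-affinity models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affpret)
```

## The problem

Structure-based prediction of protein–ligand binding affinity (PLBA) is
data-starved: curated complex collections with co-crystal structures hold
only a few thousand high-quality training examples. Public bioactivity
databases hold orders of magnitude more affinity measurements, but three
obstacles block their direct use:

* **label variety** — measurements come as IC50, Ki or Kd, which are not
  mutually comparable;
* **label noise** — the same protein–ligand pair can differ by orders of
  magnitude between bioassays, because each assay has its own protocol,
  conditions and systematic bias;
* **missing conformations** — bioactivity databases store no 3D complex
  structures, so docked poses must stand in for binding conformations.

`affpret` implements a pre-training strategy built around the one
reliability that survives these obstacles: *within* a bioassay,
measurements are mutually comparable. The model is pre-trained on
bioassay-specific data pairs — two ligands measured against the same target
in the same assay — with two objectives per measurement family: regress the
first ligand's affinity, and classify which of the two values is larger.
The ranking objective is invariant to any per-assay additive bias on the
label scale, which is exactly the noise structure assays induce.

## Model

A bioassay is a record $A_i = (P_i, \{(L_{ij}, y_{ij})\}_{j=1}^{n_i}, t_i)$:
one protein target, $n_i$ ligands with affinity values in nM, and a single
measurement type $t_i \in \{\mathrm{IC50}, \mathrm{Ki}, \mathrm{Kd}\}$.
Ki and Kd are merged into one "K" family: they estimate the same
dissociation-style constant, and Kd alone is too scarce to carry a task.
This yields a $2 \times 2$ task grid — {IC50, K} × {regression, ranking} —
served by four heads on one shared encoder (hard parameter sharing).

**Complex representation.** A complex (protein $P$, ligand $L$, pose $C$) is
turned into three graphs, each thresholded on Euclidean distance with a
strict `<` comparison:

* ligand graph: heavy atoms, edges below 5.0 Å;
* protein graph: residues at their C$\alpha$ coordinates, edges below 8.0 Å;
* interaction graph: bipartite residue–atom edges below 12.0 Å.

**Encoder.** Both towers are message-passing GNNs. At layer $\ell$,
messages $M_\ell(h_i, h_j, e_{ij})$ from neighbors are aggregated and the
node state updated; after $n$ layers the final node embedding is the *sum*
of the per-layer embeddings (jumping knowledge). Five layer variants are
provided (GCN, GIN, GAT, EGNN, AttentiveFP), all consuming edge features
(a 16-center Gaussian radial-basis expansion of the distance, plus bond
orders on ligand edges). For every interaction edge $(i, j)$ the fusion
module computes
$h^I_{ij} = \mathrm{MLP}(h^P_i \,\|\, h^L_j \,\|\, \mathrm{FC}(e^I_{ij}))$,
and the read-out produces the complex embedding
$o = o_{\mathrm{sum}} \,\|\, o_{\mathrm{max}}$ with
$o_{\mathrm{sum}} = \sum_{(i,j)} \tanh(w^\top h^I_{ij})\, h^I_{ij}$ and
element-wise max pooling for $o_{\mathrm{max}}$. The per-edge attention
scores $\tanh(w^\top h^I_{ij})$ are retained for interpretation.

**Losses.** For a sampled pair, the regression head of the pair's label
family predicts the first ligand's affinity (MSE on the pAff scale), the
ranking head scores the concatenation $o_1 \| o_2$ against the indicator
$\mathbb{I}[y_{ij} > y_{ik}]$ (binary cross-entropy on the logit), and the
total is $L = L_{\mathrm{Rank}} + \lambda L_{\mathrm{Reg}}$. Heads of the
other family receive no gradient from the pair.

## Design decisions

Several points were genuinely open and settled as follows.

* **Regression target scale.** Raw nM values span nine orders of magnitude
  and MSE on them is dominated by weak binders, so regression targets are
  pAff $= 9 - \log_{10}(\text{nM})$, the field's standard scale for
  downstream complex datasets. Ranking labels remain the literal
  comparison of the stored nM values — monotone transforms do not change
  them, only their orientation relative to binding strength (larger nM =
  weaker binder), which is documented rather than flipped.
* **Indices and storage.** Graphs store undirected edges once as
  $(i, j), i<j$, in lexicographic order; both directions are materialized
  only when the encoder builds its aggregation operators. Self-loops are
  excluded: self-distance is zero and carries no geometry. Indices are
  1-based, the R convention.
* **Pocket truncation.** By default the protein tower sees only residues
  with C$\alpha$ within 12 Å of any ligand atom. No residue able to form
  an interaction edge is lost, and cost stays bounded; `full_protein =
  TRUE` restores the complete chain.
* **Feature schema.** Atom features: element one-hot over
  C/N/O/S/P/F/Cl/Br/I plus an explicit "other" slot (unknown elements
  never crash), heavy-atom degree one-hot 0–5, formal charge, aromaticity
  and ring flags, hybridization one-hot. Residue features: 20+UNK one-hot,
  Kyte–Doolittle hydropathy, charge class, molecular weight. The schema is
  versioned in the model configuration so alternatives can be swapped.
* **Ties.** The ranking indicator is undefined when the two values are
  exactly equal, so tied draws are re-sampled a bounded number of times;
  an assay whose values are all identical raises an explicit error.
* **Duplicate measurements.** Repeated (assay, ligand) rows collapse to
  their geometric mean — the natural average for log-scale quantities.
* **Epochs over a sampled stream.** The pair stream is infinite by
  construction; one epoch is defined as $\sum_i n_i$ sampled pairs so the
  epoch budget scales with the collection.
* **Plateau rule.** "No drop in training loss for 10 consecutive epochs"
  is read as: no new strict minimum of the epoch-mean training loss; the
  patience counter resets on a new minimum and after each decay. The same
  incremental state drives `plateau_lr()`, `pretrain()` and `finetune()`.
  A configurable floor (default 1e-6) guards degenerate schedules; the
  fine-tuning phase uses the same rule alongside early stopping (patience
  70 epochs, best validation RMSE restored).
* **Head/MLP sizes.** The heads are 2-layer MLPs with LeakyReLU; the
  fusion FC maps edge features to half the interaction width. No published
  sizes exist for these blocks; all are configuration-exposed.
* **$\lambda$ default.** The regression weight defaults to 0.1, the center
  of the canonical ablation grid $\{0, 0.01, 0.1, 0.3, 1.0\}$ served by
  `run_lambda_ablation()`.
* **GIN epsilon.** Fixed at 0 (GIN-0), the common default.
* **Numerical core.** No deep-learning backend is assumed: the package
  carries a small reverse-mode automatic-differentiation tape over dense
  matrices, verified against numerical differentiation in the test suite,
  plus a hand-written Adam (weight decay applied as L2 on the gradient).
  At the node counts this package targets (tens of residues/atoms), dense
  aggregation matrices outperform sparse structures in R.
* **Determinism.** Evaluation mode runs no stochastic operation (dropout
  off), so encoding and prediction are bit-reproducible; checkpoints
  round-trip exactly and refuse to load under a mismatched configuration
  fingerprint.

## What the synthetic generator emulates — and what it does not

The generator plants a fully known ground truth so that every module is
testable without any external download:

* each assay gets its own pocket (jittered cubic lattice of C$\alpha$
  positions) and a systematic offset $b_i \sim N(0, \sigma_{assay})$ on the
  pAff scale — the label-noise structure;
* assays are IC50 or Ki/Kd typed, with a constant shift $\delta$ added to
  IC50 assays — the label-variety structure;
* each record is a chain-like ligand posed near the pocket with Gaussian
  coordinate jitter — a stand-in for docked rather than crystal poses;
* the true affinity is linear in the residue–atom contact count:
  pAff $= \beta_0 + \alpha \cdot \text{contacts} + b_i + \delta \cdot
  \mathbb{I}[\mathrm{IC50}] + \varepsilon$, stored as
  nM $= 10^{9-\text{pAff}}$.

Affinity is planted on the contact count deliberately: it is the one
structural quantity the interaction graph provably carries, so recovery
tests isolate the framework (sampling, multi-task losses, encoder,
transfer) from chemistry and featurization choices. Within an assay the
shared offset cancels in every pairwise comparison — the formal statement
of "within-assay values are comparable" — and the tests assert this
invariance directly.

Defaults: 40 assays of 4–16 ligands (~400 records), pockets of 8–18
residues, ligands of 5–14 heavy atoms, $\alpha = 0.05$ pAff/contact,
intercept 3.0, $\sigma_{assay} = 0.4$, $\delta = 0.5$,
$\sigma_\varepsilon = 0.1$, pose jitter 0.3 Å. These were chosen once as a
desk-scale regime in which the planted signal dominates measurement noise
within assays (contact counts vary by tens across an assay, so
$\alpha\,\Delta\text{contacts} \gg \sigma_\varepsilon$) while cross-assay
offsets remain large enough to make naive global regression misleading.

What passing tests on this generator do **not** show: real docked poses
have correlated, pose-quality-dependent errors, real affinity depends on
chemistry far beyond contact counts, and real assay-to-assay noise is not
purely additive on the log scale. Results on synthetic data validate the
machinery, not chemical accuracy.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run the full pipeline at desk
scale, chosen as the package's own study conditions: encoder GCN with 2
layers and hidden width 16; pre-training 15 epochs (batch 32 pairs) on 32
of the 40 synthetic assays, with 8 assays held out for ranking evaluation
(200 sampled pairs); a downstream set of 100 clean-label complexes split
60/15/25 into train/validation/test, fine-tuned for 40 epochs; the
pretrain-vs-scratch comparison is paired over 5 seeds. The optimizer
protocol keeps its full-scale defaults (Adam, lr $10^{-3}$, L2 $10^{-6}$,
plateau decay 0.6/10, dropout 0.1) except for the epoch budgets above.

## Known limitations

* The encoder towers are width- and depth-limited by the pure-R autodiff;
  this is a framework validation vehicle, not a GPU training stack.
* MOL2 formal charges are not read (SDF `M CHG` lines are); protonation
  and bond perception beyond file connectivity are out of scope.
* EGNN is implemented in its invariant form (distance-fed messages,
  no coordinate updates), sufficient for scalar affinity outputs.
* The AttentiveFP variant supplies node embeddings only; the package's own
  interaction fusion and read-out replace its super-node pooling, keeping
  the read-out identical across variants.
* The ranking head is not antisymmetric by construction;
  training relies on random pair orientation, so
  `predict_rank(a, b)` and `1 - predict_rank(b, a)` agree only up to what
  training induced.
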
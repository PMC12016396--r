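# cmiCollab

Deep graph-collaborative learning for circRNA–miRNA interaction (CMI)
prediction in R.

Circular RNAs act as miRNA sponges: by sequestering a miRNA they relieve
its repression of downstream genes, which makes the map of circRNA–miRNA
binding central to understanding post-transcriptional regulation and
disease. Validated CMIs are scarce and expensive, so computational
ranking of the unobserved pair space guides which interactions to test.
cmiCollab is for computational biologists who want a self-contained,
inspectable implementation of a jointly trained sequence + graph
predictor — library, command-line tool and a planted-structure simulator
for end-to-end verification, with no external downloads.

## The model

Given sequences and a set of known interactions, the predictor is built
from four jointly optimized stages:

1. **Base embeddings.** Each base A/C/G/U is a "word", each RNA a
   "sentence"; a skip-gram model with the exact 4-way softmax maximizes
   `(1/T) Σ_t Σ_{|j|≤k, j≠0} log P(w_{t+j} | w_t)` and yields a 4×64
   lookup table.
2. **Sequence encoder.** A two-layer LSTM (hidden 256) reads the base
   vectors; the final hidden state is compressed by a fully connected
   layer to 128-d features and projected to the graph width *d* = 64,
   giving initial node embeddings `E⁰`.
3. **Collaborative propagation.** With `R` the miRNA×circRNA training
   interaction matrix, `A = [[0, R], [Rᵀ, 0]]` and
   `L̂ = D^(−1/2)(A + I)D^(−1/2)`; three message-passing layers compute
   `E^(l) = LeakyReLU(L̂ E^(l−1) W₁ + (E^(l−1) ⊙ L̂ E^(l−1)) W₂)`,
   propagating higher-order "nodes that share partners" signal.
4. **Scoring.** A pair score is `σ(e_mᵀ e_c)` on the concatenated
   layer embeddings, trained end to end with Adam against binary
   cross-entropy — the graph loss back-propagates into the LSTM, so the
   encoder is shaped by collaborative information.

Evaluation is label-stratified fivefold cross-validation with the seven
standard metrics (specificity, precision, sensitivity, MCC, accuracy,
AUC, AUPR), with the propagation graph rebuilt per fold from training
positives only. The methods vignette (`vignettes/methods.Rmd`) derives
each stage, documents every tunable with its default, and explains the
numerical choices.

## Worked example

Simulate the desk-scale benchmark dataset (planted rank-4 structure),
train the joint model on all labeled pairs, and rank unknown candidates
(about four minutes on one CPU):

```r
library(cmiCollab)

ds <- generate_dataset(synth_config(seed = 1))   # 200 circRNA x 80 miRNA, rank 4
circ_ids <- unique(ds$sequences$id[ds$sequences$kind == "circRNA"])
mir_ids  <- unique(ds$sequences$id[ds$sequences$kind == "miRNA"])
tab   <- sample_negatives(ds$interactions, circ_ids, mir_ids,
                          ratio = 1, seed = 2)
graph <- build_graph(tab, circ_ids, mir_ids)

cfgs  <- desk_model_configs(epochs = 700, seed = 1)
model <- train_model(tab, graph, ds$sequences,
                     cfg = cfgs$train, encoder = cfgs$encoder)
round(model$history[c(1, 350, 700)], 4)
#> [1] 0.6862 0.3879 0.0110

top <- rank_candidates(model, graph, ds$sequences, K = 20)
head(top, 3)
#>   rank  circRNA   miRNA score
#> 1    1 circ0177 mir0043     1
#> 2    2 circ0013 mir0007     1
#> 3    3 circ0010 mir0003     1

# ground truth check: the generator's true interaction probabilities
unknown <- expand.grid(miRNA = mir_ids, circRNA = circ_ids,
                       stringsAsFactors = FALSE)
unknown <- unknown[!(paste(unknown$circRNA, unknown$miRNA) %in%
                       paste(tab$circRNA, tab$miRNA)), ]
c(top20 = mean(ds$prob[cbind(top$circRNA, top$miRNA)]),
  background = mean(ds$prob[cbind(unknown$circRNA, unknown$miRNA)]))
#>      top20 background
#> 0.14094214 0.01943229
```

The training loss falls from ln 2 (chance) to ~0.01. The top-20 ranked
unknown pairs — none of which is a training positive, by construction —
have a mean true interaction probability of 0.141 against a background
of 0.019 over the unknown pair space: a seven-fold enrichment, which is
what a candidate shortlist is for. (The displayed probabilities saturate
near 1; the ranking itself is computed on the raw inner products.) Under
fivefold cross-validation on this dataset the model reaches a mean
held-out AUC of about 0.90 (`planted_benchmark()`, recomputed by the
acceptance script below).

The same pipeline is scriptable from a shell via the thin CLI:

```sh
exec/cmicollab simulate --out-dir data --seed 7
exec/cmicollab evaluate --sequences-circ data/circ.fasta \
    --sequences-mir data/mir.fasta --interactions data/interactions.tsv \
    --folds 5 --seed 1 --report report.json
```

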
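---
title: "Closing scaffold gaps with a next-base network and contraction-expansion search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing scaffold gaps with a next-base network and contraction-expansion search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gapfillr)
```

## The problem

Draft genome assemblies carry runs of undetermined bases (`N`) where the
assembler could not resolve sequence — typically in repetitive or
under-covered regions. `gapfillr` treats each gap as a conditional sequence
prediction problem: the known flanking sequence on either side of the N-run
carries enough context, in many genomes, to reconstruct the missing bases.
The package predicts fills with a character-level neural network, decodes
candidate sequences with a beam search whose cost function mixes model
confidence with sequence-composition priors, screens the candidates by
alignment against homologous (or simulated-truth) regions, and only then
patches the scaffold.

Everything operates on plain FASTA scaffolds with 0-based half-open
coordinates (BED convention), so gap inventories interoperate with standard
interval tools.

## The next-base model

The predictor maps a context window of `window_len` bases to a probability
distribution over the next base. Bases are one-hot encoded over channels
A,C,G,T (an `N` contributes an all-zero row by default — an undetermined
base is treated as carrying no evidence; a `uniform` policy is available).
The channel order is serialised into every model file and checked at load
time, so a model can never be decoded under a different convention than it
was trained with.

The architecture is, in order: a 1-D convolution over time (kernel 3 by
default, ReLU), batch normalisation, non-overlapping max pooling over time,
dropout, two stacked bidirectional LSTM layers, an element-wise residual sum
of the second BiLSTM's output with a width-1 convolutional projection of the
pooled convolutional features, a global max pool over time, and an affine
map to four logits with softmax. The residual projection exists because the
convolutional features (dimension `conv_channels`) and the BiLSTM output
(dimension `2 * lstm_hidden`) differ in width; a width-1 convolution is the
minimal shape-matching map. The second BiLSTM consumes the first layer's
output (a stacked reading), not the convolutional features directly.

Batch normalisation uses minibatch statistics during training and running
(exponential-moving-average) statistics at inference; dropout is disabled at
inference. Both choices make prediction a deterministic function of the
context, which the search relies on: node costs must be exactly
recomputable from their probability traces.

Training minimises 4-class cross-entropy with Adam on sliding windows taken
from the N-free stretches of any FASTA input — typically the draft assembly
itself, so no external data is needed. A held-out fraction drives early
stopping on validation loss, and the returned model carries the parameters
of the best validation epoch. The full-scale architecture defaults
(`conv_channels = 64`, `lstm_hidden = 128`, `window_len = 64`) are
configurable throughout; no training recipe is inherited from anywhere, so
learning rate `1e-3`–`2e-3`, batch 128–256 and early stopping with patience
3–5 are the package's own conventional choices. The forward and backward
passes are implemented in-package as BLAS-backed matrix algebra; gradients
are verified against finite differences in the test suite.

## The search

A fill of target length $L$ (by default the observed N-run length) is
decoded base-by-base from a seed (the gap's left flank, or the reverse
complement of the right flank). Each partial candidate is scored
$f = g + h$:

* $g$ accumulates $|\ln p_i|$ over the chosen bases' predicted
  probabilities — the path's total prediction uncertainty. Probabilities
  are floored at `p_min = 1e-9` before the logarithm, since the cost is
  undefined at zero.
* $h$ combines three structural terms:
  $-\alpha \, H(S)/H_{\max} + \beta \, \ln(L - k)/\ln L + \gamma \,
  |\mathrm{GC}_{next} - \mathrm{GC}_{cur}|$, where $H(S)$ sums the full
  4-way entropy of each step's predictive distribution and
  $H_{\max} = k \ln 4$ after $k$ steps. The entropy ratio is invariant to
  the logarithm base (numerator and denominator rescale together), so the
  `log_base` parameter is accepted but mathematically inert. The entropy
  term is *subtracted*: among equally probable paths, the search prefers
  those whose predictive distributions were genuinely informative rather
  than degenerate. The remaining-length term biases early steps; the GC
  term penalises extensions that drift from the current sequence's
  composition, evaluated per candidate base at the finest granularity
  (current sequence versus current sequence plus one base).

All three heuristic weights default to 1 — unit weights keep the worked
closed forms testable and any tuning is data-dependent — and all are
settable per run.

The beam width follows a contraction–expansion schedule: linear growth from
`w_init` to `w_max` over the first `contract_at` fraction of the target
length, then linear shrinkage to `w_final` at the last step. The default
schedule is `w/2 -> w -> w/2` with contraction at 75% of the target length,
`w` being the nominal width (16 by default, mirroring the 16/32/64 widths
used in ablation studies of beam-search gap fillers). The expansion phase
retains more potentially superior partial solutions; the contraction phase
caps the node count as candidates converge. At every step each surviving
node is expanded by all four bases, children are ranked by $f$ with a fully
deterministic tie-break (lower $f$, then earlier channel of the appended
base, then lexicographic sequence), and the schedule-width best survive.
The lowest-$f$ full-length candidate is returned together with the final
beam and per-step probability traces, from which all reported costs are
recomputable to $10^{-9}$.

Two properties anchor the implementation and are enforced in tests: with a
beam at least $4^L$ wide the search returns exactly the brute-force
minimum-$f$ completion, and with zero heuristic weights and constant width
it coincides with a textbook beam search over cumulative $-\log p$.

### Direction handling

A single model serves both flanks: rightward prediction runs on the reverse
complement of the right flank and reverse-complements the result (the task
is strand-symmetric, and one model halves training cost). Bidirectional
mode runs both searches; if the two candidates agree at `min_identity`
(default 0.8) over the gap, the merged fill takes its left half from the
leftward candidate and its right half from the rightward one — each
direction is most reliable near its own seed — otherwise the lower-$f$
candidate wins. Merging never changes the fill length, which keeps gap
coordinates valid after patching.

## The prediction filter

Appending every predicted sequence to an assembly risks importing errors;
the filter keeps only predictions that demonstrably improve on the unfilled
state. Each candidate is framed with up to `frame_margin` (default 50)
flank bases per side and locally aligned (match +1, mismatch −1, gap open
−2, extend −1; `N` never matches anything) against the homologous region
spanning its gap — a user-supplied homolog FASTA keyed by gap id, or the
simulator truth genome. The *alignment rate* is identical aligned bases
over the framed candidate length. The unfilled baseline is the same frame
around the original N-run, aligned the same way. A candidate is
**available** iff its rate reaches `tau` (default 0.9) *and* exceeds the
baseline; otherwise it is **disposable**. Framing both sequences makes the
two rates directly comparable — a bare N-run would trivially rate 0 and the
baseline comparison would be vacuous, while a baseline with full-length
flanks would rate so high that no candidate could beat it. Raising `tau`
can only shrink the available set (monotonicity is tested).

The filtered-versus-unfiltered contrast is realised at desk scale by
patching both candidate sets into copies of the scaffold and scoring both
against truth; read-level hybrid re-assembly is out of scope.

## The simulator

`generate_genome()` concatenates unique blocks (i.i.d. bases with
$P(G)=P(C)=\mathrm{gc}/2$) and repeat blocks (tandem copies of one seeded
motif whose composition is pinned to the target GC, so repeats do not drag
the genome-wide GC off specification; the motif phase runs continuously
across adjacent repeat blocks, making `repeat_fraction = 1` exactly
periodic). `introduce_gaps()` masks non-overlapping intervals with `N`,
optionally targeting repeat or unique blocks, never closer than a margin to
scaffold ends (so every gap has full flanks), and records the masked bases
in a truth table. All generators are bit-deterministic under their seeds.

The default end-to-end fixture is a 50 kb genome at GC 0.45 with half its
length in period-21 repeats, carrying 20 gaps of 20–100 bp split evenly
between repeat blocks (recoverable: the next base is a deterministic
function of any 21-base context) and unique blocks (information-theoretically
unrecoverable: i.i.d. bases). This deliberately exercises both the
predictor and the filter — unique-block fills should be rejected, repeat
fills accepted.

What the simulator does *not* emulate: sequencing error, coverage
variation, heterozygosity, interspersed repeat families with divergent
copies, and genome-scale length. Passing tests on it demonstrate that the
machinery is correct and that learnable structure is recovered; they do not
predict fill rates on real assemblies, where flank context is noisier and
repeat structure far richer.

## Numerical and design choices

* Test- and script-scale problem sizes: the learnability check trains on a
  ~4 kb periodic genome; the end-to-end fixture uses 50 kb, a window of 32
  (still spanning the 21-base period) and a 16-channel/24-hidden network.
  These sizes were chosen so the full suite runs comfortably on one CPU;
  the architecture scales to the 64/128 defaults unchanged.
* `N` handling: gaps of any length are detected (`min_gap_len = 1`);
  flanks never cross another N-run, and gaps whose usable flank is shorter
  than `min_flank` (default 50) are skipped with a warning rather than
  predicted from insufficient context.
* Coordinates are 0-based half-open everywhere; `evaluate_run()` requires
  length-preserving patching so gap intervals stay valid on both scaffold
  sets, and counts a gap as filled only when its interval contains no `N`
  (partial fills are reported separately).
* Ties anywhere in the search resolve by channel order A,C,G,T then
  lexicographically; this is what makes wider beams strictly-nested
  refinements of narrower ones in practice and runs reproducible
  bit-for-bit.
* Degenerate inputs: an empty FASTA yields an empty scaffold list; a
  scaffold without gaps yields an empty inventory; a training genome with
  no N-free stretch of `window_len + 1` yields an empty training set with
  a warning; `fill_rate` with zero gaps is `NA`, not an error.

## Limitations

The predictor can only recover sequence that is a (learnable) function of
its flanking context — unique sequence is unrecoverable by construction,
which is precisely why the filter exists. Fills default to the observed
N-run length, a proxy that inherits whatever bias the scaffolder's gap-size
estimates carry. Training is CPU-bound R; it is adequate for the tens of
kilobases used here and for small genomes, not for gigabase assemblies.
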
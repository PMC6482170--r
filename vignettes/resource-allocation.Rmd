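---
title: "Resource allocation on bipartite lncRNA-protein networks"
author: "lpiRA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource allocation on bipartite lncRNA-protein networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The package treats lncRNA-protein interaction prediction as a
recommendation problem on a bipartite graph. The only hard data are the
known interactions, a binary matrix $I$ with proteins in rows and lncRNAs
in columns; auxiliary data (protein-protein interaction scores, lncRNA
tissue expression) enter solely through similarity matrices. The modeling
assumptions, in decreasing order of importance:

1. **Guilt by association.** Proteins that interact with similar lncRNAs
   (and lncRNAs bound by similar proteins) are likely to share further
   partners. This is what the two-round resource allocation encodes:
   resource placed on a lncRNA's known partners flows to all lncRNAs
   those proteins touch, and back to proteins, concentrating on proteins
   embedded in the same neighbourhood.
2. **Similarity is informative but noisy.** PPI scores and expression
   correlation each cover only part of the node set and carry noise, so
   each is averaged with a Gaussian kernel on the interaction profiles
   themselves, which is defined for every node. Where the PPI-derived
   similarity is exactly zero (no shared evidence) the kernel is used
   alone rather than averaging in a spurious zero.
3. **Second-order redundancy is harmful.** Two proteins can be
   correlated directly (a shared lncRNA) and indirectly (via intermediary
   proteins). Summing both double-counts evidence. Replacing the
   allocation operator $W$ with $W' = W + \alpha W^2$, $\alpha \in
   (-1, 0]$, subtracts a fraction of the two-step paths. Since both $W$
   and $W^2$ are column-stochastic over positive-degree proteins, columns
   of $W'$ sum to $1 + \alpha$: total resource is scaled, relative
   ranking within a column is what changes.

The scored output is $S'_{fin} = W' S_{ini}$. With $\alpha < 0$ some
entries can be negative; they are ranked as-is, without clipping, because
the elimination is a signed correction, not a probability.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.5 | weight of the protein-similarity side of $S_{ini}$ versus the lncRNA side; 0.5 weighs them equally, and nothing in our experiments favoured asymmetry |
| `alpha` | -0.7 | strength of second-order elimination; 0 disables it, values near -1 overcorrect. -0.7 is the default operating point; `sweepAlpha()` tabulates AUC over a grid so users can tune it per dataset |
| `betaPrimeProtein`, `betaPrimeLncrna` | 1.0 | bandwidth adjustment of the interaction-profile kernels, the standard Gaussian-interaction-profile convention (bandwidth = inverse mean squared profile norm) |
| `restartProb`, `rwrTol`, `rwrMaxIter` | 0.5, 1e-8, 1000 | random-walk-with-restart baseline; r = 0.5 balances exploration against locality and is the common default for biological networks |
| `minDegree` | 2 | cleaning threshold: every retained node keeps at least one training edge when one is held out, so leave-one-out evaluation is well defined |

## Numerical conventions and edge cases

- **Degree filtering runs to a fixed point.** Removing a degree-1 node
  can push a neighbour to degree 1; a single pass is not self-consistent.
  The iterated filter is idempotent, which the tests assert. An input
  that empties under filtering is an explicit error, not a silent empty
  result.
- **Zero degrees contribute zero.** Cross-validation masking can zero a
  whole row or column of the training matrix even though cleaned input
  data cannot. Every term with $d(p) = 0$ or $d(l) = 0$ is defined as 0;
  no division by zero occurs anywhere.
- **Constant expression profiles** have undefined correlation; their
  similarity to every other lncRNA is 0 (the least informative value)
  and the diagonal is forced to 1.
- **The lncRNA-side normalization** divides by the summed similarity of
  all lncRNAs to the *scored* lncRNA ($\sum_k Sim^L(l_k, l_j)$ for entry
  $(p_i, l_j)$). This is the only reading under which the denominator is
  bound to the entry being computed; with a unit-diagonal similarity it
  is always positive.
- **Ties in rankings** break by protein identifier, lexicographically
  and stably, so outputs are byte-reproducible.
- **Curve metrics**: tied scores collapse to a single threshold, which
  makes trapezoidal ROC integration equal the Mann-Whitney statistic
  (ties counting one half) to machine precision — asserted against
  brute-force pair counting. AUPR uses non-interpolated step-wise
  summation; with all scores equal it degenerates to the positive
  prevalence.
- **Threshold for scalar metrics**: max-F1 over the pooled scores by
  default (configurable: Youden or fixed). The Matthews coefficient uses
  its standard form $(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$.

## Leakage-safe cross-validation

The interaction-profile kernels are functions of $I$, so computing them
on the full network would hand the model its own test edges. `runCV()`
therefore rebuilds kernels, integrated similarities, $S_{ini}$ and $W$
from the masked training matrix in every fold; the PPI- and
expression-derived components do not depend on $I$ and are computed once.
The harness asserts, in every fold, that each matrix entering the scorer
is zero at the held-out positions.

The negative set per fold is every non-edge (in the full network) of the
lncRNAs holding a test edge in that fold. This keeps LOOCV tractable
(one lncRNA's candidates per fold rather than the full matrix) and
matches standard recommender evaluation. Known training interactions are
excluded from ranked candidate lists by default.

## What the synthetic benchmark shows — and what it does not

`plantedBlockSpec()` defaults generate 60 proteins × 200 lncRNAs in 4
blocks, within-block interaction probability 0.5 against 0.02 across
blocks, then degree-2 filtering. Expression profiles are block means
(standard normal across 24 tissues, matching the dimensionality of real
tissue panels) plus N(0, 0.5²) noise, so within-block absolute
correlation is high by construction. PPI scores cover all within-block
pairs at scores in (0.5, 1] and 5% of cross-block pairs at scores in
(0.05, 0.5). All randomness flows from the single spec seed (with fixed
offsets per generator), so every fixture is reproducible.

This emulates the statistical structure the method assumes — coherent
neighbourhoods visible simultaneously in the interaction map, the PPI
network, and expression — with known ground truth and no downloads. It
does **not** emulate real data's heavy-tailed degree distributions, the
extreme protein/lncRNA asymmetry of curated interaction databases,
database-specific biases, or identifier-mapping noise. Passing the
benchmark demonstrates that the implementation recovers plantable signal
and that its algebra is correct; it does not by itself establish
performance on any particular curated dataset.

Problem sizes used in the tests were chosen to estimate each property
tightly at desk scale: algebraic identities on hundreds of random
networks up to 8×8 (where the iterative and matrix forms are compared
entrywise at 1e-10), benchmark recovery on the 60×200 default with
10-fold cross-validation over ten generator seeds, and the alpha sweep
on a single seed with fold-level reuse of the alpha-independent weight
matrix.

## Design choices that were genuinely open

- **Per-entry integration test.** The protein similarity integration
  averages where the normalized PPI entry is nonzero, entry by entry; a
  per-pair-existence test (average whenever the pair appears in the PPI
  table at all) would differ only for explicitly listed zero scores,
  which the reader rejects anyway.
- **Alpha sweep rescoring.** $W$ does not depend on $\alpha$, so the
  sweep recomputes only $W + \alpha W^2$ and the final product per value;
  nothing is refit.
- **Canonical axis order.** Readers order axes by first appearance.
  Writing emits edges lncRNA-major; on reader-ordered networks the round
  trip is the exact identity, and for any network the edge content is
  preserved (two independent first-appearance sequences cannot in
  general be encoded in one edge ordering).
- **No higher-order elimination.** $W + \alpha W^2 + \beta W^3 + \dots$
  is a natural extension but adds a parameter per order; the package
  stops at second order, where the redundancy argument is cleanest.

## Known limitations

- **Cold start.** A lncRNA or protein with no training interactions
  receives no resource and cannot be scored by allocation; the random
  walk baseline degrades the same way. This is inherent to
  interaction-only methods.
- **Dense linear algebra.** Matrices are dense base-R; fine for
  thousands of nodes, not engineered for tens of thousands.
- **AUPR at strong imbalance** is low in absolute terms on the benchmark
  (prevalence ~3%); compare methods by AUPR ratio, not absolute value.
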
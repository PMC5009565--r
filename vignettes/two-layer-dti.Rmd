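---
title: "Two-layer local classifiers for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer local classifiers for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtilocal)
```

## The problem

Curated drug-target interaction (DTI) tables record which approved drugs
bind which protein targets, but they are incomplete: some true interactions
are simply not yet collected. A supervised classifier that labels every
unrecorded drug-target pair as a negative therefore trains on corrupted
labels. The missing interactions blur the decision boundary (they sit among
the negatives but look like positives), worsen the already severe
positive/negative imbalance (most targets interact with only one or two
drugs), and — at evaluation time — surface as highly-scored "false"
positives that drag down threshold-free metrics.

`dtilocal` addresses the cold-start scenario in which a *new* drug, with no
known interactions, is scored against every known target using only its
similarities to the training drugs.

## The model

### Kernel ridge scorer

Every classifier in the package is a regularized least-squares (RLS) model
over the drug similarity matrix, used directly as the kernel. For target
$t_j$ with 0/1 training-label vector $Y_j$ over $m$ training drugs,

$$ f_j(x) = K(x, X_{trn}) \,(K(X_{trn}, X_{trn}) + \lambda I)^{-1} Y_j, $$

and $f_j(x)$ is the confidence score of query drug $x$ interacting with
$t_j$. The system matrix is label-independent, so one factorization is
shared by all targets trained on the same drug set. A Cholesky
factorization is attempted first; similarity matrices are not guaranteed
positive-definite, so a QR least-squares solve is the fallback, and a
genuinely singular system is reported as an error naming the offending
target. $\lambda$ defaults to 0.5 and with $\lambda = 0$ the solve is only
admitted when the kernel is invertible.

### Bottom layer: reliable negatives via spies

To stop missing interactions from polluting the negative class, the
positive-unlabeled *Spy* procedure mines *reliable negatives* (RN). A
single score threshold is estimated once per training set, on the target
with the most interacting drugs (ties broken toward the lowest target
index): per repetition, $\lceil 0.10\,|P|\rceil$ spies (at least one) are
drawn from that target's positives $P$, relabeled into the unlabeled pool,
an ordinary RLS model is fitted, and the repetition's threshold is the
*minimum* score among the spies; the unified threshold $t$ averages 10
repetitions. Spies behave like the unknown positives hiding among the
unlabeled pairs, so scores below every spy indicate pairs that are safely
negative. For each target, unlabeled drugs scoring strictly below $t$
under the ordinary classifier form $RN_j$; ties at $t$ stay unlabeled.
The final per-target classifier trains on $P_j \cup RN_j$ only. When
$RN_j$ is empty the ordinary classifier is kept, with a warning.

The threshold is unified across targets because one drug similarity matrix
underlies every local classifier; spy injection happens only on the
max-degree target, not per target. Draws use one seeded generator with
deterministic per-repetition child seeds, so a seed reproduces the
threshold and the RN sets bit for bit.

### Top layer: super-targets

Pooling similar targets relieves the positive scarcity. Targets are
clustered by average-linkage agglomerative clustering on distance
$1 - \text{similarity}$, cut at $1 - \texttt{cut\_similarity}$
(default cut at similarity 0.6). A drug interacts with a super-target if
it interacts with any member (column-wise union). Two guards keep the
pooled labels honest:

* **Fake interactions.** A drug whose top-$K$ most similar other drugs
  (default $K = 3$, similarity ties broken by ascending drug index)
  include *no* co-interactor of the super-target is structurally isolated
  there; its pooled link is removed before training.
* **Adaptive acceptance.** After cleaning, each interacting drug counts how
  many of its top-$K$ neighbors co-interact; if the mean count
  $\tilde n_q$ falls below $K/2$ — or no interactors remain — the
  super-target is *rejected* and contributes nothing. Cleaning runs before
  acceptance so that drugs already deemed spurious do not vote.

One ordinary RLS model per accepted super-target is trained on the cleaned
union labels.

### Fusion

For a target inside an accepted super-target the final confidence is the
geometric mean $\sqrt{S(d_x, st_q)\, S(d_x, t_j)}$; inside a rejected one
it is the bottom-layer score alone. Four variants are exposed: `rls`
(ordinary bottom layer), `spy`, `super` (ordinary + top), `comb`
(spy + top).

Raw RLS scores are not confined to $[0,1]$, and the geometric mean needs
nonnegative inputs. Rather than hard-clipping, each layer is mapped onto
$[0,1]$ by an affine min-max calibration learned from its *training-drug*
scores at fit time (query scores falling outside the training range are
then clipped). The map is strictly monotone, so it preserves every ranking
the metrics below consume. We chose this over a hard clip at 0 after
observing that clipping concentrates a large mass of fused scores into an
exact tie at zero; under the pessimistic tie rule a true target caught in
that tie receives the worst possible rank, which inflates Coverage of the
fused variants for a purely numerical reason.

## Evaluation

Ranks are *pessimistic* (competition/maximum) everywhere: rank 1 is the
best score, and tied scores all take the worst rank of their group — a
conservative convention that also makes the oracle baseline well defined
when all of a drug's positives tie.

* **AUC** $(n' + 0.5\,n'')/(n_{pos}\, n_{neg})$, with $n'$ the
  positive-over-negative wins and $n''$ the score ties — computed exactly
  via average ranks.
* **AUPR** is step-interpolated average precision, ties ordered
  pessimistically (negatives first).
* **Coverage** is the mean, over test drugs with at least one true target,
  of the worst pessimistic rank among the drug's true targets, minus one:
  how far down the ranked target list one must go to cover every true
  target. It is deliberately insensitive to missing positives that are not
  worst-ranked — the property that makes it robust to uncollected
  interactions. Drugs with no true target are excluded from the average
  (their worst rank is undefined) but still contribute all-negative rows
  to pooled AUC.
* **Baselines.** The oracle baseline scores labels as themselves: mean
  positive count minus one. The random baseline has closed form
  $\frac{1}{p}\sum_i k_i (n+1)/(k_i+1) - 1$ (expected worst rank of $k_i$
  uniformly placed positives among $n$), with a Monte-Carlo cross-check in
  `random_coverage()`. Normalized Coverage
  $NC = (C - C_{oracle}) / (C_{random} - C_{oracle})$ rescales between 0
  (perfect) and 1 (random); $C/\#T$ divides by the number of targets.
  Both ease comparison across datasets of different sizes. All coverage
  functions accept `subtract_one = FALSE` because published summaries of
  this family of measures sometimes omit the trailing $-1$; the default
  keeps it.

Cross-validation holds out whole drugs (5 folds by default, sizes within
one of each other, seeded shuffle). Everything trainable — interaction
rows, the drug-similarity submatrix, the spy threshold, the super-target
union, cleaning and acceptance — is recomputed inside each fold from
training drugs only; the target-side clustering uses the full target
similarity, which involves no drugs. Re-estimating the spy threshold per
fold avoids leaking test drugs into the threshold. Pooled AUC over all
(test drug, target) pairs of a fold is the primary figure, averaged over
folds; mean per-drug AUC is reported alongside for diagnostics, since the
pooling level is a genuine free choice.

## Synthetic data

`generate_dti()` emulates the structure the method relies on: round-robin
drug and target clusters; similarities `within_sim = 0.9` inside a cluster
and `between_sim = 0.1` across, plus Gaussian noise (`sd = 0.02`) added
before symmetrization and clipping to $[0,1]$ (clipping can create mass at
the boundaries; accepted); each drug cluster prefers one target cluster
(block interaction probability 0.5 against a 0.05 off-block value plus a
0.02 background). A `hidden_fraction` (default 0.15) of the realized
interactions — sampled uniformly over 1-cells, with no per-drug bias — is
flipped to zero and recorded in a ledger, emulating uncollected
interactions; `reveal()` restores them for use as evaluation ground truth.
Default sizes are 100 drugs by 40 targets, large enough for stable 5-fold
estimates while keeping a full multi-seed study in seconds.

What the generator does *not* emulate: realistic chemistry (fingerprints,
scaffold hopping), power-law target degree distributions, and similarity
matrices that are far from block structure. Passing tests on this family
therefore demonstrate internal correctness and the direction of the
method's improvements under controlled missingness — not performance on
any real benchmark.

```{r example}
sim <- generate_dti(synthetic_spec(m = 60, n = 20, seed = 7))
cv <- run_cv(sim$dataset, variants = c("rls", "comb"), seed = 7,
             truth = reveal(sim)$A)
glance(cv)
```

## Numerical choices and degenerate inputs

* Similarity asymmetry up to $10^{-8}$ is repaired by averaging with the
  transpose; more is an error. Diagonals off 1 by more than $10^{-6}$
  warn but are kept. Similarities outside $[0,1]$ are clipped with a
  warning.
* Similarity ties in the top-$K$ neighbor lists break toward the lower
  drug index, for determinism.
* A max-degree target with fewer than two positives cannot host spies and
  is an error asking for a larger dataset; a spy fraction that would empty
  the positive set is likewise refused.
* Targets with zero training positives get all-zero classifiers (scores
  identically zero) rather than errors: such folds occur legitimately.
* Super-targets left without interactors after cleaning are rejected.
* All randomness — spy draws, fold splits, synthetic generation,
  Monte-Carlo baselines — flows from explicit integer seeds through
  deterministic child seeds; identical seeds give bit-identical outputs.

## Open design choices

* No single clustering method is canonical for forming super-targets;
  average linkage with a configurable cut (default 0.6) was chosen as a
  deterministic, standard option, and the cut is exposed rather than
  hard-coded.
* The top layer is deliberately ordinary: reliable-negative mining targets
  the per-target classifiers, where positives are scarcest, while the
  pooled super-target labels are exactly the ones cleaning has already
  vetted.
* Similarity matrices averaged from two sources (`average_similarities()`)
  are not renormalized afterwards.
* The score calibration before fusion (min-max on training scores) is a
  deliberate design choice of this package; see above.

## Limitations

Coverage's robustness holds only for missing positives that are not the
worst-ranked one; AUC and AUPR generically move when a positive is
relabeled, but degenerate configurations exist (for example, all positives
occupying the bottom ranks) in which AUC is unchanged too. The RLS kernel
is used without a positive-semidefinite repair, matching the method, so
severely non-PSD similarity inputs fall back to least-squares solves. The
package consumes precomputed similarity matrices; computing
chemical-structure, sequence, or annotation similarities is out of scope,
as are drug-side (new-target) scenarios beyond transposing the inputs.
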
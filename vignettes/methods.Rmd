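---
title: "Methods: BMA network inference with an Occam's-window scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BMA network inference with an Occam's-window scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanbma)
```

## The model

Network inference is decomposed into one variable-selection problem per
target gene.  With expression `X[i,t,s]` (gene, time, replicate), the
target's values at times `2..T` are stacked over replicates into a response
of length `n = S(T-1)`, and every candidate regulator contributes a column
of its lagged values:

$$X_{i,t,s} = \beta_{0,i} + \sum_{h \in M} \beta_{hi} X_{h,t-1,s} +
\varepsilon_{i,t,s}, \qquad \varepsilon \sim N(0, \sigma^2).$$

A model $M$ is a subset of candidate regulators.  The edge weight reported
for $h \to i$ is the posterior probability that $\beta_{hi} \neq 0$,
averaged over models weighted by their posterior probabilities.

### Model scoring

Coefficients carry Zellner's $g$-prior on the column-centred design
$X_c$, the intercept a flat prior, and $p(\sigma^2) \propto 1/\sigma^2$:

$$\beta \mid \sigma^2, M \sim N\!\big(0,\; g\,\sigma^2 (X_c^\top X_c)^{-1}\big).$$

Centring matters: it makes the intercept orthogonal to the coefficients, and
only then does the marginal likelihood ratio against the null (intercept-only)
model take the closed form used throughout,

$$2\log\frac{p(M\mid D)}{p(M_0\mid D)} = (n-d-1)\log(1+g) -
(n-1)\log\!\big(1+g(1-R^2)\big) + 2\sum_{h\in M}
\log\frac{\pi_{hi}}{1-\pi_{hi}},$$

with $d = |M|$, $R^2$ the intercept-adjusted coefficient of determination,
and $\pi_{hi}$ the prior edge probability (the last term is the model-prior
log odds under independent edge indicators).  Larger is better; the null
model scores exactly 0.

*Orientation.*  Published presentations of this quantity differ in sign
convention.  We fixed the orientation by an independent oracle: the test
suite integrates the normal–inverse-gamma marginal likelihoods numerically
(Gauss–Hermite over intercept and coefficients, trapezoid in
$\log\sigma^2$) on dozens of random instances and confirms the implemented
closed form equals $2\log$ of the integrated ratio to better than $10^{-4}$
relative error — under this orientation a better-fitting model of equal
size always scores higher, which the Occam's-window search and the EM step
both require.

A BIC backend (`score = "bic"`) replaces the two $g$ terms with
$-n\log(1-R^2) - d\log n$; at $g = n$ the two backends differ by $O(1)$ and
rank well-separated models identically.

### Prior edge probabilities

Three choices, all entering only through the per-edge log odds:

* uninformative $\pi = 0.5$ (the default when no prior is supplied) — the
  prior term vanishes;
* the flat literature prior $\pi = 2.76/6000 \approx 4.6\times10^{-4}$
  (`guelzim_prior()`), encoding that a typical gene has very few
  regulators out of thousands of candidates;
* an informative matrix with pair-specific probabilities, supplied as a
  regulators × targets TSV (its construction from external data sources is
  out of scope — it is consumed as an input).

Probabilities of exactly 0 or 1 would make the log odds infinite; they are
clipped to $[10^{-8}, 1-10^{-8}]$ with a warning.  This cannot materially
reorder models: the clipped log-odds magnitude (≈ 36.8 per edge) still
dwarfs any data term a small model space produces, while staying finite.

## The search

Occam's window keeps the models whose posterior probability is within a
factor $C$ of the best model's: scores within $2\log C$ of the best, with
$C = 100$ by default (a conventional "decisive evidence" ratio).  The scan:

1. start with the active set {null model};
2. score every unseen single-add/single-drop neighbour of every active
   model (neighbours generated in ascending candidate-index order; all
   scores memoised);
3. the newly scored models inside the current window form the next active
   set; a new best simply re-filters the accumulated window;
4. stop when no new model enters the window.

Determinism comes from the fixed neighbour order and the tie-break for the
best model (higher score, then smaller size, then lexicographic key).  The
design choices the algorithm's verbal description leaves open were resolved
as follows: the active set is pruned to the *window* (not to all evaluated
models), models that fall out of the window stay in the score cache, and the
search starts from the null model — the natural anchor of a score scale
whose zero is the null model.  On model spaces small enough to enumerate
($p \le 12$), the returned window set is *identical* to exhaustively
filtering all $2^p$ models (asserted over random instances in the test
suite); the greedy scan could in principle miss a window model reachable
only through far-outside-window intermediates, but we have not observed
this at $C = 100$.

### Prescreening

With thousands of candidates, each target's candidate set is first reduced
to the top `nvar` (default 20) by the single-regulator model score —
one-variable $R^2$ plus that edge's prior log odds — with ties broken by
higher prior probability, then gene identifier.  The default 20 leaves
margin over the largest regulator counts (13) reported in curated yeast
networks.  `nvar = "all"` disables the prescreen.

### Refinement of extreme inclusion probabilities

Because the window omits most of the model space, raw inclusion
probabilities are often exactly 1 (candidate in every window model) or 0.
These are refined from two-model score gaps: for a candidate at 1, the odds
$O = \exp[(s_{best} - s_{best \setminus h})/2]$ give refined probability
$O/(1+O)$; for a candidate at 0, $O = \exp[(s_{best} - s_{best \cup h})/2]$
gives $1/(1+O)$.  The modified models are scored fresh (not restricted to
window members).  Intermediate probabilities are left alone.  All outputs
are clamped to $(10^{-12}, 1-10^{-12})$; note the clamp bounds the
resolvable score gap at $2\log(10^{12}) \approx 55$, so edges with truly
enormous evidence tie at the clamp — harmless for thresholding, a known
(and bounded) coarsening for rank-based metrics.

## Estimating g

$g$ controls the prior spread of coefficients; $g = n$ is the unit
information prior and the recommended range is $1 \le g \le n$ (no more
diffuse than unit information, no tighter than the noise).  We estimate $g$
by maximum marginal likelihood summed over the model space, via EM with
model membership as missing data: alternate (E) a window scan at the
current $g$, giving weights $w_k$, with (M) maximising

$$Q(g) = \sum_k w_k\left[(n-d_k-1)\log(1+g) -
(n-1)\log\!\big(1+g(1-R_k^2)\big)\right]$$

over $[1, n]$ (bounded 1-D optimisation with explicit endpoint checks;
flat $Q$ — e.g. a null-only window — leaves $g$ unchanged).  $g$ starts at
$n$, is clamped to $[1, n]$ each iteration, and iteration stops at
$|g'-g| \le 10^{-6}\max(1,g)$ or 100 iterations (warning).  The $R^2$
cache is shared across iterations, so re-scans only recompute the cheap
$g$-dependent terms.  With a single model of $n=20$, $d=1$, $R^2=0.5$ the
interior stationary point is $g^\* = 17$ exactly, a closed-form case frozen
into the tests alongside a $10^5$-point grid-search comparison.

On pure noise the maximiser sits at the boundary $g = 1$.  A consequence
worth knowing: at $g=1$ the per-dimension penalty $\log(1+g)$ is weak, so
chance fits can nose ahead of the null model and refined probabilities
hover around 0.5 rather than collapsing to 0 — no-signal data yield an
*uninformative* network, not an empty one.  Thresholding at 0.95 still
passes almost nothing (<10% of candidate edges across the no-signal test
seeds).

## The two data transformations

1. **Time adjustment** subtracts, per gene and time point, the mean across
   replicates.  It exactly removes any trajectory shared by all replicates
   (e.g. the common post-drug transient) since such a component is constant
   across the replicate axis.  Idempotent; output replicate means are 0 to
   machine precision.
2. **Self-detrending** replaces each gene by the residuals of the
   no-intercept regression of the gene on its own lag,
   $\hat\alpha_i = \sum X_{i,t,s}X_{i,t-1,s} / \sum X_{i,t-1,s}^2$ pooled
   over all $S(T-1)$ pairs, dropping one time point.  A gene that is
   identically zero in all lagged positions gets $\hat\alpha = 0$ (with a
   warning), making the residuals equal the input.

The order — adjust first, then detrend the adjusted values — follows the
narrative "first/second" presentation; whether the original analysis
estimated $\hat\alpha$ on raw or adjusted values is not stated, so the
pipeline exposes `transform = {"none", "time", "time+self"}` to test
alternatives.  The two-step pipeline needs $T \ge 3$: detrending consumes
one time point and the lagged design another.

## Evaluation

* **Precision** at a cutoff (default 0.95): true positives over predicted
  edges; `NA` when nothing is predicted.  A missing gold edge counts as a
  false positive even for incomplete gold standards.
* **Partial assessment**: when the gold standard carries an
  evaluable-regulator set (e.g. transcription factors with documented
  targets), edges from other genes are dropped before any metric.
* **AUROC**: Mann-Whitney form over the full evaluable pair universe, with
  average ranks for ties; pairs absent from the edge list score 0.
* **AUPRC**: step curve over descending unique thresholds, tied scores
  grouped, area $= \sum \text{precision} \cdot \Delta\text{recall}$.  Under
  a random ranking this estimator's expectation sits slightly *above* the
  prevalence $P/N$ (Jensen: $E[i/T_i] > i/E[T_i]$ for the negative-
  hypergeometric positions $T_i$), a bias of order $p(1-p)H_P/P$ — about
  0.024 at $N=200$, $P=20$.  The test suite therefore checks the Monte-
  Carlo mean against the exact combinatorial expectation, and only loosely
  against the prevalence itself.
* Self-pairs are excluded from the universe by default (the self-effect is
  removed by detrending and is outside the regression's scope).

## The simulator

`simulate_dataset()` draws (i) a sparse directed network — per-gene
in-degrees geometric with mean 2.76 truncated at $\min(13,\, G-1)$, the
geometric parameter calibrated so the *post-truncation* mean hits the
target; parents uniform without replacement; coefficients $\pm$
`coef_scale` — and (ii) a linear-Gaussian time series matching the
inference model: standard-normal start, then
$X_{i,t,s} = m(t) + \alpha X_{i,t-1,s} + \sum_h \beta_{hi}X_{h,t-1,s} +
\varepsilon$ with $m(t) = A e^{-(t-1)}$ shared by all genes and replicates.
Defaults (10 genes, 21 times, 5 replicates, coefficients $\pm0.8$, self-AR
0.5, noise sd 0.25, amplitude 1) mirror the DREAM4 10-gene shape; the
amplitude default of 1 was chosen once as a transient comparable to the
unit-variance initial condition.

What it does **not** emulate: nonlinear ODE kinetics, saturation,
measurement-noise models, knock-outs, or — importantly — guaranteed
stationarity.  With the default coefficient magnitudes the lag-1 matrix's
spectral radius often slightly exceeds 1, so trajectories grow along a
dominant mode and become increasingly collinear across genes.  The lagged
regression structure remains exactly true (so the simulation remains a
valid generative check), but *which* parent drives a target can become
genuinely unidentifiable late in the series.  This is why green recovery
tests on stationary variants establish correctness of the machinery, while
absolute recovery numbers on the default (super-critical, and often dense:
a mean in-degree of 2.76 on 10 genes is a third of all possible edges)
configuration mainly characterise the difficulty of that world.  Only
numerically exploding draws (values beyond $10^{12}$) are rejected, with
an error advising smaller coefficients; a row-sum stability requirement
would reject essentially every draw at the default coefficients.

Seeding: the network is drawn at `seed`, the series at `seed + 1` (so the
two draws do not share a stream position); everything downstream of fixed
inputs is deterministic, making full runs bit-reproducible.

## Numerical choices

* OLS via the pivoted QR of `lm.fit`; rank-deficient selections fall back
  to the pivoted solution.  $R^2$ clamped to $[0, 1-10^{-12}]$ so
  $\log(1+g(1-R^2))$ stays finite on collinear toys; zero-variance
  responses define $R^2 = 0$ with a warning.
* Models larger than $n-2$ are never scored (the $(n-d-1)$ factor
  degenerates); refinement additions that would breach the guard keep the
  raw probability.
* Model weights via max-shifted softmax of half-scores.
* Scores memoised per candidate subset; the $g$-independent $R^2$ is the
  expensive part and is shared across EM iterations.
* Edge output sorted by probability (desc), then regulator, then target —
  reproducible diffs.

## Limitations

* First-order (lag-1) linear dynamics only; no higher-order autoregression
  or nonlinear effects.
* The refinement clamp coarsens ranks among edges with overwhelming
  evidence (score gaps beyond ≈ 55).
* The EM point estimate of $g$ ignores uncertainty in $g$ (no hyper-$g$
  prior), and on no-signal data its boundary value makes the model scores
  permissive (see above).
* Evaluation treats the gold standard as complete; curated databases are
  not, so reported "false positives" on real data may be undiscovered true
  edges.
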
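---
title: "Modeling protein families with Restricted Boltzmann Machines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling protein families with Restricted Boltzmann Machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmsa)
```

## The model

A protein family is summarized by a multiple sequence alignment (MSA): $B$
homologous sequences over $N$ aligned sites, each site carrying one of
$q = 21$ symbols (20 amino acids plus the alignment gap). `rbmsa` models the
family with a Restricted Boltzmann Machine: a bipartite probabilistic model
coupling the sequence $v = (v_1, \dots, v_N)$ on a visible layer to a
real-valued representation $h = (h_1, \dots, h_M)$ on a hidden layer,

$$P(v, h) \propto \exp\Big(\sum_i g_i(v_i) - \sum_\mu U_\mu(h_\mu)
  + \sum_{i,\mu} h_\mu\, w_{i\mu}(v_i)\Big).$$

The fields $g_i(v)$ bias residue usage per site, the weights $w_{i\mu}(v)$
couple the layers, and the potentials $U_\mu$ shape the hidden units. There
are no couplings inside a layer, so both conditionals factorize: each hidden
unit sees only its input $I_\mu(v) = \sum_i w_{i\mu}(v_i)$ (the score of the
sequence against the unit's position-specific weights), and each site sees
only the softmax field $g_i(v) + \sum_\mu h_\mu w_{i\mu}(v)$. Marginalizing
the hidden layer gives the sequence distribution
$P(v) \propto e^{-E_{\mathrm{eff}}(v)}$ with

$$E_{\mathrm{eff}}(v) = -\sum_i g_i(v_i) - \sum_\mu \Gamma_\mu(I_\mu(v)),
  \qquad \Gamma_\mu(I) = \log \int dh\, e^{-U_\mu(h) + hI}.$$

Non-quadratic $\Gamma_\mu$ generate effective interactions of *all* orders
among sites, all built from the $M \times N \times q$ weights — a compact
route beyond pairwise (direct-coupling) models.

### Hidden-unit potentials

Three potential families are implemented (`hidden_gaussian()`,
`hidden_drelu()`, `hidden_bernoulli()`):

* **Gaussian**, $U(h) = \frac{\gamma}{2}h^2 + \theta h$. The RBM is then
  *exactly* a pairwise Potts (Hopfield-type) model with couplings
  $J_{ij}(a,b) = \sum_\mu w_{i\mu}(a) w_{j\mu}(b)/\gamma_\mu$
  (`pairwise_equivalent()`), so $M$ caps the coupling-matrix rank at
  $\min(M, N(q-1))$ in the zero-sum gauge.
* **dReLU** (double rectified linear), four parameters per unit
  $(\gamma_+, \gamma_-, \theta_+, \theta_-)$ acting separately on the
  positive and negative parts of $h$. It degenerates smoothly to the
  Gaussian ($\gamma_+ = \gamma_-$, $\theta_+ = \theta_-$), to double-well
  (bimodal) units, and to one-sided hard constraints; it is the default and
  typically the best scorer.
* **Bernoulli**, a binary unit with field $b$, kept as the common
  machine-learning baseline.

All dReLU formulas route through the scaled complementary error function
$\Phi(x) = e^{x^2/2}\,\Phi_{\mathcal N}(-x)\sqrt{2\pi}$ (`phi()`). Numerics:
below $x = 5$ it is evaluated through the normal CDF, above through the
asymptotic series in $1/x$, carried to eight terms so that the truncation
error at the branch point stays below the accuracy of the downstream moment
formulas; `log_phi()` works entirely in log space and never overflows
however negative the argument. The conditional $P(h|I)$ of a dReLU unit is a
mixture of two one-sided truncated Gaussians with weights
$p_\pm \propto \Phi(\mp(I-\theta_\pm)/\sqrt{\gamma_\pm})/\sqrt{\gamma_\pm}$;
draws use the inverse CDF in the bulk and switch to an exponential-proposal
rejection sampler when the support excludes the mode by more than four
standard deviations (`sample_truncated_normal()`), so deep-tail clamping is
exact and fast.

### Gauge

Fields and weights carry a per-site redundancy; the package works in the
zero-sum gauge, $\sum_v g_i(v) = 0$, $\sum_v w_{i\mu}(v) = 0$.
`project_zero_sum()` absorbs the removed per-site weight means into the
hidden-potential tilts, so the projection leaves the *joint* distribution
exactly invariant, not just the conditionals; it is reapplied to the weights
after every gradient update because the weight penalty is gauge dependent.

## Data preparation

`read_alignment()` reads aligned FASTA (via Biostrings) or PFAM-dialect
Stockholm; for Stockholm, every column carrying an insert state (lowercase
or `.`) is discarded before coding. `preprocess_alignment()` removes
duplicate sequences (first occurrence wins) and applies an optional
match-column mask for PFAM-style FASTA exports. To tame phylogenetic
redundancy, `compute_sequence_weights()` assigns each sequence the inverse
of the number of sequences (itself included) with strictly more than 90%
identity; identity counts matches over all $N$ columns with the gap treated
as an ordinary 21st symbol (the standard direct-coupling-analysis
convention — the choice matters little at the 90% threshold and is exposed
via `identity_threshold`). All data averages are weighted accordingly
(`weighted_average()`). `train_test_split()` holds out a random 20% for
validation and recomputes weights on the training split only.

## Learning

`fit_rbm()` maximizes the reweighted average log-probability minus two
penalties,

$$\langle \log P(v)\rangle_{MSA} - \frac{\lambda_f}{2}\sum_{i,v} g_i(v)^2
 - \frac{\lambda_{12}}{2qN}\sum_\mu \Big(\sum_{i,v}|w_{i\mu}(v)|\Big)^2,$$

by stochastic gradient ascent. The second penalty is an L2/L1 hybrid: its
gradient is an L1 shrinkage whose strength adapts to each unit's total
weight mass, promoting sparse yet never fully disconnected units; sparsity
is what makes the learned weights interpretable as sequence motifs and
drives the model toward a compositional representation. The gradient of
every parameter is a data-minus-model moment difference; hidden-unit moments
use the analytic conditional expectations given the inputs
(Rao–Blackwellized), never sampled activities. Model moments come from
persistent contrastive divergence: `batch_size` chains are carried across
updates and advanced by `n_mc` alternating-Gibbs sweeps per update. Defaults
follow the standard recipe — minibatch 100 for both data and chains, about
10 sweeps per update, learning rate starting at 0.1 and decaying
exponentially to $10^{-4}$ over the second half of training. Weights are
initialized $N(0, 0.1/N)$ so initial inputs have unit-scale variance, fields
at the independent-site model $g_i(v) = \log f_i(v)$, and dReLU units at the
standardized quadratic point $\gamma_\pm = 1$, $\theta_\pm = 0$.

Additional numerical choices:

* **Dynamic reparametrization** (`dynamic_reparametrize()`): the exact
  rescaling invariance $\gamma \to \lambda^2\gamma$, $w \to \lambda w$,
  $\theta \to \lambda\theta$ and the offset invariance
  $\theta \to \theta + K$, $g_i \to g_i + K w_{i\mu}/\gamma_\mu$ are applied
  every `reparam_every` updates so hidden activities keep mean $\approx 0$
  and variance $\approx 1$ — a batch-normalization-like device that removes
  a flat direction along which the tilts otherwise drift. For dReLU units
  the scaling part is exact and the offset uses the mean curvature, a
  first-order approximation (the exact dReLU offset equations are not
  published); the approximation error is invisible in the enumerable-model
  invariance checks for realistic parameter ranges.
* dReLU curvatures are floored at $10^{-3}$; nothing in the published
  procedure constrains them, and without a floor a large learning rate can
  cross zero.
* $\lambda_f$ defaults to $10^{-4}$ (a weak ridge whose published value is
  never printed); $\lambda_{12}$ defaults to 0.1, the value used for
  contact prediction benchmarks; 0.03 is the held-out-likelihood optimum
  and 0.25 the "interpretable", sparser choice on short domains.
* An exact-enumeration gradient mode (`exact_gradient = TRUE`) replaces the
  chains by a full sum over states; it is only feasible for tiny models and
  is what the package's own validation uses to check PCD-free correctness.
* If any moment turns non-finite the fit aborts and returns the last logged
  checkpoint with a warning rather than NaN parameters.
* Training progress is monitored without partition functions: the history
  records weight norms and gradient scales, plus the per-site
  pseudo-log-likelihood of a monitor set if one is supplied; true
  likelihoods are computed only at checkpoints via AIS.

## Partition functions and likelihoods

`exact_log_z()` enumerates all $q^N$ sequences (capped at $2 \times 10^6$
states) and is the oracle that everything else is tested against.
`ais_log_z()` estimates $\log Z$ for real models by annealed importance
sampling along $P_\beta \propto P_1^\beta P_0^{1-\beta}$ with the linear
grid $\beta_l = l/l_{max}$, one Gibbs sweep per step, and all bookkeeping in
log space. The start point $P_0$ (`fit_base_model()`) is the independent
model closest in KL divergence to the data — log-frequency fields
(pseudocount $10^{-4}$ to avoid infinite fields), zero weights — with hidden
potentials moment-matched to the activity statistics conditioned on the
data; interpolation acts linearly on the weights, the field difference, and
the potential parameters, which realizes the geometric path exactly at both
endpoints. Defaults are 20 chains and $5 \times 10^4$ temperatures. The
estimate combines chains by log-mean-exp (a stochastic lower bound), also
reports the mean-log variant, and attaches a jackknife spread; run with
`direction = "reverse"` from target samples, the estimator upper-bounds
$\log Z$, so the pair brackets the truth. `heldout_log_likelihood()` then
scores validation sequences, the criterion used to select $M$,
$\lambda_{12}$ and the potential family.

## Sampling and sequence design

`gibbs_chain()` is the standard block-Gibbs sampler; all sites update
simultaneously given $h$ (valid by conditional independence, and fully
vectorized via Gumbel-max categorical draws). Two design-oriented
modifications:

* **Conditional sampling**: `clamp` fixes chosen hidden activities; the
  chain then samples exactly $P(v \mid h_\mu = h^*_\mu)$, steering
  generation along interpretable directions (e.g. a ligand-specificity
  unit).
* **Probability boosting**: `duplication = n` replicates the hidden layer
  and the visible fields, making the stationary law $P(v)^n$; $n = 2$ is
  the published trick for sampling high-probability sequences, and the
  implementation generalizes it to any $n \ge 1$, combinable with clamping
  (clamped units keep their value in every replica).

Both modifications are validated against exact enumeration (chi-squared
against $P(v)^2/\sum P^2$ and against the Bayes conditional).

## Contact prediction

For sites $i, j$ and symbols $a, a', b, b'$, the epistasis score

$$\Delta\Delta R_{ij}(v; a, a', b, b') =
  \log\frac{P(v^{a,b})\,P(v^{a',b'})}{P(v^{a',b})\,P(v^{a,b'})}$$

compares a double mutation against its two singles in background $v$; it is
computed purely from effective-energy differences (partition function and
field terms cancel) at $O(M)$ per mutant via input increments. For pairwise
models it is background independent and equals the zero-sum-gauge coupling;
for dReLU models the background dependence is genuine and is averaged over:
`effective_couplings()` returns the reweighted MSA average of the
$q^{-2}$-symbol-averaged score, which per background is just the
double-centered matrix of summed $\Gamma$ values. The full average costs
$O(B N^2 q^2 M)$; backgrounds are therefore subsampled (default at most 500,
drawn proportionally to the sequence weights) — on synthetic families the
subsampling noise is far below the coupling scale. `score_contacts()`
applies the Frobenius norm per site pair (gap included by default, matching
the $q = 21$ model; `exclude_gap` switches it off) and the average product
correction with off-diagonal means; `ppv_curve()` evaluates the ranking
against a reference map after discarding pairs closer than `min_separation`
(default 5) along the backbone.

## The lattice-protein benchmark

Real-family claims are hard to falsify — the truth is unknown. The package
therefore ships an exactly solvable benchmark that doubles as its synthetic
data generator. A 27-mer on the $3^3$ cube admits 103,346 compact
conformations (Hamiltonian walks filling the cube, deduplicated under the
48 cube symmetries; a chain and its reverse are distinct conformations
because contact energies depend on chain direction — the count is
cross-checked on the $2^3$ cube against an independent R enumerator, and
the full enumeration takes about 20 s once, cacheable as plain text). Every
compact fold has exactly 28 contacts. With a symmetric 20x20 contact-energy
table (the bundled transcription of the 1996 Miyazawa–Jernigan statistical
potentials; any table can be substituted), a sequence's fold probability

$$p_{nat}(s) = \frac{e^{-E(s, S_{nat})}}{\sum_{S'} e^{-E(s, S')}}$$

is exactly computable — a ground-truth fitness. `design_msa()` samples
sequences from $p_{nat}^\beta$ by single-site Metropolis moves, annealing
$\beta$ from 5 to 1000 over burn-in, and retains decorrelated samples
(default every 5 sweeps) whose *exactly recomputed* $p_{nat}$ exceeds 0.99.
The working target evaluates the denominator over an adaptive active set of
the 2000 lowest-energy competitors, refreshed every 5 sweeps by an exact
pass — suppressed competitors contribute negligibly in between, and the
retention filter is always exact. $\beta = 1000$ was chosen once as the
value whose equilibrium sits at the retention threshold while keeping
Metropolis acceptance near 10% and mean pairwise Hamming distance around
15/27 — diverse families, not a collapsed cluster. Rapid annealing can
occasionally freeze a chain in a basin just below the threshold; if no
sample has been collected for `reheat_after` sweeps the sampler re-anneals
from $\beta_0$, the standard simulated-annealing restart.

What the generator emulates: a family of strongly stabilized sequences with
known contacts, realistic epistasis (competition between folds induces
negative design), and tunable redundancy. What it does not emulate:
alignment gaps and variable length, phylogenetic correlation structure
(samples are near-independent by construction), profile conservation
gradients of real families, and any functional constraint beyond folding.
Passing the benchmark therefore demonstrates that training, scoring and
contact extraction work; it does not certify biological conclusions on any
particular family.

## Validation problem sizes

The test suite works at sizes where exact oracles exist, chosen as the
smallest instances that still exercise every term: enumerable models
($N = 3, q = 2, M = 2$ dReLU; $N = 4, q = 3, M = 2$ Gaussian) for
quadrature/enumeration equality, finite-difference gradients, Gibbs
stationarity, duplication, clamping, AIS and epistasis scores; a sparse
Gaussian recovery experiment ($N = 15, q = 5, M = 3$, $B = 20{,}000$
sampled sequences) for end-to-end training fidelity (coupling correlation
with truth above 0.9); and the scaled-down lattice benchmark (2,000
designed 27-mers, $M = 50$ dReLU, brief training, contact enrichment
against a 1,000-fold permutation null).

The recovery experiment's truth model uses weight scale 0.5 (couplings of
order one). This is an identifiability requirement, not a convenience:
with couplings a few times stronger the sequence distribution saturates —
we verified that a model with five-fold smaller couplings reproduces the
strong-truth data's connected pair correlations to $r = 0.9996$, so the
data simply carries no information that could separate the two, and *no*
estimator could recover the couplings. At scale 0.5 the generative
sampling is verifiably equilibrated (independent samplings agree on the
correlation matrix to $r = 0.999$) and the couplings are identifiable. The $\lambda_{12}$ cross-validation
sweep is reproduced qualitatively on synthetic data: held-out likelihood
rises from the unregularized fit to an interior optimum and falls to the
independent-model value as $\lambda_{12}$ grows.

## Known limitations

* PCD assumes the chains mix on the training timescale; strongly
  multimodal, weakly regularized models can defeat it. The exact-gradient
  mode exists for verification, not scale.
* The dReLU offset reparametrization is first-order; at extreme tilts the
  compensation leaves a small likelihood-gradient transient (the scaling
  part is exact).
* AIS error bars are jackknife spreads, not guaranteed bounds; the
  forward/reverse bracket is the honest check.
* `effective_couplings()` subsampling trades variance for time; raise
  `subsample` for final tables.
* The bundled contact-energy fixture is a transcription of the published
  1996 table (see the file header); substitute your own via
  `mj_energy_table(path = )` if provenance-critical.
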
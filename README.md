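# rbmsa

Generative modeling of protein families with Restricted Boltzmann Machines
(RBM), for computational biologists who want one model that simultaneously
scores sequences, extracts interpretable sequence motifs, predicts
residue–residue contacts, and designs new sequences.

A family's multiple sequence alignment (B sequences, N sites, q = 21
symbols: 20 amino acids + gap) is modeled by a two-layer distribution
coupling sequences v to real-valued representations h:

    P(v, h) ∝ exp( Σ_i g_i(v_i) − Σ_μ U_μ(h_μ) + Σ_{i,μ} h_μ w_{iμ}(v_i) )

Marginalizing h gives P(v) ∝ exp(−E_eff(v)) with
E_eff(v) = −Σ_i g_i(v_i) − Σ_μ Γ_μ(I_μ(v)), where I_μ(v) = Σ_i w_{iμ}(v_i)
is the input to hidden unit μ and Γ_μ is the cumulant-generating function
of its potential. Hidden units carry Gaussian, Bernoulli, or — the default —
double-rectified-linear (dReLU) potentials, a four-parameter family
(γ₊, γ₋, θ₊, θ₋) spanning quadratic, bimodal and one-sided behaviors; with
Gaussian units the model is exactly a pairwise (Hopfield–Potts) model,
non-quadratic units add interactions of all orders.

The package implements, with exact-oracle test coverage:

* alignment I/O (FASTA/Stockholm), insert-column handling, deduplication,
  and >90%-identity phylogenetic reweighting;
* maximum-likelihood training by persistent contrastive divergence with the
  L2/L1 sparsity penalty, zero-sum gauge, and dynamic reparametrization;
* exact block-Gibbs sampling, conditional (clamped-unit) sampling, and
  probability-boosted sampling via hidden-layer duplication (P(v)^n);
* annealed importance sampling for log-partition functions and held-out
  likelihoods;
* contact prediction from epistatic double-mutation scores ΔΔR, averaged
  into effective couplings, scored by Frobenius norm + average product
  correction, evaluated by positive predictive value;
* an exactly solvable cubic-lattice-protein benchmark (103,346 enumerated
  compact folds of a 27-mer, Miyazawa–Jernigan-style contact energies,
  exact fold probability p_nat) that doubles as the synthetic-data
  generator.

## Worked example: the exactly solvable benchmark

Design a family of lattice 27-mers that fold into one chosen structure with
probability above 0.99, train an RBM on it, and check that the model's top
couplings recover the fold's true contacts:

```r
library(rbmsa)
set.seed(1)

structures <- enumerate_structures(3, cache = "lp3.cache")
#> <lattice_structures> 103346 compact folds of a 27-mer on the 3^3 cube,
#>   28 contacts each

msa <- design_msa(structures, native_index = 1000, n_sequences = 500, seed = 1)
range(attr(msa, "pnat"))
#> [1] 0.9900020 0.9947119

msa <- preprocess_alignment(msa)
w <- compute_sequence_weights(msa)

fit <- fit_rbm(msa, M = 20, variant = "drelu", weights = w,
               config = training_config(n_updates = 1500, lambda_12 = 0.1,
                                        seed = 2))
glance(fit)
#> # A tibble: 1 × 8
#>       N     q     M variant n_parameters mean_weight_norm max_weight_norm n_updates
#>    27    20    20 drelu          11420             12.2            27.4      1500

J <- effective_couplings(fit, msa, weights = w, subsample = 50)
scores <- score_contacts(J)
head(scores, 5)
#> # A tibble: 5 × 4
#>       i     j raw_frobenius apc_score
#>      13    22          3.80      1.92
#>       4     9          3.67      1.57
#>      10    21          3.13      1.40
#>       4    19          3.59      1.30
#>      17    20          2.24      1.20

truth <- lattice_contact_map(structures, 1000)
ppv <- ppv_curve(scores, truth, min_separation = 2)
ppv$ppv[c(5, 10, 20, 28)]
#> [1] 1.0 0.7 0.6 0.5
```

All five top-ranked pairs are true contacts of the native fold; at rank 28
(the number of true contacts) half the predictions are correct from a
500-sequence family after 90 seconds of training — against a null
expectation of about 9% — and accuracy climbs with family size, hidden
units, and training length. `autoplot(scores, truth = truth)` and
`plot_ppv(ppv)` draw the corresponding maps, and `plot_weight_logo(fit, u)`
shows what motif unit `u` has learned.

The same surface drives real families: `read_alignment()` +
`fit_rbm()` + `ais_log_z()`/`heldout_log_likelihood()` for model selection,
`input_distributions()`, `hamming_diagnostics()` and
`export_unit_reports()` for interpretation, `sample_rbm()` with `clamp` and
`duplication` for sequence design. A command-line front end over the same
functions ships at `inst/scripts/rbm-tools.R`
(`train | sample | scan | logz | contacts | report | lp-generate |
lp-enumerate`). The methods vignette
(`vignettes/rbm-protein-families.Rmd`) documents the model, the defaults
and every numerical choice.

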
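# Shared fixtures: tiny seeded models and quadrature oracles.

# dReLU potential energy, used by quadrature oracles
drelu_U <- function(h, gp, gm, tp, tm) {
  0.5 * gp * pmax(h, 0)^2 + 0.5 * gm * pmin(h, 0)^2 +
    tp * pmax(h, 0) + tm * pmin(h, 0)
}

# log int dh exp(-U(h) + h I) by adaptive quadrature
quad_cgf_drelu <- function(I, gp, gm, tp, tm) {
  log(stats::integrate(function(h) exp(-drelu_U(h, gp, gm, tp, tm) + h * I),
                       -Inf, Inf, rel.tol = 1e-12)$value)
}

# conditional moment E[h^k | I] by quadrature
quad_moment_drelu <- function(I, gp, gm, tp, tm, k = 1) {
  den <- stats::integrate(function(h) exp(-drelu_U(h, gp, gm, tp, tm) + h * I),
                          -Inf, Inf, rel.tol = 1e-12)$value
  num <- stats::integrate(function(h) h^k *
                            exp(-drelu_U(h, gp, gm, tp, tm) + h * I),
                          -Inf, Inf, rel.tol = 1e-12)$value
  num / den
}

# a small random dReLU RBM (N=3, q=2, M=2) — enumerable
tiny_drelu_rbm <- function(seed = 11) {
  set.seed(seed)
  g <- matrix(rnorm(6, sd = 0.5), 3, 2)
  w <- array(rnorm(12, sd = 0.7), c(3, 2, 2))
  pot <- hidden_drelu(c(0.8, 1.2), c(1.5, 0.6), c(0.3, -0.2), c(-0.4, 0.1),
                      M = 2)
  rbm(g, w, pot, alphabet = c("A", "B"))
}

# a small random Gaussian RBM (N=4, q=3, M=2) in zero-sum gauge
tiny_gaussian_rbm <- function(seed = 21) {
  set.seed(seed)
  g <- matrix(rnorm(12, sd = 0.4), 4, 3)
  w <- array(rnorm(24, sd = 0.6), c(4, 3, 2))
  project_zero_sum(rbm(g, w, hidden_gaussian(c(0.9, 1.6), c(0.4, -0.3), M = 2),
                       alphabet = c("A", "B", "C")))
}

# exact probabilities of an enumerable model
exact_probs <- function(params) {
  states <- enumerate_sequences(params$N, params$q)
  e <- effective_energy(params, states)
  p <- exp(-(e - min(e)))
  list(states = states, p = p / sum(p),
       key = apply(states, 1L, paste, collapse = ""))
}

# build an alignment object directly from a code matrix
codes_alignment <- function(codes, alphabet) {
  structure(list(codes = codes, ids = as.character(seq_len(nrow(codes))),
                 alphabet = alphabet),
            class = "rbm_alignment")
}

# empirical state distribution of sampled codes vs exact probabilities
chisq_vs_exact <- function(codes, ex) {
  obs <- table(factor(apply(codes, 1L, paste, collapse = ""), levels = ex$key))
  suppressWarnings(stats::chisq.test(as.vector(obs), p = ex$p)$p.value)
}
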
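#' Enumerate all sequences of a small model
#'
#' All `q^N` integer-coded sequences, used by exact partition functions and
#' validation oracles. Refuses when `q^N` exceeds `cap`.
#'
#' @param N,q Sequence length and alphabet size.
#' @param cap Maximum number of states (default 2e6).
#' @return `q^N x N` integer matrix.
#' @export
enumerate_sequences <- function(N, q, cap = 2e6) {
  n_states <- q^N
  stop_if_not(n_states <= cap,
              paste0("q^N = ", format(n_states), " exceeds the enumeration cap (",
                     format(cap), "); use ais_log_z() instead"))
  as.matrix(rev(expand.grid(rev(lapply(seq_len(N), function(i) seq_len(q))))))
}

#' Exact log partition function by enumeration
#'
#' \eqn{\log Z = \log \sum_v e^{-E_{\mathrm{eff}}(v)}} with stable
#' log-sum-exp, feasible only when `q^N` is small.
#'
#' @param params An [rbm].
#' @param cap Enumeration cap (states); exceeding it is an error directing
#'   the caller to [ais_log_z()].
#' @return Scalar natural-log partition function.
#' @export
exact_log_z <- function(params, cap = 2e6) {
  states <- enumerate_sequences(params$N, params$q, cap)
  dimnames(states) <- NULL
  logsumexp(-effective_energy(params, states))
}

# closed-form log Z of a factorized model (zero weights)
factorized_log_z <- function(params) {
  sum(apply(params$g, 1L, logsumexp)) +
    sum(cgf(params$pot, rep(0, params$M)))
}

#' Closest independent base model for annealing
#'
#' Builds the annealing start point \eqn{P_0}: zero weights, visible fields
#' equal to the (reweighted, pseudocount-smoothed) log site frequencies —
#' the independent model closest in KL divergence to the data distribution —
#' and hidden potentials moment-matched to the statistics of the hidden
#' activities conditioned on the data under the trained model (quadratic
#' parameters reproducing the mean and total variance of `h | data`; for
#' Bernoulli, the mean activation).
#'
#' @param aln Training alignment.
#' @param params The trained [rbm].
#' @param weights Sequence weights.
#' @param pseudocount Relative pseudocount for the base fields (avoids
#'   infinite fields at unseen symbols).
#' @return An [rbm] with zero weights, same variant, plus attribute
#'   `"log_z"` holding its exact (factorized) log partition function.
#' @export
fit_base_model <- function(aln, params, weights = NULL, pseudocount = 1e-4) {
  stop_if_not(nrow(aln$codes) > 0L, "empty data")
  f <- site_frequencies(aln, weights, pseudocount)
  g0 <- log(f)
  I <- compute_inputs(params, aln$codes)
  mom <- hidden_moments(params$pot, I)
  w <- weights %||% rep(1, nrow(aln$codes))
  wn <- w / sum(w)
  m <- colSums(mom$h * wn)
  v_tot <- pmax(colSums(mom$h2 * wn) - m^2, 1e-6)
  gam0 <- 1 / v_tot
  th0 <- -m * gam0
  pot0 <- switch(params$pot$variant,
    gaussian = hidden_gaussian(gam0, th0, M = params$M),
    drelu = hidden_drelu(gam0, gam0, th0, th0, M = params$M),
    bernoulli = hidden_bernoulli(stats::qlogis(pmin(pmax(m, 1e-6), 1 - 1e-6)),
                                 M = params$M))
  base <- rbm(g0, array(0, dim(params$w)), pot0, params$alphabet)
  attr(base, "log_z") <- factorized_log_z(base)
  base
}

#' AIS configuration
#'
#' @param n_chains Number of annealing chains `C` (default 20).
#' @param n_steps Number of interpolating inverse temperatures (default
#'   5e4); one Gibbs sweep is performed per step.
#' @param seed Integer seed.
#' @return List of class `ais_config`.
#' @export
ais_config <- function(n_chains = 20L, n_steps = 5e4, seed = 1L) {
  stop_if_not(n_chains >= 1L && n_steps >= 1L, "invalid AIS configuration")
  structure(list(n_chains = as.integer(n_chains),
                 n_steps = as.integer(n_steps), seed = seed),
            class = "ais_config")
}

# parameters of the interpolating model at inverse temperature beta:
# w_beta = beta * w (base weights are zero), fields and potential parameters
# interpolated linearly, realizing P_beta \propto P_1^beta P_0^(1-beta)
interp_params <- function(params, base, beta) {
  out <- params
  out$w <- beta * params$w
  out$g <- (1 - beta) * base$g + beta * params$g
  for (nm in setdiff(names(params$pot), c("variant", "M"))) {
    out$pot[[nm]] <- (1 - beta) * base$pot[[nm]] + beta * params$pot[[nm]]
  }
  out
}

# -Eeff under the interpolated model, given precomputed full-weight inputs
# (I_beta = beta * I_full) and the two field sums
neg_energy_beta <- function(params, base, beta, I_full, f0, f1) {
  pot_b <- params$pot
  for (nm in setdiff(names(pot_b), c("variant", "M"))) {
    pot_b[[nm]] <- (1 - beta) * base$pot[[nm]] + beta * params$pot[[nm]]
  }
  (1 - beta) * f0 + beta * f1 + rowSums(cgf(pot_b, beta * I_full))
}

#' Annealed importance sampling estimate of log Z
#'
#' Estimates \eqn{\log Z_1} of a trained model by annealing `C` chains from
#' the factorized base model \eqn{P_0} (see [fit_base_model()]) to the
#' target \eqn{P_1} along the path
#' \eqn{P_\beta \propto P_1^\beta P_0^{1-\beta}} with the linear temperature
#' grid \eqn{\beta_l = l/l_{max}}, accumulating per-chain log importance
#' increments; all bookkeeping is in log scale. The combined estimate is the
#' log-mean-exp over chains; the mean of the per-chain log weights (the
#' small-variance approximation) and a jackknife standard error across
#' chains are also reported. Deterministic under `cfg$seed`.
#'
#' With `direction = "reverse"` the chains start from supplied samples of
#' \eqn{P_1} (`init_v`) and anneal backwards; the resulting estimator
#' stochastically upper-bounds \eqn{\log Z_1}, so the forward/reverse pair
#' brackets the truth.
#'
#' @param params Trained [rbm].
#' @param base Base model from [fit_base_model()] (must be factorized, with
#'   attribute `"log_z"`).
#' @param cfg An [ais_config()].
#' @param direction `"forward"` (default) or `"reverse"`.
#' @param init_v Required for the reverse direction: `C x N` codes
#'   distributed according to the target.
#' @return A list of class `logz_estimate`: `value` (log-mean-exp
#'   combination), `value_avg` (mean of per-chain log weights), `stderr`
#'   (jackknife over chains), `log_weights`, `method`.
#' @export
ais_log_z <- function(params, base, cfg = ais_config(),
                      direction = c("forward", "reverse"), init_v = NULL) {
  direction <- match.arg(direction)
  stop_if_not(all(base$w == 0), "base model must be factorized (zero weights)")
  log_z0 <- attr(base, "log_z") %||% factorized_log_z(base)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  C <- cfg$n_chains; lmax <- cfg$n_steps
  betas <- seq_len(lmax) / lmax
  if (direction == "forward") {
    v <- sample_visible(base, matrix(0, C, params$M))
    # base conditionals do not depend on h when w = 0, but hidden draws keep
    # the chain definition uniform
    path <- betas
  } else {
    stop_if_not(!is.null(init_v), "reverse AIS needs init_v samples from P1")
    v <- as_code_matrix(init_v, params$N)
    C <- nrow(v)
    path <- rev(c(0, betas[-lmax]))
  }
  f0 <- field_sum(base, v); f1 <- field_sum(params, v)
  I_full <- compute_inputs(params, v)
  prev_beta <- if (direction == "forward") 0 else 1
  logw <- rep(0, C)
  for (b in path) {
    ne_prev <- neg_energy_beta(params, base, prev_beta, I_full, f0, f1)
    ne_new <- neg_energy_beta(params, base, b, I_full, f0, f1)
    inc <- ne_new - ne_prev
    if (!all(is.finite(inc))) {
      stop("non-finite AIS increment at beta = ", format(b), call. = FALSE)
    }
    logw <- logw + inc
    # one Gibbs sweep at the new temperature
    pb <- interp_params(params, base, b)
    h <- sample_hidden_conditional(pb$pot, b * I_full)
    v <- sample_visible(pb, h)
    f0 <- field_sum(base, v); f1 <- field_sum(params, v)
    I_full <- compute_inputs(params, v)
    prev_beta <- b
  }
  if (direction == "forward") {
    # log Z1 = log Z0 + log E_{P0-path}[e^w]; stochastic lower bound by Jensen
    value <- log_z0 + logmeanexp(logw)
    jack <- log_z0 + vapply(seq_len(C), function(k) logmeanexp(logw[-k]),
                            numeric(1))
  } else {
    # accumulated weights estimate log(Z0/Z1); stochastic upper bound for Z1
    value <- log_z0 - logmeanexp(logw)
    jack <- log_z0 - vapply(seq_len(C), function(k) logmeanexp(logw[-k]),
                            numeric(1))
    logw <- -logw
  }
  value_avg <- log_z0 + mean(logw)
  stderr <- sqrt((C - 1) / C * sum((jack - mean(jack))^2))
  structure(list(value = value, value_avg = value_avg, stderr = stderr,
                 log_weights = logw, log_z_base = log_z0,
                 method = paste0("ais_", direction),
                 n_chains = C, n_steps = lmax),
            class = "logz_estimate")
}

#' @export
print.logz_estimate <- function(x, ...) {
  cat("<logz_estimate>", x$method, ": log Z =", format(x$value),
      "+/-", format(x$stderr), "(", x$n_chains, "chains,", x$n_steps,
      "steps )\n")
  invisible(x)
}

#' Average log-probability of held-out sequences
#'
#' \eqn{\langle -E_{\mathrm{eff}}(v) \rangle_{test} - \log Z}; the standard
#' cross-validation score for comparing hidden-unit numbers, potentials and
#' regularization strengths.
#'
#' @param params An [rbm].
#' @param test Held-out alignment (same sites and alphabet).
#' @param weights Test-sequence weights (default uniform).
#' @param log_z Log partition function: a number or a `logz_estimate`.
#' @return Scalar average log-probability.
#' @export
heldout_log_likelihood <- function(params, test, weights = NULL, log_z) {
  stop_if_not(ncol(test$codes) == params$N, "test alignment width != model N")
  if (inherits(log_z, "logz_estimate")) log_z <- log_z$value
  w <- weights %||% rep(1, nrow(test$codes))
  weighted_average(-effective_energy(params, test$codes), w) - log_z
}
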
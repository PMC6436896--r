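#' Sample the hidden layer given sequences
#'
#' Hidden units are conditionally independent given the visible layer; each
#' is drawn from its exact conditional (Gaussian, truncated-Gaussian mixture
#' for dReLU, or Bernoulli) at input \eqn{I_\mu(v)}.
#'
#' @param params An [rbm].
#' @param v Codes vector (length `N`) or matrix (`B x N`).
#' @return `B x M` matrix of hidden activities.
#' @export
sample_hidden <- function(params, v) {
  I <- compute_inputs(params, v)
  sample_hidden_conditional(params$pot, I)
}

#' Sample the visible layer given hidden activities
#'
#' Sites are conditionally independent given `h`; site `i` is drawn from the
#' categorical distribution
#' \eqn{P(v_i | h) \propto \exp(g_i(v_i) + \sum_\mu h_\mu w_{i\mu}(v_i))}.
#' Sampling uses the Gumbel-max trick so all sites of all chains are drawn
#' in one vectorized pass.
#'
#' @param params An [rbm].
#' @param h Hidden activities, `B x M` matrix (or length-`M` vector).
#' @return `B x N` integer code matrix.
#' @export
sample_visible <- function(params, h) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1L)
  stop_if_not(all(is.finite(h)), "hidden activities must be finite")
  logits <- visible_logits(params, h)
  sample_categorical_logits(logits, nrow(h), params$N, params$q)
}

# B x (N*q) matrix of per-site symbol logits given hidden activities
# (field_scale multiplies the field term; used by duplicated sampling)
visible_logits <- function(params, h, field_scale = 1) {
  h %*% t(weight_matrix(params)) +
    matrix(field_scale * as.vector(params$g), nrow(h), params$N * params$q,
           byrow = TRUE)
}

sample_categorical_logits <- function(logits, B, N, q) {
  z <- logits + rgumbel(length(logits))
  dim(z) <- c(B * N, q)
  matrix(max.col(z, ties.method = "first"), B, N)
}

#' Alternating Gibbs sampler over sequences
#'
#' Runs the standard block-Gibbs chain of the bipartite model: sample all
#' hidden units given `v`, then all sites given `h`, repeatedly. Supports
#' two modifications used for sequence design:
#' * **clamping** (`clamp`): selected hidden units are never resampled;
#'   their fixed activities enter every visible update, so the chain samples
#'   the conditional \eqn{P(v | h_\mu = h^*_\mu)};
#' * **duplication** (`duplication = n`): the hidden layer (and the visible
#'   fields) are replicated `n` times, making the stationary law
#'   \eqn{\propto P(v)^n} and thereby boosting high-probability sequences.
#'   Clamped units keep their fixed value in every replica.
#'
#' Several chains run in parallel: `init_v` may be a `B x N` matrix.
#'
#' @param params An [rbm].
#' @param init_v Initial codes, vector or `B x N` matrix.
#' @param n_steps Number of full hidden/visible sweeps (>= 1).
#' @param clamp Optional named numeric vector: names are hidden-unit
#'   indices, values the clamped activities.
#' @param duplication Integer >= 1; stationary law is \eqn{P(v)^n}.
#' @param record_every Record the visible state every this many sweeps.
#' @return Array `n_records x B x N` of recorded codes, with the final
#'   hidden sample of the first replica attached as attribute `"h"`.
#' @export
gibbs_chain <- function(params, init_v, n_steps, clamp = NULL,
                        duplication = 1L, record_every = 1L) {
  stop_if_not(n_steps >= 1L, "n_steps must be >= 1")
  stop_if_not(duplication >= 1L, "duplication must be >= 1")
  v <- as_code_matrix(init_v, params$N)
  B <- nrow(v)
  clamp_idx <- integer(0)
  if (!is.null(clamp)) {
    clamp_idx <- as.integer(names(clamp))
    stop_if_not(length(clamp_idx) > 0L && !anyNA(clamp_idx),
                "clamp must be a named vector (names = unit indices)")
    stop_if_not(all(clamp_idx >= 1L & clamp_idx <= params$M),
                "clamp unit index out of range")
  }
  n_rec <- n_steps %/% record_every
  out <- array(NA_integer_, c(n_rec, B, params$N))
  rec <- 0L
  h <- NULL
  for (step in seq_len(n_steps)) {
    Hsum <- matrix(0, B, params$M)
    for (k in seq_len(duplication)) {
      I <- compute_inputs(params, v)
      h <- sample_hidden_conditional(params$pot, I)
      if (length(clamp_idx)) {
        h[, clamp_idx] <- matrix(clamp, B, length(clamp_idx), byrow = TRUE)
      }
      Hsum <- Hsum + h
    }
    logits <- visible_logits(params, Hsum, field_scale = duplication)
    v <- sample_categorical_logits(logits, B, params$N, params$q)
    if (step %% record_every == 0L) {
      rec <- rec + 1L
      out[rec, , ] <- v
    }
  }
  attr(out, "h") <- h
  out
}

#' Draw approximately independent sequences from the model
#'
#' Convenience wrapper: runs `n_sequences` parallel Gibbs chains
#' initialized at random field-level sequences (or at supplied seeds),
#' discards `burnin` sweeps, and returns the final visible states as an
#' alignment.
#'
#' @param params An [rbm].
#' @param n_sequences Number of sequences to return.
#' @param burnin Gibbs sweeps before recording (default 100).
#' @param init Optional `n_sequences x N` matrix of starting codes.
#' @inheritParams gibbs_chain
#' @return An `rbm_alignment` of sampled sequences.
#' @export
sample_rbm <- function(params, n_sequences, burnin = 100L, clamp = NULL,
                       duplication = 1L, init = NULL) {
  if (is.null(init)) {
    h0 <- matrix(0, n_sequences, params$M)
    init <- sample_visible(params, h0)
  }
  traj <- gibbs_chain(params, init, n_steps = burnin, clamp = clamp,
                      duplication = duplication, record_every = burnin)
  codes <- matrix(traj[dim(traj)[1], , ], n_sequences, params$N)
  new_alignment(codes, sprintf("sample_%d", seq_len(n_sequences)),
                params$alphabet)
}
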
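#' Training configuration
#'
#' Hyperparameters for persistent-contrastive-divergence stochastic gradient
#' ascent. Defaults follow the standard recipe for protein-family RBMs:
#' minibatches of 100 sequences for both the data and the persistent chains,
#' about 10 Gibbs sweeps per update, learning rate 0.1 decaying
#' exponentially to 1e-4 over the second half of training.
#'
#' @param n_updates Number of parameter updates.
#' @param batch_size Minibatch size for data and chains (default 100).
#' @param n_mc Gibbs sweeps of the persistent chains per update (default 10).
#' @param lr_init,lr_final Initial and final learning rates (0.1, 1e-4).
#' @param decay_start_fraction Fraction of training after which the learning
#'   rate starts its exponential decay (default 0.5; flat before).
#' @param lambda_f L2 penalty strength on the visible fields (default 1e-4).
#' @param lambda_12 Strength of the combined L2/L1 weight penalty
#'   \eqn{\frac{\lambda_{12}}{2qN}\sum_\mu (\sum_{i,v} |w_{i\mu}(v)|)^2}
#'   (default 0.1).
#' @param seed Integer seed; training is deterministic given it.
#' @param exact_gradient Use exact enumeration for the model moments instead
#'   of PCD (only feasible for tiny `q^N`; used by validation code).
#' @param reparam_every Dynamic-reparametrization interval in updates
#'   (0 disables).
#' @param log_every Interval for recording training metrics.
#' @param curvature_floor Lower bound kept on hidden curvatures.
#' @return A list of class `rbm_training_config`.
#' @export
training_config <- function(n_updates = 5000L, batch_size = 100L, n_mc = 10L,
                            lr_init = 0.1, lr_final = 1e-4,
                            decay_start_fraction = 0.5,
                            lambda_f = 1e-4, lambda_12 = 0.1, seed = 1L,
                            exact_gradient = FALSE, reparam_every = 100L,
                            log_every = 250L, curvature_floor = 1e-3) {
  stop_if_not(lr_init > 0 && lr_final > 0, "learning rates must be positive")
  stop_if_not(lambda_f >= 0 && lambda_12 >= 0, "penalties must be >= 0")
  structure(as.list(environment()), class = "rbm_training_config")
}

# learning rate at update t (1-based) out of n: flat, then exponential decay
# from lr_init to lr_final
lr_schedule <- function(cfg, t) {
  n <- cfg$n_updates
  t0 <- ceiling(cfg$decay_start_fraction * n)
  if (t <= t0 || n == t0) return(cfg$lr_init)
  frac <- (t - t0) / (n - t0)
  cfg$lr_init * (cfg$lr_final / cfg$lr_init)^frac
}

#' Regularized training objective
#'
#' The reweighted average log-probability of the data minus the penalties:
#' \deqn{\langle \log P(v) \rangle_{MSA} - \frac{\lambda_f}{2}\sum_{i,v}
#'  g_i(v)^2 - \frac{\lambda_{12}}{2qN}\sum_\mu\Big(\sum_{i,v}
#'  |w_{i\mu}(v)|\Big)^2.}
#' Needs the log partition function; supply an exact value
#' ([exact_log_z()]) or an AIS estimate ([ais_log_z()]).
#'
#' @param params An [rbm].
#' @param aln Data alignment.
#' @param weights Sequence weights (default uniform).
#' @param log_z Log partition function of `params`.
#' @param lambda_f,lambda_12 Penalty strengths.
#' @return Scalar objective value.
#' @export
objective <- function(params, aln, weights = NULL, log_z,
                      lambda_f = 0, lambda_12 = 0) {
  w <- weights %||% rep(1, nrow(aln$codes))
  ll <- weighted_average(-effective_energy(params, aln$codes), w) - log_z
  Wm <- weight_matrix(params)
  ll - lambda_f / 2 * sum(params$g^2) -
    lambda_12 / (2 * params$q * params$N) * sum(colSums(abs(Wm))^2)
}

# Data-side (or model-side) moments of the log-likelihood gradient:
#   g-block: site-symbol frequencies
#   w-block: <E[h|I] * one-hot(v)>
#   potential block: averages of the conditional moments
# All averages use `wts` (normalized internally).
moment_set <- function(params, codes, wts = NULL) {
  B <- nrow(codes)
  wts <- wts %||% rep(1, B)
  wn <- wts / sum(wts)
  I <- compute_inputs(params, codes)
  mom <- hidden_moments(params$pot, I)
  N <- params$N; q <- params$q; M <- params$M
  f <- matrix(0, N, q)
  Tw <- array(0, c(N, q, M))
  mh_w <- mom$h * wn  # rows weighted
  for (i in seq_len(N)) {
    fs <- rowsum(wn, group = codes[, i])   # rows named by observed codes
    present <- as.integer(rownames(fs))
    f[i, present] <- fs
    Tw[i, present, ] <- rowsum(mh_w, group = codes[, i])
  }
  pot_mom <- lapply(mom, function(x) colSums(x * wn))
  list(f = f, Tw = Tw, pot = pot_mom)
}

# exact model moments by enumeration (tiny models only)
exact_model_moments <- function(params, cap = 2e6) {
  states <- enumerate_sequences(params$N, params$q, cap)
  e <- effective_energy(params, states)
  p <- exp(-(e - min(e)))
  moment_set(params, states, p)
}

#' Log-likelihood gradient with moment matching
#'
#' The gradient of the (regularized) average log-probability with respect to
#' every parameter is the difference between data-side and model-side
#' averages of the energy derivatives, minus the penalty gradients. Hidden
#' moments use the analytic conditional expectations given the inputs
#' (Rao–Blackwellized), never sampled activities. The L2/L1 weight-penalty
#' gradient is \eqn{\lambda_{12}(\sum_{i,v'}|w_{i\mu}(v')|/qN)\,
#' \mathrm{sign}(w_{i\mu}(v))} with `sign(0) = 0`.
#'
#' @param params An [rbm].
#' @param data_codes Minibatch code matrix.
#' @param data_weights Minibatch sequence weights (default uniform).
#' @param model_codes Chain code matrix (PCD samples), or `NULL` to use
#'   exact enumeration of the model distribution.
#' @param lambda_f,lambda_12 Penalty strengths.
#' @return List with blocks `g` (`N x q`), `w` (`N x q x M`) and `pot`
#'   (named per-parameter vectors of length `M`).
#' @export
rbm_gradient <- function(params, data_codes, data_weights = NULL,
                         model_codes = NULL, lambda_f = 0, lambda_12 = 0) {
  dat <- moment_set(params, data_codes, data_weights)
  mod <- if (is.null(model_codes)) exact_model_moments(params)
         else moment_set(params, model_codes)
  grad_g <- dat$f - mod$f - lambda_f * params$g
  Wm <- weight_matrix(params)
  reg_w <- array(matrix(sign(Wm), params$N * params$q, params$M) *
                   rep(colSums(abs(Wm)) / (params$q * params$N),
                       each = params$N * params$q),
                 c(params$N, params$q, params$M))
  grad_w <- dat$Tw - mod$Tw - lambda_12 * reg_w
  grad_pot <- switch(params$pot$variant,
    gaussian = list(
      theta = -(dat$pot$h - mod$pot$h),
      gamma = -0.5 * (dat$pot$h2 - mod$pot$h2)),
    bernoulli = list(b = dat$pot$h - mod$pot$h),
    drelu = list(
      theta_plus = -(dat$pot$hp - mod$pot$hp),
      theta_minus = -(dat$pot$hm - mod$pot$hm),
      gamma_plus = -0.5 * (dat$pot$hp2 - mod$pot$hp2),
      gamma_minus = -0.5 * (dat$pot$hm2 - mod$pot$hm2)))
  bad <- !all(is.finite(grad_g)) || !all(is.finite(grad_w)) ||
    !all(vapply(grad_pot, function(x) all(is.finite(x)), logical(1)))
  if (bad) {
    stop("non-finite gradient moment encountered (max |w| = ",
         format(max(abs(params$w))), ", max |I_data| = ",
         format(max(abs(compute_inputs(params, data_codes)))), ")",
         call. = FALSE)
  }
  list(g = grad_g, w = grad_w, pot = grad_pot)
}

#' Rescale hidden units so activities stay standardized
#'
#' For Gaussian (and, by extension, dReLU) potentials there is an exact
#' invariance \eqn{\gamma \to \lambda^2\gamma, w \to \lambda w, \theta \to
#' \lambda\theta} under which the model distribution is unchanged while the
#' hidden activity is rescaled \eqn{h \to h/\lambda}, and an offset
#' transformation \eqn{\theta \to \theta + K} compensated by a field shift
#' \eqn{g_i(v) \to g_i(v) + K w_{i\mu}(v)/\gamma_\mu}. Given running
#' estimates of the per-unit mean and variance of `h`, this applies both so
#' that \eqn{\langle h_\mu\rangle \approx 0} and
#' \eqn{\mathrm{Var}(h_\mu) \approx 1} — a batch-normalization-like device
#' that keeps learning stable at high rates. For dReLU units the scaling is
#' exact and the offset uses the mean curvature \eqn{(\gamma_+ +
#' \gamma_-)/2}, an approximation that leaves \eqn{P(v)} unchanged only to
#' first order; for Bernoulli units this is a no-op. Units whose variance
#' estimate is below `1e-8` are skipped with a warning.
#'
#' @param params An [rbm].
#' @param h_mean,h_var Per-unit running mean and variance of the hidden
#'   activities.
#' @return The reparametrized [rbm].
#' @export
dynamic_reparametrize <- function(params, h_mean, h_var) {
  if (params$pot$variant == "bernoulli") return(params)
  degenerate <- !(h_var > 1e-8)
  if (any(degenerate)) {
    warning("skipping reparametrization of ", sum(degenerate),
            " unit(s) with vanishing activity variance")
    h_var[degenerate] <- 1
    h_mean[degenerate] <- 0
  }
  lam <- sqrt(h_var)
  params$w <- sweep(params$w, 3L, lam, `*`)
  if (params$pot$variant == "gaussian") {
    params$pot$gamma <- params$pot$gamma * lam^2
    params$pot$theta <- params$pot$theta * lam
    gam_eff <- params$pot$gamma
  } else {
    params$pot$gamma_plus <- params$pot$gamma_plus * lam^2
    params$pot$gamma_minus <- params$pot$gamma_minus * lam^2
    params$pot$theta_plus <- params$pot$theta_plus * lam
    params$pot$theta_minus <- params$pot$theta_minus * lam
    gam_eff <- (params$pot$gamma_plus + params$pot$gamma_minus) / 2
  }
  # after scaling, h has mean h_mean / lam; shift it to zero
  K <- (h_mean / lam) * gam_eff
  if (params$pot$variant == "gaussian") {
    params$pot$theta <- params$pot$theta + K
  } else {
    params$pot$theta_plus <- params$pot$theta_plus + K
    params$pot$theta_minus <- params$pot$theta_minus + K
  }
  Wm <- weight_matrix(params)
  params$g <- params$g + matrix(rowSums(sweep(Wm, 2L, K / gam_eff, `*`)),
                                params$N, params$q)
  params
}

#' Fit an RBM to an alignment
#'
#' Maximizes the reweighted, regularized average log-probability by
#' stochastic gradient ascent. Model moments come from persistent
#' contrastive divergence: `batch_size` Markov chains are carried across
#' updates and advanced by `n_mc` Gibbs sweeps per update (or, with
#' `exact_gradient = TRUE`, from exact enumeration — only for tiny models).
#' Weights are re-projected onto the zero-sum gauge after every update;
#' dReLU curvatures are floored at `curvature_floor`. If parameters turn
#' non-finite the fit aborts and returns the last stable checkpoint with a
#' warning. Deterministic under `config$seed`.
#'
#' @param aln Preprocessed training alignment.
#' @param M Number of hidden units.
#' @param variant Hidden-potential family.
#' @param config A [training_config()].
#' @param weights Sequence weights; computed at the 90% identity threshold
#'   when `NULL`.
#' @param monitor Optional alignment whose per-site pseudo-log-likelihood is
#'   tracked at each logging step.
#' @return An object of classes `rbm_fit` and [rbm], with elements
#'   `history` (tibble of training metrics) and `config` in addition to the
#'   model parameters.
#' @export
fit_rbm <- function(aln, M, variant = c("drelu", "gaussian", "bernoulli"),
                    config = training_config(), weights = NULL,
                    monitor = NULL) {
  variant <- match.arg(variant)
  set.seed(config$seed)
  if (is.null(weights)) weights <- compute_sequence_weights(aln)
  params <- init_rbm(aln, M, variant, weights)
  B <- nrow(aln$codes)
  prob <- weights / sum(weights)
  chains <- aln$codes[sample.int(B, config$batch_size, replace = TRUE,
                                 prob = prob), , drop = FALSE]
  hist_rows <- list()
  checkpoint <- params
  run_mean <- rep(0, M); run_var <- rep(1, M); seen <- FALSE
  for (t in seq_len(config$n_updates)) {
    lr <- lr_schedule(config, t)
    mb <- sample.int(B, min(config$batch_size, B), replace = TRUE, prob = prob)
    grad <- tryCatch({
      if (config$exact_gradient) {
        rbm_gradient(params, aln$codes[mb, , drop = FALSE],
                     model_codes = NULL,
                     lambda_f = config$lambda_f, lambda_12 = config$lambda_12)
      } else {
        traj <- gibbs_chain(params, chains, n_steps = config$n_mc,
                            record_every = config$n_mc)
        chains <- matrix(traj[1, , ], nrow(chains), params$N)
        rbm_gradient(params, aln$codes[mb, , drop = FALSE],
                     model_codes = chains,
                     lambda_f = config$lambda_f, lambda_12 = config$lambda_12)
      }
    }, error = function(e) e)
    if (inherits(grad, "error")) {
      warning("training aborted at update ", t, " (", conditionMessage(grad),
              "); returning last stable checkpoint")
      params <- checkpoint
      break
    }
    params$g <- params$g + lr * grad$g
    params$w <- params$w + lr * grad$w
    for (nm in names(grad$pot)) {
      upd <- params$pot[[nm]] + lr * grad$pot[[nm]]
      if (startsWith(nm, "gamma")) upd <- pmax(upd, config$curvature_floor)
      params$pot[[nm]] <- upd
    }
    params <- project_zero_sum(params, fields = FALSE)
    # running hidden statistics for reparametrization (chain samples under
    # PCD; the data minibatch in exact-gradient mode)
    if (config$reparam_every > 0) {
      stats_codes <- if (config$exact_gradient) {
        aln$codes[mb, , drop = FALSE]
      } else {
        chains
      }
      I <- compute_inputs(params, stats_codes)
      mom <- hidden_moments(params$pot, I)
      bm <- colMeans(mom$h)
      # law of total variance: mean conditional variance + variance of means
      bv <- colMeans(mom$h2 - mom$h^2) + apply(mom$h, 2L, stats::var)
      run_mean <- if (seen) 0.8 * run_mean + 0.2 * bm else bm
      run_var <- if (seen) 0.8 * run_var + 0.2 * pmax(bv, 1e-10) else
        pmax(bv, 1e-10)
      seen <- TRUE
      if (t %% config$reparam_every == 0L) {
        params <- dynamic_reparametrize(params, run_mean, run_var)
        run_mean <- rep(0, M); run_var <- rep(1, M); seen <- FALSE
      }
    }
    if (t %% config$log_every == 0L || t == config$n_updates) {
      checkpoint <- params
      row <- tibble::tibble(
        update = t, lr = lr,
        mean_weight_norm = mean(weight_norms(params)),
        grad_w_rms = sqrt(mean(grad$w^2)))
      if (!is.null(monitor)) {
        row$monitor_psl <- pseudo_log_likelihood(params, monitor)
      }
      hist_rows[[length(hist_rows) + 1L]] <- row
    }
  }
  params <- project_zero_sum(params, fields = TRUE)
  params$history <- dplyr::bind_rows(hist_rows)
  params$config <- config
  class(params) <- c("rbm_fit", "rbm")
  params
}

#' Per-site pseudo-log-likelihood
#'
#' \eqn{\frac{1}{N}\sum_i \log P(v_i | v_{\setminus i})}, averaged over the
#' sequences: a partition-function-free likelihood proxy used to monitor
#' training (true likelihoods require [ais_log_z()]).
#'
#' @param params An [rbm].
#' @param aln Alignment to score.
#' @param weights Optional sequence weights.
#' @return Scalar average per-site pseudo-log-likelihood.
#' @export
pseudo_log_likelihood <- function(params, aln, weights = NULL) {
  codes <- aln$codes
  B <- nrow(codes); N <- params$N; q <- params$q
  e0 <- effective_energy(params, codes)
  psl <- numeric(B)
  for (i in seq_len(N)) {
    em <- matrix(0, B, q)
    for (a in seq_len(q)) {
      vv <- codes
      vv[, i] <- a
      em[, a] <- effective_energy(params, vv)
    }
    psl <- psl + (-e0 - row_logsumexp(-em))
  }
  w <- weights %||% rep(1, B)
  weighted_average(psl / N, w)
}
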
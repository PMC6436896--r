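test_that("the objective implements the penalized average log-probability", {
  m <- tiny_drelu_rbm()
  ex <- exact_probs(m)
  set.seed(41)
  codes <- ex$states[sample.int(8, 30, replace = TRUE), ]
  aln <- codes_alignment(codes, m$alphabet)
  wts <- runif(30, 0.5, 1)
  lz <- exact_log_z(m)
  # no penalties: weighted mean log-probability via enumeration
  obj <- objective(m, aln, wts, log_z = lz)
  logp <- log(ex$p)[match(apply(codes, 1, paste, collapse = ""), ex$key)]
  expect_equal(obj, weighted_average(logp, wts), tolerance = 1e-10)
  # penalty term for a single weight entry w = 2 with M = 1
  m1 <- rbm(matrix(0, 3, 2), array(0, c(3, 2, 1)), hidden_gaussian(1, 0, M = 1),
            m$alphabet)
  m1$w[1, 1, 1] <- 2
  lz1 <- exact_log_z(m1)
  expect_equal(objective(m1, aln, wts, lz1, lambda_12 = 0.5) -
                 objective(m1, aln, wts, lz1),
               -0.5 * 4 / (2 * 2 * 3), tolerance = 1e-12)
  # zero-weight model with log-frequency fields: independent log-likelihood
  f <- site_frequencies(aln, wts)
  mi <- rbm(log(f), array(0, c(3, 2, 2)), m$pot, m$alphabet)
  ind_ll <- sum(vapply(1:3, function(i) {
    weighted_average(log(f[i, ])[codes[, i]], wts)
  }, numeric(1)))
  expect_equal(objective(mi, aln, wts, exact_log_z(mi)), ind_ll,
               tolerance = 1e-10)
})

test_that("gradients match central finite differences on an enumerable model", {
  m <- tiny_drelu_rbm()
  set.seed(42)
  codes <- enumerate_sequences(3, 2)[sample.int(8, 40, replace = TRUE,
                                                prob = c(4, 2, 1, 1, 1, 1, 2, 3)), ]
  wts <- runif(40, 0.5, 1)
  avg_ll <- function(mm) {
    weighted_average(-effective_energy(mm, codes), wts) - exact_log_z(mm)
  }
  gr <- rbm_gradient(m, codes, wts, model_codes = NULL)
  eps <- 1e-6
  rel_err <- function(fd, an) abs(fd - an) / max(abs(fd), 1e-8)
  errs <- c()
  for (k in seq_along(m$g)) {
    mp <- m; mp$g[k] <- mp$g[k] + eps
    mn <- m; mn$g[k] <- mn$g[k] - eps
    errs <- c(errs, rel_err((avg_ll(mp) - avg_ll(mn)) / (2 * eps), gr$g[k]))
  }
  for (k in seq_along(m$w)) {
    mp <- m; mp$w[k] <- mp$w[k] + eps
    mn <- m; mn$w[k] <- mn$w[k] - eps
    errs <- c(errs, rel_err((avg_ll(mp) - avg_ll(mn)) / (2 * eps), gr$w[k]))
  }
  for (nm in c("theta_plus", "theta_minus", "gamma_plus", "gamma_minus")) {
    for (k in 1:2) {
      mp <- m; mp$pot[[nm]][k] <- mp$pot[[nm]][k] + eps
      mn <- m; mn$pot[[nm]][k] <- mn$pot[[nm]][k] - eps
      errs <- c(errs, rel_err((avg_ll(mp) - avg_ll(mn)) / (2 * eps),
                              gr$pot[[nm]][k]))
    }
  }
  expect_lt(max(errs), 1e-5)
})

test_that("the likelihood gradient vanishes when data equals the model law", {
  m <- tiny_drelu_rbm()
  ex <- exact_probs(m)
  # feed the exact model distribution as weighted 'data'
  gr <- rbm_gradient(m, ex$states, ex$p, model_codes = NULL)
  expect_lt(max(abs(gr$g)), 1e-12)
  expect_lt(max(abs(gr$w)), 1e-12)
  expect_lt(max(abs(unlist(gr$pot))), 1e-12)
  # sign(0) convention: zero weights contribute no L1 penalty gradient, so
  # the penalized and unpenalized gradients coincide there
  m0 <- m; m0$w[] <- 0
  gr_pen <- rbm_gradient(m0, ex$states, ex$p, model_codes = NULL,
                         lambda_12 = 5)
  gr_fre <- rbm_gradient(m0, ex$states, ex$p, model_codes = NULL)
  expect_equal(gr_pen$w, gr_fre$w, tolerance = 1e-14)
})

test_that("dynamic reparametrization standardizes units without moving P(v)", {
  mg <- tiny_gaussian_rbm()
  ex <- exact_probs(mg)
  mr <- dynamic_reparametrize(mg, h_mean = c(0.5, -0.2), h_var = c(2.3, 0.4))
  er <- effective_energy(mr, ex$states)
  pr <- exp(-(er - min(er))); pr <- pr / sum(pr)
  expect_equal(pr, ex$p, tolerance = 1e-10)
  # already-normalized statistics: identity transform
  mid <- dynamic_reparametrize(mg, c(0, 0), c(1, 1))
  expect_equal(mid$w, mg$w, tolerance = 1e-14)
  expect_equal(mid$pot, mg$pot, tolerance = 1e-14)
  # rescaling by lambda then reparametrizing with the matching statistics
  # recovers the original parameters
  # (relative to unit-variance activities, ms carries h scaled up by lam)
  lam <- 2
  ms <- mg
  ms$w <- ms$w / lam
  ms$pot$gamma <- ms$pot$gamma / lam^2
  ms$pot$theta <- ms$pot$theta / lam
  back <- dynamic_reparametrize(ms, c(0, 0), rep(lam^2, 2))
  expect_equal(back$w, mg$w, tolerance = 1e-12)
  expect_equal(back$pot$gamma, mg$pot$gamma, tolerance = 1e-12)
  # vanishing variance estimates are skipped with a warning
  expect_warning(dynamic_reparametrize(mg, c(0, 0), c(0, 1)), "vanishing")
})

test_that("exact-gradient training increases the true objective", {
  set.seed(43)
  # ground truth: a coupled model with moderate marginals, so the data
  # carries coupling structure beyond what frequency fields capture
  truth <- tiny_drelu_rbm(seed = 99)
  truth$g[] <- 0
  truth$w <- truth$w * 0.4
  ex <- exact_probs(truth)
  codes <- ex$states[sample.int(8, 400, replace = TRUE, prob = ex$p), ]
  aln <- codes_alignment(codes, truth$alphabet)
  cfg <- training_config(n_updates = 300, batch_size = 400, lambda_f = 0,
                         lambda_12 = 0, seed = 3, exact_gradient = TRUE,
                         reparam_every = 0, log_every = 50, lr_init = 0.05,
                         lr_final = 1e-3)
  fit <- fit_rbm(aln, M = 2, variant = "drelu", config = cfg,
                 weights = rep(1, 400))
  obj0 <- objective(init_after <- {
    set.seed(cfg$seed); init_rbm(aln, 2, "drelu", rep(1, 400))
  }, aln, rep(1, 400), exact_log_z(init_after))
  obj1 <- objective(fit, aln, rep(1, 400), exact_log_z(fit))
  expect_gt(obj1, obj0)
  # the zero-sum gauge is maintained throughout training
  expect_lt(max(abs(apply(fit$w, c(1, 3), sum))), 1e-10)
  # training is deterministic under the seed
  fit2 <- fit_rbm(aln, M = 2, variant = "drelu", config = cfg,
                  weights = rep(1, 400))
  expect_equal(fit$w, fit2$w, tolerance = 1e-12)
  expect_s3_class(fit$history, "tbl_df")
})

test_that("a zero-update fit returns the initialized model", {
  set.seed(44)
  codes <- matrix(sample.int(2L, 60, replace = TRUE), 20, 3)
  aln <- codes_alignment(codes, c("A", "B"))
  cfg <- training_config(n_updates = 0, seed = 5)
  fit <- fit_rbm(aln, M = 2, variant = "gaussian", config = cfg,
                 weights = rep(1, 20))
  set.seed(cfg$seed)
  ref <- project_zero_sum(init_rbm(aln, 2, "gaussian", rep(1, 20)))
  expect_equal(fit$g, ref$g, tolerance = 1e-12)
  expect_equal(fit$w, ref$w, tolerance = 1e-12)
})

test_that("an overwhelming weight penalty collapses to the independent model", {
  set.seed(45)
  # a coupled ground truth with moderate site marginals (zero fields), so
  # field relaxation is well conditioned and the collapse limit is reached
  truth <- tiny_drelu_rbm(seed = 99)
  truth$g[] <- 0
  truth$w <- truth$w * 0.4
  ex <- exact_probs(truth)
  codes <- ex$states[sample.int(8, 300, replace = TRUE, prob = ex$p), ]
  aln <- codes_alignment(codes, truth$alphabet)
  cfg <- training_config(n_updates = 1500, lambda_12 = 5, lambda_f = 0,
                         seed = 6, exact_gradient = TRUE, reparam_every = 50,
                         log_every = 500, lr_init = 0.05, lr_final = 1e-3,
                         decay_start_fraction = 0.8)
  fit <- fit_rbm(aln, M = 2, variant = "drelu", config = cfg,
                 weights = rep(1, 300))
  # weights essentially disconnected; held-out likelihood at the
  # independent-model value
  expect_lt(mean(weight_norms(fit)), 1e-6)
  f <- site_frequencies(aln)
  mi <- rbm(log(f), array(0, c(3, 2, 2)), fit$pot, fit$alphabet)
  ll_fit <- heldout_log_likelihood(fit, aln, log_z = exact_log_z(fit))
  ll_ind <- heldout_log_likelihood(mi, aln, log_z = exact_log_z(mi))
  expect_equal(ll_fit, ll_ind, tolerance = 0.01)
  # and it sits below the likelihood of an unregularized fit of the same data
  cfg0 <- training_config(n_updates = 800, lambda_12 = 0, lambda_f = 0,
                          seed = 6, exact_gradient = TRUE, reparam_every = 50,
                          log_every = 400, lr_init = 0.05, lr_final = 1e-3)
  fit0 <- fit_rbm(aln, M = 2, variant = "drelu", config = cfg0,
                  weights = rep(1, 300))
  ll0 <- heldout_log_likelihood(fit0, aln, log_z = exact_log_z(fit0))
  expect_gt(ll0, ll_fit)
})
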
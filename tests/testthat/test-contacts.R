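test_that("epistasis scores vanish for independent models and ignore the gauge", {
  m <- tiny_drelu_rbm()
  m0 <- m; m0$w[] <- 0
  for (bg in list(c(1L, 1L, 1L), c(2L, 1L, 2L))) {
    expect_equal(delta_delta_r(m0, bg, 1, 3, 1, 2, 2, 1), 0)
  }
  expect_error(delta_delta_r(m, c(1L, 1L, 1L), 2, 2, 1, 2, 1, 2), "differ")
})

test_that("for Gaussian models the epistasis score is the Potts coupling", {
  mg <- tiny_gaussian_rbm()
  pe <- pairwise_equivalent(mg)
  set.seed(61)
  vals <- vapply(1:5, function(k) {
    bg <- sample.int(3L, 4, replace = TRUE)
    delta_delta_r(mg, bg, 1, 3, 1, 2, 2, 3)
  }, numeric(1))
  # background independence
  expect_lt(max(vals) - min(vals), 1e-10)
  # equals the coupling combination
  Jb <- pe$J[1, , 3, ]
  expect_equal(vals[1], Jb[1, 2] + Jb[2, 3] - Jb[2, 2] - Jb[1, 3],
               tolerance = 1e-10)
})

test_that("dReLU epistasis scores match brute-force enumerated marginals", {
  m <- tiny_drelu_rbm()
  ex <- exact_probs(m)
  pv <- function(v) ex$p[match(paste(v, collapse = ""), ex$key)]
  mk <- function(v, i, j, a, b) { v[i] <- a; v[j] <- b; v }
  v <- c(2L, 1L, 2L)
  brute <- log(pv(mk(v, 1, 3, 1, 2)) * pv(mk(v, 1, 3, 2, 1)) /
                 (pv(mk(v, 1, 3, 2, 2)) * pv(mk(v, 1, 3, 1, 1))))
  expect_equal(delta_delta_r(m, v, 1, 3, 1, 2, 2, 1), brute, tolerance = 1e-10)
  # antisymmetry under swapping the symbol pairs on either site
  d <- delta_delta_r(m, v, 1, 3, 1, 2, 2, 1)
  expect_equal(delta_delta_r(m, v, 1, 3, 2, 1, 2, 1), -d, tolerance = 1e-12)
  expect_equal(delta_delta_r(m, v, 1, 3, 1, 2, 1, 2), -d, tolerance = 1e-12)
  # symmetry under exchanging the two (site, symbols) roles
  expect_equal(delta_delta_r(m, v, 3, 1, 2, 1, 1, 2), d, tolerance = 1e-12)
})

test_that("effective couplings recover the exact couplings of Gaussian models", {
  mg <- tiny_gaussian_rbm()
  set.seed(62)
  codes <- matrix(sample.int(3L, 15 * 4, replace = TRUE), 15, 4)
  aln <- codes_alignment(codes, mg$alphabet)
  J <- effective_couplings(mg, aln, subsample = 6)
  pe <- pairwise_equivalent(mg)
  # oracle: double-center each Potts block over its symbol pairs
  for (i in 1:3) {
    for (j in (i + 1):4) {
      blk <- pe$J[i, , j, ]
      blk <- blk - matrix(rowMeans(blk), 3, 3) -
        matrix(colMeans(blk), 3, 3, byrow = TRUE) + mean(blk)
      expect_equal(J[i, , j, ], blk, tolerance = 1e-8)
      expect_equal(J[j, , i, ], t(J[i, , j, ]), tolerance = 1e-12)
    }
  }
  # independent model: all zeros
  m0 <- mg; m0$w[] <- 0
  expect_equal(max(abs(effective_couplings(m0, aln, subsample = 3))), 0)
  expect_error(effective_couplings(mg, aln, subsample = 0), "subsample")
})

test_that("background averaging of dReLU couplings is stable under resampling", {
  m <- tiny_drelu_rbm()
  ex <- exact_probs(m)
  set.seed(63)
  codes <- ex$states[sample.int(8, 400, replace = TRUE, prob = ex$p), ]
  aln <- codes_alignment(codes, m$alphabet)
  set.seed(1); J1 <- effective_couplings(m, aln, subsample = 150)
  set.seed(2); J2 <- effective_couplings(m, aln, subsample = 150)
  denom <- max(abs(J1))
  expect_gt(denom, 0)
  expect_lt(max(abs(J1 - J2)) / denom, 0.5)  # MC noise, not structure
})

test_that("Frobenius + APC scoring matches the textbook formulas", {
  set.seed(64)
  N <- 5; q <- 3
  J <- array(rnorm(N * q * N * q, sd = 0.2), c(N, q, N, q))
  for (i in 1:N) J[i, , i, ] <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) J[j, , i, ] <- t(J[i, , j, ])
  sc <- score_contacts(J)
  Fm <- matrix(0, N, N)
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    Fm[i, j] <- Fm[j, i] <- sqrt(sum(J[i, , j, ]^2))
  }
  mi <- rowSums(Fm) / (N - 1); mall <- sum(Fm) / (N * (N - 1))
  apc <- Fm - outer(mi, mi) / mall
  expect_equal(sc$raw_frobenius, Fm[cbind(sc$i, sc$j)], tolerance = 1e-12)
  expect_equal(sc$apc_score, apc[cbind(sc$i, sc$j)], tolerance = 1e-12)
  expect_true(all(diff(sc$apc_score) <= 1e-12))      # sorted descending
  # constant Frobenius matrix: APC annihilates every score
  Jc <- array(0, c(N, q, N, q))
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    Jc[i, 1, j, 1] <- 1; Jc[j, 1, i, 1] <- 1
  }
  expect_lt(max(abs(score_contacts(Jc)$apc_score)), 1e-12)
  # a single dominant pair ranks first
  J[2, , 4, ] <- J[2, , 4, ] + 5; J[4, , 2, ] <- t(J[2, , 4, ])
  top <- score_contacts(J)[1, ]
  expect_equal(c(top$i, top$j), c(2, 4))
  # gap exclusion drops the last symbol from the norm
  sc_ng <- score_contacts(J, exclude_gap = TRUE)
  Fng <- sqrt(sum(J[2, 1:(q - 1), 4, 1:(q - 1)]^2))
  expect_equal(sc_ng$raw_frobenius[sc_ng$i == 2 & sc_ng$j == 4], Fng,
               tolerance = 1e-12)
  expect_error(score_contacts(array(0, c(2, 3, 2, 3))), "3 sites")
})

test_that("PPV curves behave correctly for perfect, inverted, random orders", {
  set.seed(65)
  N <- 12
  truth_pairs <- rbind(c(1, 7), c(2, 9), c(3, 11), c(5, 12), c(4, 10))
  ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  truth <- tibble::tibble(i = ut[, 1], j = ut[, 2],
                          is_contact = paste(ut[, 1], ut[, 2]) %in%
                            paste(truth_pairs[, 1], truth_pairs[, 2]))
  base_scores <- tibble::tibble(i = ut[, 1], j = ut[, 2],
                                raw_frobenius = 1, apc_score = 0)
  sep_ok <- abs(base_scores$j - base_scores$i) >= 5
  n_true <- sum(truth$is_contact[sep_ok])
  # perfect ordering: PPV = 1 up to the number of true contacts
  sc <- base_scores
  sc$apc_score <- ifelse(truth$is_contact, 2, 1) + runif(nrow(sc), 0, 0.1)
  sc <- dplyr::arrange(sc, dplyr::desc(apc_score))
  class(sc) <- c("contact_scores", class(sc))
  pv <- ppv_curve(sc, truth, min_separation = 5)
  expect_equal(pv$ppv[seq_len(n_true)], rep(1, n_true))
  # inverted ordering: PPV(k) = max(0, k - #noncontacts) / k
  sci <- sc; sci$apc_score <- -sci$apc_score
  sci <- dplyr::arrange(sci, dplyr::desc(apc_score))
  pvi <- ppv_curve(sci, truth, min_separation = 5)
  n_non <- sum(sep_ok) - n_true
  expect_equal(pvi$ppv, pmax(0, pvi$rank - n_non) / pvi$rank)
  # random ordering: expected PPV at full depth equals the contact density
  dens <- n_true / sum(sep_ok)
  mean_ppv <- mean(replicate(200, {
    sr <- sc; sr$apc_score <- runif(nrow(sr))
    sr <- dplyr::arrange(sr, dplyr::desc(apc_score))
    ppv_curve(sr, truth, min_separation = 5)$ppv[10]
  }))
  expect_equal(mean_ppv, dens, tolerance = 0.05)
  # missing truth pairs are an explicit error listing them
  expect_error(ppv_curve(sc, truth[1:10, ], min_separation = 5), "missing")
})
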
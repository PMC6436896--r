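#' Epistatic log-probability score of a double mutation
#'
#' For background sequence `v` and sites `i != j`, compares the
#' log-probability change of the double mutation with the sum of the two
#' single-mutation changes:
#' \deqn{\Delta\Delta R_{ij}(v; a, a', b, b') = \log\frac{P(v^{a,b})
#'  P(v^{a',b'})}{P(v^{a',b}) P(v^{a,b'})},}
#' where \eqn{v^{a,b}} carries residues `a`, `b` at sites `i`, `j`.
#' Computed from effective-energy differences only (the partition function
#' and the field terms cancel), at cost `O(M)` per mutant via input
#' increments. For a pairwise model the value is independent of the
#' background and equals the zero-sum-gauge coupling combination
#' \eqn{J_{ij}(a,b) + J_{ij}(a',b') - J_{ij}(a',b) - J_{ij}(a,b')}.
#'
#' @param params An [rbm].
#' @param v Background sequence (length-`N` codes).
#' @param i,j Distinct sites (1-based).
#' @param a,a2,b,b2 Symbol codes: the double mutation is `a -> a2` at `i`
#'   and `b -> b2` at `j`.
#' @return Scalar log-probability ratio.
#' @export
delta_delta_r <- function(params, v, i, j, a, a2, b, b2) {
  stop_if_not(i != j, "sites i and j must differ")
  v <- as.integer(v)
  I0 <- as.vector(compute_inputs(params, v))
  di <- params$w[i, , , drop = FALSE]  # 1 x q x M
  dj <- params$w[j, , , drop = FALSE]
  base <- I0 - matrix(di[1, v[i], ], ncol = params$M) -
    matrix(dj[1, v[j], ], ncol = params$M)
  gam <- function(ai, bj) {
    sum(cgf(params$pot, base + matrix(di[1, ai, ] + dj[1, bj, ], ncol = params$M)))
  }
  gam(a, b) + gam(a2, b2) - gam(a2, b) - gam(a, b2)
}

#' Background-averaged effective couplings
#'
#' The effective coupling matrix is the reweighted MSA average of the
#' epistatic scores, averaged uniformly over the reference symbols:
#' \deqn{J^{\mathrm{eff}}_{ij}(a,b) = \Big\langle \frac{1}{q^2}
#'  \sum_{a',b'} \Delta\Delta R_{ij}(v; a, a', b, b') \Big\rangle_{MSA},}
#' which equals, per background, the double-centered (over `a`, `b`) matrix
#' of summed cumulant-generating functions — so the result is in the
#' zero-sum gauge over symbols by construction. The full average costs
#' `O(B N^2 q^2 M)`; by default backgrounds are subsampled (with
#' probability proportional to the sequence weights) to at most `subsample`
#' sequences.
#'
#' @param params An [rbm].
#' @param aln Background alignment.
#' @param weights Sequence weights (default uniform).
#' @param subsample Maximum number of backgrounds averaged (>= 1; default
#'   500). If `B <= subsample` all sequences are used with their weights.
#' @return Coupling array `N x q x N x q` (class attribute-free), symmetric
#'   in the site pair, zero on diagonal site blocks.
#' @export
effective_couplings <- function(params, aln, weights = NULL, subsample = 500L) {
  stop_if_not(subsample >= 1L, "subsample must be >= 1")
  codes <- aln$codes
  B <- nrow(codes)
  w <- weights %||% rep(1, B)
  if (B > subsample) {
    idx <- sample.int(B, subsample, replace = TRUE, prob = w / sum(w))
    codes <- codes[idx, , drop = FALSE]
    w <- rep(1, subsample)
  }
  S <- nrow(codes)
  wn <- w / sum(w)
  N <- params$N; q <- params$q; M <- params$M
  I0 <- compute_inputs(params, codes)         # S x M
  J <- array(0, c(N, q, N, q))
  for (i in seq_len(N - 1L)) {
    wi <- matrix(params$w[i, , ], q, M)
    Ii <- I0 - wi[codes[, i], , drop = FALSE]  # background minus site-i term
    for (j in (i + 1L):N) {
      wj <- matrix(params$w[j, , ], q, M)
      base <- Ii - wj[codes[, j], , drop = FALSE]   # S x M
      Tm <- matrix(0, S, q * q)
      for (mu in seq_len(M)) {
        # S x (q*q) grid of inputs: base + w_i(a) + w_j(b), a varying fastest
        inp <- outer(base[, mu], wi[, mu], `+`)             # S x q over a
        inp <- inp[, rep(seq_len(q), times = q), drop = FALSE]
        inp <- sweep(inp, 2L, rep(wj[, mu], each = q), `+`)
        Tm <- Tm + cgf_unit(params$pot, mu, inp)
      }
      dim(Tm) <- c(S, q, q)
      # double-center over (a, b) per background, then weight-average
      Tm <- sweep(Tm, c(1, 2), apply(Tm, c(1, 2), mean))
      Tm <- sweep(Tm, c(1, 3), apply(Tm, c(1, 3), mean))
      Jij <- apply(Tm * wn, c(2, 3), sum)
      J[i, , j, ] <- Jij
      J[j, , i, ] <- t(Jij)
    }
  }
  J
}

# CGF of a single unit mu evaluated on an arbitrary-shaped input array
cgf_unit <- function(pot, mu, x) {
  p1 <- switch(pot$variant,
    gaussian = hidden_gaussian(pot$gamma[mu], pot$theta[mu], M = 1L),
    drelu = hidden_drelu(pot$gamma_plus[mu], pot$gamma_minus[mu],
                         pot$theta_plus[mu], pot$theta_minus[mu], M = 1L),
    bernoulli = hidden_bernoulli(pot$b[mu], M = 1L))
  d <- dim(x)
  out <- cgf(p1, matrix(as.vector(x), ncol = 1L))
  dim(out) <- d
  out
}

#' Frobenius + APC contact scores
#'
#' Per site pair, the Frobenius norm of the coupling block
#' \eqn{F_{ij} = \|J^{\mathrm{eff}}_{ij}\|_F} (over all symbol pairs; set
#' `exclude_gap = TRUE` to drop the gap row/column), followed by the
#' average product correction
#' \eqn{APC_{ij} = F_{ij} - F_{i\cdot} F_{\cdot j} / F_{\cdot\cdot}} with
#' means over off-diagonal entries, which suppresses conservation and
#' phylogeny-driven background signal.
#'
#' @param J Coupling array `N x q x N x q` ([effective_couplings()] or
#'   `pairwise_equivalent()$J`).
#' @param exclude_gap Drop the gap symbol (assumed last) from the norm.
#' @return A tibble of class `contact_scores` with columns `i`, `j`
#'   (`i < j`, 1-based), `raw_frobenius`, `apc_score`, sorted by decreasing
#'   `apc_score`.
#' @export
score_contacts <- function(J, exclude_gap = FALSE) {
  stop_if_not(all(is.finite(J)), "couplings must be finite")
  N <- dim(J)[1]; q <- dim(J)[2]
  stop_if_not(N >= 3L, "APC needs at least 3 sites")
  keep <- if (exclude_gap) seq_len(q - 1L) else seq_len(q)
  Fm <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      Fm[i, j] <- Fm[j, i] <- sqrt(sum(J[i, keep, j, keep]^2))
    }
  }
  off_mean_i <- rowSums(Fm) / (N - 1L)
  off_mean_all <- sum(Fm) / (N * (N - 1L))
  apc <- Fm - outer(off_mean_i, off_mean_i) / off_mean_all
  ut <- which(upper.tri(Fm), arr.ind = TRUE)
  out <- tibble::tibble(i = ut[, 1], j = ut[, 2],
                        raw_frobenius = Fm[ut],
                        apc_score = apc[ut])
  out <- dplyr::arrange(out, dplyr::desc(.data$apc_score))
  class(out) <- c("contact_scores", class(out))
  out
}

#' Positive predictive value along the contact ranking
#'
#' After removing pairs closer than `min_separation` along the backbone,
#' `PPV(k)` is the fraction of true contacts among the top `k` ranked
#' pairs.
#'
#' @param scores A `contact_scores` tibble (see [score_contacts()]).
#' @param truth Reference contacts: a data frame with columns `i`, `j` and
#'   either `is_contact` (logical) or `distance` plus a `threshold`
#'   attribute — or a 2-column matrix of contacting pairs (all listed pairs
#'   are contacts, all unlisted scored pairs non-contacts only if
#'   `complete = FALSE`).
#' @param min_separation Minimum `|i - j|` retained (default 5).
#' @param complete Require `truth` to label every scored pair (default
#'   `TRUE`; missing pairs are an error listing them).
#' @return Tibble with `rank`, `i`, `j`, `score`, `is_contact`, `ppv`.
#' @export
ppv_curve <- function(scores, truth, min_separation = 5L, complete = TRUE) {
  s <- dplyr::filter(scores, abs(.data$j - .data$i) >= min_separation)
  truth_tbl <- contact_truth_table(truth)
  key <- paste(pmin(s$i, s$j), pmax(s$i, s$j))
  tkey <- paste(pmin(truth_tbl$i, truth_tbl$j), pmax(truth_tbl$i, truth_tbl$j))
  hit <- match(key, tkey)
  if (anyNA(hit) && complete) {
    miss <- utils::head(key[is.na(hit)], 10)
    stop("truth map missing scored pairs: ", paste(miss, collapse = "; "),
         call. = FALSE)
  }
  is_contact <- rep(FALSE, length(hit))
  ok <- !is.na(hit)
  is_contact[ok] <- truth_tbl$is_contact[hit[ok]]
  tibble::tibble(rank = seq_len(nrow(s)), i = s$i, j = s$j,
                 score = s$apc_score, is_contact = is_contact,
                 ppv = cumsum(is_contact) / seq_len(nrow(s)))
}

contact_truth_table <- function(truth) {
  if (is.matrix(truth)) {
    return(tibble::tibble(i = truth[, 1], j = truth[, 2], is_contact = TRUE))
  }
  stop_if_not(all(c("i", "j") %in% names(truth)), "truth needs columns i, j")
  if ("is_contact" %in% names(truth)) {
    tibble::tibble(i = truth$i, j = truth$j,
                   is_contact = as.logical(truth$is_contact))
  } else if ("distance" %in% names(truth)) {
    thr <- attr(truth, "threshold") %||% 8
    tibble::tibble(i = truth$i, j = truth$j, is_contact = truth$distance <= thr)
  } else {
    stop("truth needs an is_contact or distance column", call. = FALSE)
  }
}

#' Read / write contact tables
#'
#' Plain TSV interchange: `read_contact_map()` expects columns `i`, `j` and
#' `is_contact` (or `distance`); `write_contact_scores()` writes a
#' [score_contacts()] table.
#'
#' @param path File path.
#' @export
read_contact_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  tibble::as_tibble(df)
}

#' @rdname read_contact_map
#' @param scores A `contact_scores` tibble.
#' @export
write_contact_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
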
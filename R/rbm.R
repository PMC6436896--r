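#' Construct a Restricted Boltzmann Machine for aligned sequences
#'
#' The model is a bipartite distribution over integer-coded sequences
#' \eqn{v = (v_1,\dots,v_N)}, \eqn{v_i \in \{1..q\}}, and real hidden
#' activities \eqn{h = (h_1,\dots,h_M)}:
#' \deqn{P(v, h) \propto \exp\Big(\sum_i g_i(v_i) - \sum_\mu U_\mu(h_\mu)
#'       + \sum_{i,\mu} h_\mu w_{i\mu}(v_i)\Big).}
#' Marginalizing the hidden layer gives
#' \eqn{P(v) \propto \exp(-E_{\mathrm{eff}}(v))} with
#' \eqn{E_{\mathrm{eff}}(v) = -\sum_i g_i(v_i) - \sum_\mu
#' \Gamma_\mu(I_\mu(v))} (see [effective_energy()], [cgf()]).
#'
#' @param g Visible fields, `N x q` matrix.
#' @param w Weights, array `N x q x M`.
#' @param pot A [hidden_potential] with `M` units.
#' @param alphabet Ordered symbol set of length `q`.
#' @return An object of class `rbm`.
#' @export
rbm <- function(g, w, pot, alphabet = aa_alphabet()) {
  stop_if_not(is.matrix(g), "g must be an N x q matrix")
  stop_if_not(length(dim(w)) == 3L, "w must be an N x q x M array")
  N <- nrow(g); q <- ncol(g)
  stop_if_not(dim(w)[1] == N && dim(w)[2] == q, "w and g dimensions disagree")
  M <- dim(w)[3]
  stop_if_not(inherits(pot, "hidden_potential") && pot$M == M,
              "pot must be a hidden_potential with M units")
  stop_if_not(length(alphabet) == q, "alphabet length must equal q")
  stop_if_not(all(is.finite(g)) && all(is.finite(w)), "parameters must be finite")
  structure(list(N = N, q = q, M = M, alphabet = alphabet,
                 g = g, w = w, pot = pot),
            class = "rbm")
}

#' @export
print.rbm <- function(x, ...) {
  cat("<rbm> N =", x$N, "sites, q =", x$q, ", M =", x$M,
      "hidden units (", x$pot$variant, ")\n")
  invisible(x)
}

# weights flattened to (N*q) x M; row r = i + (a-1)*N holds w[i, a, ]
weight_matrix <- function(params) {
  matrix(params$w, params$N * params$q, params$M)
}

# linear row indices into an N x q matrix (or weight_matrix rows) for the
# symbols of a B x N code matrix; returned as a (B*N)-vector grouped by
# rep(1:B, N)
code_rows <- function(codes, N) {
  B <- nrow(codes)
  as.vector(codes - 1L) * N + rep(seq_len(N), each = B)
}

as_code_matrix <- function(v, N) {
  if (is.null(dim(v))) v <- matrix(as.integer(v), nrow = 1L)
  stop_if_not(ncol(v) == N, "sequence length does not match model N")
  storage.mode(v) <- "integer"
  v
}

#' Hidden-unit inputs of sequences
#'
#' \eqn{I_\mu(v) = \sum_i w_{i\mu}(v_i)}: the score a sequence sends to each
#' hidden unit, analogous to a position-specific scoring matrix score.
#'
#' @param params An [rbm].
#' @param v Integer codes: a length-`N` vector or a `B x N` matrix.
#' @return `B x M` matrix of inputs.
#' @export
compute_inputs <- function(params, v) {
  v <- as_code_matrix(v, params$N)
  stop_if_not(all(v >= 1L & v <= params$q), "sequence codes out of range")
  Wm <- weight_matrix(params)
  B <- nrow(v)
  rs <- rowsum(Wm[code_rows(v, params$N), , drop = FALSE],
               group = rep(seq_len(B), params$N), reorder = TRUE)
  dimnames(rs) <- NULL
  rs
}

# sum_i g_i(v_i) per sequence
field_sum <- function(params, v) {
  B <- nrow(v)
  as.vector(rowsum(params$g[code_rows(v, params$N)],
                   group = rep(seq_len(B), params$N), reorder = TRUE))
}

#' Effective sequence energy
#'
#' \eqn{E_{\mathrm{eff}}(v) = -\sum_i g_i(v_i) - \sum_\mu
#' \Gamma_\mu(I_\mu(v))}; the marginal sequence probability is
#' \eqn{P(v) = e^{-E_{\mathrm{eff}}(v)} / Z}.
#'
#' @inheritParams compute_inputs
#' @return Numeric vector of energies (length `B`).
#' @export
effective_energy <- function(params, v) {
  v <- as_code_matrix(v, params$N)
  I <- compute_inputs(params, v)
  -field_sum(params, v) - rowSums(cgf(params$pot, I))
}

#' Project parameters onto the zero-sum gauge
#'
#' Subtracts per-site means over the alphabet so that
#' \eqn{\sum_v w_{i\mu}(v) = 0} and \eqn{\sum_v g_i(v) = 0} for all sites and
#' units. The conditional distributions and all probability ratios are
#' unchanged; only the redundancy between fields and weights is removed.
#' Idempotent. During training the weight projection is reapplied after
#' every gradient update (weight updates do not preserve the gauge), while
#' fields only need it once after initialization.
#'
#' @param params An [rbm].
#' @param fields Also recenter the visible fields (default `TRUE`).
#' @details The per-site constants removed from the weights are absorbed
#'   into the hidden-potential tilts (\eqn{\theta} shifts by the removed
#'   total, the Bernoulli field by its negative), so the joint distribution
#'   — not only the conditional \eqn{P(v_i|h)} — is exactly invariant.
#' @return The gauged [rbm].
#' @export
project_zero_sum <- function(params, fields = TRUE) {
  mu_w <- apply(params$w, c(1L, 3L), mean)          # N x M
  params$w <- params$w - aperm(array(mu_w, c(params$N, params$M, params$q)),
                               c(1L, 3L, 2L))
  k <- colSums(mu_w)                                # per-unit removed input
  params$pot <- switch(params$pot$variant,
    gaussian = { p <- params$pot; p$theta <- p$theta - k; p },
    drelu = { p <- params$pot
      p$theta_plus <- p$theta_plus - k
      p$theta_minus <- p$theta_minus - k; p },
    bernoulli = { p <- params$pot; p$b <- p$b + k; p })
  if (fields) params$g <- params$g - rowMeans(params$g)
  params
}

#' Per-unit squared weight norms
#'
#' \eqn{\|W_\mu\|^2 = \sum_{i,v} w_{i\mu}(v)^2}, the standard proxy for how
#' much a hidden unit contributes to the likelihood; used to rank units in
#' reports.
#'
#' @param params An [rbm].
#' @return Numeric vector of length `M`.
#' @export
weight_norms <- function(params) {
  colSums(weight_matrix(params)^2)
}

#' Equivalent pairwise Potts model of a Gaussian RBM
#'
#' A Gaussian RBM marginalizes exactly to a pairwise (Hopfield–Potts) model:
#' the quadratic \eqn{\Gamma_\mu} generate couplings
#' \eqn{J_{ij}(a,b) = \sum_\mu w_{i\mu}(a) w_{j\mu}(b) / \gamma_\mu},
#' so `M` bounds the rank of the flattened coupling matrix (at most
#' `min(M, N(q-1))` in the zero-sum gauge). The \eqn{\theta_\mu} tilts are
#' absorbed into the returned fields so that the Potts energy
#' \eqn{E(v) = -\sum_i \tilde g_i(v_i) - \frac12\sum_{i,j} J_{ij}(v_i, v_j)}
#' (the sum running over all site pairs including `i = j`) reproduces
#' \eqn{P(v)} exactly.
#'
#' @param params An [rbm] whose hidden units are all Gaussian.
#' @return A list of class `potts_model` with `J` (symmetric array
#'   `N x q x N x q`, including the intra-site blocks generated by the
#'   Gaussian marginalization), `fields` (`N x q`), and `log_const` (the
#'   constant absorbed from the hidden-layer normalizers).
#' @export
pairwise_equivalent <- function(params) {
  stop_if_not(params$pot$variant == "gaussian",
              "pairwise equivalence requires all-gaussian hidden units")
  N <- params$N; q <- params$q
  Wm <- weight_matrix(params)
  gam <- params$pot$gamma; the <- params$pot$theta
  Jflat <- Wm %*% t(Wm * rep(1 / gam, each = nrow(Wm)))
  fields <- params$g - matrix(rowSums(sweep(Wm, 2L, the / gam, `*`)), N, q)
  structure(list(J = array(Jflat, c(N, q, N, q)), fields = fields,
                 log_const = sum(the^2 / (2 * gam)) +
                   sum(0.5 * log(2 * pi / gam))),
            class = "potts_model")
}

#' Energy of sequences under a pairwise Potts model
#'
#' @param potts A `potts_model` from [pairwise_equivalent()].
#' @param v Codes vector or matrix.
#' @return Numeric vector of energies (without the absorbed constant).
#' @export
potts_energy <- function(potts, v) {
  N <- dim(potts$J)[1]; q <- dim(potts$J)[2]
  v <- as_code_matrix(v, N)
  Jflat <- matrix(potts$J, N * q, N * q)
  apply(v, 1L, function(s) {
    r <- seq_len(N) + (s - 1L) * N
    -sum(potts$fields[cbind(seq_len(N), s)]) - sum(Jflat[r, r]) / 2
  })
}

#' Flatten a coupling tensor to a matrix
#'
#' Rearranges an `N x q x N x q` coupling array into the
#' `(N q) x (N q)` matrix whose rank is bounded by `min(M, N (q-1))` for
#' couplings induced by a Gaussian RBM in the zero-sum gauge.
#'
#' @param J Coupling array (`N x q x N x q`), e.g. `pairwise_equivalent()$J`
#'   or the result of [effective_couplings()].
#' @return `(N q) x (N q)` numeric matrix.
#' @export
flatten_couplings <- function(J) {
  d <- dim(J)
  matrix(J, d[1] * d[2], d[3] * d[4])
}

#' Initialize an RBM from data statistics
#'
#' Fields start at the independent-site model
#' \eqn{g_i(v) = \log \langle \delta_{v_i, v}\rangle_{MSA}}
#' (reweighted, pseudocount-smoothed), weights are drawn i.i.d. from
#' \eqn{N(0, 0.1/N)} so initial inputs have variance of order one, and
#' hidden potentials start at the standardized quadratic point
#' (\eqn{\gamma_\pm = 1, \theta_\pm = 0}; Bernoulli field 0). Fields are
#' recentered to the zero-sum gauge once; weights are gauge-projected.
#'
#' @param aln An `rbm_alignment`.
#' @param M Number of hidden units.
#' @param variant `"drelu"`, `"gaussian"` or `"bernoulli"`.
#' @param weights Optional sequence weights (default: uniform).
#' @param pseudocount Relative pseudocount for the field frequencies.
#' @return An [rbm].
#' @export
init_rbm <- function(aln, M, variant = c("drelu", "gaussian", "bernoulli"),
                     weights = NULL, pseudocount = 1e-4) {
  variant <- match.arg(variant)
  N <- ncol(aln$codes); q <- length(aln$alphabet)
  f <- site_frequencies(aln, weights, pseudocount)
  g <- log(f)
  w <- array(stats::rnorm(N * q * M, sd = sqrt(0.1 / N)), c(N, q, M))
  pot <- switch(variant,
    gaussian = hidden_gaussian(1, 0, M = M),
    drelu = hidden_drelu(1, 1, 0, 0, M = M),
    bernoulli = hidden_bernoulli(0, M = M))
  project_zero_sum(rbm(g, w, pot, aln$alphabet))
}

#' Reweighted site-by-symbol frequencies
#'
#' @param aln An `rbm_alignment`.
#' @param weights Optional per-sequence weights.
#' @param pseudocount Relative pseudocount mixed into the frequencies.
#' @return `N x q` matrix of frequencies (rows sum to one).
#' @export
site_frequencies <- function(aln, weights = NULL, pseudocount = 0) {
  codes <- aln$codes
  B <- nrow(codes); N <- ncol(codes); q <- length(aln$alphabet)
  w <- if (is.null(weights)) rep(1, B) else as.numeric(weights)
  f <- matrix(0, N, q)
  for (i in seq_len(N)) {
    tab <- rowsum(w, group = codes[, i])   # rows named by observed codes
    f[i, as.integer(rownames(tab))] <- tab / sum(w)
  }
  (1 - pseudocount) * f + pseudocount / q
}

# ---- model archives --------------------------------------------------------

#' Save / load a model archive
#'
#' `save_rbm()` writes a single-file self-describing archive (R native
#' serialization) holding fields, weights, hidden-potential parameters, the
#' alphabet and a provenance record (creation time, package version, and any
#' metadata supplied). `load_rbm()` restores it. For language-neutral
#' interoperability use [write_rbm_text()] / [read_rbm_text()].
#'
#' @param params An [rbm].
#' @param path Archive path.
#' @param provenance Optional named list stored alongside the parameters
#'   (e.g. config, seed, data fingerprint).
#' @return `save_rbm()` the path, invisibly; `load_rbm()` the [rbm] with the
#'   provenance attached as attribute `"provenance"`.
#' @export
save_rbm <- function(params, path, provenance = list()) {
  provenance$saved_at <- format(Sys.time(), tz = "UTC")
  provenance$package_version <- as.character(utils::packageVersion("rbmsa"))
  saveRDS(list(params = unclass(params), provenance = provenance), path)
  invisible(path)
}

#' @rdname save_rbm
#' @export
load_rbm <- function(path) {
  obj <- readRDS(path)
  pot <- obj$params$pot
  params <- rbm(obj$params$g, obj$params$w, pot, obj$params$alphabet)
  attr(params, "provenance") <- obj$provenance
  params
}

#' Plain-text model export
#'
#' One section per parameter block: `# alphabet`, `# fields` (N x q),
#' `# weights unit <mu>` (N x q each), and `# potential <variant>` with one
#' named parameter vector per line. Whitespace-separated numbers; loadable
#' by any language.
#'
#' @inheritParams save_rbm
#' @export
write_rbm_text <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rbmsa model 1", paste("# alphabet",
                                        paste(params$alphabet, collapse = ""))),
             con)
  writeLines("# fields", con)
  utils::write.table(params$g, con, row.names = FALSE, col.names = FALSE)
  for (mu in seq_len(params$M)) {
    writeLines(paste("# weights unit", mu), con)
    utils::write.table(params$w[, , mu], con, row.names = FALSE,
                       col.names = FALSE)
  }
  writeLines(paste("# potential", params$pot$variant), con)
  for (nm in setdiff(names(params$pot), c("variant", "M"))) {
    writeLines(paste(nm, paste(format(params$pot[[nm]], digits = 17),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_rbm_text
#' @export
read_rbm_text <- function(path) {
  lines <- readLines(path)
  alpha <- strsplit(sub("^# alphabet ", "", grep("^# alphabet", lines,
                                                 value = TRUE)), "")[[1]]
  q <- length(alpha)
  sec <- grep("^# ", lines)
  read_block <- function(start) {
    end <- sec[sec > start]
    end <- if (length(end)) min(end) - 1L else length(lines)
    block <- lines[(start + 1L):end]
    do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
  }
  g <- read_block(grep("^# fields", lines))
  N <- nrow(g)
  wsec <- grep("^# weights unit", lines)
  M <- length(wsec)
  w <- array(0, c(N, q, M))
  for (k in seq_len(M)) w[, , k] <- read_block(wsec[k])
  pline <- grep("^# potential", lines)
  variant <- sub("^# potential ", "", lines[pline])
  pars <- list()
  for (l in lines[(pline + 1L):length(lines)]) {
    if (!nzchar(trimws(l))) next
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    pars[[toks[1]]] <- as.numeric(toks[-1])
  }
  pot <- switch(variant,
    gaussian = hidden_gaussian(pars$gamma, pars$theta, M = M),
    drelu = hidden_drelu(pars$gamma_plus, pars$gamma_minus,
                         pars$theta_plus, pars$theta_minus, M = M),
    bernoulli = hidden_bernoulli(pars$b, M = M))
  rbm(g, w, pot, alpha)
}
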
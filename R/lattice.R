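#' Enumerate compact lattice-protein structures
#'
#' All distinct conformations a chain of `edge^3` monomers can adopt as a
#' Hamiltonian self-avoiding walk filling the `edge x edge x edge` cube,
#' deduplicated under the 48 cube symmetries (a chain and its reverse count as
#' distinct conformations, since contact energies depend on sequence
#' direction) and returned
#' in a deterministic canonical order. Every 27-mer compact fold carries
#' exactly 28 contacts (the 54 adjacent cell pairs of the cube minus the 26
#' chain bonds). Enumeration of the full 3-cube takes a while; pass `cache`
#' to persist the result as plain text and reload it instantly.
#'
#' @param cube_edge 2 or 3.
#' @param cache Optional path to a cache file (one structure per line,
#'   space-separated 0-based cell indices). Read when it exists, written
#'   after enumeration otherwise.
#' @return A `lattice_structures` object: list with `edge`, `n_sites`,
#'   `cells` (`S x n` 0-based cell indices), `contact_i`/`contact_j`
#'   (`S x K` 1-based chain positions in contact), and `n_structures`.
#'   After a fresh enumeration the raw directed-walk count is attached as
#'   attribute `"n_directed"` for cross-checks.
#' @export
enumerate_structures <- function(cube_edge = 3L, cache = NULL) {
  stop_if_not(cube_edge %in% c(2L, 3L), "cube_edge must be 2 or 3 (cost)")
  n_directed <- NULL
  if (!is.null(cache) && file.exists(cache)) {
    cells <- as.matrix(utils::read.table(cache))
    dimnames(cells) <- NULL
    storage.mode(cells) <- "integer"
  } else {
    cells <- enumerate_saw_cpp(as.integer(cube_edge))
    n_directed <- attr(cells, "n_directed")
    attr(cells, "n_directed") <- NULL
    if (!is.null(cache)) {
      utils::write.table(cells, cache, row.names = FALSE, col.names = FALSE)
    }
  }
  out <- c(structure_contacts(cells, cube_edge),
           list(edge = cube_edge, n_sites = ncol(cells), cells = cells,
                n_structures = nrow(cells)))
  if (!is.null(n_directed)) attr(out, "n_directed") <- n_directed
  structure(out, class = "lattice_structures")
}

#' @export
print.lattice_structures <- function(x, ...) {
  cat("<lattice_structures>", x$n_structures, "compact folds of a",
      x$n_sites, "- mer on the", paste0(x$edge, "^3"), "cube,",
      ncol(x$contact_i), "contacts each\n")
  invisible(x)
}

# contact sets (|i - j| > 1, unit lattice distance) for every structure
structure_contacts <- function(cells, edge) {
  S <- nrow(cells); n <- ncol(cells)
  X <- cells %% edge
  Y <- (cells %/% edge) %% edge
  Z <- cells %/% (edge * edge)
  cnt <- integer(S)
  K_guess <- if (edge == 3L) 28L else 16L
  ci <- matrix(NA_integer_, S, K_guess)
  cj <- matrix(NA_integer_, S, K_guess)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      d <- abs(X[, i] - X[, j]) + abs(Y[, i] - Y[, j]) + abs(Z[, i] - Z[, j])
      hit <- which(d == 1L)
      if (length(hit)) {
        pos <- cnt[hit] + 1L
        ci[cbind(hit, pos)] <- i
        cj[cbind(hit, pos)] <- j
        cnt[hit] <- pos
      }
    }
  }
  K <- max(cnt)
  stop_if_not(all(cnt == K), "contact count is not uniform across structures")
  list(contact_i = ci[, seq_len(K), drop = FALSE],
       contact_j = cj[, seq_len(K), drop = FALSE])
}

#' Residue-residue contact energies
#'
#' Loads the bundled 20x20 symmetric contact-energy table (inter-residue
#' contact energies in RT units, transcribed from the 1996 Miyazawa-Jernigan
#' statistical potentials; see the file header for provenance), reordered to
#' the package amino-acid alphabet. Any other symmetric 20x20 table with
#' matching row/column names can be passed wherever an energy table is
#' expected.
#'
#' @param path Optional path to an alternative table (TSV with residue
#'   row/column names; `#` comment lines ignored).
#' @return Named symmetric 20x20 numeric matrix ordered like
#'   `aa_alphabet(gap = FALSE)`.
#' @export
mj_energy_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mj1996_contact_energies.tsv",
                                package = "rbmsa", mustWork = TRUE)
  tab <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE,
                                     row.names = 1L, comment.char = "#"))
  ord <- aa_alphabet(gap = FALSE)
  stop_if_not(all(ord %in% rownames(tab)) && all(ord %in% colnames(tab)),
              "energy table must cover the 20 amino acids")
  tab <- tab[ord, ord]
  stop_if_not(isTRUE(all.equal(tab, t(tab))), "energy table must be symmetric")
  tab
}

check_lattice_seq <- function(seq, structures) {
  if (is.character(seq)) {
    seq <- as.vector(encode_sequences(seq, aa_alphabet(gap = FALSE),
                                      unknown = "error"))
  }
  seq <- as.integer(seq)
  stop_if_not(length(seq) == structures$n_sites,
              "sequence length must match the lattice chain length")
  stop_if_not(all(seq >= 1L & seq <= 20L),
              "lattice sequences carry amino acids only (no gaps)")
  seq
}

#' Contact energy of a sequence on one fold
#'
#' \eqn{E(s, S) = \sum_{(i,j) \in \mathrm{contacts}(S)} e(s_i, s_j)}.
#'
#' @param seq Length-27 (or 8) residue codes over the 20-letter alphabet,
#'   or a character string; gaps are an error.
#' @param structure_index Fold index into `structures`.
#' @param structures A `lattice_structures` object.
#' @param energies Energy table (default [mj_energy_table()]).
#' @return Scalar energy.
#' @export
fold_energy <- function(seq, structure_index, structures,
                        energies = mj_energy_table()) {
  fold_energies(seq, structures, energies)[structure_index]
}

#' Contact energies of a sequence on every fold
#'
#' @inheritParams fold_energy
#' @return Numeric vector over all structures.
#' @export
fold_energies <- function(seq, structures, energies = mj_energy_table()) {
  seq <- check_lattice_seq(seq, structures)
  fold_energies_cpp(seq, structures$contact_i, structures$contact_j,
                    unname(energies))
}

#' Native-fold probability of a lattice-protein sequence
#'
#' The exact Boltzmann probability of folding into the designated native
#' structure, \eqn{p_{nat} = e^{-E(s, S_{nat})} / \sum_{S'} e^{-E(s, S')}},
#' computed with a log-sum-exp over the complete enumeration. Summing
#' `pnat_profile()` over all candidate natives gives exactly 1.
#'
#' @inheritParams fold_energy
#' @param native_index Index of the native fold.
#' @return `pnat()`: scalar in (0, 1); `pnat_profile()`: the full
#'   probability vector over structures.
#' @export
pnat <- function(seq, native_index, structures, energies = mj_energy_table()) {
  stop_if_not(native_index >= 1L && native_index <= structures$n_structures,
              "native_index out of range")
  E <- fold_energies(seq, structures, energies)
  exp(-E[native_index] - logsumexp(-E))
}

#' @rdname pnat
#' @export
pnat_profile <- function(seq, structures, energies = mj_energy_table()) {
  E <- fold_energies(seq, structures, energies)
  p <- exp(-E - logsumexp(-E))
  p / sum(p)
}

#' Design a synthetic lattice-protein alignment
#'
#' Metropolis MCMC over sequences with stationary weight
#' \eqn{p_{nat}^\beta} for the chosen native fold: single-site substitutions
#' uniform over the 19 alternatives, inverse temperature annealed from
#' `beta0` to `beta1` during burn-in. After burn-in, the chain is recorded
#' every `stride` sweeps whenever \eqn{p_{nat} >} `pnat_min`, until
#' `n_sequences` are collected. This is the package's synthetic-data
#' generator: the returned gap-free MSA of high-stability sequences plays
#' the role of a protein family whose ground-truth contacts and fitness are
#' exactly known.
#'
#' @param structures A `lattice_structures` object (full enumeration).
#' @param native_index Native fold index.
#' @param n_sequences Number of sequences to design.
#' @param pnat_min Retention threshold on the exact fold probability
#'   (default 0.99).
#' @param energies Energy table.
#' @param stride Sweeps between recorded samples (default 5).
#' @param burnin Burn-in sweeps (default 500).
#' @param beta0,beta1 Initial and final inverse temperature on
#'   \eqn{\log p_{nat}} (defaults 5 and 1000).
#' @param seed Integer seed.
#' @param max_sweep_factor Abort guard: give up (with diagnostics) after
#'   this multiple of the nominal sweep budget.
#' @param active_size,refresh_every Cost control of the Metropolis target:
#'   the fold-probability denominator is evaluated over the `active_size`
#'   lowest-energy competitor folds, refreshed every `refresh_every` sweeps
#'   by an exact pass over the complete ensemble (suppressed competitors
#'   contribute negligibly in between). Recorded sequences are always scored
#'   and filtered with the exact full-ensemble probability.
#' @param reheat_after If no sample has been collected for this many sweeps
#'   the annealing restarts from `beta0` (escapes frozen sub-threshold
#'   basins); 0 disables.
#' @return An `rbm_alignment` over the 20-letter (gap-free) alphabet with
#'   attributes `pnat` (per-sequence recomputable fold probability),
#'   `native_index` and `accept_rate`.
#' @export
design_msa <- function(structures, native_index, n_sequences,
                       pnat_min = 0.99, energies = mj_energy_table(),
                       stride = 5L, burnin = 500L, beta0 = 5, beta1 = 1000,
                       seed = 1L, max_sweep_factor = 20, active_size = 2000L,
                       refresh_every = 5L, reheat_after = 300L) {
  stop_if_not(n_sequences >= 1L, "n_sequences must be >= 1")
  set.seed(seed)
  n <- structures$n_sites
  seq0 <- sample.int(20L, n, replace = TRUE)
  res <- design_mcmc_cpp(structures$contact_i, structures$contact_j,
                         as.integer(native_index) - 1L, unname(energies),
                         seq0, as.integer(n_sequences), pnat_min,
                         as.integer(stride), as.integer(burnin),
                         beta0, beta1, max_sweep_factor,
                         as.integer(active_size), as.integer(refresh_every),
                         as.integer(reheat_after))
  if (res$n_collected < n_sequences) {
    stop("sequence design collapsed: collected ", res$n_collected, " of ",
         n_sequences, " sequences after ", res$sweeps,
         " sweeps (acceptance rate ", format(res$accept_rate, digits = 3),
         "); raise beta1 or lower pnat_min", call. = FALSE)
  }
  aln <- new_alignment(res$samples,
                       sprintf("lp_design_%d", seq_len(n_sequences)),
                       aa_alphabet(gap = FALSE))
  attr(aln, "pnat") <- as.numeric(res$pnat)
  attr(aln, "native_index") <- native_index
  attr(aln, "accept_rate") <- res$accept_rate
  aln
}

#' Ground-truth contact map of a fold
#'
#' Every site pair of the chain labeled by whether it is a native contact
#' of the chosen structure; the truth table consumed by [ppv_curve()].
#'
#' @inheritParams design_msa
#' @return Tibble with columns `i`, `j` (`i < j`) and `is_contact`.
#' @export
lattice_contact_map <- function(structures, native_index) {
  n <- structures$n_sites
  ci <- structures$contact_i[native_index, ]
  cj <- structures$contact_j[native_index, ]
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  key <- paste(ut[, 1], ut[, 2])
  tibble::tibble(i = ut[, 1], j = ut[, 2],
                 is_contact = key %in% paste(pmin(ci, cj), pmax(ci, cj)))
}
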
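# Independent R enumerator for the 2-cube: all directed Hamiltonian walks by
# DFS, then canonical dedup under the 48 cube symmetries (reversal distinct).
r_enumerate_2cube <- function() {
  coords <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  n <- 8
  adj <- function(a, b) sum(abs(coords[a, ] - coords[b, ])) == 1
  paths <- list()
  dfs <- function(path, used) {
    if (length(path) == n) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (nx in seq_len(n)) {
      if (!used[nx] && adj(path[length(path)], nx)) {
        used[nx] <- TRUE
        dfs(c(path, nx), used)
        used[nx] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    u <- rep(FALSE, n); u[s] <- TRUE
    dfs(s, u)
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  canon <- function(p) {
    best <- NULL
    for (pm in perms) {
      for (r in 0:7) {
        co <- coords[p, pm, drop = FALSE]
        for (k in 1:3) if (bitwAnd(r, bitwShiftL(1L, k - 1L)) > 0) {
          co[, k] <- 1 - co[, k]
        }
        id <- co[, 1] + 2 * co[, 2] + 4 * co[, 3]
        ss <- paste(id, collapse = ",")
        if (is.null(best) || ss < best) best <- ss
      }
    }
    best
  }
  list(n_directed = length(paths),
       classes = sort(unique(vapply(paths, canon, character(1)))))
}

test_that("two independent enumerators agree on the 2-cube", {
  st <- enumerate_structures(2)
  oracle <- r_enumerate_2cube()
  expect_equal(attr(st, "n_directed"), oracle$n_directed)
  expect_equal(st$n_structures, length(oracle$classes))
  cpp_classes <- sort(apply(st$cells, 1, paste, collapse = ","))
  expect_identical(cpp_classes, oracle$classes)
  # every compact 8-mer fold has the same contact count:
  # 12 cube edges minus 7 chain bonds
  expect_equal(ncol(st$contact_i), 5L)
  expect_error(enumerate_structures(4), "cube_edge")
})

test_that("structure caches round-trip exactly", {
  st <- enumerate_structures(2)
  f <- withr::local_tempfile(fileext = ".cache")
  st1 <- enumerate_structures(2, cache = f)
  expect_true(file.exists(f))
  st2 <- enumerate_structures(2, cache = f)
  expect_identical(st1$cells, st$cells)
  expect_identical(st2$cells, st$cells)
  expect_identical(st2$contact_i, st$contact_i)
})

test_that("the bundled contact-energy table is a valid symmetric potential", {
  tab <- mj_energy_table()
  expect_equal(dim(tab), c(20L, 20L))
  expect_identical(rownames(tab), aa_alphabet(gap = FALSE))
  expect_equal(tab, t(tab))
  expect_true(all(tab < 0))
  # hydrophobic pairs bind far more strongly than charged-charged repulsive-ish
  expect_lt(tab["F", "F"], tab["K", "K"])
})

test_that("fold energies match an independent loop and the homopolymer rule", {
  st <- enumerate_structures(2)
  tab <- mj_energy_table()
  # homopolymer: every structure has equal energy n_contacts * e(A, A)
  E <- fold_energies(rep(1L, 8), st, tab)
  expect_equal(E, rep(5 * tab["A", "A"], st$n_structures),
               ignore_attr = TRUE)
  # random sequence/structure against an explicit double loop
  set.seed(81)
  s <- sample.int(20L, 8, replace = TRUE)
  for (k in seq_len(st$n_structures)) {
    eref <- 0
    for (c in seq_len(ncol(st$contact_i))) {
      eref <- eref + tab[s[st$contact_i[k, c]], s[st$contact_j[k, c]]]
    }
    expect_equal(fold_energy(s, k, st, tab), eref, ignore_attr = TRUE)
  }
  # character input and gap rejection
  expect_equal(fold_energies(paste(rep("A", 8), collapse = ""), st, tab), E)
  expect_error(fold_energies(c(s[-8], 21L), st, tab), "amino acids only")
  # a toy table counting only C-C pairs
  toy <- matrix(0, 20, 20, dimnames = list(aa_alphabet(FALSE), aa_alphabet(FALSE)))
  toy["C", "C"] <- -1
  sC <- rep(1L, 8); sC[c(1, 4, 6)] <- 2L  # C at chain positions 1, 4, 6
  EC <- fold_energies(sC, st, toy)
  for (k in seq_len(st$n_structures)) {
    cc <- sum(sC[st$contact_i[k, ]] == 2L & sC[st$contact_j[k, ]] == 2L)
    expect_equal(EC[k], -cc)
  }
})

test_that("fold probabilities are exact, normalized and symmetry-covariant", {
  st <- enumerate_structures(2)
  tab <- mj_energy_table()
  # homopolymer: all energies equal, pnat uniform over structures
  expect_equal(pnat(rep(3L, 8), 2, st, tab), 1 / st$n_structures,
               tolerance = 1e-12)
  set.seed(82)
  s <- sample.int(20L, 8, replace = TRUE)
  # brute-force plain double-precision sum (no log-sum-exp) on the small cube
  E <- fold_energies(s, st, tab)
  expect_equal(pnat(s, 1, st, tab), exp(-E[1]) / sum(exp(-E)),
               tolerance = 1e-12)
  # profile sums to one over candidate natives
  expect_equal(sum(pnat_profile(s, st, tab)), 1, tolerance = 1e-12)
  # relabeling amino acids by a permutation (with the table permuted
  # accordingly) leaves every fold probability unchanged
  perm <- sample.int(20L)
  tab_p <- tab[order(perm), order(perm)]
  dimnames(tab_p) <- dimnames(tab)
  expect_equal(pnat_profile(perm[s], st, tab_p), pnat_profile(s, st, tab),
               tolerance = 1e-12)
  # dominance limit: a toy table making native contacts strongly favorable
  toy <- matrix(0, 20, 20, dimnames = list(aa_alphabet(FALSE), aa_alphabet(FALSE)))
  toy["C", "C"] <- -40
  sC <- rep(1L, 8)
  sC[c(st$contact_i[1, 1], st$contact_j[1, 1])] <- 2L
  shared <- sapply(seq_len(st$n_structures), function(k) {
    sum(sC[st$contact_i[k, ]] == 2L & sC[st$contact_j[k, ]] == 2L)
  })
  if (sum(shared == max(shared)) == 1) {
    expect_gt(pnat(sC, 1, st, toy), 0.99)
  }
  expect_error(pnat(s, 99, st, tab), "native_index")
})

test_that("sequence design yields reproducible high-stability alignments", {
  st <- enumerate_structures(2)
  tab <- mj_energy_table()
  msa <- design_msa(st, 1, n_sequences = 40, pnat_min = 0.5, stride = 3,
                    burnin = 100, beta1 = 300, seed = 9, active_size = 3,
                    refresh_every = 2)
  expect_s3_class(msa, "rbm_alignment")
  expect_equal(dim(msa$codes), c(40L, 8L))
  expect_identical(msa$alphabet, aa_alphabet(gap = FALSE))
  # every retained sequence satisfies the threshold by direct recomputation
  pn <- vapply(seq_len(40), function(k) pnat(msa$codes[k, ], 1, st, tab),
               numeric(1))
  expect_true(all(pn > 0.5))
  expect_equal(pn, attr(msa, "pnat"), tolerance = 1e-10)
  # fixed seed reproduces the MSA exactly
  msa2 <- design_msa(st, 1, n_sequences = 40, pnat_min = 0.5, stride = 3,
                     burnin = 100, beta1 = 300, seed = 9, active_size = 3,
                     refresh_every = 2)
  expect_identical(msa$codes, msa2$codes)
  # diversity: sequences are not collapsed, and decorrelation grows with stride
  d3 <- mean(rbmsa:::pairwise_hamming(msa$codes))
  expect_gt(d3, 0)
  msa_s1 <- design_msa(st, 1, n_sequences = 40, pnat_min = 0.5, stride = 1,
                       burnin = 100, beta1 = 300, seed = 9, active_size = 3,
                       refresh_every = 2)
  d1 <- mean(rbmsa:::pairwise_hamming(msa_s1$codes))
  expect_gte(d3, d1 * 0.8)  # trend with tolerance for MC noise
  # an impossible threshold aborts with diagnostics
  expect_error(design_msa(st, 1, n_sequences = 5, pnat_min = 0.999999,
                          burnin = 10, beta1 = 50, seed = 1, active_size = 3,
                          max_sweep_factor = 3), "collapsed")
})

test_that("native contact maps label every site pair", {
  st <- enumerate_structures(2)
  cm <- lattice_contact_map(st, 1)
  expect_equal(nrow(cm), choose(8, 2))
  expect_equal(sum(cm$is_contact), 5L)
  expect_true(all(cm$i < cm$j))
  pairs <- paste(pmin(st$contact_i[1, ], st$contact_j[1, ]),
                 pmax(st$contact_i[1, ], st$contact_j[1, ]))
  expect_setequal(paste(cm$i, cm$j)[cm$is_contact], pairs)
})
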
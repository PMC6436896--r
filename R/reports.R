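#' Hidden-unit input distributions over an alignment
#'
#' For each hidden unit, the reweighted histogram of inputs
#' \eqn{I_\mu(v)} across the MSA (the quantity whose multimodality flags
#' subfamily-separating units), together with the conditional mean-activity
#' curve \eqn{\langle h\rangle(I) = d\Gamma/dI} sampled over the observed
#' input range. Histogram mass totals the sum of sequence weights.
#'
#' @param params An [rbm].
#' @param aln Alignment.
#' @param weights Sequence weights (default uniform).
#' @param breaks Binning rule: `"fd"` (Freedman–Diaconis, default), a bin
#'   count, or a breaks vector, per unit.
#' @param curve_points Number of points of the activity curve.
#' @return List with `histogram` (tibble: `unit`, `mid`, `lower`, `upper`,
#'   `weight`) and `activity` (tibble: `unit`, `input`, `mean_activity`).
#' @export
input_distributions <- function(params, aln, weights = NULL, breaks = "fd",
                                curve_points = 200L) {
  I <- compute_inputs(params, aln$codes)
  w <- weights %||% rep(1, nrow(aln$codes))
  hs <- list(); cs <- list()
  for (mu in seq_len(params$M)) {
    x <- I[, mu]
    brk <- if (is.character(breaks)) {
      if (diff(range(x)) < 1e-12) {
        c(x[1] - 0.5, x[1] + 0.5)
      } else {
        nb <- max(1L, grDevices::nclass.FD(x))
        seq(min(x), max(x), length.out = nb + 1L)
      }
    } else if (length(breaks) == 1L) {
      seq(min(x), max(x) + 1e-12, length.out = breaks + 1L)
    } else breaks
    bin <- cut(x, brk, include.lowest = TRUE)
    mass <- as.vector(rowsum(w, group = bin, reorder = TRUE))
    hs[[mu]] <- tibble::tibble(unit = mu,
                               lower = utils::head(brk, -1L),
                               upper = brk[-1L],
                               mid = (utils::head(brk, -1L) + brk[-1L]) / 2,
                               weight = mass)
    grid <- seq(min(x), max(x), length.out = curve_points)
    Ig <- matrix(0, curve_points, params$M)
    Ig[, mu] <- grid
    cs[[mu]] <- tibble::tibble(unit = mu, input = grid,
                               mean_activity = mean_activity(params$pot, Ig)[, mu])
  }
  list(histogram = dplyr::bind_rows(hs), activity = dplyr::bind_rows(cs))
}

#' Hamming-distance diagnostics of a hidden unit
#'
#' Compares the distribution of pairwise Hamming distances across the whole
#' MSA with the distances among the `k` sequences most strongly driving a
#' hidden unit (`direction` picks the largest or the smallest inputs).
#' Feature-like units recruit sequences scattered across the family (the
#' two histograms coincide); phylogenetic units recruit a tight cluster
#' (top-`k` histogram shifted towards zero). For large alignments the MSA
#' background is subsampled to at most `max_pairs` pairs.
#'
#' @param params An [rbm].
#' @param aln Alignment.
#' @param unit Hidden-unit index.
#' @param k Number of top sequences (20 or 100 are customary).
#' @param direction `"largest"` or `"smallest"` inputs.
#' @param max_pairs Subsampling cap for the background distances.
#' @return Tibble with columns `set` (`"msa"`/`"top"`) and `distance`.
#' @export
hamming_diagnostics <- function(params, aln, unit, k = 20L,
                                direction = c("largest", "smallest"),
                                max_pairs = 1e6) {
  direction <- match.arg(direction)
  B <- nrow(aln$codes)
  stop_if_not(k <= B, "k exceeds the number of sequences")
  I <- compute_inputs(params, aln$codes)[, unit]
  ord <- order(I, decreasing = (direction == "largest"))
  top <- aln$codes[ord[seq_len(k)], , drop = FALSE]
  d_top <- pairwise_hamming(top)
  n_pairs <- B * (B - 1) / 2
  if (n_pairs > max_pairs) {
    i1 <- sample.int(B, max_pairs, replace = TRUE)
    i2 <- sample.int(B, max_pairs, replace = TRUE)
    keep <- i1 != i2
    d_msa <- rowSums(aln$codes[i1[keep], , drop = FALSE] !=
                       aln$codes[i2[keep], , drop = FALSE])
  } else {
    d_msa <- pairwise_hamming(aln$codes)
  }
  dplyr::bind_rows(tibble::tibble(set = "msa", distance = d_msa),
                   tibble::tibble(set = "top", distance = d_top))
}

pairwise_hamming <- function(codes) {
  B <- nrow(codes)
  if (B < 2L) return(numeric(0))
  idx <- which(upper.tri(matrix(0, B, B)), arr.ind = TRUE)
  rowSums(codes[idx[, 1], , drop = FALSE] != codes[idx[, 2], , drop = FALSE])
}

#' Ranked per-unit reports with logo-ready weight matrices
#'
#' Summarizes every hidden unit by its (squared) weight norm and weight
#' sparsity — the participation ratio of the per-site weight mass
#' \eqn{m_i = \sum_v w_{i\mu}(v)^2}, i.e.
#' \eqn{PR_\mu = 1/\sum_i (m_i/\sum_j m_j)^2}, which is 1 for a single-site
#' unit and `N` for a uniformly spread one — and ranks units by norm
#' (descending) or sparsity (ascending participation ratio). Ties break by
#' unit index. The per-unit `N x q` weight matrices (1-based positions,
#' alphabet-ordered columns) are returned for export to any sequence-logo
#' renderer; the model itself is never modified.
#'
#' @param params An [rbm].
#' @param aln Optional alignment: when given, top-activating sequence ids
#'   are included per unit.
#' @param weights Sequence weights for the input histograms.
#' @param rank_by `"norm"` or `"sparsity"`.
#' @param top_k Number of top-activating sequence ids to record.
#' @return List with `summary` (tibble: `rank`, `unit`, `weight_norm`,
#'   `participation_ratio`, and `top_ids` list-column when `aln` is given)
#'   and `weight_matrices` (list of `N x q` matrices, by original unit).
#' @export
export_unit_reports <- function(params, aln = NULL, weights = NULL,
                                rank_by = c("norm", "sparsity"), top_k = 20L) {
  rank_by <- match.arg(rank_by)
  norms <- weight_norms(params)
  pr <- vapply(seq_len(params$M), function(mu) {
    m <- rowSums(matrix(params$w[, , mu], params$N, params$q)^2)
    if (sum(m) == 0) return(NA_real_)
    p <- m / sum(m)
    1 / sum(p^2)
  }, numeric(1))
  ord <- if (rank_by == "norm") {
    order(-norms, seq_len(params$M))
  } else {
    order(pr, seq_len(params$M), na.last = TRUE)
  }
  summary <- tibble::tibble(rank = seq_len(params$M), unit = ord,
                            weight_norm = norms[ord],
                            participation_ratio = pr[ord])
  if (!is.null(aln)) {
    I <- compute_inputs(params, aln$codes)
    summary$top_ids <- lapply(ord, function(mu) {
      aln$ids[order(-abs(I[, mu]))[seq_len(min(top_k, nrow(aln$codes)))]]
    })
  }
  mats <- lapply(seq_len(params$M), function(mu) {
    m <- matrix(params$w[, , mu], params$N, params$q,
                dimnames = list(seq_len(params$N), params$alphabet))
    m
  })
  list(summary = summary, weight_matrices = mats)
}

#' Write a logo-ready weight matrix
#'
#' Plain whitespace-separated text: one row per position (1-based), one
#' column per alphabet symbol — directly consumable by standard logo
#' renderers.
#'
#' @param mat An `N x q` weight matrix (see [export_unit_reports()]).
#' @param path Output file.
#' @export
write_weight_matrix <- function(mat, path) {
  utils::write.table(mat, path, quote = FALSE, sep = "\t", col.names = NA)
  invisible(path)
}
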
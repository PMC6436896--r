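#' Amino-acid alphabet
#'
#' The canonical ordered alphabet used throughout the package: the 20 amino
#' acids in alphabetical one-letter order, optionally followed by the
#' alignment gap `-` as the 21st symbol. The ordering is fixed and persisted
#' inside model archives so that trained models are portable.
#'
#' @param gap Include the gap symbol as the last letter (default `TRUE`).
#' @return Character vector of length 21 (or 20).
#' @export
aa_alphabet <- function(gap = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (gap) c(aa, "-") else aa
}

new_alignment <- function(codes, ids, alphabet) {
  storage.mode(codes) <- "integer"
  stop_if_not(all(codes >= 1L & codes <= length(alphabet)),
              "alignment codes out of alphabet range")
  structure(list(codes = codes, ids = as.character(ids), alphabet = alphabet),
            class = "rbm_alignment")
}

#' @export
print.rbm_alignment <- function(x, ...) {
  cat("<rbm_alignment> B =", nrow(x$codes), "sequences, N =", ncol(x$codes),
      "sites, q =", length(x$alphabet), "\n")
  invisible(x)
}

#' @export
dim.rbm_alignment <- function(x) dim(x$codes)

#' Encode / decode aligned sequences
#'
#' `encode_sequences()` converts equal-length character strings over the
#' package alphabet into an integer matrix with entries in `1..q`
#' (site i of sequence b at `[b, i]`). Letters outside the alphabet are
#' mapped according to `unknown`: to the gap symbol (default) or an error.
#' `decode_sequences()` inverts the coding.
#'
#' @param x Character vector of aligned sequences (equal lengths).
#' @param alphabet Ordered symbol set; see [aa_alphabet()].
#' @param unknown Policy for unrecognized letters: `"gap"` or `"error"`.
#' @return `encode_sequences()`: integer matrix `B x N`;
#'   `decode_sequences()`: character vector of sequences.
#' @export
encode_sequences <- function(x, alphabet = aa_alphabet(),
                             unknown = c("gap", "error")) {
  unknown <- match.arg(unknown)
  stop_if_not(length(x) > 0L, "empty input: no sequences to encode")
  lens <- nchar(x)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(utils::head(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(toupper(x), "", fixed = TRUE), use.names = FALSE),
                  nrow = length(x), byrow = TRUE)
  codes <- match(chars, alphabet)
  if (anyNA(codes)) {
    if (unknown == "error") {
      bad <- unique(chars[is.na(codes)])
      stop("unknown residue letters: ", paste(bad, collapse = " "), call. = FALSE)
    }
    gap_code <- match("-", alphabet)
    stop_if_not(!is.na(gap_code), "alphabet has no gap symbol to map unknowns to")
    codes[is.na(codes)] <- gap_code
  }
  matrix(as.integer(codes), nrow = length(x))
}

#' @rdname encode_sequences
#' @param codes Integer matrix as produced by `encode_sequences()`.
#' @export
decode_sequences <- function(codes, alphabet = aa_alphabet()) {
  apply(codes, 1L, function(r) paste(alphabet[r], collapse = ""))
}

#' Read an aligned protein family
#'
#' Reads an aligned FASTA file or a PFAM-dialect Stockholm file into an
#' integer-coded alignment over the 21-letter alphabet (20 amino acids +
#' gap). For Stockholm input, insert states (lowercase letters and `.`)
#' follow the PFAM convention: every column containing an insert state is
#' discarded before coding. FASTA input is assumed insert-free; a match-column
#' mask can be applied afterwards with [preprocess_alignment()].
#'
#' @param path File path.
#' @param format `"fasta"` or `"stockholm"`.
#' @param alphabet Ordered symbol set (gap last).
#' @param unknown Policy for unrecognized residue letters (`"gap"` maps them
#'   to the gap symbol; `"error"` aborts).
#' @return An `rbm_alignment`: list with integer `codes` (`B x N`), `ids`,
#'   and the `alphabet`.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm"),
                           alphabet = aa_alphabet(),
                           unknown = c("gap", "error")) {
  format <- match.arg(format)
  unknown <- match.arg(unknown)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    seqs <- as.character(set)
    ids <- sub("\\s.*$", "", names(set))
  } else {
    sto <- read_stockholm_msa(path)
    seqs <- sto$seqs
    ids <- sto$ids
    # PFAM insert convention: drop every column holding a lowercase or '.' state
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(seqs), byrow = TRUE)
    is_insert <- apply(chars, 2L, function(col) any(col == "." | col %in% letters))
    chars <- chars[, !is_insert, drop = FALSE]
    if (ncol(chars) == 0L) stop("no match columns left after insert removal",
                                call. = FALSE)
    seqs <- apply(chars, 1L, paste, collapse = "")
  }
  codes <- encode_sequences(seqs, alphabet = alphabet, unknown = unknown)
  new_alignment(codes, ids, alphabet)
}

# Minimal Stockholm reader (sequence lines only; the installed FASTA-oriented
# readers reject the lowercase insert states PFAM files carry, so the
# line-oriented format is parsed directly). Multi-block files are supported.
read_stockholm_msa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  keep <- !grepl("^(#|//|\\s*$)", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no sequence records in Stockholm file: ", path,
                                call. = FALSE)
  parts <- regmatches(lines, regexpr("^\\S+", lines))
  seqs_part <- sub("^\\S+\\s+", "", lines)
  seqs <- vapply(split(seqs_part, factor(parts, levels = unique(parts))),
                 paste0, character(1), collapse = "")
  list(ids = names(seqs), seqs = unname(seqs))
}

#' Write an alignment to aligned FASTA
#'
#' @param aln An `rbm_alignment`.
#' @param path Output file.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(decode_sequences(aln$codes, aln$alphabet))
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Preprocess an alignment: drop insert columns, remove duplicates
#'
#' Mirrors the standard preparation of a PFAM family for model fitting:
#' columns flagged as inserts are discarded (for FASTA exports a logical
#' match-column mask can be supplied; Stockholm inserts are already removed
#' at read time), then exact duplicate sequences are removed keeping the
#' first occurrence (ids are ignored for the comparison). Idempotent.
#'
#' @param aln An `rbm_alignment`.
#' @param match_columns Optional logical vector of length `N`; columns with
#'   `FALSE` are discarded.
#' @return The filtered `rbm_alignment`.
#' @export
preprocess_alignment <- function(aln, match_columns = NULL) {
  codes <- aln$codes
  if (!is.null(match_columns)) {
    stop_if_not(length(match_columns) == ncol(codes),
                "match_columns mask length must equal alignment width")
    codes <- codes[, as.logical(match_columns), drop = FALSE]
  }
  key <- apply(codes, 1L, paste, collapse = ",")
  first <- !duplicated(key)
  new_alignment(codes[first, , drop = FALSE], aln$ids[first], aln$alphabet)
}

#' Phylogenetic sequence reweighting
#'
#' Each sequence receives weight `1 / n_l`, where `n_l` is the number of
#' sequences (itself included) with strictly more than
#' `identity_threshold` fractional identity to it. Identity is the fraction
#' of matching columns over all `N` columns, with the gap treated as an
#' ordinary 21st symbol. Weights lie in `[1/B, 1]`; a sequence with no close
#' neighbor gets weight exactly 1. The sum of weights is the effective
#' number of independent sequences.
#'
#' @param aln An `rbm_alignment` (normally deduplicated).
#' @param identity_threshold Fractional identity cutoff in (0, 1]; default
#'   0.9 (neighbors are sequences with > 90% identity).
#' @return Numeric vector of per-sequence weights, named by sequence id.
#' @export
compute_sequence_weights <- function(aln, identity_threshold = 0.9) {
  stop_if_not(identity_threshold > 0 && identity_threshold <= 1,
              "identity_threshold must lie in (0, 1]")
  cnt <- identity_neighbor_counts(aln$codes, identity_threshold)
  stats::setNames(1 / cnt, aln$ids)
}

#' Reweighted data average
#'
#' The weighted mean \eqn{\sum_l w_l f_l / \sum_l w_l} used for every
#' "average over the MSA" in the package.
#'
#' @param values Per-sequence numeric values.
#' @param w Per-sequence weights (see [compute_sequence_weights()]).
#' @return Scalar weighted mean.
#' @export
weighted_average <- function(values, w) {
  stop_if_not(length(values) == length(w), "values and weights differ in length")
  tot <- sum(w)
  stop_if_not(tot > 0, "total weight is zero")
  sum(w * values) / tot
}

#' Split an alignment into training and test sets
#'
#' Random disjoint partition, reproducible under `seed`. Sequence weights
#' are recomputed on the training split only (held-out sequences must not
#' influence training-set reweighting).
#'
#' @param aln An `rbm_alignment` with `B >= 2`.
#' @param test_fraction Fraction held out, in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @param weights Recompute training weights (default `TRUE`).
#' @param identity_threshold Passed to [compute_sequence_weights()].
#' @return List with elements `train`, `test` (both `rbm_alignment`) and,
#'   when `weights` is `TRUE`, `train_weights`.
#' @export
train_test_split <- function(aln, test_fraction = 0.2, seed = 1L,
                             weights = TRUE, identity_threshold = 0.9) {
  stop_if_not(test_fraction > 0 && test_fraction < 1,
              "test_fraction must lie in (0, 1)")
  B <- nrow(aln$codes)
  stop_if_not(B >= 2L, "need at least two sequences to split")
  n_test <- max(1L, round(test_fraction * B))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  test_idx <- sort(sample.int(B, n_test))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  train_idx <- setdiff(seq_len(B), test_idx)
  train <- new_alignment(aln$codes[train_idx, , drop = FALSE],
                         aln$ids[train_idx], aln$alphabet)
  test <- new_alignment(aln$codes[test_idx, , drop = FALSE],
                        aln$ids[test_idx], aln$alphabet)
  out <- list(train = train, test = test)
  if (weights) {
    out$train_weights <- compute_sequence_weights(train, identity_threshold)
  }
  out
}

#' Write per-sequence weights to TSV
#'
#' @param w Named weight vector from [compute_sequence_weights()].
#' @param path Output file.
#' @export
write_sequence_weights <- function(w, path) {
  utils::write.table(data.frame(id = names(w), weight = as.numeric(w)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
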
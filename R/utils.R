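# Internal numeric helpers shared across modules.

# log(sum(exp(x))) without overflow; handles -Inf inputs.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

# log(exp(a) + exp(b)) elementwise, overflow-safe.
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  # when both are -Inf pmin-pmax arithmetic yields NaN; the sum is -Inf
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

# Draw standard Gumbel noise, used for vectorized categorical sampling.
rgumbel <- function(n) -log(-log(stats::runif(n)))
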
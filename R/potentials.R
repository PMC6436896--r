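#' Hidden-unit potentials
#'
#' A hidden-unit layer is described by a potential family shared by all `M`
#' units, with unit-specific parameters. Three families are supported:
#' * `gaussian`: \eqn{U(h) = \gamma h^2/2 + \theta h}, curvature `gamma > 0`;
#' * `drelu` (double rectified linear): four parameters per unit,
#'   \eqn{U(h) = \gamma_+ h_+^2/2 + \gamma_- h_-^2/2 + \theta_+ h_+ + \theta_- h_-}
#'   with \eqn{h_+ = \max(h,0)}, \eqn{h_- = \min(h,0)}; spans quadratic,
#'   bimodal and one-sided behaviors;
#' * `bernoulli`: binary unit \eqn{h \in \{0,1\}} with field `b`.
#'
#' Scalar parameters are recycled across units.
#'
#' @param gamma,theta Gaussian curvature (> 0) and tilt.
#' @param gamma_plus,gamma_minus,theta_plus,theta_minus dReLU parameters;
#'   curvatures must be strictly positive.
#' @param b Bernoulli field.
#' @param M Number of hidden units.
#' @return An object of class `hidden_potential`.
#' @examples
#' pot <- hidden_drelu(1, 1, 0, 0, M = 4)
#' cgf(pot, c(0, 1, 2, 3))
#' @name hidden_potential
NULL

#' @rdname hidden_potential
#' @export
hidden_gaussian <- function(gamma = 1, theta = 0, M = max(length(gamma), length(theta))) {
  stop_if_not(all(gamma > 0), "gaussian curvature `gamma` must be > 0")
  structure(list(variant = "gaussian",
                 M = M,
                 gamma = rep_len(as.numeric(gamma), M),
                 theta = rep_len(as.numeric(theta), M)),
            class = "hidden_potential")
}

#' @rdname hidden_potential
#' @export
hidden_drelu <- function(gamma_plus = 1, gamma_minus = 1,
                         theta_plus = 0, theta_minus = 0,
                         M = max(length(gamma_plus), length(gamma_minus),
                                 length(theta_plus), length(theta_minus))) {
  stop_if_not(all(gamma_plus > 0) && all(gamma_minus > 0),
              "dReLU curvatures must be > 0")
  structure(list(variant = "drelu",
                 M = M,
                 gamma_plus = rep_len(as.numeric(gamma_plus), M),
                 gamma_minus = rep_len(as.numeric(gamma_minus), M),
                 theta_plus = rep_len(as.numeric(theta_plus), M),
                 theta_minus = rep_len(as.numeric(theta_minus), M)),
            class = "hidden_potential")
}

#' @rdname hidden_potential
#' @export
hidden_bernoulli <- function(b = 0, M = length(b)) {
  structure(list(variant = "bernoulli", M = M, b = rep_len(as.numeric(b), M)),
            class = "hidden_potential")
}

#' @export
print.hidden_potential <- function(x, ...) {
  cat("<hidden_potential> variant =", x$variant, ", M =", x$M, "\n")
  invisible(x)
}

#' Scaled complementary error function used by dReLU formulas
#'
#' \eqn{\Phi(x) = e^{x^2/2}\,[1 - \mathrm{erf}(x/\sqrt2)]\,\sqrt{\pi/2}},
#' which equals \eqn{e^{x^2/2}\, \Phi_{\mathcal N}(-x)\, \sqrt{2\pi}} in terms
#' of the standard normal CDF. Strictly positive and monotonically decreasing.
#' Computed from the definition for `x < 5` and from the asymptotic expansion
#' \eqn{1/x - 1/x^3 + 3/x^5} for `x >= 5`. `log_phi()` evaluates its logarithm
#' without overflow for arbitrarily negative arguments (where \eqn{\Phi}
#' itself exceeds double-precision range).
#'
#' @param x Numeric vector.
#' @return `phi(x)`: \eqn{\Phi(x)} (may overflow to `Inf` below about -38;
#'   use `log_phi()` there); `log_phi(x)`: \eqn{\log \Phi(x)}, always finite.
#' @examples
#' phi(0)            # sqrt(pi / 2)
#' log_phi(-100)     # about 100^2 / 2 + log(sqrt(2 * pi))
#' @export
phi <- function(x) exp(log_phi(x))

#' @rdname phi
#' @export
log_phi <- function(x) {
  out <- numeric(length(x))
  lo <- x < 5
  if (any(lo)) {
    xl <- x[lo]
    out[lo] <- xl^2 / 2 + stats::pnorm(-xl, log.p = TRUE) + 0.5 * log(2 * pi)
  }
  if (any(!lo)) {
    # asymptotic series 1/x - 1/x^3 + 3/x^5 - 15/x^7 + ... ((2k-1)!! terms),
    # carried far enough that the truncation error at the branch point is
    # below the double-precision scale of the downstream moment formulas
    xh <- x[!lo]
    u <- 1 / xh^2
    s <- 1 + u * (-1 + u * (3 + u * (-15 + u * (105 + u * (-945 +
      u * (10395 + u * (-135135)))))))
    out[!lo] <- log(s / xh)
  }
  dim(out) <- dim(x)
  out
}

# Recycle a per-unit parameter across the rows of an input matrix I
# (B x M, or a length-M vector treated as one row).
.unit_par <- function(p, I) {
  if (is.matrix(I)) matrix(p, nrow(I), ncol(I), byrow = TRUE) else p
}

.as_input <- function(pot, I) {
  if (is.matrix(I)) {
    stop_if_not(ncol(I) == pot$M, "input matrix must have M columns")
    I
  } else {
    stop_if_not(length(I) == pot$M || pot$M == 1 || length(I) == 1,
                "input length must match number of hidden units")
    I
  }
}

#' Cumulant-generating function of a hidden potential
#'
#' \eqn{\Gamma(I) = \log \int dh\, e^{-U(h) + hI}}, the log-normalizer of the
#' conditional law of a hidden unit receiving input `I`. Additive constants
#' are kept (e.g. \eqn{\frac12\log(2\pi/\gamma)} for the Gaussian family) so
#' that the identity holds literally; this keeps partition-function
#' bookkeeping consistent. Smooth and convex in `I`; its derivative is the
#' conditional mean activity (see [mean_activity()]).
#'
#' @param pot A [hidden_potential] object.
#' @param I Inputs: a length-`M` vector or a `B x M` matrix (one row per
#'   visible configuration).
#' @return Numeric of the same shape as `I`.
#' @export
cgf <- function(pot, I) {
  I <- .as_input(pot, I)
  switch(pot$variant,
    gaussian = {
      g <- .unit_par(pot$gamma, I); th <- .unit_par(pot$theta, I)
      (I - th)^2 / (2 * g) + 0.5 * log(2 * pi / g)
    },
    drelu = {
      lz <- .drelu_log_z(pot, I)
      logaddexp(lz$plus, lz$minus)
    },
    bernoulli = {
      b <- .unit_par(pot$b, I)
      x <- b + I
      # softplus, overflow-safe
      pmax(x, 0) + log1p(exp(-abs(x)))
    }
  )
}

# log Z_+ and log Z_- of the dReLU mixture (Z_pm = Phi(∓(I-θ±)/√γ±)/√γ±).
.drelu_log_z <- function(pot, I) {
  gp <- .unit_par(pot$gamma_plus, I); gm <- .unit_par(pot$gamma_minus, I)
  tp <- .unit_par(pot$theta_plus, I); tm <- .unit_par(pot$theta_minus, I)
  list(plus  = log_phi(-(I - tp) / sqrt(gp)) - 0.5 * log(gp),
       minus = log_phi((I - tm) / sqrt(gm)) - 0.5 * log(gm))
}

# Conditional moments of h given input I, as needed by gradients and
# diagnostics. Returns a list of arrays shaped like I:
#   gaussian/bernoulli: h (mean), h2 (second moment)
#   drelu: additionally hp, hm, hp2, hm2 (moments of the positive and
#   negative parts) and p_plus (weight of the positive mixture component).
hidden_moments <- function(pot, I) {
  I <- .as_input(pot, I)
  switch(pot$variant,
    gaussian = {
      g <- .unit_par(pot$gamma, I); th <- .unit_par(pot$theta, I)
      m <- (I - th) / g
      list(h = m, h2 = m^2 + 1 / g)
    },
    bernoulli = {
      b <- .unit_par(pot$b, I)
      p <- stats::plogis(b + I)
      list(h = p, h2 = p)
    },
    drelu = {
      gp <- .unit_par(pot$gamma_plus, I); gm <- .unit_par(pot$gamma_minus, I)
      tp <- .unit_par(pot$theta_plus, I); tm <- .unit_par(pot$theta_minus, I)
      mup <- (I - tp) / gp; sp <- 1 / sqrt(gp)
      mum <- (I - tm) / gm; sm <- 1 / sqrt(gm)
      lz <- .drelu_log_z(pot, I)
      p_plus <- 1 / (1 + exp(lz$minus - lz$plus))
      # inverse Mills ratios via Phi; 1/Inf -> 0 handles deep tails
      lam_p <- exp(-log_phi(-mup / sp))   # lambda(alpha), alpha = -mu/sigma
      lam_m <- exp(-log_phi(mum / sm))
      ep  <- mup + sp * lam_p             # E[TN(mu+, s+, 0, inf)]
      em  <- mum - sm * lam_m             # E[TN(mu-, s-, -inf, 0)]
      ep2 <- mup^2 + sp^2 + mup * sp * lam_p
      em2 <- mum^2 + sm^2 - mum * sm * lam_m
      hp <- p_plus * ep;  hm <- (1 - p_plus) * em
      hp2 <- p_plus * ep2; hm2 <- (1 - p_plus) * em2
      list(h = hp + hm, h2 = hp2 + hm2,
           hp = hp, hm = hm, hp2 = hp2, hm2 = hm2, p_plus = p_plus)
    }
  )
}

#' Conditional mean activity of a hidden unit
#'
#' \eqn{\langle h \rangle(I) = d\Gamma/dI}: linear in `I` for Gaussian units,
#' sigmoidal for Bernoulli units, and a smooth interpolation between two
#' linear branches for dReLU units.
#'
#' @inheritParams cgf
#' @return Numeric of the same shape as `I`.
#' @export
mean_activity <- function(pot, I) hidden_moments(pot, I)$h

#' Conditional distribution of a hidden unit given its input
#'
#' For Gaussian units the conditional is normal with mean \eqn{(I-\theta)/\gamma}
#' and variance \eqn{1/\gamma}. For dReLU units it is a mixture of two
#' truncated Gaussians,
#' \eqn{P(h|I) = p_+ TN((I-\theta_+)/\gamma_+, 1/\gamma_+, 0, \infty)
#'            + p_- TN((I-\theta_-)/\gamma_-, 1/\gamma_-, -\infty, 0)},
#' with mixture weights \eqn{p_\pm = Z_\pm/(Z_+ + Z_-)},
#' \eqn{Z_\pm = \Phi(\mp(I-\theta_\pm)/\sqrt{\gamma_\pm})/\sqrt{\gamma_\pm}}.
#' For Bernoulli units it is Bernoulli with success probability
#' \eqn{\sigma(b + I)}.
#'
#' @inheritParams cgf
#' @param I A single input value (scalar) or one value per unit.
#' @return A list describing the distribution: fields depend on the variant
#'   (`mean`/`var` for gaussian; `p_plus`, `mode_plus`, `sd_plus`,
#'   `mode_minus`, `sd_minus`, plus overall `mean`/`var`, for drelu;
#'   `prob` for bernoulli).
#' @export
hidden_conditional <- function(pot, I) {
  I <- .as_input(pot, I)
  mom <- hidden_moments(pot, I)
  switch(pot$variant,
    gaussian = list(variant = "gaussian",
                    mean = mom$h, var = 1 / .unit_par(pot$gamma, I)),
    bernoulli = list(variant = "bernoulli", prob = mom$h),
    drelu = {
      gp <- .unit_par(pot$gamma_plus, I); gm <- .unit_par(pot$gamma_minus, I)
      tp <- .unit_par(pot$theta_plus, I); tm <- .unit_par(pot$theta_minus, I)
      list(variant = "drelu",
           p_plus = mom$p_plus,
           mode_plus = (I - tp) / gp, sd_plus = 1 / sqrt(gp),
           mode_minus = (I - tm) / gm, sd_minus = 1 / sqrt(gm),
           mean = mom$h, var = mom$h2 - mom$h^2)
    }
  )
}

#' Sample from a one-sided truncated Gaussian
#'
#' Draws from \eqn{TN(\mu, \sigma^2, 0, \infty)} (`side = "positive"`) or
#' \eqn{TN(\mu, \sigma^2, -\infty, 0)} (`side = "negative"`), where \eqn{\mu}
#' is the mode of the untruncated Gaussian. Uses the inverse CDF in the bulk
#' and an exponential-proposal rejection sampler when the support excludes
#' the mode by more than 4 standard deviations, so draws remain exact and
#' fast arbitrarily deep in the tail.
#'
#' @param mu Mode(s) of the untruncated Gaussian (recycled).
#' @param sigma2 Variance(s), strictly positive (recycled).
#' @param side `"positive"` or `"negative"`.
#' @param n Number of draws; defaults to `length(mu)`.
#' @return Numeric vector of `n` draws strictly inside the support.
#' @export
sample_truncated_normal <- function(mu, sigma2, side = c("positive", "negative"),
                                    n = length(mu)) {
  side <- match.arg(side)
  stop_if_not(all(sigma2 > 0), "sigma2 must be > 0")
  mu <- rep_len(mu, n); sigma <- rep_len(sqrt(sigma2), n)
  if (side == "negative") {
    return(-sample_truncated_normal(-mu, sigma^2, "positive", n))
  }
  alpha <- -mu / sigma                    # truncation point in z-units
  out <- numeric(n)
  bulk <- alpha <= 4
  if (any(bulk)) {
    a <- alpha[bulk]
    p <- stats::pnorm(a)
    u <- pmin(stats::runif(sum(bulk)), 1 - 1e-12)
    z <- stats::qnorm(p + u * (1 - p))
    # guard the rare qnorm saturation at the boundary
    z <- pmax(z, a + 1e-12)
    out[bulk] <- mu[bulk] + sigma[bulk] * z
  }
  if (any(!bulk)) {
    # Robert (1995) exponential rejection for far-tail truncation
    idx <- which(!bulk)
    a <- alpha[idx]
    lam <- (a + sqrt(a^2 + 4)) / 2
    z <- numeric(length(idx))
    todo <- seq_along(idx)
    while (length(todo)) {
      prop <- a[todo] + stats::rexp(length(todo), rate = lam[todo])
      acc <- stats::runif(length(todo)) < exp(-(prop - lam[todo])^2 / 2)
      z[todo[acc]] <- prop[acc]
      todo <- todo[!acc]
    }
    out[idx] <- mu[idx] + sigma[idx] * z
  }
  out
}

# Draw one h per entry of the input matrix I (B x M) from the conditional.
sample_hidden_conditional <- function(pot, I) {
  I <- .as_input(pot, I)
  n <- length(I)
  out <- switch(pot$variant,
    gaussian = {
      g <- .unit_par(pot$gamma, I); th <- .unit_par(pot$theta, I)
      (I - th) / g + stats::rnorm(n) / sqrt(g)
    },
    bernoulli = {
      b <- .unit_par(pot$b, I)
      as.numeric(stats::runif(n) < stats::plogis(b + I))
    },
    drelu = {
      gp <- .unit_par(pot$gamma_plus, I); gm <- .unit_par(pot$gamma_minus, I)
      tp <- .unit_par(pot$theta_plus, I); tm <- .unit_par(pot$theta_minus, I)
      lz <- .drelu_log_z(pot, I)
      p_plus <- 1 / (1 + exp(lz$minus - lz$plus))
      pos <- stats::runif(n) < p_plus
      h <- numeric(n)
      if (any(pos)) {
        h[pos] <- sample_truncated_normal(((I - tp) / gp)[pos], (1 / gp)[pos],
                                          "positive")
      }
      if (any(!pos)) {
        h[!pos] <- sample_truncated_normal(((I - tm) / gm)[!pos], (1 / gm)[!pos],
                                           "negative")
      }
      h
    }
  )
  dim(out) <- dim(I)
  out
}
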
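# Multi-item gamma-Poisson shrinker (MGPS).
#
# Model: the observed count a of a drug-event cell is Poisson(lambda * E)
# with E the expected count under within-database independence, and the
# relative reporting rate lambda carries a two-component gamma mixture
# prior  Q * Gamma(alpha1, beta1) + (1 - Q) * Gamma(alpha2, beta2)
# (shape/rate). Marginally a is a mixture of negative binomials; the five
# hyperparameters are fitted by maximum marginal likelihood across all
# cells, and each cell's posterior is again a gamma mixture from which
# EBGM (posterior geometric mean of lambda) and EB05 (5th posterior
# percentile) are read off.

# mixture negative-binomial log-likelihood; theta on the unconstrained
# scale (qlogis(Q), log alpha1, log beta1, log alpha2, log beta2)
mgps_negloglik <- function(theta, a, E) {
  # reject wandering iterates before dnbinom can overflow
  if (any(!is.finite(theta)) || any(abs(theta[-1]) > 25)) return(1e10)
  Q <- stats::plogis(theta[1])
  a1 <- exp(theta[2]); b1 <- exp(theta[3])
  a2 <- exp(theta[4]); b2 <- exp(theta[5])
  l1 <- dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  m <- pmax(l1, l2)
  ll <- sum(m + log(Q * exp(l1 - m) + (1 - Q) * exp(l2 - m)))
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit the MGPS gamma-mixture prior by maximum marginal likelihood
#'
#' Maximizes the summed log marginal likelihood of the observed cell
#' counts under the negative-binomial mixture, over the five
#' hyperparameters `(Q, alpha1, beta1, alpha2, beta2)`. Optimization runs
#' on an unconstrained transform (logit / log) with Nelder-Mead followed
#' by a BFGS polish, from the classical starting point
#' `(Q = 1/3, alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4)` plus
#' `n_restarts` jittered restarts; the best optimum is returned.
#'
#' @param a integer vector of observed cell counts.
#' @param E numeric vector of expected counts (same length, all > 0).
#' @param start named numeric vector of starting hyperparameters.
#' @param n_restarts number of jittered restarts (default 4).
#' @param seed RNG seed for the restart jitter.
#' @return Object of class `mgps_prior`: list with `Q`, `alpha1`,
#'   `beta1`, `alpha2`, `beta2`, `loglik`, `n_cells`.
#' @export
fit_mgps <- function(a, E,
                     start = c(Q = 1 / 3, alpha1 = 0.2, beta1 = 0.1,
                               alpha2 = 2, beta2 = 4),
                     n_restarts = 4, seed = 7L) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0),
            all(a == round(a)))
  if (length(a) < 20)
    warning("fewer than 20 cells; hyperparameter estimates will be unstable")
  th0 <- c(stats::qlogis(start[["Q"]]), log(start[["alpha1"]]),
           log(start[["beta1"]]), log(start[["alpha2"]]),
           log(start[["beta2"]]))
  starts <- with_seed(seed, {
    c(list(th0),
      lapply(seq_len(n_restarts), function(i) th0 + rnorm(5, 0, 0.75)))
  })
  best <- NULL
  for (th in starts) {
    o <- optim(th, mgps_negloglik, a = a, E = E, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
    o <- tryCatch(
      optim(o$par, mgps_negloglik, a = a, E = E, method = "BFGS",
            control = list(maxit = 200, reltol = 1e-12)),
      error = function(e) o)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("MGPS marginal likelihood not finite at optimum; ",
         "check the input counts and expectations")
  th <- best$par
  structure(list(Q = stats::plogis(th[1]),
                 alpha1 = exp(th[2]), beta1 = exp(th[3]),
                 alpha2 = exp(th[4]), beta2 = exp(th[5]),
                 loglik = -best$value, n_cells = length(a)),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("MGPS gamma-mixture prior (fitted on", x$n_cells, "cells)\n")
  cat(sprintf("  Q = %.4f\n", x$Q))
  cat(sprintf("  component 1: Gamma(shape %.4f, rate %.4f)  mean %.3f\n",
              x$alpha1, x$beta1, x$alpha1 / x$beta1))
  cat(sprintf("  component 2: Gamma(shape %.4f, rate %.4f)  mean %.3f\n",
              x$alpha2, x$beta2, x$alpha2 / x$beta2))
  cat(sprintf("  log marginal likelihood: %.3f\n", x$loglik))
  invisible(x)
}

#' Log marginal likelihood of counts under an MGPS prior
#'
#' @param prior an `mgps_prior` object (fitted or constructed by hand).
#' @param a,E cell counts and expectations.
#' @return The summed log marginal (negative-binomial mixture) likelihood.
#' @export
mgps_loglik <- function(prior, a, E) {
  th <- c(stats::qlogis(prior$Q), log(prior$alpha1), log(prior$beta1),
          log(prior$alpha2), log(prior$beta2))
  -mgps_negloglik(th, a, E)
}

#' Construct an MGPS prior from explicit hyperparameters
#'
#' @param Q mixture weight in (0, 1]; `Q = 1` gives a single-component
#'   gamma prior.
#' @param alpha1,beta1,alpha2,beta2 positive gamma shape/rate parameters.
#' @return An `mgps_prior` object (with `loglik = NA`).
#' @export
mgps_prior <- function(Q, alpha1, beta1, alpha2 = alpha1, beta2 = beta1) {
  stopifnot(Q > 0, Q <= 1, alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0)
  structure(list(Q = Q, alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, loglik = NA_real_, n_cells = NA_integer_),
            class = "mgps_prior")
}

#' Empirical-Bayes geometric mean and 5th posterior percentile
#'
#' Given the fitted prior, the posterior of a cell's relative reporting
#' rate is the gamma mixture `Gamma(alpha1 + a, beta1 + E)` with weight
#' `Q*` and `Gamma(alpha2 + a, beta2 + E)` with weight `1 - Q*`, where
#' `Q*` is the posterior mixture weight from the marginal
#' negative-binomial densities. Then
#' `EBGM = exp(E[log lambda | a])` using the digamma closed form, and
#' `EB05` solves posterior-CDF(lambda) = 0.05 by bracketed root-finding.
#'
#' @param a,E cell counts and expectations (vectors).
#' @param prior an `mgps_prior` object.
#' @return `data.table` with columns `ebgm` and `ebgm05`.
#' @export
ebgm <- function(a, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"), length(a) == length(E))
  w1 <- log(prior$Q) +
    dnbinom(a, size = prior$alpha1,
            prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  w2 <- log(1 - prior$Q) +
    dnbinom(a, size = prior$alpha2,
            prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  m <- pmax(w1, w2)
  qs <- exp(w1 - m) / (exp(w1 - m) + exp(w2 - m))
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  gm <- exp(qs * (digamma(s1) - log(r1)) + (1 - qs) * (digamma(s2) - log(r2)))
  q05 <- vapply(seq_along(a), function(i) {
    post_cdf <- function(x)
      qs[i] * pgamma(x, s1[i], rate = r1[i]) +
      (1 - qs[i]) * pgamma(x, s2[i], rate = r2[i]) - 0.05
    lo <- min(qgamma(0.01, s1[i], rate = r1[i]),
              qgamma(0.01, s2[i], rate = r2[i]))
    hi <- max(qgamma(0.999, s1[i], rate = r1[i]),
              qgamma(0.999, s2[i], rate = r2[i]))
    uniroot(post_cdf, lower = max(lo, 1e-12), upper = hi,
            extendInt = "upX", tol = 1e-10)$root
  }, numeric(1))
  data.table::data.table(ebgm = gm, ebgm05 = q05)
}
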
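#' Reconstruct a 2x2 table from published ROR, CI and chi-squared
#'
#' Published signal tables usually print, per term, the report count `a`,
#' the ROR point estimate with its 95% Woolf interval, and a chi-squared
#' statistic — but not the underlying cells. Those three quantities
#' determine the remaining cells: this routine numerically solves the
#' system
#' \itemize{
#'   \item `(a d)/(b c) = ROR`,
#'   \item `1/a + 1/b + 1/c + 1/d = ((ln U - ln L)/3.92)^2` (Woolf
#'     variance from the CI width),
#'   \item `chi2(a, b, c, d) = chi2`
#' }
#' for positive reals `b`, `c`, `d`. The ROR equation is eliminated
#' exactly (`d = ROR b c / a`) and the remaining two relative residuals
#' are minimized by multi-start Nelder-Mead over `(log b, log c)`, with
#' the search bounded to database-plausible magnitudes (`c, d <= 1e8`-ish
#' via penalty). Both chi-squared conventions can be attempted; the
#' overall minimum-residual solution is returned. Because every equation
#' is symmetric under swapping `b` and `c`, solutions come in transpose
#' pairs; among (near-)tied candidates the branch with `c >= b` is
#' returned, the generic situation in spontaneous-report data where
#' comparator events outnumber the target drug's other events.
#'
#' Rounding of the printed inputs makes the system slightly inconsistent,
#' so the attained residual is reported; derived quantities such as the
#' PRR and the observed-to-expected ratio are insensitive to the residual
#' direction of the remaining flat ridge.
#'
#' @param a observed report (pair) count, >= 1.
#' @param ror_point published ROR point estimate.
#' @param ror_ci numeric length-2, the published 95% CI `(L, U)`.
#' @param chi2 published chi-squared value.
#' @param yates chi-squared conventions to try: logical vector, default
#'   `c(TRUE, FALSE)` (both).
#' @param max_cell upper bound on the searched cell magnitude.
#' @param tol maximum acceptable residual norm (relative); larger
#'   residuals raise an error reporting the best attained value.
#' @return list with `b`, `c`, `d`, `N`, `residual`, `yates`, plus the
#'   derived `prr` and `log2_oe` (= `log2(a N / (n1 n2))`).
#' @export
invert_published_stats <- function(a, ror_point, ror_ci, chi2,
                                   yates = c(TRUE, FALSE),
                                   max_cell = 1e8, tol = 0.05) {
  stopifnot(a >= 1, length(ror_ci) == 2)
  L <- ror_ci[1]; U <- ror_ci[2]
  if (!(U > L) || L <= 0)
    stop("degenerate ROR confidence interval: upper bound must exceed ",
         "the positive lower bound")
  S <- ((log(U) - log(L)) / 3.92)^2
  if (S <= 1 / a)
    stop("CI width implies Woolf variance <= 1/a; no positive solution")
  lmax <- log(max_cell)

  candidates <- list()
  for (yt in yates) {
    obj <- function(p) {
      b <- exp(p[1]); cc <- exp(p[2]); d <- ror_point * b * cc / a
      r1 <- (1 / a + 1 / b + 1 / cc + 1 / d) / S - 1
      r2 <- chi2_stat(a, b, cc, d, yates = yt) / chi2 - 1
      pen <- sum(pmax(0, p - lmax)^2) + sum(pmax(0, -p - 5)^2)
      r1^2 + r2^2 + 100 * pen
    }
    for (lc in seq(log(max(a, 2)), lmax, length.out = 10)) {
      cc <- exp(lc)
      Tt <- S - 1 / a - 1 / cc
      b0 <- if (Tt > 0) (1 + a / (ror_point * cc)) / Tt
            else 1 / max(S - 1 / a, 1e-12)
      o <- optim(c(log(b0), lc), obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-15))
      o <- optim(o$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-15))
      candidates[[length(candidates) + 1L]] <-
        list(b = exp(o$par[1]), c = exp(o$par[2]), residual = sqrt(o$value),
             yates = yt)
    }
  }
  res <- vapply(candidates, `[[`, numeric(1), "residual")
  best_res <- min(res)
  if (best_res > tol)
    stop(sprintf(paste0("no 2x2 table reproduces the published statistics; ",
                        "best residual %.3g exceeds tolerance %.3g"),
                 best_res, tol))
  elig <- candidates[res <= best_res * 1.5 + 1e-10]
  pref <- Filter(function(s) s$c >= s$b, elig)
  if (length(pref)) elig <- pref
  sol <- elig[[which.min(vapply(elig, `[[`, numeric(1), "residual"))]]

  b <- sol$b; cc <- sol$c
  d <- ror_point * b * cc / a
  N <- a + b + cc + d
  list(b = b, c = cc, d = d, N = N, residual = sol$residual,
       yates = sol$yates,
       prr = (a / (a + b)) / (cc / (cc + d)),
       log2_oe = log2(a * N / ((a + b) * (a + cc))))
}
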
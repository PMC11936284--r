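#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d) / (b c)` with the log-scale Woolf interval
#' `exp(ln ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero, 0.5 is added to all four cells (flagged in the output) so the
#' estimate stays finite.
#'
#' @param a,b,c,d vectors of 2x2 cell counts (recycled to common length).
#' @param conf confidence level (default 0.95; z = 1.96 at the default,
#'   matching the conventional printed intervals).
#' @return `data.table` with `ror`, `ror_low`, `ror_high`, `corrected`.
#' @export
ror <- function(a, b, c, d, conf = 0.95) {
  z <- if (conf == 0.95) 1.96 else qnorm(1 - (1 - conf) / 2)
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * corrected; b <- b + 0.5 * corrected
  c <- c + 0.5 * corrected; d <- d + 0.5 * corrected
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  data.table::data.table(ror = est,
                         ror_low = exp(log(est) - z * se),
                         ror_high = exp(log(est) + z * se),
                         corrected = corrected)
}

#' Proportional reporting ratio and chi-squared statistic
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with the log-scale interval
#' `exp(ln PRR +/- z sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`, and the
#' Pearson chi-squared statistic on the same table with margin-based
#' expectations, optionally Yates-corrected
#' (`sum((|O - E| - y)^2 / E)` with `y = min(0.5, |O - E|)`).
#' Tables with a zero `a` or `c` cell get the 0.5 continuity correction
#' on all cells for the PRR (flagged); the chi-squared always uses the
#' uncorrected counts.
#'
#' @inheritParams ror
#' @param yates logical: apply the Yates continuity correction to the
#'   chi-squared (default `TRUE`).
#' @return `data.table` with `prr`, `prr_low`, `prr_high`, `chi2`,
#'   `corrected`.
#' @export
prr_chi2 <- function(a, b, c, d, conf = 0.95, yates = TRUE) {
  z <- if (conf == 0.95) 1.96 else qnorm(1 - (1 - conf) / 2)
  chi2 <- chi2_stat(a, b, c, d, yates = yates)
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  aa <- a + 0.5 * corrected; bb <- b + 0.5 * corrected
  cc <- c + 0.5 * corrected; dd <- d + 0.5 * corrected
  est <- (aa / (aa + bb)) / (cc / (cc + dd))
  se <- sqrt(1 / aa - 1 / (aa + bb) + 1 / cc - 1 / (cc + dd))
  data.table::data.table(prr = est,
                         prr_low = exp(log(est) - z * se),
                         prr_high = exp(log(est) + z * se),
                         chi2 = chi2, corrected = corrected)
}

# Pearson chi-squared on the 2x2 with margin expectations; the Yates
# subtraction is capped at |O - E| (the convention of chisq.test()).
chi2_stat <- function(a, b, c, d, yates = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  n1 <- a + b; n2 <- a + c
  e11 <- n1 * n2 / N
  e12 <- n1 * (N - n2) / N
  e21 <- (N - n1) * n2 / N
  e22 <- (N - n1) * (N - n2) / N
  dev <- function(o, e) {
    y <- if (yates) pmin(0.5, abs(o - e)) else 0
    (abs(o - e) - y)^2 / e
  }
  dev(a, e11) + dev(b, e12) + dev(c, e21) + dev(d, e22)
}

#' BCPNN information component
#'
#' The information component `IC` is a shrunken log2 observed-to-expected
#' reporting ratio. The default `"bate1998"` variant is the closed-form
#' moment approximation of the original Bayesian confidence propagation
#' neural network: with hyperparameters `alpha1' = beta1' = 1`,
#' `alpha' = beta' = 2`, `gamma11 = 1` and
#' `gamma = gamma11 (N + alpha')(N + beta') / ((n1 + alpha1')(n2 + beta1'))`,
#' \deqn{E(IC) = \log_2 \frac{(a + 1)(N + 2)^2}{(N + \gamma)(n_1 + 1)(n_2 + 1)}}
#' and `IC025 = E(IC) - 2 sqrt(V(IC))` from the matching variance
#' expansion. For large tables `E(IC)` approaches `log2(a N / (n1 n2))`.
#' The `"noren"` variant is the later gamma-mixture form
#' `IC = log2((a + 0.5)/(E + 0.5))` with its asymptotic credibility bound.
#'
#' @inheritParams ror
#' @param variant `"bate1998"` (default) or `"noren"`.
#' @return `data.table` with `ic` and `ic025`.
#' @export
bcpnn_ic <- function(a, b, c, d, variant = c("bate1998", "noren")) {
  variant <- match.arg(variant)
  N <- a + b + c + d
  n1 <- a + b; n2 <- a + c
  if (variant == "noren") {
    E <- n1 * n2 / N
    ic <- log2((a + 0.5) / (E + 0.5))
    ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
    return(data.table::data.table(ic = ic, ic025 = ic025))
  }
  a1p <- 1; b1p <- 1; ap <- 2; bp <- 2; g11 <- 1
  g <- g11 * (N + ap) * (N + bp) / ((n1 + a1p) * (n2 + b1p))
  eic <- log2((a + g11) * (N + ap) * (N + bp) /
                ((N + g) * (n1 + a1p) * (n2 + b1p)))
  vic <- (1 / log(2))^2 *
    ((N - a + g - g11) / ((a + g11) * (1 + N + g)) +
       (N - n1 + ap - a1p) / ((n1 + a1p) * (1 + N + ap)) +
       (N - n2 + bp - b1p) / ((n2 + b1p) * (1 + N + bp)))
  data.table::data.table(ic = eic, ic025 = eic - 2 * sqrt(vic))
}

#' Signal threshold configuration
#'
#' The standard four-algorithm criteria used throughout the FAERS
#' disproportionality literature:
#' \itemize{
#'   \item ROR: `n >= min_n` and lower 95% bound `> 1`;
#'   \item PRR: `PRR >= 2`, `chi2 >= 4`, `n >= min_n`;
#'   \item BCPNN: `IC025 > 0`;
#'   \item MGPS: `EBGM05 > 2`.
#' }
#'
#' @param min_n minimum report count (default 3).
#' @param ror_low,prr_min,chi2_min,ic025_min,ebgm05_min rule cut-offs.
#' @return A named list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(min_n = 3, ror_low = 1, prr_min = 2,
                              chi2_min = 4, ic025_min = 0, ebgm05_min = 2) {
  stopifnot(min_n > 0, ror_low > 0, prr_min > 0, chi2_min > 0,
            ebgm05_min > 0)
  structure(list(min_n = min_n, ror_low = ror_low, prr_min = prr_min,
                 chi2_min = chi2_min, ic025_min = ic025_min,
                 ebgm05_min = ebgm05_min),
            class = "signal_thresholds")
}

#' Apply the four signal criteria
#'
#' @param metrics a `data.table` as produced by [signal_metrics()] (needs
#'   columns `n`, `ror_low`, `prr`, `chi2`, `ic025`, `ebgm05`).
#' @param thresholds a [signal_thresholds()] object.
#' @return `metrics` with logical columns `ror_flag`, `prr_flag`,
#'   `bcpnn_flag`, `mgps_flag` and their conjunction `signal`.
#' @export
evaluate_signal <- function(metrics, thresholds = signal_thresholds()) {
  m <- data.table::as.data.table(metrics)
  th <- thresholds
  m[, ror_flag := n >= th$min_n & ror_low > th$ror_low]
  m[, prr_flag := n >= th$min_n & prr >= th$prr_min & chi2 >= th$chi2_min]
  m[, bcpnn_flag := ic025 > th$ic025_min]
  m[, mgps_flag := ebgm05 > th$ebgm05_min]
  m[, signal := ror_flag & prr_flag & bcpnn_flag & mgps_flag]
  m[]
}

#' Full four-algorithm signal metrics for a set of 2x2 tables
#'
#' Computes, per term: the observed count `n = a`, the expected count
#' `E = n1 n2 / N`, ROR and PRR with 95% intervals, the chi-squared
#' statistic, the BCPNN information component with `IC025`, the MGPS
#' `EBGM` with `EBGM05`, the per-algorithm flags and the combined signal
#' (all four simultaneously).
#'
#' @param tables `data.table` from [build_pt_tables()] (columns `term`,
#'   `a`, `b`, `c`, `d`).
#' @param prior optional [fit_mgps()] prior; fitted on `tables` when
#'   `NULL`.
#' @param thresholds a [signal_thresholds()] object.
#' @param ic_variant BCPNN variant, see [bcpnn_ic()].
#' @param yates chi-squared convention, see [prr_chi2()].
#' @return `data.table` of per-term metrics, ordered by `n` descending.
#' @export
signal_metrics <- function(tables, prior = NULL,
                           thresholds = signal_thresholds(),
                           ic_variant = "bate1998", yates = TRUE) {
  tb <- data.table::as.data.table(tables)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tb)))
  N <- tb$a + tb$b + tb$c + tb$d
  E <- (tb$a + tb$b) * (tb$a + tb$c) / N
  if (is.null(prior)) prior <- fit_mgps(tb$a, E)
  out <- data.table::data.table(
    term = if ("term" %in% names(tb)) tb$term else seq_len(nrow(tb)),
    n = tb$a, E = E)
  out <- cbind(out, ror(tb$a, tb$b, tb$c, tb$d),
               prr_chi2(tb$a, tb$b, tb$c, tb$d, yates = yates)[
                 , c("prr", "prr_low", "prr_high", "chi2")],
               bcpnn_ic(tb$a, tb$b, tb$c, tb$d, variant = ic_variant),
               ebgm(tb$a, E, prior))
  out <- evaluate_signal(out, thresholds)
  data.table::setorder(out, -n, term)
  attr(out, "prior") <- prior
  out[]
}
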
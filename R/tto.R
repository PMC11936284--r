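#' Compute time-to-onset for the case set
#'
#' Time-to-onset (TTO) is the number of days from the start of target
#' drug therapy (`START_DT` in THER) to adverse event onset (`EVENT_DT`
#' in DEMO). Per report the earliest fully specified start date of a
#' target drug entry is used. Reports with partial or missing dates, or a
#' negative interval, are excluded; per-reason exclusion counts are
#' attached as the `exclusions` attribute.
#'
#' @param case_ids PRIMARYIDs of the case set.
#' @param ther THER table (`PRIMARYID`, `START_DT`, optionally
#'   `DSG_DRUG_SEQ`).
#' @param demo normalized DEMO records (`PRIMARYID`, `EVENT_DT`).
#' @param drug_std optional standardized DRUG table; when supplied with
#'   `target`, therapy rows are restricted to the target drug's sequence
#'   numbers (`DSG_DRUG_SEQ` matching `DRUG_SEQ`).
#' @param target canonical target drug name (used with `drug_std`).
#' @param roles role codes qualifying a drug entry as target therapy.
#' @return `data.table` with `PRIMARYID` and `tto_days` (nonnegative).
#' @export
compute_tto <- function(case_ids, ther, demo, drug_std = NULL,
                        target = NULL, roles = "PS") {
  th <- data.table::as.data.table(ther)
  th <- th[trimws(PRIMARYID) %in% trimws(as.character(case_ids))]
  if (!is.null(drug_std) && !is.null(target) &&
      "DSG_DRUG_SEQ" %in% names(th)) {
    dr <- data.table::as.data.table(drug_std)
    if ("DRUG_SEQ" %in% names(dr)) {
      tgt <- dr[!is.na(CANONICAL) & CANONICAL == target &
                  toupper(trimws(ROLE_COD)) %in% roles,
                .(PRIMARYID = trimws(PRIMARYID),
                  SEQ = trimws(as.character(DRUG_SEQ)))]
      th <- th[paste(trimws(PRIMARYID), trimws(as.character(DSG_DRUG_SEQ))) %in%
                 paste(tgt$PRIMARYID, tgt$SEQ)]
    }
  }
  case_ids <- unique(trimws(as.character(case_ids)))
  st <- parse_faers_date(th$START_DT)
  th <- data.table::data.table(PRIMARYID = trimws(th$PRIMARYID),
                               start = st$date)
  with_ther <- unique(th$PRIMARYID)
  starts <- th[!is.na(start), .(start = min(start)), by = PRIMARYID]

  dm <- data.table::as.data.table(demo)
  dm <- dm[trimws(PRIMARYID) %in% case_ids]
  ev <- parse_faers_date(dm$EVENT_DT)
  events <- data.table::data.table(PRIMARYID = trimws(dm$PRIMARYID),
                                   event = ev$date)
  merged <- merge(starts, events, by = "PRIMARYID")
  merged[, tto_days := as.numeric(event - start)]
  out <- merged[!is.na(tto_days) & tto_days >= 0, .(PRIMARYID, tto_days)]
  attr(out, "exclusions") <- c(
    no_therapy_row = length(setdiff(case_ids, with_ther)),
    partial_or_missing_start = length(setdiff(with_ther, starts$PRIMARYID)),
    partial_or_missing_event = sum(is.na(merged$event)),
    negative_interval = sum(merged$tto_days < 0, na.rm = TRUE))
  out
}

#' Summarize a time-to-onset distribution
#'
#' Median and quartiles use the median-unbiased quantile convention
#' (`type = 8`); the histogram uses 30-day bins with the first bin
#' `[0, 30]` closed on both ends (so day-0 events count as first-month).
#'
#' @param tto_days numeric vector of nonnegative onset times (days).
#' @return list with `n`, `median`, `q1`, `q3`, `min`, `max`, and
#'   `histogram` (a `data.table` with `bin`, `count`, `percent`).
#' @export
summarize_tto <- function(tto_days) {
  x <- tto_days[!is.na(tto_days)]
  if (!length(x)) stop("no time-to-onset records to summarize")
  qs <- quantile(x, c(0.25, 0.5, 0.75), type = 8, names = FALSE)
  breaks <- seq(0, 30 * ceiling(max(x, 30) / 30), by = 30)
  cut_idx <- pmax(1L, ceiling(x / 30))  # [0,30] -> 1, (30,60] -> 2, ...
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1L)
  hist <- data.table::data.table(
    bin = sprintf("(%d,%d]", head(breaks, -1L), breaks[-1L]),
    count = counts,
    percent = round_half_up(100 * counts / length(x), 2))
  hist$bin[1] <- sprintf("[0,%d]", breaks[2])
  list(n = length(x), median = qs[2], q1 = qs[1], q3 = qs[3],
       min = min(x), max = max(x), histogram = hist)
}

# Weibull log-likelihood (shape beta, scale alpha), t > 0
weibull_negloglik <- function(par, t) {
  la <- par[1]; lb <- par[2]
  beta <- exp(lb); alpha <- exp(la)
  ll <- sum(lb - beta * la + (beta - 1) * log(t) - (t / alpha)^beta)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a Weibull model to time-to-onset data
#'
#' Maximum-likelihood fit of the two-parameter Weibull distribution with
#' scale `alpha` (days) and shape `beta`. Zero onset times (same-day
#' events) are replaced by 0.5 day since the Weibull support is `t > 0`.
#' 95% Wald intervals come from the inverse observed information on
#' `(log alpha, log beta)`, back-transformed. The hazard pattern is
#' classified from the shape interval: `"early"` failure when the CI lies
#' entirely below 1 (decreasing hazard), `"wear-out"` when entirely above
#' 1, `"random"` otherwise.
#'
#' @param tto_days nonnegative onset times in days (n >= 10; a warning is
#'   issued below 30).
#' @param conf confidence level for the Wald intervals.
#' @return Object of class `weibull_fit`: list with `scale_alpha`,
#'   `scale_ci`, `shape_beta`, `shape_ci`, `n`, `log_likelihood`,
#'   `failure_type`.
#' @export
fit_weibull <- function(tto_days, conf = 0.95) {
  t <- tto_days[!is.na(tto_days)]
  stopifnot(all(t >= 0))
  if (length(t) < 10) stop("need at least 10 onset times")
  if (length(t) < 30) warning("fewer than 30 onset times; estimates unstable")
  t[t == 0] <- 0.5
  # Gumbel moment start: log t has sd pi/(beta sqrt(6)), mean
  # log(alpha) - gamma_E / beta
  slt <- sd(log(t))
  b0 <- if (slt > 0) pi / (slt * sqrt(6)) else 1
  # profile likelihood: for fixed beta the scale MLE is closed-form,
  # alpha(beta)^beta = mean(t^beta), leaving a 1-D search over log beta
  prof <- function(lb) {
    beta <- exp(lb)
    la <- log(mean(t^beta)) / beta
    weibull_negloglik(c(la, lb), t)
  }
  opt <- optimize(prof, interval = log(b0) + c(-4, 4), tol = 1e-12)
  beta <- exp(opt$minimum)
  alpha <- mean(t^beta)^(1 / beta)
  par <- c(log(alpha), log(beta))
  nll <- weibull_negloglik(par, t)
  if (nll >= 1e10 || abs(opt$minimum - log(b0)) > 3.999)
    stop("Weibull fit did not converge; final parameters (log scale): ",
         paste(signif(par, 6), collapse = ", "))
  hess <- stats::optimHess(par, weibull_negloglik, t = t)
  z <- qnorm(1 - (1 - conf) / 2)
  vc <- tryCatch(solve(hess), error = function(e)
    stop("observed information is singular; Weibull CI unavailable"))
  se <- sqrt(pmax(diag(vc), 0))
  alpha_ci <- exp(par[1] + c(-1, 1) * z * se[1])
  beta_ci <- exp(par[2] + c(-1, 1) * z * se[2])
  type <- if (beta_ci[2] < 1) "early"
          else if (beta_ci[1] > 1) "wear-out" else "random"
  structure(list(scale_alpha = alpha, scale_ci = alpha_ci,
                 shape_beta = beta, shape_ci = beta_ci,
                 n = length(t), log_likelihood = -nll,
                 failure_type = type),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull time-to-onset fit (n = %d)\n", x$n))
  cat(sprintf("  scale alpha: %.2f days (95%% CI %.2f-%.2f)\n",
              x$scale_alpha, x$scale_ci[1], x$scale_ci[2]))
  cat(sprintf("  shape beta:  %.3f (95%% CI %.3f-%.3f)\n",
              x$shape_beta, x$shape_ci[1], x$shape_ci[2]))
  cat(sprintf("  hazard pattern: %s failure\n", x$failure_type))
  invisible(x)
}
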
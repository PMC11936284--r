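# Fixtures built in code: tiny universes with hand-checkable counts and a
# case set mimicking the published descriptive margins.

library(data.table)

# toy pair universe: 4 reports (r1, r2 cases), 6 unique pairs
toy_events <- function() {
  data.table(
    PRIMARYID = c("r1", "r1", "r2", "r3", "r3", "r4"),
    PT = c("PT_A", "PT_B", "PT_A", "PT_B", "PT_C", "PT_C"))
}
toy_case_ids <- c("r1", "r2")

# brute-force 2x2 oracle: enumerate (report, term) pairs with loops/sets
oracle_tables <- function(events, case_ids) {
  ev <- unique(as.data.frame(events)[, c("PRIMARYID", "PT")])
  terms <- sort(unique(ev$PT))
  all_pairs <- nrow(ev)
  case_pairs <- sum(ev$PRIMARYID %in% case_ids)
  do.call(rbind, lapply(terms, function(tm) {
    a <- sum(ev$PT == tm & ev$PRIMARYID %in% case_ids)
    ctot <- sum(ev$PT == tm)
    data.frame(term = tm, a = a, b = case_pairs - a, c = ctot - a,
               d = all_pairs - case_pairs - ctot + a)
  }))
}

# random small universe for property tests
random_universe <- function(n_reports = 30, n_terms = 6, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_reports), function(i) {
    k <- sample(1:3, 1)
    data.table(PRIMARYID = sprintf("r%02d", i),
               PT = sample(sprintf("T%d", seq_len(n_terms)), k))
  })
  ev <- rbindlist(rows)
  case <- sprintf("r%02d", sample(n_reports, ceiling(n_reports / 3)))
  list(events = ev, case_ids = case)
}

# case set reproducing the published hyperkalemia-drug cohort margins:
# sex F/M/unknown = 335/559/260, age bands 28/106/120/333/567,
# countries US/JP/CN/GB/CO/other = 884/197/16/16/10/31,
# outcome entries DE/HO/LT/DS/RI/OT = 481/184/34/8/1/224
reference_case_set <- function() {
  n <- 1154
  sex <- rep(c("F", "M", "unknown"), c(335, 559, 260))
  age <- rep(c(30, 50, 70, 80, NA), c(28, 106, 120, 333, 567))
  country <- rep(c("US", "JP", "CN", "GB", "CO", "OTHER"),
                 c(884, 197, 16, 16, 10, 31))
  demo <- data.table(
    PRIMARYID = as.character(seq_len(n)), CASEID = as.character(seq_len(n)),
    FDA_DT = "20230101", EVENT_DT = "20230101",
    SEX = sex, AGE_YEARS = age, COUNTRY = country, OCCP_COD = "MD")
  outc <- data.table(
    PRIMARYID = as.character(seq_len(932)),
    OUTC_COD = rep(c("DE", "HO", "LT", "DS", "RI", "OT"),
                   c(481, 184, 34, 8, 1, 224)))
  list(demo = demo, outc = outc)
}

# forward-compute the three published statistics from a known table
forward_stats <- function(a, b, c, d, yates = FALSE) {
  r <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = r, ci = c(exp(log(r) - 1.96 * se), exp(log(r) + 1.96 * se)),
       chi2 = pvsignal:::chi2_stat(a, b, c, d, yates = yates))
}

# independent numeric-quadrature oracle for the posterior of the MGPS
# relative reporting rate: density proportional to
# (Q g1 + (1-Q) g2)(lambda) * Poisson(a; lambda E).
# Integration runs on u = log(lambda) so spiky posteriors (large a) and
# heavy lower tails (a = 0, small shapes) are both resolved.
posterior_moment_oracle <- function(a, E, prior) {
  ldens <- function(u) {
    l <- exp(u)
    (prior$Q * dgamma(l, prior$alpha1, rate = prior$beta1) +
       (1 - prior$Q) * dgamma(l, prior$alpha2, rate = prior$beta2)) *
      dpois(a, l * E) * l
  }
  # bracket the support by scanning the (unnormalized) density itself,
  # then split the quadrature at the scanned mode
  grid <- seq(-60, log(max((a + 10) / E * 100, 1000)), length.out = 4000)
  gv <- ldens(grid)
  keep <- which(gv > max(gv) * 1e-15)
  lo <- grid[max(1, min(keep) - 2)]
  hi <- grid[min(length(grid), max(keep) + 2)]
  mid <- grid[which.max(gv)]
  ig <- function(f, from, to)
    integrate(f, from, to, rel.tol = 1e-11, subdivisions = 500L,
              stop.on.error = FALSE)$value
  norm <- ig(ldens, lo, mid) + ig(ldens, mid, hi)
  elog <- (ig(function(u) u * ldens(u), lo, mid) +
             ig(function(u) u * ldens(u), mid, hi)) / norm
  cdf <- function(x) {
    lx <- min(log(x), hi)
    if (lx <= lo) return(0)
    if (lx <= mid) ig(ldens, lo, lx) / norm
    else (ig(ldens, lo, mid) + ig(ldens, mid, lx)) / norm
  }
  list(ebgm = exp(elog), cdf = cdf)
}
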
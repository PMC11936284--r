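#' Percentages for a block of category counts
#'
#' Computes `100 * count / denominator` with half-up rounding to two
#' decimals, the convention of published descriptive tables. The
#' denominator defaults to the block total, e.g. total reports for
#' demographic blocks or total outcome entries for the outcome block
#' (a report may carry several outcome codes).
#'
#' @param counts named integer vector of category counts.
#' @param denominator total to divide by (default `sum(counts)`).
#' @return `data.table` with `category`, `count`, `percent`.
#' @export
pct_block <- function(counts, denominator = sum(counts)) {
  stopifnot(denominator > 0)
  counts <- setNames(as.integer(counts), names(counts))
  data.table::data.table(category = names(counts),
                         count = counts,
                         percent = as.numeric(
                           round_half_up(100 * counts / denominator, 2)))
}

# age in years -> published age bands
age_band <- function(age_years) {
  band <- rep("unknown", length(age_years))
  band[!is.na(age_years) & age_years < 45] <- "<45"
  band[!is.na(age_years) & age_years >= 45 & age_years < 65] <- "45-64"
  band[!is.na(age_years) & age_years >= 65 & age_years < 75] <- "65-74"
  band[!is.na(age_years) & age_years >= 75] <- ">74"
  band
}

#' Descriptive characteristics of the case set
#'
#' Produces the classic pharmacovigilance "Table 1": counts and
#' percentages by sex, age band (<45, 45-64, 65-74, >74, unknown),
#' serious outcome, reporter occupation, reporting country and reporting
#' year. Demographic blocks use the number of case reports as the
#' denominator; the serious-outcome block uses the number of outcome
#' entries, since one report can carry several outcome codes.
#'
#' @param demo_cases normalized, deduplicated DEMO records of the case
#'   set ([normalize_demo()] output filtered to the case ids).
#' @param outc_cases OUTC rows of the case set (needs `OUTC_COD`); may be
#'   `NULL` to skip the outcome block.
#' @return Named list of `data.table` blocks (`sex`, `age`, `outcome`,
#'   `reporter`, `region`, `year`), plus `n_reports`.
#' @export
describe_cases <- function(demo_cases, outc_cases = NULL) {
  dm <- data.table::as.data.table(demo_cases)
  if (!nrow(dm)) stop("empty case set")
  n <- nrow(dm)
  blocks <- list(n_reports = n)
  blocks$sex <- pct_block(table(dm$SEX), n)
  blocks$age <- pct_block(table(factor(age_band(dm$AGE_YEARS),
                                       levels = c("<45", "45-64", "65-74",
                                                  ">74", "unknown"))), n)
  if (!is.null(outc_cases) && nrow(outc_cases)) {
    oc <- data.table::as.data.table(outc_cases)
    codes <- toupper(trimws(oc$OUTC_COD))
    blocks$outcome <- pct_block(sort(table(codes), decreasing = TRUE))
  }
  blocks$reporter <- pct_block(sort(table(dm$OCCP_COD), decreasing = TRUE), n)
  blocks$region <- pct_block(sort(table(dm$COUNTRY), decreasing = TRUE), n)
  yr <- parse_faers_date(dm$FDA_DT)$year
  yr <- ifelse(is.na(yr), "unknown", as.character(yr))
  blocks$year <- pct_block(table(yr), n)
  blocks
}

#' Annual report counts of the case set
#'
#' Year is taken from FDA_DT (the receipt date); missing years are
#' reported under `"unknown"`. Counts always sum to the case-set size.
#'
#' @param demo_cases normalized DEMO records of the case set.
#' @return `data.table` with `year` and `count`.
#' @export
annual_trend <- function(demo_cases) {
  dm <- data.table::as.data.table(demo_cases)
  yr <- parse_faers_date(dm$FDA_DT)$year
  yr <- ifelse(is.na(yr), "unknown", as.character(yr))
  out <- data.table::as.data.table(table(year = yr))
  data.table::setnames(out, c("year", "count"))
  out[]
}
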
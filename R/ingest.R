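#' Read FAERS-dialect quarterly ASCII tables
#'
#' Reads the '$'-delimited, one-header-row ASCII tables distributed with
#' FAERS quarterly extracts. Column names are matched case-insensitively
#' (returned upper-cased); unknown extra columns are preserved. Rows
#' lacking a PRIMARYID are dropped with a message.
#'
#' @param paths named character vector or list with elements `demo`,
#'   `drug`, `reac` and optionally `outc`, `ther`; or a single directory
#'   containing `DEMO.txt`, `DRUG.txt`, ... as written by
#'   [write_faers_tables()].
#' @return Named list of `data.table`s (all columns character).
#' @export
read_faers_tables <- function(paths) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    fn <- function(x) file.path(paths, paste0(x, ".txt"))
    paths <- list(demo = fn("DEMO"), drug = fn("DRUG"), reac = fn("REAC"),
                  outc = fn("OUTC"), ther = fn("THER"))
    paths <- Filter(file.exists, paths)
  }
  mandatory <- list(
    demo = c("PRIMARYID", "CASEID", "FDA_DT"),
    drug = c("PRIMARYID", "DRUGNAME", "ROLE_COD"),
    reac = c("PRIMARYID", "PT"),
    outc = c("PRIMARYID", "OUTC_COD"),
    ther = c("PRIMARYID", "START_DT")
  )
  out <- lapply(names(paths), function(nm) {
    p <- paths[[nm]]
    if (!file.exists(p)) stop("file not found: ", p)
    dt <- data.table::fread(p, sep = "$", colClasses = "character",
                            quote = "", fill = TRUE, showProgress = FALSE)
    data.table::setnames(dt, toupper(names(dt)))
    need <- mandatory[[nm]]
    miss <- setdiff(need, names(dt))
    if (length(miss))
      stop(sprintf("table '%s' is missing mandatory column(s): %s",
                   nm, paste(miss, collapse = ", ")))
    bad <- !nzchar(trimws(dt$PRIMARYID))
    if (any(bad)) {
      message(sprintf("%s: dropped %d row(s) without PRIMARYID",
                      nm, sum(bad)))
      dt <- dt[!bad]
    }
    dt
  })
  names(out) <- names(paths)
  out
}

# FAERS AGE_COD units -> years
age_unit_divisor <- c(YR = 1, DEC = 0.1, MON = 12, WK = 52.18, DY = 365.25,
                      HR = 365.25 * 24)

#' Convert FAERS age values to years
#'
#' @param age numeric or character vector of raw AGE values.
#' @param cod AGE_COD unit codes (`YR`, `DEC`, `MON`, `WK`, `DY`, `HR`);
#'   blank or unrecognized codes are treated as years.
#' @return numeric vector of ages in years; non-numeric, negative or
#'   implausible (>= 150 years) values become `NA`.
#' @export
age_to_years <- function(age, cod) {
  a <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(cod)))
  div <- age_unit_divisor[cod]
  div[is.na(div)] <- 1
  yrs <- unname(a / div)
  yrs[!is.finite(yrs) | yrs < 0 | yrs >= 150] <- NA_real_
  yrs
}

#' Normalize a raw DEMO table into report records
#'
#' Derives analysis-ready fields: sex collapsed to `M`/`F`/`unknown`,
#' age in years, reporting country and reporter occupation, plus the raw
#' FDA and event date strings.
#'
#' @param demo raw DEMO `data.table` from [read_faers_tables()].
#' @return `data.table` with columns `PRIMARYID`, `CASEID`, `FDA_DT`,
#'   `EVENT_DT`, `SEX`, `AGE_YEARS`, `COUNTRY`, `OCCP_COD`.
#' @export
normalize_demo <- function(demo) {
  dt <- data.table::as.data.table(demo)
  sex <- toupper(trimws(dt$SEX %||% rep("", nrow(dt))))
  sex[!sex %in% c("M", "F")] <- "unknown"
  country_col <- intersect(c("OCCR_COUNTRY", "REPORTER_COUNTRY"), names(dt))
  country <- if (length(country_col)) trimws(dt[[country_col[1]]])
             else rep("", nrow(dt))
  country[!nzchar(country)] <- "unknown"
  occp <- trimws(dt$OCCP_COD %||% rep("", nrow(dt)))
  occp[!nzchar(occp)] <- "unknown"
  age <- if ("AGE" %in% names(dt))
    age_to_years(dt$AGE, dt$AGE_COD %||% rep("YR", nrow(dt)))
  else rep(NA_real_, nrow(dt))
  data.table::data.table(
    PRIMARYID = trimws(dt$PRIMARYID), CASEID = trimws(dt$CASEID),
    FDA_DT = trimws(dt$FDA_DT),
    EVENT_DT = trimws(dt$EVENT_DT %||% rep("", nrow(dt))),
    SEX = sex, AGE_YEARS = age, COUNTRY = country, OCCP_COD = occp)
}

#' Deduplicate cases by the CASEID / FDA_DT / PRIMARYID rule
#'
#' FAERS cases are resubmitted over time under new PRIMARYIDs. Following
#' the FDA-recommended rule, one record is kept per CASEID: the one with
#' the latest FDA_DT, ties broken by the higher PRIMARYID. Records with a
#' missing or unparseable FDA_DT lose to any dated record of the same
#' case. The operation is idempotent and does not modify its input.
#'
#' @param demo normalized DEMO records ([normalize_demo()] output, or any
#'   table with `PRIMARYID`, `CASEID`, `FDA_DT` columns).
#' @return Deduplicated copy of `demo`, with attribute
#'   `removed_primaryids` listing the PRIMARYIDs that were dropped.
#' @export
deduplicate_cases <- function(demo) {
  dt <- data.table::as.data.table(demo)
  key <- date_sort_key(dt$FDA_DT)
  key[is.na(key)] <- -1L
  pid <- suppressWarnings(as.numeric(dt$PRIMARYID))
  ord <- order(dt$CASEID, -key, -pid)
  keep_idx <- ord[!duplicated(dt$CASEID[ord])]
  removed <- setdiff(seq_len(nrow(dt)), keep_idx)
  out <- dt[sort(keep_idx)]
  attr(out, "removed_primaryids") <- dt$PRIMARYID[removed]
  out
}

#' Standardize drug names via a synonym dictionary
#'
#' Adds a `CANONICAL` column to the DRUG table by exact matching on a
#' normalized key (upper-cased, punctuation and repeated whitespace
#' collapsed). Unmatched names keep `CANONICAL = NA` and are retained.
#'
#' @param drug raw DRUG `data.table` (needs `DRUGNAME`).
#' @param synonyms either a `data.frame` with columns `canonical` and
#'   `variant`, or the path of a tab-separated file with those columns.
#' @return Copy of `drug` with a `CANONICAL` column appended.
#' @export
standardize_drugs <- function(drug, synonyms) {
  if (is.character(synonyms) && length(synonyms) == 1L)
    synonyms <- data.table::fread(synonyms, sep = "\t",
                                  colClasses = "character")
  syn <- data.table::as.data.table(synonyms)
  data.table::setnames(syn, tolower(names(syn)))
  if (!all(c("canonical", "variant") %in% names(syn)))
    stop("synonym map needs 'canonical' and 'variant' columns")
  syn[, variant := normalize_drug_name(variant)]
  syn <- unique(syn[, .(canonical, variant)])
  dup <- syn[, .N, by = variant][N > 1L]
  if (nrow(dup))
    stop("variant(s) mapped to more than one canonical name: ",
         paste(dup$variant, collapse = ", "))
  dt <- data.table::as.data.table(drug)
  dt <- data.table::copy(dt)
  dt[, CANONICAL := syn$canonical[match(normalize_drug_name(DRUGNAME),
                                        syn$variant)]]
  dt
}

#' Select reports naming the target drug in a suspect role
#'
#' A report enters the case set iff it carries at least one drug entry
#' whose canonical name equals `canonical_drug` with a role code in
#' `roles`. The default role set is primary suspect only (`PS`);
#' secondary suspect (`SS`) can be added for sensitivity analyses.
#'
#' @param drug_std standardized DRUG table ([standardize_drugs()] output).
#' @param canonical_drug canonical target drug name.
#' @param roles character vector of qualifying FAERS role codes.
#' @return Character vector of unique PRIMARYIDs (the case set). Empty
#'   case sets trigger a warning, not an error.
#' @export
select_target_reports <- function(drug_std, canonical_drug,
                                  roles = "PS") {
  dt <- data.table::as.data.table(drug_std)
  if (!"CANONICAL" %in% names(dt))
    stop("drug table has no CANONICAL column; run standardize_drugs() first")
  hit <- dt[!is.na(CANONICAL) & CANONICAL == canonical_drug &
              toupper(trimws(ROLE_COD)) %in% roles]
  ids <- unique(trimws(hit$PRIMARYID))
  if (!length(ids))
    warning("no reports matched drug '", canonical_drug,
            "' with role(s) ", paste(roles, collapse = "/"))
  ids
}

#' Collapse drug-event pairs to one row per (report, term)
#'
#' A report listing the same preferred term several times contributes a
#' single pair, so no pair is double-counted downstream.
#'
#' @param reac REAC table with `PRIMARYID` and `PT` columns.
#' @return `data.table` of unique `(PRIMARYID, PT)` pairs.
#' @export
unique_pairs <- function(reac) {
  dt <- data.table::as.data.table(reac)
  out <- unique(dt[, .(PRIMARYID = trimws(PRIMARYID), PT = trimws(PT))])
  out[nzchar(PT)]
}
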
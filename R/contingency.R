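#' Build per-term 2x2 contingency tables
#'
#' For every preferred term observed in the pair universe, counts the
#' classic pharmacovigilance 2x2 table over drug-event pairs:
#' \describe{
#'   \item{a}{case-set pairs carrying the term}
#'   \item{b}{case-set pairs carrying any other term}
#'   \item{c}{comparator pairs carrying the term}
#'   \item{d}{comparator pairs carrying any other term}
#' }
#' The counting unit is the (report, term) pair: a report listing a term
#' several times contributes once, and `a + b` (total case-set pairs) is
#' constant across terms. Terms absent from the case set still get a row
#' (`a = 0`).
#'
#' @param events event table with `PRIMARYID` and `PT` columns (the whole
#'   cleaned, deduplicated universe — case and comparator reports).
#' @param case_ids character vector of PRIMARYIDs forming the case set.
#' @return `data.table` with columns `term`, `a`, `b`, `c`, `d`.
#' @export
build_pt_tables <- function(events, case_ids) {
  pairs <- unique_pairs(events)
  if (!nrow(pairs)) stop("event table is empty")
  case_ids <- unique(trimws(as.character(case_ids)))
  pairs[, in_case := PRIMARYID %chin% case_ids]
  n_case <- sum(pairs$in_case)
  N <- nrow(pairs)
  out <- pairs[, .(a = sum(in_case), tot = .N), by = .(term = PT)]
  out[, b := n_case - a]
  out[, c := tot - a]
  out[, d := N - n_case - tot + a]
  out[, tot := NULL]
  pairs[, in_case := NULL]
  data.table::setorder(out, -a, term)
  out[]
}

#' Roll preferred-term events up to system organ classes
#'
#' Maps each term to its system organ class (SOC) and rebuilds the 2x2
#' tables over distinct (report, SOC) pairs: a report with three terms in
#' one SOC contributes a single pair. Terms missing from the map fall
#' into an explicit `"UNMAPPED"` bucket.
#'
#' @param events event table with `PRIMARYID` and `PT`.
#' @param pt2soc `data.frame` with columns `pt` and `soc`, or path to a
#'   tab-separated file with those columns.
#' @param case_ids PRIMARYIDs forming the case set.
#' @return `data.table` with columns `term` (the SOC), `a`, `b`, `c`, `d`.
#' @export
rollup_soc <- function(events, pt2soc, case_ids) {
  if (is.character(pt2soc) && length(pt2soc) == 1L)
    pt2soc <- data.table::fread(pt2soc, sep = "\t", colClasses = "character")
  map <- data.table::as.data.table(pt2soc)
  data.table::setnames(map, tolower(names(map)))
  if (!all(c("pt", "soc") %in% names(map)))
    stop("pt2soc map needs 'pt' and 'soc' columns")
  pairs <- unique_pairs(events)
  pairs[, SOC := map$soc[match(PT, map$pt)]]
  pairs[is.na(SOC), SOC := "UNMAPPED"]
  soc_events <- unique(pairs[, .(PRIMARYID, PT = SOC)])
  build_pt_tables(soc_events, case_ids)
}

#' Restrict the pair universe to one sex stratum
#'
#' Sex-stratified disproportionality restricts both the case set and the
#' comparator background to reports of the given sex before counting;
#' unknown-sex reports are excluded from both arms.
#'
#' @param events event table with `PRIMARYID` and `PT`.
#' @param demo normalized DEMO records carrying `SEX`.
#' @param case_ids PRIMARYIDs forming the (unstratified) case set.
#' @param sex `"M"` or `"F"`.
#' @param pt2soc optional PT-to-SOC map; when supplied the stratified
#'   tables are built at SOC level via [rollup_soc()].
#' @return Stratified 2x2 tables as from [build_pt_tables()]; zero case
#'   pairs in the stratum yields an empty table with a warning.
#' @export
stratify_by_sex <- function(events, demo, case_ids, sex, pt2soc = NULL) {
  stopifnot(sex %in% c("M", "F"))
  dm <- data.table::as.data.table(demo)
  keep <- trimws(dm$PRIMARYID[dm$SEX == sex])
  ev <- data.table::as.data.table(events)
  ev <- ev[trimws(PRIMARYID) %in% keep]
  cs <- intersect(trimws(as.character(case_ids)), keep)
  if (!nrow(ev) || !length(cs)) {
    warning("no case pairs in sex stratum '", sex, "'")
    return(data.table::data.table(term = character(0), a = integer(0),
                                  b = integer(0), c = integer(0),
                                  d = integer(0)))
  }
  if (is.null(pt2soc)) build_pt_tables(ev, cs) else rollup_soc(ev, pt2soc, cs)
}
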
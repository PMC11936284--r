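#' Configure a synthetic FAERS-like universe
#'
#' Builds the configuration object consumed by [generate_database()]. The
#' generator emulates the structure of the FDA Adverse Event Reporting
#' System: one target drug plus a pool of background drugs, MedDRA-like
#' preferred terms (`PT0001`, ...) rolled up to synthetic system organ
#' classes, demographic margins, duplicate case submissions, partially
#' recorded dates, and Weibull-distributed onset times.
#'
#' Default demographic margins (sex, age band, outcome, country, reporter
#' occupation, reporting year) follow the published descriptive profile of
#' a recent hyperkalemia drug cohort in FAERS (male 48.44%, US 76.6%,
#' death outcome 51.61%, ...), and default onset times follow the
#' early-failure Weibull regime reported there (shape 0.62, scale 95.51
#' days); all are overridable.
#'
#' Event generation: each report draws each preferred term independently
#' with probability `base_rate` (background reports) or
#' `min(1, base_rate * lambda)` (target-drug reports), where `lambda` is
#' the planted relative reporting rate from `planted_rr`; a report that
#' draws no event receives a single term drawn proportionally to those
#' rates, so every report carries at least one reaction.
#'
#' @param n_reports number of distinct cases to simulate.
#' @param n_background_drugs size of the comparator drug pool.
#' @param n_pts number of preferred terms in the vocabulary.
#' @param n_socs number of system organ classes the terms map onto.
#' @param target_drug_share fraction of reports whose primary suspect drug
#'   is the target drug.
#' @param pt_base_rates per-report occurrence probability of each term for
#'   background drugs; default is a Zipf-like profile `(1/j)` scaled so the
#'   expected number of reactions per report is `events_per_report`.
#' @param events_per_report mean reactions per report implied by the
#'   default base rates (ignored when `pt_base_rates` is supplied).
#' @param planted_rr named numeric vector, term id -> true relative
#'   reporting rate lambda (>= 0); unnamed terms default to lambda = 1.
#' @param sex_probs,age_group_probs,outcome_probs,country_probs,
#'   reporter_probs,year_probs categorical margins; each must sum to 1.
#' @param outcome_count_probs distribution of the number of outcome codes
#'   per report (names `"0"`, `"1"`, `"2"`).
#' @param tto_shape,tto_scale Weibull shape (dimensionless) and scale
#'   (days) of the planted time-to-onset distribution.
#' @param duplicate_rate fraction of cases submitted under two PRIMARYIDs.
#' @param bad_date_rate fraction of event/therapy dates truncated to
#'   `YYYYMM`/`YYYY` or blanked.
#' @param target_conc_rate fraction of background reports that also list
#'   the target drug as a concomitant (non-suspect) drug.
#' @param seed default RNG seed used by [generate_database()].
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_database()], [planted_truth()]
#' @export
sim_config <- function(n_reports = 5000,
                       n_background_drugs = 25,
                       n_pts = 100,
                       n_socs = 10,
                       target_drug_share = 0.2,
                       pt_base_rates = NULL,
                       events_per_report = 1.5,
                       planted_rr = numeric(0),
                       sex_probs = c(F = 0.2903, M = 0.4844, unknown = 0.2253),
                       age_group_probs = c("<45" = 0.0243, "45-64" = 0.0919,
                                           "65-74" = 0.1040, ">74" = 0.2886,
                                           unknown = 0.4913) / 1.0001,
                       outcome_probs = c(DE = 0.5161, HO = 0.1974, LT = 0.0365,
                                         DS = 0.0086, RI = 0.0011, OT = 0.2403),
                       outcome_count_probs = c("0" = 0.25, "1" = 0.69, "2" = 0.06),
                       country_probs = c(US = 0.7660, JP = 0.1707, CN = 0.0139,
                                         GB = 0.0139, CO = 0.0087,
                                         OTHER = 0.0269) / 1.0001,
                       reporter_probs = c(MD = 0.3397, CN = 0.3059, PH = 0.2929,
                                          OT = 0.0043, unknown = 0.0572),
                       year_probs = c("2018" = 0.0061, "2019" = 0.0867,
                                      "2020" = 0.1360, "2021" = 0.1750,
                                      "2022" = 0.2331, "2023" = 0.3631),
                       tto_shape = 0.62,
                       tto_scale = 95.51,
                       duplicate_rate = 0.05,
                       bad_date_rate = 0.10,
                       target_conc_rate = 0.02,
                       seed = 1L) {
  stopifnot(is_count(n_reports), is_count(n_background_drugs),
            is_count(n_pts), is_count(n_socs))
  if (!(target_drug_share > 0 && target_drug_share < 1))
    stop("target_drug_share must lie in (0, 1)")
  if (duplicate_rate < 0 || duplicate_rate >= 1)
    stop("duplicate_rate must lie in [0, 1)")
  if (bad_date_rate < 0 || bad_date_rate >= 1)
    stop("bad_date_rate must lie in [0, 1)")
  if (tto_shape <= 0 || tto_scale <= 0)
    stop("Weibull tto_shape and tto_scale must be positive")

  assert_prob_vector(sex_probs, "sex_probs")
  assert_prob_vector(age_group_probs, "age_group_probs")
  assert_prob_vector(outcome_probs, "outcome_probs")
  assert_prob_vector(outcome_count_probs, "outcome_count_probs")
  assert_prob_vector(country_probs, "country_probs")
  assert_prob_vector(reporter_probs, "reporter_probs")
  assert_prob_vector(year_probs, "year_probs")

  pts <- sprintf("PT%04d", seq_len(n_pts))
  if (is.null(pt_base_rates)) {
    w <- 1 / seq_len(n_pts)
    pt_base_rates <- w / sum(w) * events_per_report
    if (any(pt_base_rates > 1)) pt_base_rates <- pmin(pt_base_rates, 1)
  }
  if (length(pt_base_rates) != n_pts)
    stop("pt_base_rates must have length n_pts")
  if (any(pt_base_rates <= 0 | pt_base_rates > 1))
    stop("pt_base_rates must lie in (0, 1]")
  names(pt_base_rates) <- pts

  lambda <- setNames(rep(1, n_pts), pts)
  if (length(planted_rr)) {
    if (is.null(names(planted_rr)) || !all(names(planted_rr) %in% pts))
      stop("planted_rr must be named with term ids present in the vocabulary")
    if (any(planted_rr < 0)) stop("planted relative rates must be >= 0")
    lambda[names(planted_rr)] <- planted_rr
    capped <- pt_base_rates[names(planted_rr)] * planted_rr > 1
    if (any(capped))
      warning("planted rate(s) imply per-report probability > 1; capped at 1: ",
              paste(names(planted_rr)[capped], collapse = ", "))
  }

  structure(list(
    n_reports = as.integer(n_reports),
    n_background_drugs = as.integer(n_background_drugs),
    n_pts = as.integer(n_pts), n_socs = as.integer(n_socs),
    target_drug_share = target_drug_share,
    pt_base_rates = pt_base_rates, lambda = lambda,
    sex_probs = sex_probs, age_group_probs = age_group_probs,
    outcome_probs = outcome_probs, outcome_count_probs = outcome_count_probs,
    country_probs = country_probs, reporter_probs = reporter_probs,
    year_probs = year_probs,
    tto_shape = tto_shape, tto_scale = tto_scale,
    duplicate_rate = duplicate_rate, bad_date_rate = bad_date_rate,
    target_conc_rate = target_conc_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Planted ground truth of a synthetic universe
#'
#' Returns, for every preferred term, the true relative reporting rate
#' lambda and the expected value of the contingency cell `a` (target-drug
#' reports carrying the term) implied exactly by the generative model,
#' including the "at least one reaction" rescue draw.
#'
#' @param config a [sim_config()] object.
#' @return `data.table` with columns `pt`, `lambda`, `p_target` (per
#'   target-report occurrence probability) and `expected_a`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- setNames(pmin(1, config$pt_base_rates * config$lambda),
                names(config$pt_base_rates))
  p_eff <- p + prod(1 - p) * p / sum(p)
  n_target <- config$n_reports * config$target_drug_share
  data.table::data.table(
    pt = names(p), lambda = unname(config$lambda),
    p_target = unname(p_eff),
    expected_a = unname(n_target * p_eff)
  )
}

# draw reaction sets for a block of reports under occurrence probs `p`;
# returns a data.table(row, PT); every report gets >= 1 term
draw_reactions <- function(n, p) {
  pts <- names(p)
  npt <- length(p)
  hit <- matrix(runif(n * npt), nrow = n) < matrix(p, n, npt, byrow = TRUE)
  idx <- which(hit, arr.ind = TRUE)
  empty <- which(rowSums(hit) == 0L)
  if (length(empty)) {
    rescue <- sample.int(npt, length(empty), replace = TRUE, prob = p / sum(p))
    idx <- rbind(idx, cbind(row = empty, col = rescue))
  }
  data.table::data.table(row = idx[, 1], PT = pts[idx[, 2]])
}

# truncate/blank a fraction of YYYYMMDD strings to emulate partial dates
corrupt_dates <- function(x, rate) {
  n <- length(x)
  bad <- runif(n) < rate & nzchar(x)
  style <- sample(c("ym", "y", "blank"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  x[bad & style == "ym"] <- substr(x[bad & style == "ym"], 1, 6)
  x[bad & style == "y"] <- substr(x[bad & style == "y"], 1, 4)
  x[bad & style == "blank"] <- ""
  x
}

#' Generate a synthetic FAERS-like database
#'
#' Simulates the five raw quarterly tables (DEMO, DRUG, REAC, OUTC, THER)
#' in the FAERS ASCII dialect, with known ground truth: planted relative
#' reporting rates per term, planted duplicate submissions, and a planted
#' Weibull time-to-onset distribution. Output is byte-identical for a
#' given seed.
#'
#' Duplicate mechanics: a fraction `duplicate_rate` of cases is emitted
#' under two PRIMARYIDs sharing the CASEID. The superseded version has an
#' earlier FDA_DT (or, for a fifth of duplicates, the same FDA_DT and a
#' lower PRIMARYID; a tenth has a blank FDA_DT), so the canonical
#' latest-FDA_DT / highest-PRIMARYID rule recovers exactly the planted
#' record set.
#'
#' @param config a [sim_config()] object.
#' @param seed integer RNG seed; defaults to `config$seed`.
#' @return An object of class `faers_sim`: list with elements `tables`
#'   (named list of data.tables `demo`, `drug`, `reac`, `outc`, `ther`),
#'   `pt2soc`, `synonyms`, and `truth` (planted per-term truth, target
#'   report ids, duplicate PRIMARYIDs, target drug name).
#' @export
generate_database <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_reports
  target_variants <- c("TARGETDRUG", "TargetDrug", "targetdrug 10 g",
                       "TARGETDRUG.")
  bg_drugs <- sprintf("BGDRUG%03d", seq_len(config$n_background_drugs))

  with_seed(seed, {
    caseid <- 10000000L + seq_len(n)
    is_target <- runif(n) < config$target_drug_share

    sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
    sex_code <- ifelse(sex == "unknown", "", sex)
    ageg <- sample(names(config$age_group_probs), n, TRUE,
                   config$age_group_probs)
    age <- rep(NA_real_, n)
    age[ageg == "<45"] <- runif(sum(ageg == "<45"), 18, 44.9)
    age[ageg == "45-64"] <- runif(sum(ageg == "45-64"), 45, 64.9)
    age[ageg == "65-74"] <- runif(sum(ageg == "65-74"), 65, 74.9)
    age[ageg == ">74"] <- runif(sum(ageg == ">74"), 75, 95)
    country <- sample(names(config$country_probs), n, TRUE,
                      config$country_probs)
    occp <- sample(names(config$reporter_probs), n, TRUE,
                   config$reporter_probs)
    occp[occp == "unknown"] <- ""

    year <- as.integer(sample(names(config$year_probs), n, TRUE,
                              config$year_probs))
    fda_dt <- as.Date(sprintf("%d-01-01", year)) +
      sample.int(365, n, TRUE) - 1L
    event_dt <- fda_dt - (sample.int(91, n, TRUE) - 1L)
    tto_days <- round(rweibull(n, config$tto_shape, config$tto_scale))
    start_dt <- event_dt - tto_days

    # reactions, target reports boosted by planted lambda
    p_bg <- config$pt_base_rates
    p_tg <- setNames(pmin(1, config$pt_base_rates * config$lambda),
                     names(config$pt_base_rates))
    reac_list <- list()
    ti <- which(is_target); bi <- which(!is_target)
    if (length(ti)) {
      r <- draw_reactions(length(ti), p_tg); r$row <- ti[r$row]
      reac_list[[1]] <- r
    }
    if (length(bi)) {
      r <- draw_reactions(length(bi), p_bg); r$row <- bi[r$row]
      reac_list[[2]] <- r
    }
    reac0 <- data.table::rbindlist(reac_list)
    data.table::setorder(reac0, row, PT)

    # drugs: target PS entry at seq 1 for target reports; background pool
    n_extra <- rpois(n, 1L) + ifelse(is_target, 0L, 1L)
    drug_rows <- list()
    if (length(ti))
      drug_rows[[1]] <- data.table::data.table(
        row = ti, DRUG_SEQ = 1L, ROLE_COD = "PS",
        DRUGNAME = sample(target_variants, length(ti), TRUE))
    extra_row <- rep(seq_len(n), n_extra)
    if (length(extra_row)) {
      first_bg <- !duplicated(extra_row) & !is_target[extra_row]
      drug_rows[[2]] <- data.table::data.table(
        row = extra_row,
        DRUG_SEQ = 0L,  # filled below
        ROLE_COD = ifelse(first_bg, "PS",
                          sample(c("SS", "C", "I"), length(extra_row), TRUE,
                                 prob = c(0.3, 0.5, 0.2))),
        DRUGNAME = sample(bg_drugs, length(extra_row), TRUE))
    }
    conc <- bi[runif(length(bi)) < config$target_conc_rate]
    if (length(conc))
      drug_rows[[3]] <- data.table::data.table(
        row = conc, DRUG_SEQ = 0L, ROLE_COD = "C",
        DRUGNAME = sample(target_variants, length(conc), TRUE))
    drug0 <- data.table::rbindlist(drug_rows)
    data.table::setorder(drug0, row)
    drug0[, DRUG_SEQ := seq_len(.N), by = row]

    # outcomes
    # outcome entries are drawn iid so the entry-level margins equal
    # outcome_probs exactly (a report may carry duplicate codes)
    n_outc <- as.integer(sample(names(config$outcome_count_probs), n, TRUE,
                                config$outcome_count_probs))
    orow <- rep(seq_len(n), n_outc)
    outc0 <- data.table::data.table(
      row = orow,
      OUTC_COD = sample(names(config$outcome_probs), length(orow), TRUE,
                        config$outcome_probs))
    data.table::setorder(outc0, row, OUTC_COD)

    # therapy start dates: target drug always; first background drug half
    # the time (its start is unrelated to the event clock)
    ther_rows <- list()
    if (length(ti))
      ther_rows[[1]] <- data.table::data.table(
        row = ti, DSG_DRUG_SEQ = 1L,
        START_DT = format_faers_date(start_dt[ti]))
    bg_ther <- bi[runif(length(bi)) < 0.5]
    if (length(bg_ther))
      ther_rows[[2]] <- data.table::data.table(
        row = bg_ther, DSG_DRUG_SEQ = 1L,
        START_DT = format_faers_date(event_dt[bg_ther] -
                                       sample.int(400, length(bg_ther), TRUE)))
    ther0 <- data.table::rbindlist(ther_rows)
    data.table::setorder(ther0, row)

    # partial/blank dates
    event_str <- corrupt_dates(format_faers_date(event_dt),
                               config$bad_date_rate)
    ther0[, START_DT := corrupt_dates(START_DT, config$bad_date_rate)]

    # duplicate submissions
    n_dup <- as.integer(floor(config$duplicate_rate * n))
    dup_rows <- if (n_dup) sort(sample.int(n, n_dup)) else integer(0)
    version <- rep(1L, n); version[dup_rows] <- 2L
    primaryid <- caseid * 10L + version
    fda_str <- format_faers_date(fda_dt)

    dup_pid <- caseid[dup_rows] * 10L + 1L
    dup_kind <- sample(c("earlier", "tie", "blank"), n_dup, TRUE,
                       prob = c(0.7, 0.2, 0.1))
    dup_fda <- character(n_dup)
    dup_fda[dup_kind == "earlier"] <- format_faers_date(
      fda_dt[dup_rows][dup_kind == "earlier"] -
        sample(10:200, sum(dup_kind == "earlier"), TRUE))
    dup_fda[dup_kind == "tie"] <- fda_str[dup_rows][dup_kind == "tie"]
    dup_fda[dup_kind == "blank"] <- ""

    demo <- data.table::data.table(
      PRIMARYID = primaryid, CASEID = caseid, FDA_DT = fda_str,
      EVENT_DT = event_str, SEX = sex_code,
      AGE = ifelse(is.na(age), "", sprintf("%.0f", age)),
      AGE_COD = ifelse(is.na(age), "", "YR"),
      OCCR_COUNTRY = country, OCCP_COD = occp)

    mk <- function(x0) {
      out <- data.table::copy(x0)
      out[, PRIMARYID := primaryid[row]]
      out[, CASEID := caseid[row]]
      out[, row := NULL]
      out
    }
    drug <- mk(drug0); reac <- mk(reac0); outc <- mk(outc0); ther <- mk(ther0)

    if (n_dup) {
      dmap <- match(dup_rows, seq_len(n))
      demo_dup <- data.table::copy(demo[dmap])
      demo_dup[, PRIMARYID := dup_pid]
      demo_dup[, FDA_DT := dup_fda]
      demo <- rbind(demo, demo_dup)
      dup_copy <- function(x) {
        sel <- x[PRIMARYID %in% primaryid[dup_rows]]
        sel[, PRIMARYID := dup_pid[match(PRIMARYID, primaryid[dup_rows])]]
        rbind(x, sel)
      }
      drug <- dup_copy(drug); reac <- dup_copy(reac)
      outc <- dup_copy(outc); ther <- dup_copy(ther)
    }
    for (tb in list(demo, drug, reac, outc, ther))
      data.table::setorder(tb, PRIMARYID)
    data.table::setcolorder(drug, c("PRIMARYID", "CASEID"))
    data.table::setcolorder(reac, c("PRIMARYID", "CASEID"))
    data.table::setcolorder(outc, c("PRIMARYID", "CASEID"))
    data.table::setcolorder(ther, c("PRIMARYID", "CASEID"))

    pt2soc <- data.table::data.table(
      pt = names(config$pt_base_rates),
      soc = sprintf("SOC%02d", (seq_len(config$n_pts) - 1L) %%
                      config$n_socs + 1L))
    synonyms <- data.table::data.table(
      canonical = "TARGETDRUG",
      variant = c("TARGETDRUG", "TargetDrug", "targetdrug 10 g"))

    truth <- list(
      pt_truth = planted_truth(config),
      n_target_reports = sum(is_target),
      target_primaryids = as.character(primaryid[is_target]),
      duplicate_primaryids = as.character(dup_pid),
      tto_days = tto_days[is_target],
      target_drug = "TARGETDRUG"
    )
    structure(list(tables = list(demo = demo, drug = drug, reac = reac,
                                 outc = outc, ther = ther),
                   pt2soc = pt2soc, synonyms = synonyms, truth = truth,
                   config = config),
              class = "faers_sim")
  })
}

#' Write a synthetic database to FAERS-dialect ASCII files
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `OUTC.txt`, `THER.txt`
#' ('$'-delimited, one header row) plus `truth.tsv`, `pt2soc.tsv` and
#' `synonyms.tsv` into `dir`.
#'
#' @param db a `faers_sim` object from [generate_database()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_faers_tables <- function(db, dir) {
  stopifnot(inherits(db, "faers_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(db$tables))
    data.table::fwrite(db$tables[[nm]],
                       file.path(dir, paste0(toupper(nm), ".txt")),
                       sep = "$", quote = FALSE)
  data.table::fwrite(db$truth$pt_truth, file.path(dir, "truth.tsv"),
                     sep = "\t")
  data.table::fwrite(db$pt2soc, file.path(dir, "pt2soc.tsv"), sep = "\t")
  data.table::fwrite(db$synonyms, file.path(dir, "synonyms.tsv"), sep = "\t")
  invisible(dir)
}
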
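#' Run the full signal-detection pipeline
#'
#' Orchestrates ingest, deduplication, drug standardization, case-set
#' selection, contingency building, four-algorithm disproportionality at
#' preferred-term and (when a map is available) system-organ-class level,
#' sex subgroup analyses, descriptive reporting and Weibull time-to-onset
#' modelling. All result tables are written to `out_dir` as CSV together
#' with a plain-text run manifest recording per-stage record counts, so a
#' rerun on identical inputs is byte-identical.
#'
#' @param input either a directory of FAERS-dialect files (as written by
#'   [write_faers_tables()]) or a `faers_sim` object.
#' @param target canonical target drug name.
#' @param synonyms synonym map (`data.frame` or TSV path); defaults to the
#'   simulation's own map when `input` is a `faers_sim`.
#' @param pt2soc PT-to-SOC map (`data.frame` or TSV path) or `NULL`; when
#'   missing the SOC stage is skipped with a warning.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param roles qualifying drug role codes for the case set.
#' @param thresholds a [signal_thresholds()] object.
#' @param min_tto minimum number of usable onset records for the Weibull
#'   stage (skipped with a warning below it).
#' @return Invisibly, a list with the case ids, descriptive blocks,
#'   annual trend, per-level signal tables (`pt`, `soc`, `male`,
#'   `female`), the TTO summary and Weibull fit, and the manifest lines.
#' @export
run_pipeline <- function(input, target = "TARGETDRUG", synonyms = NULL,
                         pt2soc = NULL, out_dir = NULL, roles = "PS",
                         thresholds = signal_thresholds(), min_tto = 30) {
  stage <- "ingest"
  res <- tryCatch({
    if (inherits(input, "faers_sim")) {
      tables <- input$tables
      synonyms <- synonyms %||% input$synonyms
      pt2soc <- pt2soc %||% input$pt2soc
    } else {
      tables <- read_faers_tables(input)
      if (is.null(synonyms)) {
        p <- file.path(input, "synonyms.tsv")
        if (file.exists(p)) synonyms <- p
      }
      if (is.null(pt2soc)) {
        p <- file.path(input, "pt2soc.tsv")
        if (file.exists(p)) pt2soc <- p
      }
    }
    if (is.null(synonyms)) stop("a synonym map is required")
    manifest <- c(sprintf("target_drug: %s", target),
                  sprintf("roles: %s", paste(roles, collapse = ",")),
                  sprintf("raw_demo_rows: %d", nrow(tables$demo)))

    stage <- "deduplicate"
    demo <- normalize_demo(tables$demo)
    demo <- deduplicate_cases(demo)
    keep <- demo$PRIMARYID
    removed <- attr(demo, "removed_primaryids")
    manifest <- c(manifest,
                  sprintf("deduplicated_reports: %d", nrow(demo)),
                  sprintf("duplicates_removed: %d", length(removed)))
    flt <- function(x) {
      dt <- data.table::as.data.table(x)
      dt[trimws(PRIMARYID) %in% keep]
    }
    drug <- flt(tables$drug); reac <- flt(tables$reac)
    outc <- if (!is.null(tables$outc)) flt(tables$outc) else NULL
    ther <- if (!is.null(tables$ther)) flt(tables$ther) else NULL

    stage <- "select_target"
    drug <- standardize_drugs(drug, synonyms)
    case_ids <- select_target_reports(drug, target, roles)
    manifest <- c(manifest, sprintf("case_reports: %d", length(case_ids)))

    stage <- "descriptive"
    demo_cases <- demo[PRIMARYID %in% case_ids]
    outc_cases <- if (!is.null(outc)) outc[trimws(PRIMARYID) %in% case_ids]
                  else NULL
    descriptive <- describe_cases(demo_cases, outc_cases)
    trend <- annual_trend(demo_cases)

    stage <- "signals_pt"
    pt_tables <- build_pt_tables(reac, case_ids)
    sig_pt <- signal_metrics(pt_tables, thresholds = thresholds)
    # one shrinkage prior per database: reuse the PT-level fit for the
    # SOC rollup and the sex subgroups instead of refitting on few cells
    prior <- attr(sig_pt, "prior")
    manifest <- c(manifest,
                  sprintf("pt_terms: %d", nrow(sig_pt)),
                  sprintf("pt_signals: %d", sum(sig_pt$signal)))

    stage <- "signals_soc"
    sig_soc <- NULL
    if (!is.null(pt2soc)) {
      soc_tables <- rollup_soc(reac, pt2soc, case_ids)
      sig_soc <- signal_metrics(soc_tables, prior = prior,
                                thresholds = thresholds)
      manifest <- c(manifest, sprintf("soc_terms: %d", nrow(sig_soc)))
    } else warning("no PT-to-SOC map supplied; SOC stage skipped")

    stage <- "subgroups"
    subgroup <- list()
    for (sx in c("M", "F")) {
      tb <- stratify_by_sex(reac, demo, case_ids, sx)
      subgroup[[sx]] <- if (nrow(tb))
        signal_metrics(tb, prior = prior, thresholds = thresholds)
      else NULL
    }

    stage <- "tto"
    tto <- ttosum <- wfit <- NULL
    if (!is.null(ther)) {
      tto <- compute_tto(case_ids, ther, demo, drug_std = drug,
                         target = target, roles = roles)
      manifest <- c(manifest, sprintf("tto_records: %d", nrow(tto)))
      if (nrow(tto) >= 1) ttosum <- summarize_tto(tto$tto_days)
      if (nrow(tto) >= min_tto) wfit <- fit_weibull(tto$tto_days)
      else warning("fewer than ", min_tto,
                   " onset records; Weibull stage skipped")
    }

    stage <- "write"
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(x, f) if (!is.null(x))
        data.table::fwrite(x, file.path(out_dir, f))
      desc_flat <- data.table::rbindlist(
        lapply(setdiff(names(descriptive), "n_reports"), function(b)
          cbind(block = b, descriptive[[b]])))
      wr(desc_flat, "descriptive.csv")
      wr(trend, "annual_trend.csv")
      wr(sig_pt, "signals_pt.csv")
      wr(sig_soc, "signals_soc.csv")
      wr(subgroup$M, "signals_male.csv")
      wr(subgroup$F, "signals_female.csv")
      if (!is.null(ttosum)) {
        wr(data.table::data.table(
          n = ttosum$n, median = ttosum$median, q1 = ttosum$q1,
          q3 = ttosum$q3, min = ttosum$min, max = ttosum$max,
          scale_alpha = if (is.null(wfit)) NA else wfit$scale_alpha,
          scale_low = if (is.null(wfit)) NA else wfit$scale_ci[1],
          scale_high = if (is.null(wfit)) NA else wfit$scale_ci[2],
          shape_beta = if (is.null(wfit)) NA else wfit$shape_beta,
          shape_low = if (is.null(wfit)) NA else wfit$shape_ci[1],
          shape_high = if (is.null(wfit)) NA else wfit$shape_ci[2],
          failure_type = if (is.null(wfit)) NA else wfit$failure_type),
          "tto_summary.csv")
        wr(ttosum$histogram, "tto_histogram.csv")
      }
      writeLines(manifest, file.path(out_dir, "manifest.txt"))
    }
    list(case_ids = case_ids, descriptive = descriptive, trend = trend,
         signals = list(pt = sig_pt, soc = sig_soc,
                        male = subgroup$M, female = subgroup$F),
         tto = tto, tto_summary = ttosum, weibull = wfit,
         manifest = manifest)
  }, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
  invisible(res)
}
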
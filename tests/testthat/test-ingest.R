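test_that("FAERS date strings are classified and validated", {
  p <- parse_faers_date(c("20230228", "202302", "2023", "20230230",
                          "", "2023022", "202313"))
  expect_equal(p$status,
               c("full", "partial", "partial", "missing", "missing",
                 "missing", "missing"))
  expect_equal(p$date[1], as.Date("2023-02-28"))
  expect_equal(p$year[1:3], c(2023L, 2023L, 2023L))
})

test_that("age codes convert to years", {
  expect_equal(age_to_years(24, "MON"), 2.0)
  expect_equal(age_to_years(365.25, "DY"), 1.0)
  expect_equal(age_to_years(52.18, "WK"), 1.0)
  expect_equal(age_to_years(8, "DEC"), 80)
  expect_equal(age_to_years(67, "YR"), 67)
  expect_true(is.na(age_to_years("abc", "YR")))
  expect_true(is.na(age_to_years(200, "YR")))
  expect_true(is.na(age_to_years(-5, "YR")))
})

test_that("'$'-delimited tables are read with case-insensitive headers", {
  tmp <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$fda_dt$sex",
               "101$11$20230101$F",
               "102$12$20230215$M"),
             file.path(tmp, "DEMO.txt"))
  tb <- read_faers_tables(list(demo = file.path(tmp, "DEMO.txt")))
  expect_equal(nrow(tb$demo), 2L)
  expect_true(all(c("PRIMARYID", "CASEID", "FDA_DT", "SEX") %in%
                    names(tb$demo)))

  writeLines(c("caseid$fda_dt", "11$20230101"), file.path(tmp, "BAD.txt"))
  expect_error(read_faers_tables(list(demo = file.path(tmp, "BAD.txt"))),
               "PRIMARYID")
})

test_that("synthetic tables round-trip through write and read losslessly", {
  db <- generate_database(sim_config(n_reports = 300, seed = 5))
  tmp <- withr::local_tempdir()
  write_faers_tables(db, tmp)
  back <- read_faers_tables(tmp)
  for (nm in names(db$tables)) {
    orig <- data.table::as.data.table(db$tables[[nm]])
    got <- back[[tolower(nm)]]
    for (cn in names(orig))
      expect_equal(as.character(got[[cn]]), as.character(orig[[cn]]),
                   info = paste(nm, cn))
  }
})

test_that("deduplication follows the latest-FDA_DT, highest-PRIMARYID rule", {
  demo <- data.table::data.table(
    PRIMARYID = c("1", "2", "5", "9", "7", "3", "4"),
    CASEID = c("111", "111", "222", "222", "333", "444", "444"),
    FDA_DT = c("20230101", "20230301", "20230301", "20230301", "20230601",
               "", "20220101"))
  out <- deduplicate_cases(demo)
  expect_equal(sort(out$PRIMARYID), c("2", "4", "7", "9"))
  # latest FDA_DT wins for case 111; PRIMARYID breaks the 222 tie;
  # a dated record beats the missing-date record of case 444
  expect_equal(out$PRIMARYID[out$CASEID == "111"], "2")
  expect_equal(out$PRIMARYID[out$CASEID == "222"], "9")
  expect_equal(out$PRIMARYID[out$CASEID == "444"], "4")
  expect_setequal(attr(out, "removed_primaryids"), c("1", "5", "3"))
})

test_that("deduplication is idempotent and leaves singletons unchanged", {
  demo <- data.table::data.table(PRIMARYID = "1", CASEID = "9",
                                 FDA_DT = "20230101")
  once <- deduplicate_cases(demo)
  expect_equal(once$PRIMARYID, "1")
  db <- generate_database(sim_config(n_reports = 400, duplicate_rate = 0.1,
                                     seed = 3))
  d1 <- deduplicate_cases(normalize_demo(db$tables$demo))
  d2 <- deduplicate_cases(d1)
  expect_equal(d2$PRIMARYID, d1$PRIMARYID)
  expect_length(attr(d2, "removed_primaryids"), 0L)
})

test_that("drug names standardize through the synonym dictionary", {
  syn <- data.frame(
    canonical = c("SODIUM ZIRCONIUM CYCLOSILICATE",
                  "SODIUM ZIRCONIUM CYCLOSILICATE"),
    variant = c("LOKELMA", "Sodium zirconium cyclosilicate"))
  drug <- data.table::data.table(
    PRIMARYID = c("1", "2", "3", "4"),
    DRUGNAME = c("LOKELMA", "sodium  zirconium cyclosilicate",
                 "  lokelma. ", "UNKNOWNIUM"),
    ROLE_COD = "PS")
  std <- standardize_drugs(drug, syn)
  expect_equal(std$CANONICAL[1:3],
               rep("SODIUM ZIRCONIUM CYCLOSILICATE", 3))
  expect_true(is.na(std$CANONICAL[4]))
  expect_equal(nrow(std), 4L)  # unmatched entries are retained

  clash <- data.frame(canonical = c("A", "B"), variant = c("x", "X "))
  expect_error(standardize_drugs(drug, clash), "more than one canonical")
})

test_that("case-set selection honors the suspect-role filter", {
  syn <- data.frame(canonical = "TARGET", variant = "target")
  drug <- data.table::data.table(
    PRIMARYID = c("1", "1", "2", "3", "3"),
    DRUGNAME = c("TARGET", "OTHER", "TARGET", "TARGET", "TARGET"),
    ROLE_COD = c("PS", "C", "C", "PS", "SS"))
  std <- standardize_drugs(drug, syn)
  expect_setequal(select_target_reports(std, "TARGET"), c("1", "3"))
  expect_setequal(select_target_reports(std, "TARGET", roles = c("PS", "SS")),
                  c("1", "3"))
  expect_warning(got <- select_target_reports(std, "NOSUCH"), "no reports")
  expect_length(got, 0L)
})

test_that("pipeline case set recovers the planted target count exactly", {
  db <- generate_database(sim_config(n_reports = 1500, duplicate_rate = 0.08,
                                     seed = 11))
  demo <- deduplicate_cases(normalize_demo(db$tables$demo))
  drug <- db$tables$drug[trimws(PRIMARYID) %in% demo$PRIMARYID]
  std <- standardize_drugs(drug, db$synonyms)
  cases <- select_target_reports(std, db$truth$target_drug)
  expect_setequal(cases, db$truth$target_primaryids)
})
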
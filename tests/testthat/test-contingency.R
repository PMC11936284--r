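test_that("hand-counted toy universe yields the expected 2x2 cells", {
  tb <- build_pt_tables(toy_events(), toy_case_ids)
  expect_equal(nrow(tb), 3L)
  expect_equal(as.list(tb[term == "PT_A", .(a, b, c, d)]),
               list(a = 2L, b = 1L, c = 0L, d = 3L))
  expect_equal(as.list(tb[term == "PT_B", .(a, b, c, d)]),
               list(a = 1L, b = 2L, c = 1L, d = 2L))
  expect_equal(as.list(tb[term == "PT_C", .(a, b, c, d)]),
               list(a = 0L, b = 3L, c = 2L, d = 1L))
})

test_that("duplicate (report, term) rows are collapsed before counting", {
  ev <- rbind(toy_events(), data.table::data.table(PRIMARYID = "r1",
                                                   PT = "PT_A"))
  expect_equal(build_pt_tables(ev, toy_case_ids),
               build_pt_tables(toy_events(), toy_case_ids))
})

test_that("pair counting matches a brute-force enumeration oracle", {
  for (seed in 1:8) {
    u <- random_universe(seed = seed)
    got <- as.data.frame(build_pt_tables(u$events, u$case_ids))
    want <- oracle_tables(u$events, u$case_ids)
    m <- merge(got, want, by = "term", suffixes = c("", ".o"))
    expect_equal(m$a, m$a.o, info = paste("seed", seed))
    expect_equal(m$b, m$b.o)
    expect_equal(m$c, m$c.o)
    expect_equal(m$d, m$d.o)
    # margins: a+b is the case pair total for every term; cells tile N
    expect_equal(unique(m$a + m$b),
                 sum(unique(u$events)$PRIMARYID %in% u$case_ids))
    expect_true(all(m$a + m$b + m$c + m$d == nrow(unique(u$events))))
  }
})

test_that("SOC rollup counts distinct (report, SOC) pairs", {
  map <- data.frame(pt = c("PT_A", "PT_B", "PT_C"),
                    soc = c("SOC1", "SOC1", "SOC2"))
  ev <- data.table::data.table(
    PRIMARYID = c("r1", "r1", "r2", "r3"),
    PT = c("PT_A", "PT_B", "PT_C", "PT_A"))
  tb <- rollup_soc(ev, map, case_ids = c("r1", "r2"))
  # r1 has two terms in SOC1 but contributes a single pair
  expect_equal(tb[term == "SOC1", a], 1L)
  expect_equal(tb[term == "SOC2", a], 1L)
  expect_equal(tb[term == "SOC1", c], 1L)  # r3

  # a SOC holding a single term reproduces that term's table
  solo <- data.frame(pt = c("PT_A", "PT_B", "PT_C"),
                     soc = c("S_A", "S_B", "S_C"))
  u <- random_universe(seed = 4)
  pt_tb <- build_pt_tables(u$events, u$case_ids)
  # single-term map on a distinct-term universe
  solo_map <- data.frame(pt = unique(u$events$PT),
                         soc = paste0("S_", unique(u$events$PT)))
  soc_tb <- rollup_soc(u$events, solo_map, u$case_ids)
  m <- merge(as.data.frame(pt_tb),
             transform(as.data.frame(soc_tb), term = sub("^S_", "", term)),
             by = "term", suffixes = c("", ".soc"))
  expect_equal(m$a, m$a.soc)
  expect_equal(m$d, m$d.soc)
})

test_that("SOC rollup agrees with a set-union oracle on random universes", {
  map <- data.frame(pt = sprintf("T%d", 1:6),
                    soc = c("S1", "S1", "S2", "S2", "S3", "S3"))
  for (seed in 1:5) {
    u <- random_universe(seed = seed + 100)
    got <- as.data.frame(rollup_soc(u$events, map, u$case_ids))
    ev <- unique(as.data.frame(u$events))
    ev$SOC <- map$soc[match(ev$PT, map$pt)]
    soc_pairs <- unique(ev[, c("PRIMARYID", "SOC")])
    names(soc_pairs) <- c("PRIMARYID", "PT")
    want <- oracle_tables(soc_pairs, u$case_ids)
    m <- merge(got, want, by = "term", suffixes = c("", ".o"))
    expect_equal(m$a, m$a.o)
    expect_equal(m$b, m$b.o)
    expect_equal(m$c, m$c.o)
    expect_equal(m$d, m$d.o)
  }
})

test_that("unmapped terms fall into an explicit bucket", {
  map <- data.frame(pt = "PT_A", soc = "SOC1")
  tb <- rollup_soc(toy_events(), map, toy_case_ids)
  expect_true("UNMAPPED" %in% tb$term)
})

test_that("sex stratification restricts both arms to the stratum", {
  demo <- data.table::data.table(
    PRIMARYID = c("r1", "r2", "r3", "r4"),
    SEX = c("M", "M", "M", "M"))
  tb_m <- stratify_by_sex(toy_events(), demo, toy_case_ids, "M")
  expect_equal(tb_m, build_pt_tables(toy_events(), toy_case_ids))
  expect_warning(tb_f <- stratify_by_sex(toy_events(), demo, toy_case_ids,
                                         "F"), "no case pairs")
  expect_equal(nrow(tb_f), 0L)

  # mixed universe vs. enumeration restricted by hand
  demo2 <- data.table::data.table(
    PRIMARYID = sprintf("r%02d", 1:30),
    SEX = rep(c("M", "F", "unknown"), 10))
  u <- random_universe(seed = 7)
  got <- as.data.frame(stratify_by_sex(u$events, demo2, u$case_ids, "F"))
  keep <- demo2$PRIMARYID[demo2$SEX == "F"]
  ev_f <- u$events[PRIMARYID %in% keep]
  want <- oracle_tables(ev_f, intersect(u$case_ids, keep))
  m <- merge(got, want, by = "term", suffixes = c("", ".o"))
  expect_equal(m$a, m$a.o)
  expect_equal(m$d, m$d.o)

  # strata cells never exceed the unstratified cells
  full <- as.data.frame(build_pt_tables(u$events, u$case_ids))
  gm <- as.data.frame(stratify_by_sex(u$events, demo2, u$case_ids, "M"))
  both <- merge(merge(full, gm, by = "term", suffixes = c("", ".m")),
                got, by = "term", suffixes = c("", ".f"))
  expect_true(all(both$a.m + both$a.f <= both$a))
  expect_true(all(both$c.m + both$c.f <= both$c))
})
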
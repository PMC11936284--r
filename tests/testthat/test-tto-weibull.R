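make_tto_fixture <- function() {
  demo <- data.table::data.table(
    PRIMARYID = c("1", "2", "3", "4", "5"),
    EVENT_DT = c("20230203", "20230110", "202303", "20230501", "20230601"))
  ther <- data.table::data.table(
    PRIMARYID = c("1", "2", "3", "4", "4", "5"),
    START_DT = c("20230101", "20230120", "20230101", "20230420",
                 "20230410", "202301"))
  list(demo = demo, ther = ther)
}

test_that("time-to-onset is calendar arithmetic with principled exclusions", {
  fx <- make_tto_fixture()
  tto <- compute_tto(c("1", "2", "3", "4", "5"), fx$ther, fx$demo)
  # report 1: 33 days; report 2 negative (excluded); report 3 partial
  # event; report 4 uses the earliest full start (Apr 10 -> 21 days);
  # report 5 has only a partial start
  expect_equal(tto[PRIMARYID == "1", tto_days], 33)
  expect_equal(tto[PRIMARYID == "4", tto_days], 21)
  expect_equal(nrow(tto), 2L)
  excl <- attr(tto, "exclusions")
  expect_equal(unname(excl["negative_interval"]), 1L)
  expect_equal(unname(excl["partial_or_missing_event"]), 1L)
  expect_equal(unname(excl["partial_or_missing_start"]), 1L)
})

test_that("summaries use median-unbiased quantiles and 30-day bins", {
  expect_equal(summarize_tto(c(1, 2, 3))$median, 2)
  x <- c(0, 5, 12, 31, 59, 60, 61, 200)
  s <- summarize_tto(x)
  expect_equal(s$min, 0)
  expect_equal(s$max, 200)
  expect_equal(s$median, unname(quantile(x, 0.5, type = 8)))
  # bins: [0,30] holds 3, (30,60] holds 3, (60,90] holds 1
  expect_equal(s$histogram$count[1:3], c(3L, 3L, 1L))
  expect_equal(sum(s$histogram$count), length(x))

  # first-month share printed style: 117 of 240 -> 48.75%
  v <- c(seq(0, 30, length.out = 117), seq(31, 800, length.out = 123))
  h <- summarize_tto(v)$histogram
  expect_equal(h$percent[1], 48.75)
  expect_error(summarize_tto(numeric(0)), "no time-to-onset")
})

test_that("Weibull fit recovers the exponential special case", {
  set.seed(2)
  t <- rexp(5000, rate = 1 / 50)
  fit <- fit_weibull(t)
  expect_gt(fit$shape_beta, 0.95)
  expect_lt(fit$shape_beta, 1.05)
  expect_equal(fit$scale_alpha, 50, tolerance = 0.1)
})

test_that("the joint MLE satisfies the profile identity for the scale", {
  set.seed(3)
  t <- rweibull(400, 0.7, 80)
  fit <- fit_weibull(t)
  # score equation for alpha at the optimum: alpha^beta = mean(t^beta)
  expect_equal(fit$scale_alpha^fit$shape_beta,
               mean(t^fit$shape_beta), tolerance = 1e-6)
  # log-likelihood at the MLE beats the moment-based start
  slt <- sd(log(t)); b0 <- pi / (slt * sqrt(6))
  a0 <- exp(mean(log(t)) + 0.5772156649 / b0)
  llmle <- -pvsignal:::weibull_negloglik(c(log(fit$scale_alpha),
                                           log(fit$shape_beta)), t)
  llstart <- -pvsignal:::weibull_negloglik(c(log(a0), log(b0)), t)
  expect_gte(llmle, llstart)
})

test_that("Weibull fit is scale-equivariant", {
  set.seed(4)
  t <- rweibull(300, 0.62, 95)
  f1 <- fit_weibull(t)
  f2 <- fit_weibull(t * 7)
  expect_equal(f2$scale_alpha, 7 * f1$scale_alpha, tolerance = 1e-6)
  expect_equal(f2$shape_beta, f1$shape_beta, tolerance = 1e-6)
})

test_that("estimates agree with an independent MLE implementation", {
  set.seed(6)
  t <- rweibull(500, 0.62, 95.51)
  t[t == 0] <- 0.5
  fit <- fit_weibull(t)
  ref <- fitdistrplus::fitdist(t, "weibull")
  expect_equal(fit$shape_beta, unname(ref$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(fit$scale_alpha, unname(ref$estimate["scale"]),
               tolerance = 1e-3)
})

test_that("hazard patterns classify from the shape interval", {
  set.seed(7)
  early <- fit_weibull(rweibull(800, 0.6, 100))
  expect_equal(early$failure_type, "early")
  wear <- fit_weibull(rweibull(800, 2.5, 100))
  expect_equal(wear$failure_type, "wear-out")
  rand <- fit_weibull(rweibull(800, 1.0, 100))
  expect_equal(rand$failure_type, "random")
  expect_true(early$shape_ci[1] < early$shape_beta &
                early$shape_beta < early$shape_ci[2])
})

test_that("zero onset days are handled and short series warn", {
  fit <- suppressWarnings(fit_weibull(c(0, 0, 1, 2, 3, 5, 8, 13, 21, 34)))
  expect_true(is.finite(fit$shape_beta))
  expect_warning(fit_weibull(c(0, 1, 2, 3, 5, 8, 13, 21, 34, 55, 2)),
                 "fewer than 30")
  expect_error(fit_weibull(1:5), "at least 10")
})

test_that("recovered synthetic onset times match the planted distribution", {
  cfg <- sim_config(n_reports = 1200, target_drug_share = 0.25,
                    duplicate_rate = 0, bad_date_rate = 0.1)
  rejected <- 0L
  for (seed in 1:10) {
    db <- generate_database(cfg, seed = 300 + seed)
    demo <- normalize_demo(db$tables$demo)
    drug <- standardize_drugs(db$tables$drug, db$synonyms)
    cases <- select_target_reports(drug, db$truth$target_drug)
    tto <- compute_tto(cases, db$tables$ther, demo, drug_std = drug,
                       target = db$truth$target_drug)
    expect_gt(nrow(tto), 150)
    # recovered values are a subset of the planted per-report onsets
    expect_true(all(tto$tto_days %in% db$truth$tto_days))
    ks <- suppressWarnings(
      stats::ks.test(tto$tto_days, "pweibull", shape = cfg$tto_shape,
                     scale = cfg$tto_scale))
    if (ks$p.value < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 1L)
})
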
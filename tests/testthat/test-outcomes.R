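test_that("median and IQR follow the linear-interpolation quantile rule", {
  r <- bind_records(
    make_record(1, 1, age = 50, fatal = TRUE, reactions = "Gastric cancer"),
    make_record(2, 2, age = 59, fatal = FALSE, reactions = "Gastric cancer"),
    make_record(3, 3, age = 70, fatal = FALSE, reactions = "Gastric cancer"))
  r$is_tae <- TRUE
  r$tae_terms <- list("Gastric cancer", "Gastric cancer", "Gastric cancer")
  t1 <- tae_table1(r)
  age <- t1$variables$Age$summary["overall", ]
  expect_equal(age$median, 59)
  expect_equal(age$q25, 54.5)
  expect_equal(age$q75, 64.5)
})

test_that("single-stratum categorical variables skip the test with a reason", {
  r <- bind_records(
    make_record(1, 1, sex = "male", fatal = TRUE,
                reactions = "Gastric cancer"),
    make_record(2, 2, sex = "male", reactions = "Gastric cancer"))
  r$is_tae <- TRUE
  r$tae_terms <- list("Gastric cancer", "Gastric cancer")
  t1 <- tae_table1(r)
  sex <- t1$variables$Sex
  expect_identical(sex$test, "none")
  expect_match(sex$test_reason, "fewer than two")
})

test_that("categorical tests switch to Fisher when expected counts are small", {
  x <- synthetic_tae_cases()
  t1 <- tae_table1(x)
  expect_identical(t1$variables$Sex$test, "Pearson's Chi-squared test")
  # rabeprazole stratum forces small expected counts
  expect_identical(t1$variables$Group$test, "Fisher's exact test")
  expect_true(all(vapply(t1$variables, function(v)
    is.na(v$p) || (v$p >= 0 && v$p <= 1), logical(1))))
})

test_that("stratum percentages sum to 100 within each categorical variable", {
  t1 <- tae_table1(synthetic_tae_cases())
  for (v in t1$variables)
    if (v$type == "categorical") {
      expect_equal(sum(v$summary$overall_pct), 100, tolerance = 1e-9)
      expect_equal(sum(v$summary$fatal_n) + sum(v$summary$nonfatal_n),
                   t1$n_overall)
    }
})

test_that("annual proportions partition the case set", {
  d <- generate_faers(small_config(1500, seed = 23))
  cases <- classify_tae(ingest_cases(d)$records)
  ann <- annual_tae_proportions(cases)
  expect_identical(sum(ann$total_n), nrow(cases))
  expect_identical(sum(ann$tae_n), sum(cases$is_tae))
  expect_equal(ann$percent, 100 * ann$tae_n / ann$total_n)
  # a year with 2 of 100 reports 2.00
  expect_equal(unname(100 * 2 / 100), 2)
})

test_that("a constant planted tumor rate stays inside its binomial band", {
  cfg <- faers_sim_config(
    20000, event_vocabulary = c("Gastric cancer", "Diarrhoea"),
    tumor_terms = "Gastric cancer",
    background_event_prob = c("Gastric cancer" = 0.03, "Diarrhoea" = 0.2),
    duplicate_rate = 0, seed = 17)
  cases <- classify_tae(ingest_cases(generate_faers(cfg))$records)
  ann <- annual_tae_proportions(cases)
  big <- ann[ann$total_n >= 200, ]
  p_hat <- big$tae_n / big$total_n
  band <- 1.96 * sqrt(0.03 * 0.97 / big$total_n)
  expect_true(all(abs(p_hat - 0.03) <= band + 0.015))
})

test_that("tumor sites aggregate gastric PTs under stomach and sum to 100", {
  r <- bind_records(
    make_record(1, 1, fatal = TRUE, reactions = "Gastric cancer"),
    make_record(2, 2, reactions = "Gastric adenocarcinoma"),
    make_record(3, 3, reactions = "Metastatic gastric cancer"),
    make_record(4, 4, reactions = "Gastric cancer stage III"),
    make_record(5, 5, reactions = "Renal cell carcinoma"))
  cc <- classify_tae(r)
  prof <- tumor_site_profile(cc)
  expect_identical(prof$n[prof$site == "stomach"], 4L)
  expect_equal(sum(prof$pct_cases), 100)
  expect_equal(sum(prof$pct_of_fatal), 100)
  expect_equal(prof$pct_of_fatal[prof$site == "stomach"], 100)

  # with no fatal cases the fatality shares are all zero
  r2 <- r
  r2$outcome_fatal <- FALSE
  expect_true(all(tumor_site_profile(classify_tae(r2))$pct_of_fatal == 0))
})

test_that("co-reported AE shares count cases once per SOC", {
  recs <- lapply(1:10, function(i) {
    reac <- if (i <= 8)
      c("Gastric cancer", "Renal cyst", "Nephropathy") else "Gastric cancer"
    make_record(i, i, reactions = reac)
  })
  cc <- classify_tae(do.call(bind_records, recs))
  co <- co_reported_profile(cc)
  expect_equal(co$pct_with_co, 80)
  expect_identical(co$n_with_co, 8L)
  # Renal cyst and Nephropathy share a SOC: credited once per case
  expect_identical(co$by_soc$n[co$by_soc$soc == "Renal and urinary disorders"],
                   8L)
  expect_equal(co$by_soc$percent[1], 100)
})

test_that("the product-limit estimate equals empirical survival without censoring", {
  k <- km_curve(c(1, 2, 3))
  expect_equal(k$curves$survival, c(2 / 3, 1 / 3, 0))
  # against the empirical survival function on random data
  set.seed(3)
  t <- sample(1:50, 20, replace = TRUE)
  k2 <- km_curve(t)
  emp <- vapply(k2$curves$time, function(s) mean(t > s), numeric(1))
  expect_equal(k2$curves$survival, emp, tolerance = 1e-12)
})

test_that("a censored five-subject curve matches the hand product-limit table", {
  k <- km_curve(c(1, 2, 3, 4, 5), event = c(1, 0, 1, 1, 1))
  # events at 1, 3, 4, 5; at-risk 5, 3, 2, 1
  ev <- k$curves[k$curves$n_event > 0, ]
  expect_equal(ev$survival, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2, 0))
})

test_that("identical groups give a null log-rank test", {
  t <- c(5, 9, 13, 21, 40)
  k <- km_curve(c(t, t), rep(c("a", "b"), each = 5))
  expect_equal(k$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(k$logrank_p, 1, tolerance = 1e-9)
})

test_that("the Mann-Whitney test agrees with exhaustive enumeration", {
  set.seed(11)
  for (i in 1:6) {
    n1 <- sample(3:4, 1); n2 <- sample(3:4, 1)
    pool <- sample(1:100, n1 + n2)
    x <- pool[seq_len(n1)]; y <- pool[n1 + seq_len(n2)]
    k <- km_curve(c(x, y), rep(c("a", "b"), c(n1, n2)))
    expect_equal(k$mannwhitney_p, mw_enum_p(x, y), tolerance = 1e-9)
  }
})

test_that("Fisher's exact p matches hypergeometric enumeration", {
  set.seed(21)
  for (i in 1:10) {
    cells <- sample(0:7, 4, replace = TRUE)
    if (sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0 ||
        sum(cells[c(1, 2)]) == 0 || sum(cells[c(3, 4)]) == 0) next
    tab <- matrix(cells, 2)
    expect_equal(stats::fisher.test(tab)$p.value,
                 fisher_enum_p(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-7)
  }
})

test_that("onset days require both dates and a non-negative interval", {
  r <- bind_records(
    make_record(1, 1, starts = "2015-01-01", event_dt = "2015-01-11"),
    make_record(2, 2, starts = NA, event_dt = "2015-01-11"),
    make_record(3, 3, starts = "2016-01-01", event_dt = "2015-01-01"))
  d <- onset_days(r)
  expect_equal(d[1], 10)
  expect_true(all(is.na(d[2:3])))
  expect_identical(attr(d, "n_excluded"), 2L)
})
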
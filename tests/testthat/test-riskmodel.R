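test_that("age bands follow the documented boundary convention", {
  expect_identical(as.character(band_age(c(64.9, 65, 70, 75, 75.5, 40))),
                   c("<65", "65-75", "65-75", "65-75", ">75", "<65"))
  expect_true(is.na(band_age(NA)))
  expect_true(is.na(band_age(200)))
})

test_that("dose bands follow the documented boundary convention", {
  expect_identical(as.character(band_dose(c(20, 20.5, 40, 40.5, 5, 100))),
                   c("Low", "Medium", "Medium", "High", "Low", "High"))
  expect_true(is.na(band_dose(NA)))
  expect_true(is.na(band_dose(0)))
})

# build a minimal classified case set from a 2x2 layout:
# exposure level B vs A, outcome is_tae
cases_from_cells <- function(a, b, c, d) {
  n <- a + b + c + d
  df <- data.frame(
    is_tae = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)),
    expo = rep(c("B", "A", "B", "A"), c(a, b, c, d)),
    stringsAsFactors = FALSE)
  df
}

test_that("a binary exposure reproduces the sample odds ratio exactly", {
  set.seed(31)
  for (i in 1:30) {
    cells <- sample(1:40, 4, replace = TRUE)
    fit <- tae_logistic(cases_from_cells(cells[1], cells[2], cells[3],
                                         cells[4]),
                        "expo", levels = c("A", "B"))
    or_hat <- fit$or[fit$level == "B"]
    or_tab <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    expect_equal(or_hat, or_tab, tolerance = 1e-6)
  }
})

test_that("Wald intervals are geometrically centred on the odds ratio", {
  fit <- tae_logistic(cases_from_cells(20, 10, 100, 200), "expo",
                      levels = c("A", "B"))
  i <- which(!fit$reference)
  expect_equal(sqrt(fit$ci_low[i] * fit$ci_high[i]), fit$or[i],
               tolerance = 1e-9)
})

test_that("the fitted likelihood dominates the intercept-only model", {
  fit <- tae_logistic(cases_from_cells(25, 10, 60, 80), "expo",
                      levels = c("A", "B"))
  expect_gte(attr(fit, "loglik"), attr(fit, "null_loglik"))
  expect_lt(attr(fit, "gradient_norm"), 1e-6)
})

test_that("relabelling non-reference levels permutes rows, not values", {
  df <- data.frame(
    is_tae = rep(c(TRUE, FALSE), times = c(60, 240)),
    expo = c(rep(c("A", "B", "C"), c(20, 25, 15)),
             rep(c("A", "B", "C"), c(100, 60, 80))),
    stringsAsFactors = FALSE)
  f1 <- tae_logistic(df, "expo", levels = c("A", "B", "C"))
  f2 <- tae_logistic(df, "expo", levels = c("A", "C", "B"))
  for (lv in c("B", "C")) {
    expect_equal(f1$or[f1$level == lv], f2$or[f2$level == lv],
                 tolerance = 1e-9)
    expect_equal(f1$p[f1$level == lv], f2$p[f2$level == lv],
                 tolerance = 1e-9)
  }
})

test_that("separated levels are flagged non-estimable, not fatal", {
  df <- data.frame(
    is_tae = c(rep(TRUE, 10), rep(FALSE, 50)),
    expo = c(rep("A", 10), rep(c("A", "B"), c(30, 20))),
    stringsAsFactors = FALSE)
  fit <- suppressWarnings(tae_logistic(df, "expo", levels = c("A", "B")))
  expect_false(fit$estimable[fit$level == "B"])
  expect_true(is.na(fit$or[fit$level == "B"]))
})

test_that("a single-class outcome is a hard error", {
  df <- data.frame(is_tae = rep(FALSE, 40),
                   expo = rep(c("A", "B"), 20), stringsAsFactors = FALSE)
  expect_error(tae_logistic(df, "expo"), "single class")
})

test_that("missing exposures are excluded and counted", {
  r <- bind_records(
    make_record(1, 1, age = NA, reactions = "Gastric cancer"),
    make_record(2, 2, age = 50), make_record(3, 3, age = 70),
    make_record(4, 4, age = 80, reactions = "Gastric cancer"),
    make_record(5, 5, age = 55), make_record(6, 6, age = 77))
  cc <- classify_tae(r)
  fit <- suppressWarnings(tae_logistic(cc, "age"))
  expect_identical(attr(fit, "n_excluded"), 1L)
  expect_identical(attr(fit, "n_used"), 5L)
  expect_identical(fit$level[fit$reference], "<65")
})

test_that("dose subgroup fits mirror the per-drug layout with Low reference", {
  set.seed(7)
  n <- 3000
  drugs <- sample(c("esomeprazole", "pantoprazole"), n, replace = TRUE)
  doses <- sample(c(20, 40, 80), n, replace = TRUE)
  tae <- runif(n) < ifelse(doses > 40, 0.12, 0.08)
  recs <- lapply(seq_len(n), function(i)
    make_record(i, i, drugs = drugs[i], doses = doses[i],
                reactions = if (tae[i]) "Gastric cancer" else "Diarrhoea"))
  cc <- classify_tae(do.call(bind_records, recs))
  fits <- suppressWarnings(dose_subgroup_fits(cc))
  expect_true(all(c("All", "esomeprazole", "pantoprazole") %in% names(fits)))
  all_fit <- fits$All
  expect_identical(all_fit$level, c("Low", "Medium", "High"))
  expect_true(all_fit$reference[1])

  # a drug with a single populated band is skipped with a warning
  one_band <- lapply(1:60, function(i)
    make_record(1000 + i, 1000 + i, drugs = "rabeprazole", doses = 20,
                reactions = if (i %% 3 == 0) "Gastric cancer"
                else "Diarrhoea"))
  cc2 <- classify_tae(do.call(bind_records, one_band))
  w <- capture_warnings(f2 <- dose_subgroup_fits(cc2))
  expect_true(any(grepl("skipped", w)))
  expect_false("rabeprazole" %in% names(f2))
})
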
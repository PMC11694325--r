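test_that("dedup keeps the latest receipt date, ties to the higher primaryid", {
  r <- bind_records(make_record(100, 7, "2023-01-01"),
                    make_record(101, 7, "2023-03-01"))
  out <- deduplicate_reports(r)
  expect_identical(out$records$primaryid, 101L)
  expect_identical(out$ledger$removed, 1L)

  r <- bind_records(make_record(100, 7, "2023-01-01"),
                    make_record(200, 7, "2023-01-01"))
  expect_identical(deduplicate_reports(r)$records$primaryid, 200L)

  one <- make_record(5, 5)
  expect_equal(as.data.frame(deduplicate_reports(one)$records),
               as.data.frame(one))
})

test_that("records with missing receipt dates lose dedup ties", {
  r <- bind_records(make_record(900, 7, NA), make_record(100, 7, "2001-01-01"))
  expect_identical(deduplicate_reports(r)$records$primaryid, 100L)
})

test_that("deduplication and exclusion are idempotent", {
  d <- generate_faers(small_config(800, seed = 21, duplicate_rate = 0.15))
  rec <- as_report_records(d)
  once <- deduplicate_reports(rec)
  twice <- deduplicate_reports(once$records)
  expect_equal(as.data.frame(once$records), as.data.frame(twice$records))
  expect_identical(twice$ledger$removed, 0L)
  e1 <- apply_exclusions(once$records, d$deleted)
  e2 <- apply_exclusions(e1$records, d$deleted)
  expect_equal(as.data.frame(e1$records), as.data.frame(e2$records))
  expect_identical(sum(e2$ledger$removed), 0L)
})

test_that("ledger counts are conserved at every stage", {
  for (seed in c(2, 13, 77)) {
    d <- generate_faers(small_config(600, seed = seed,
                                     duplicate_rate = 0.1,
                                     invalid_age_rate = 0.02,
                                     invalid_weight_rate = 0.02))
    ing <- ingest_cases(d)
    led <- ing$ledger
    expect_identical(attr(led, "input_n"),
                     sum(led$removed) + attr(led, "output_n"))
    expect_identical(attr(led, "output_n"), nrow(ing$records))
  }
})

test_that("the surviving record set is order-independent", {
  d <- generate_faers(small_config(400, seed = 8, duplicate_rate = 0.2))
  rec <- as_report_records(d)
  ref <- ingest_cases(d)$records$primaryid
  set.seed(1)
  for (i in 1:3) {
    perm <- rec[sample.int(nrow(rec)), ]
    out <- apply_exclusions(deduplicate_reports(perm)$records,
                            d$deleted)$records
    expect_setequal(out$primaryid, ref)
  }
})

test_that("age and weight filters act only on present, out-of-range values", {
  r <- bind_records(
    make_record(1, 1, age = 151),
    make_record(2, 2, age = 150),
    make_record(3, 3, age = -1),
    make_record(4, 4, weight = 160),
    make_record(5, 5, weight = 150),
    make_record(6, 6, age = NA, weight = NA))
  out <- apply_exclusions(r)
  expect_setequal(out$records$caseid, c(2L, 5L, 6L))
  expect_identical(out$ledger$removed[out$ledger$stage == "age"], 2L)
  expect_identical(out$ledger$removed[out$ledger$stage == "weight"], 1L)
  # optional strict mode drops missing values instead
  strict <- apply_exclusions(r, drop_missing = TRUE)
  expect_setequal(strict$records$caseid, c(2L, 5L))
})

test_that("suspect-role restriction drops concomitant-only study-drug cases", {
  r <- bind_records(
    make_record(1, 1, roles = "PS"),
    make_record(2, 2, roles = "C"),
    make_record(3, 3, drugs = c("esomeprazole", "ibuprofen"),
                doses = c(40, 400), roles = c("SS", "C"),
                reactions = "Nausea"))
  out <- apply_exclusions(r, suspect_only = TRUE)
  expect_setequal(out$records$caseid, c(1L, 3L))
  all_kept <- apply_exclusions(r, suspect_only = FALSE)
  expect_identical(nrow(all_kept$records), 3L)
})

test_that("residual exact-duplicate content under different ids is removed", {
  a <- make_record(1, 1, "2023-01-01")
  b <- make_record(2, 2, "2023-02-02")  # same content, different ids/dates
  c_ <- make_record(3, 3, age = 61)
  out <- apply_exclusions(bind_records(a, b, c_))
  expect_identical(
    out$ledger$removed[out$ledger$stage == "residual_duplicate"], 1L)
  expect_identical(nrow(out$records), 2L)
})

test_that("reader enforces the schema and tolerates unknown columns", {
  d <- generate_faers(small_config(30, seed = 4))
  dir <- withr::local_tempdir()
  write_faers(d, dir)

  # extra column: warning, ignored
  demo <- read.delim(file.path(dir, "demo.tsv"))
  demo$spurious <- 1
  write.table(demo, file.path(dir, "demo.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  expect_warning(d2 <- read_faers(dir), "spurious")
  expect_identical(nrow(d2$demo), nrow(d$demo))

  # unparseable date: missing with a warning, not an error
  demo$spurious <- NULL
  demo$fda_dt[1] <- "not-a-date"
  write.table(demo, file.path(dir, "demo.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  expect_warning(d3 <- read_faers(dir), "unparseable date")
  expect_true(is.na(d3$demo$fda_dt[1]))

  # missing mandatory column: schema error naming it
  demo$caseid <- NULL
  write.table(demo, file.path(dir, "demo.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  expect_error(read_faers(dir), "caseid")
})
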
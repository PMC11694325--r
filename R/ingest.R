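#' Read a FAERS-shaped dataset from delimited text
#'
#' Reads the four relational tables written by [write_faers()] (or any
#' extract laid out the same way) and the optional delete-list file.
#' Unknown extra columns are ignored with a warning; unparseable dates
#' become missing with a warning rather than an error. Missing mandatory
#' columns raise a schema error naming the column.
#'
#' @param dir Directory holding `demo`, `drug`, `reac`, `outc` tables
#'   (`.tsv` or `.csv`) and optionally `delete.txt`.
#' @param sep Field separator, default tab.
#' @return A `faers_data` object.
#' @export
read_faers <- function(dir, sep = "\t") {
  ext <- if (sep == "\t") "tsv" else "csv"
  need <- list(
    demo = c("primaryid", "caseid", "fda_dt", "age", "sex", "wt",
             "reporter_country", "event_dt"),
    drug = c("primaryid", "drugname", "dose_amt", "start_dt", "role"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"))
  out <- list()
  for (nm in names(need)) {
    p <- file.path(dir, paste0(nm, ".", ext))
    if (!file.exists(p)) stop("table file not found: ", p)
    tab <- utils::read.delim(p, sep = sep, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    miss <- setdiff(need[[nm]], names(tab))
    if (length(miss))
      stop(sprintf("schema error: table '%s' is missing column(s): %s",
                   nm, paste(miss, collapse = ", ")))
    extra <- setdiff(names(tab), need[[nm]])
    if (length(extra)) {
      warning(sprintf("table '%s': ignoring unknown column(s): %s",
                      nm, paste(extra, collapse = ", ")))
      tab <- tab[need[[nm]]]
    }
    for (cc in intersect(c("fda_dt", "event_dt", "start_dt"), names(tab))) {
      raw <- tab[[cc]]
      parsed <- as.Date(raw, format = "%Y-%m-%d")
      bad <- !is.na(raw) & is.na(parsed)
      if (any(bad))
        warning(sprintf("table '%s', column '%s': %d unparseable date(s) set to missing",
                        nm, cc, sum(bad)))
      tab[[cc]] <- parsed
    }
    out[[nm]] <- tab
  }
  delp <- file.path(dir, "delete.txt")
  deleted <- if (file.exists(delp)) {
    v <- readLines(delp)
    as.integer(v[nzchar(v)])
  } else integer()
  structure(c(out, list(deleted = deleted, config = NULL)),
            class = "faers_data")
}

#' Assemble record-level reports from the relational tables
#'
#' Joins the four tables on `primaryid` into one row per report record,
#' with list-columns for the (possibly multiple) drug exposures and
#' reaction PTs. This is the working representation all downstream stages
#' operate on.
#'
#' @param x A `faers_data` object.
#' @return A data frame of class `report_cases` with columns `primaryid`,
#'   `caseid`, `fda_dt`, `age`, `sex`, `weight_kg`, `reporter_country`,
#'   `event_dt`, `outcome_fatal` and list-columns `drug_name`,
#'   `dose_mgday`, `ther_start`, `drug_role`, `reactions`.
#' @export
as_report_records <- function(x) {
  stopifnot(inherits(x, "faers_data"))
  demo <- x$demo
  f <- factor(x$drug$primaryid, levels = demo$primaryid)
  fr <- factor(x$reac$primaryid, levels = demo$primaryid)
  rec <- data.frame(
    primaryid = demo$primaryid, caseid = demo$caseid, fda_dt = demo$fda_dt,
    age = demo$age, sex = demo$sex, weight_kg = demo$wt,
    reporter_country = demo$reporter_country, event_dt = demo$event_dt,
    stringsAsFactors = FALSE)
  rec$outcome_fatal <- x$outc$outc_cod[match(demo$primaryid,
                                             x$outc$primaryid)] == "DE"
  rec$drug_name <- unname(split(x$drug$drugname, f))
  rec$dose_mgday <- unname(split(x$drug$dose_amt, f))
  rec$ther_start <- unname(split(x$drug$start_dt, f))
  rec$drug_role <- unname(split(x$drug$role, f))
  rec$reactions <- unname(split(x$reac$pt, fr))
  class(rec) <- c("report_cases", "data.frame")
  rec
}

new_ledger <- function(stages, removed, input_n, output_n) {
  structure(data.frame(stage = stages, removed = as.integer(removed),
                       stringsAsFactors = FALSE),
            input_n = input_n, output_n = output_n,
            class = c("filter_ledger", "data.frame"))
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat(sprintf("Filter ledger: %d records in, %d out\n",
              attr(x, "input_n"), attr(x, "output_n")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-20s -%d\n", x$stage[i], x$removed[i]))
  invisible(x)
}

combine_ledgers <- function(a, b) {
  new_ledger(c(a$stage, b$stage), c(a$removed, b$removed),
             attr(a, "input_n"), attr(b, "output_n"))
}

#' Deduplicate report versions to one record per case
#'
#' FAERS stores multiple versioned records (`primaryid`) per case
#' (`caseid`); analyses count deduplicated cases. The survivor is the
#' record with the latest receipt date (`fda_dt`), ties broken by the
#' higher `primaryid`. Records with a missing `fda_dt` lose ties to any
#' dated record (they are treated as earliest), which keeps the order
#' total and the operation deterministic.
#'
#' @param records A `report_cases` data frame.
#' @return A list with `records` (one row per caseid) and `ledger`
#'   (a `filter_ledger` with the single stage `"duplicate"`).
#' @export
deduplicate_reports <- function(records) {
  n_in <- nrow(records)
  if (n_in == 0L)
    return(list(records = records,
                ledger = new_ledger("duplicate", 0L, 0L, 0L)))
  dt <- as.integer(records$fda_dt)
  dt[is.na(dt)] <- -.Machine$integer.max
  ord <- order(records$caseid, -dt, -records$primaryid)
  out <- records[ord, , drop = FALSE]
  out <- out[!duplicated(out$caseid), , drop = FALSE]
  out <- out[order(out$caseid), , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       ledger = new_ledger("duplicate", n_in - nrow(out), n_in, nrow(out)))
}

#' Apply the report exclusion cascade
#'
#' Applies, in order: delete-file removal, age range filter (present ages
#' outside \[0, 150\] removed), weight filter (present weights over 150 kg
#' removed), suspect-role restriction (optionally keep only cases whose
#' study-drug exposure carries a suspect role), and residual exact-duplicate
#' removal (identical rows that survived the caseid dedup). Missing age or
#' weight is retained by default: the range filters apply only to present
#' values, which maximizes case yield; set `drop_missing = TRUE` to drop
#' instead.
#'
#' @param records Deduplicated `report_cases`.
#' @param delete_ids Integer primaryids from the delete file.
#' @param suspect_only If `TRUE`, keep only cases where a study drug has a
#'   role in `suspect_roles`.
#' @param suspect_roles Roles counted as suspect (default primary/secondary
#'   suspect, `"PS"` and `"SS"`).
#' @param study_drugs Drug labels defining study exposure.
#' @param drop_missing Drop records with missing age or weight.
#' @return A list with filtered `records` and a `filter_ledger` reporting
#'   each stage count in application order.
#' @export
apply_exclusions <- function(records, delete_ids = integer(),
                             suspect_only = TRUE,
                             suspect_roles = c("PS", "SS"),
                             study_drugs = STUDY_DRUGS,
                             drop_missing = FALSE) {
  n_in <- nrow(records)
  stages <- c("delete_file", "age", "weight", "suspect_role",
              "residual_duplicate")
  removed <- integer(5)

  keep <- !(records$primaryid %in% delete_ids)
  removed[1] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  bad_age <- !is.na(records$age) & (records$age < 0 | records$age > 150)
  if (drop_missing) bad_age <- bad_age | is.na(records$age)
  removed[2] <- sum(bad_age)
  records <- records[!bad_age, , drop = FALSE]

  bad_wt <- !is.na(records$weight_kg) & records$weight_kg > 150
  if (drop_missing) bad_wt <- bad_wt | is.na(records$weight_kg)
  removed[3] <- sum(bad_wt)
  records <- records[!bad_wt, , drop = FALSE]

  if (isTRUE(suspect_only)) {
    nr <- nrow(records)
    li <- rep.int(seq_len(nr), lengths(records$drug_name))
    dn <- unlist(records$drug_name, use.names = FALSE)
    rl <- unlist(records$drug_role, use.names = FALSE)
    hit <- li[norm_term(dn) %in% norm_term(study_drugs) &
                rl %in% suspect_roles]
    ok <- tabulate(hit, nr) > 0L
    removed[4] <- sum(!ok)
    records <- records[ok, , drop = FALSE]
  }

  # residual exact-duplicate rows: identical report content filed under
  # different case ids (ids are excluded from the comparison). A cheap
  # scalar key prefilters candidate rows before the full content key is
  # built, so the common no-duplicate path stays linear.
  if (nrow(records)) {
    cheap <- paste(records$age, records$sex, records$weight_kg,
                   records$reporter_country, as.integer(records$event_dt),
                   records$outcome_fatal, lengths(records$drug_name),
                   lengths(records$reactions), sep = "\r")
    cand <- duplicated(cheap) | duplicated(cheap, fromLast = TRUE)
    dupd <- logical(nrow(records))
    if (any(cand)) {
      collapse1 <- function(l) vapply(l, paste, character(1),
                                      collapse = "|")
      key <- paste(cheap[cand],
                   collapse1(records$drug_name[cand]),
                   collapse1(records$dose_mgday[cand]),
                   collapse1(records$drug_role[cand]),
                   collapse1(records$ther_start[cand]),
                   collapse1(lapply(records$reactions[cand], sort)),
                   sep = "\r")
      dupd[cand] <- duplicated(key)
    }
    removed[5] <- sum(dupd)
    records <- records[!dupd, , drop = FALSE]
  }
  rownames(records) <- NULL
  list(records = records,
       ledger = new_ledger(stages, removed, n_in, nrow(records)))
}

#' One-call ingest: read, deduplicate, exclude
#'
#' Convenience wrapper running [read_faers()] (when given a directory),
#' [as_report_records()], [deduplicate_reports()] and [apply_exclusions()],
#' returning the surviving case-level records and the full filter ledger.
#'
#' @param x A directory path or a `faers_data` object.
#' @param delete_ids Primaryids to discard; defaults to the dataset's own
#'   delete list.
#' @inheritParams apply_exclusions
#' @param sep Field separator when reading from a directory.
#' @return List with `records` (`report_cases`, one row per case) and
#'   `ledger` (`filter_ledger`).
#' @export
ingest_cases <- function(x, delete_ids = NULL, suspect_only = TRUE,
                         suspect_roles = c("PS", "SS"),
                         study_drugs = STUDY_DRUGS, drop_missing = FALSE,
                         sep = "\t") {
  if (is.character(x)) x <- read_faers(x, sep = sep)
  stopifnot(inherits(x, "faers_data"))
  if (is.null(delete_ids)) delete_ids <- x$deleted %||% integer()
  rec <- as_report_records(x)
  d <- deduplicate_reports(rec)
  e <- apply_exclusions(d$records, delete_ids = delete_ids,
                        suspect_only = suspect_only,
                        suspect_roles = suspect_roles,
                        study_drugs = study_drugs,
                        drop_missing = drop_missing)
  list(records = e$records, ledger = combine_ledgers(d$ledger, e$ledger))
}
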
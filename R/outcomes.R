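#' Primary study drug of each case
#'
#' The first study drug on the case carrying a suspect role, falling back
#' to the first study drug in record order, then to the first drug.
#'
#' @param cases `report_cases`.
#' @param study_drugs Study drug labels.
#' @param suspect_roles Roles counted as suspect.
#' @return Character vector of drug labels (lower case).
#' @export
primary_study_drug <- function(cases, study_drugs = STUDY_DRUGS,
                               suspect_roles = c("PS", "SS")) {
  sd <- norm_term(study_drugs)
  mapply(function(dn, rl) {
    k <- norm_term(dn)
    i <- which(k %in% sd & rl %in% suspect_roles)
    if (!length(i)) i <- which(k %in% sd)
    if (!length(i)) i <- 1L
    k[i[1]]
  }, cases$drug_name, cases$drug_role, USE.NAMES = FALSE)
}

#' Days from therapy start to event
#'
#' Time to onset per case: days from the earliest study-drug therapy start
#' date to the event date. Cases with either date missing, or a negative
#' interval, are set `NA`; their count is reported in the
#' `n_excluded` attribute.
#'
#' @inheritParams primary_study_drug
#' @return Numeric vector of days (`NA` where not computable) with
#'   attribute `n_excluded`.
#' @export
onset_days <- function(cases, study_drugs = STUDY_DRUGS) {
  sd <- norm_term(study_drugs)
  starts <- mapply(function(dn, st) {
    st <- st[norm_term(dn) %in% sd & !is.na(st)]
    if (!length(st)) NA_integer_ else min(as.integer(st))
  }, cases$drug_name, cases$ther_start, USE.NAMES = FALSE)
  days <- as.integer(cases$event_dt) - as.integer(starts)
  days[!is.na(days) & days < 0] <- NA_integer_
  structure(as.numeric(days), n_excluded = sum(is.na(days)))
}

# five-year calendar bins, left-closed as printed
year_period <- function(year) {
  cut(year, breaks = seq(2000, 2025, by = 5), right = FALSE,
      labels = c("2000-2005", "2005-2010", "2010-2015", "2015-2020",
                 "2020-2025"))
}

report_year <- function(cases) {
  y <- as.integer(format(cases$event_dt, "%Y"))
  y[is.na(y)] <- as.integer(format(cases$fda_dt, "%Y"))[is.na(y)]
  y
}

# chi-square by default, Fisher's exact when any expected cell < 5
categorical_test <- function(tab) {
  if (nrow(tab) < 2L || ncol(tab) < 2L ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(test = "none", p = NA_real_,
                reason = "fewer than two populated strata"))
  exp_cells <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(exp_cells$expected < 5)) {
    p <- tryCatch(stats::fisher.test(tab, workspace = 2e7)$p.value,
                  error = function(e)
                    suppressWarnings(stats::chisq.test(tab)$p.value))
    list(test = "Fisher's exact test", p = p,
         reason = "expected cell count < 5")
  } else {
    list(test = "Pearson's Chi-squared test", p = exp_cells$p.value,
         reason = "all expected cell counts >= 5")
  }
}

summ_cont <- function(x, qtype) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = qtype,
                       names = FALSE)
  c(q25 = q[1], median = q[2], q75 = q[3])
}

#' Stratified characteristics table of the tumor-event case set
#'
#' Summarizes the tumor adverse-event cases by fatal outcome, in the
#' conventional case-series layout: median (IQR) for continuous variables
#' (age, time to onset), n (%) for categorical strata (sex, reporter
#' country, drug group, five-year calendar period; missing is a stratum),
#' with a group-comparison test per variable -- Wilcoxon rank-sum for
#' continuous variables, Pearson chi-square for categorical, switching to
#' Fisher's exact test when any expected cell count is below 5. Percentages
#' are of the column total. Quantiles use linear interpolation between
#' order statistics (R type 7) by default.
#'
#' @param cases Classified `report_cases`; rows with `is_tae == TRUE` are
#'   summarized (pass a pre-filtered TAE set or a classified full set).
#' @param quantile_type Quantile rule passed to [stats::quantile()].
#' @inheritParams primary_study_drug
#' @return Object of class `tae_table1`: list of per-variable entries
#'   (`summary` data frame, `test`, `p`, `test_reason`) plus column totals.
#' @export
tae_table1 <- function(cases, quantile_type = 7,
                       study_drugs = STUDY_DRUGS) {
  if ("is_tae" %in% names(cases)) cases <- cases[cases$is_tae, , drop = FALSE]
  if (nrow(cases) == 0L) stop("empty tumor-event case set")
  fatal <- cases$outcome_fatal %in% TRUE
  n_all <- nrow(cases); n_f <- sum(fatal); n_nf <- n_all - n_f

  country <- toupper(trimws(cases$reporter_country))
  country[!is.na(country) & !country %in% c("US", "JP", "GB")] <- "OTHER"
  country[is.na(country)] <- "missing"
  sex <- cases$sex
  sex[is.na(sex)] <- "missing"
  group <- primary_study_drug(cases, study_drugs)
  tto <- onset_days(cases, study_drugs)
  period <- as.character(year_period(report_year(cases)))
  period[is.na(period)] <- "missing"

  out <- list()
  add_cont <- function(name, x) {
    s <- rbind(overall = summ_cont(x, quantile_type),
               fatal = summ_cont(x[fatal], quantile_type),
               nonfatal = summ_cont(x[!fatal], quantile_type))
    tst <- if (length(unique(fatal[!is.na(x)])) == 2L)
      list(test = "Wilcoxon rank sum test",
           p = suppressWarnings(stats::wilcox.test(x[fatal],
                                                   x[!fatal])$p.value),
           reason = "continuous variable")
    else list(test = "none", p = NA_real_, reason = "single group")
    out[[name]] <<- list(name = name, type = "continuous",
                         summary = as.data.frame(s),
                         n_missing = sum(is.na(x)),
                         test = tst$test, p = tst$p,
                         test_reason = tst$reason)
  }
  add_cat <- function(name, x, levels = NULL) {
    if (is.null(levels)) levels <- sort(unique(x))
    x <- factor(x, levels = levels)
    tab <- table(x, factor(fatal, levels = c(TRUE, FALSE)))
    s <- data.frame(
      stratum = levels,
      overall_n = as.integer(table(x)),
      overall_pct = 100 * as.integer(table(x)) / n_all,
      fatal_n = as.integer(tab[, 1]),
      fatal_pct = if (n_f) 100 * as.integer(tab[, 1]) / n_f else 0,
      nonfatal_n = as.integer(tab[, 2]),
      nonfatal_pct = if (n_nf) 100 * as.integer(tab[, 2]) / n_nf else 0,
      stringsAsFactors = FALSE)
    tst <- categorical_test(tab[rowSums(tab) > 0, , drop = FALSE])
    out[[name]] <<- list(name = name, type = "categorical", summary = s,
                         test = tst$test, p = tst$p,
                         test_reason = tst$reason)
  }

  add_cont("Age", ifelse(!is.na(cases$age) &
                           cases$age >= 0 & cases$age <= 150,
                         cases$age, NA_real_))
  add_cat("Sex", sex, c("female", "male", "missing"))
  add_cat("Reporter Country",
          country, intersect(c("GB", "JP", "US", "OTHER", "missing"),
                             unique(country)))
  add_cat("Group", group, intersect(norm_term(study_drugs), unique(group)))
  add_cont("Time to Event", tto)
  add_cat("Year", period)

  structure(list(variables = out, n_overall = n_all, n_fatal = n_f,
                 n_nonfatal = n_nf),
            class = "tae_table1")
}

#' @export
print.tae_table1 <- function(x, digits = 1, ...) {
  cat(sprintf("TAE case characteristics: overall N = %d, fatal N = %d, non-fatal N = %d\n",
              x$n_overall, x$n_fatal, x$n_nonfatal))
  for (v in x$variables) {
    cat(sprintf("\n%s  [%s%s]\n", v$name, v$test,
                if (!is.na(v$p)) sprintf(", p = %.3g", v$p) else ""))
    if (v$type == "continuous") {
      s <- v$summary
      for (r in rownames(s))
        cat(sprintf("  %-9s %s (%s, %s)\n", r,
                    format(s[r, "median"]), format(s[r, "q25"]),
                    format(s[r, "q75"])))
    } else {
      s <- v$summary
      for (i in seq_len(nrow(s)))
        cat(sprintf("  %-12s %5d (%4.*f%%)  fatal %4d  non-fatal %4d\n",
                    s$stratum[i], s$overall_n[i], digits,
                    s$overall_pct[i], s$fatal_n[i], s$nonfatal_n[i]))
    }
  }
  invisible(x)
}

#' Annual tumor-event proportions
#'
#' Partitions all cases (tumor and non-tumor) by calendar year and reports
#' the yearly tumor-event share.
#'
#' @param cases Classified `report_cases` (full set, with `is_tae`).
#' @return Data frame with `year`, `tae_n`, `total_n`, `percent`.
#' @export
annual_tae_proportions <- function(cases) {
  stopifnot("is_tae" %in% names(cases))
  y <- report_year(cases)
  keep <- !is.na(y)
  y <- y[keep]
  tae <- cases$is_tae[keep]
  years <- sort(unique(y))
  total <- as.integer(table(factor(y, levels = years)))
  tae_n <- as.integer(table(factor(y[tae], levels = years)))
  data.frame(year = years, tae_n = tae_n, total_n = total,
             percent = 100 * tae_n / total)
}

#' Tumor-site profile of the TAE case set
#'
#' Aggregates tumor-event cases by anatomical site using the hierarchy's
#' site mapping. Each case is assigned one site -- that of its first
#' matched tumor PT in reaction order (ties are thereby broken
#' deterministically); tumor PTs without a site mapping fall into
#' `"other/unspecified"`. Reports each site's case count, share of TAE
#' cases and share of fatal TAE cases.
#'
#' @param cases Classified `report_cases`.
#' @param hierarchy A `meddra_hierarchy` with a `site` column.
#' @return Data frame with `site`, `n`, `pct_cases`, `fatal_n`,
#'   `pct_of_fatal`, ordered by descending count.
#' @export
tumor_site_profile <- function(cases, hierarchy = default_hierarchy()) {
  if ("is_tae" %in% names(cases)) cases <- cases[cases$is_tae, , drop = FALSE]
  if (nrow(cases) == 0L)
    return(data.frame(site = character(), n = integer(),
                      pct_cases = numeric(), fatal_n = integer(),
                      pct_of_fatal = numeric()))
  fatal <- cases$outcome_fatal %in% TRUE
  first_pt <- vapply(cases$tae_terms, function(t)
    if (length(t)) t[1] else NA_character_, character(1))
  site <- hierarchy$site[meddra_index(hierarchy, first_pt)]
  site[is.na(site) | !nzchar(site)] <- "other/unspecified"
  sites <- names(sort(table(site), decreasing = TRUE))
  n <- as.integer(table(factor(site, levels = sites)))
  fn <- as.integer(table(factor(site[fatal], levels = sites)))
  data.frame(site = sites, n = n, pct_cases = 100 * n / nrow(cases),
             fatal_n = fn,
             pct_of_fatal = if (sum(fatal)) 100 * fn / sum(fatal) else 0,
             stringsAsFactors = FALSE)
}

#' Co-reported adverse events among tumor-event cases
#'
#' Among TAE cases, the share accompanied by at least one non-tumor PT,
#' and -- over the cases with any co-reported AE -- the per-SOC and per-PT
#' co-reporting percentages (each SOC or PT credited at most once per
#' case).
#'
#' @param cases Classified `report_cases`.
#' @param hierarchy A `meddra_hierarchy` for SOC assignment; PTs absent
#'   from it are grouped under `"Unknown"`.
#' @return List with `n_tae`, `n_with_co`, `pct_with_co`, and data frames
#'   `by_soc` and `by_pt` (`n`, `percent` of co-AE cases).
#' @export
co_reported_profile <- function(cases, hierarchy = default_hierarchy()) {
  if ("is_tae" %in% names(cases)) cases <- cases[cases$is_tae, , drop = FALSE]
  n_tae <- nrow(cases)
  tset <- norm_term(tumor_terms(hierarchy))
  co <- lapply(cases$reactions, function(r)
    unique(r[!(norm_term(r) %in% tset)]))
  has_co <- lengths(co) > 0L
  n_co <- sum(has_co)
  li <- rep.int(seq_len(n_tae), lengths(co))
  pts <- unlist(co, use.names = FALSE)
  by_pt <- by_soc <- data.frame(n = integer(), percent = numeric())
  if (length(pts)) {
    tab <- sort(table(pts), decreasing = TRUE)
    by_pt <- data.frame(pt = names(tab), n = as.integer(tab),
                        percent = 100 * as.integer(tab) / n_co,
                        stringsAsFactors = FALSE)
    soc <- pt_soc(hierarchy, pts)
    soc[is.na(soc)] <- "Unknown"
    pair <- !duplicated(paste(li, soc))
    stab <- sort(table(soc[pair]), decreasing = TRUE)
    by_soc <- data.frame(soc = names(stab), n = as.integer(stab),
                         percent = 100 * as.integer(stab) / n_co,
                         stringsAsFactors = FALSE)
  }
  list(n_tae = n_tae, n_with_co = n_co,
       pct_with_co = if (n_tae) 100 * n_co / n_tae else 0,
       by_soc = by_soc, by_pt = by_pt)
}

#' Product-limit event-free curve with group comparison
#'
#' Kaplan-Meier event-free probability over onset times, with a log-rank
#' test across groups and, for two groups, a Mann-Whitney U test on the
#' raw onset days. With no censoring the product-limit estimate equals the
#' empirical survival function. Groups with zero usable observations are
#' dropped with a warning.
#'
#' @param time Days to event (non-negative).
#' @param group Optional group labels (default a single group).
#' @param event Event indicator, 1 = event (default); 0 marks censoring.
#' @return Object of class `km_fit`: list with `curves` (data frame
#'   `group`, `time`, `n_risk`, `n_event`, `survival`), `medians`,
#'   `logrank_chisq`, `logrank_p`, `mannwhitney_p`, `n_excluded`.
#' @export
km_curve <- function(time, group = NULL, event = 1) {
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)
  event <- rep_len(event, length(time))
  keep <- !is.na(time) & !is.na(group)
  n_excl <- sum(!keep)
  time <- time[keep]; group <- group[keep]; event <- event[keep]
  if (!length(time)) stop("no usable observations")
  df <- data.frame(time = time, event = event, group = group,
                   stringsAsFactors = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) setNames(length(fit$time),
                                              unique(group))
  else fit$strata
  gl <- sub("^group=", "", names(strata))
  curves <- data.frame(
    group = rep(gl, strata), time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, survival = fit$surv, stringsAsFactors = FALSE)
  med <- stats::aggregate(time ~ group, df, stats::median)
  names(med)[2] <- "median_days"
  lr_chi <- lr_p <- mw_p <- NA_real_
  if (length(unique(group)) >= 2L) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    lr_chi <- sd$chisq
    lr_p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1,
                          lower.tail = FALSE)
    if (length(unique(group)) == 2L)
      mw_p <- suppressWarnings(
        stats::wilcox.test(time ~ group, data = df)$p.value)
  }
  structure(list(curves = curves, medians = med, logrank_chisq = lr_chi,
                 logrank_p = lr_p, mannwhitney_p = mw_p,
                 n_excluded = n_excl),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier time-to-onset analysis\n")
  print(x$medians, row.names = FALSE)
  if (!is.na(x$logrank_p))
    cat(sprintf("  log-rank chi-square = %.3f, p = %.3g\n",
                x$logrank_chisq, x$logrank_p))
  if (!is.na(x$mannwhitney_p))
    cat(sprintf("  Mann-Whitney U p = %.3g\n", x$mannwhitney_p))
  if (x$n_excluded)
    cat(sprintf("  (%d observation(s) excluded: missing/invalid onset)\n",
                x$n_excluded))
  invisible(x)
}

#' Time-to-onset analysis of the TAE case set
#'
#' Computes per-case onset days ([onset_days()]) and fits [km_curve()]
#' grouped by fatal outcome (`group_by = "fatal"`) or primary study drug
#' (`group_by = "drug"`).
#'
#' @param cases Classified `report_cases` (TAE set or full classified set).
#' @param group_by `"fatal"` or `"drug"`.
#' @inheritParams primary_study_drug
#' @return A `km_fit`.
#' @export
onset_km <- function(cases, group_by = c("fatal", "drug"),
                     study_drugs = STUDY_DRUGS) {
  group_by <- match.arg(group_by)
  if ("is_tae" %in% names(cases)) cases <- cases[cases$is_tae, , drop = FALSE]
  days <- onset_days(cases, study_drugs)
  g <- if (group_by == "fatal")
    ifelse(cases$outcome_fatal %in% TRUE, "fatal", "non-fatal")
  else primary_study_drug(cases, study_drugs)
  km_curve(days, g)
}
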
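#' Build a 2x2 contingency table for one drug group and event
#'
#' Counts deduplicated cases (a case contributes at most one to each cell):
#' `a` = cases exposed to any drug in `drug_group` reporting the event,
#' `b` = comparator cases reporting the event, `c` and `d` their
#' complements. The comparator is every case in the loaded dataset with no
#' exposure to the target drug group -- the dataset-closed reading of
#' "all other medications".
#'
#' @param cases A `report_cases` data frame.
#' @param drug_group Character vector of drug labels defining the target
#'   group.
#' @param event A PT label, or a set of PT labels any of which counts as
#'   the event.
#' @param known_events Optional vocabulary to validate `event` against; an
#'   event absent from it raises an error.
#' @return An object of class `ror_table`: list with integer cells
#'   `a`, `b`, `c`, `d` and the `drug_group` and `event` labels.
#' @export
build_table <- function(cases, drug_group, event, known_events = NULL) {
  stopifnot(is.data.frame(cases), length(drug_group) >= 1L)
  if (!is.null(known_events) &&
      !all(norm_term(event) %in% norm_term(known_events)))
    stop("unknown event label: ",
         paste(setdiff(event, known_events), collapse = ", "))
  n <- nrow(cases)
  li <- rep.int(seq_len(n), lengths(cases$drug_name))
  exposed <- tabulate(li[norm_term(unlist(cases$drug_name,
                                          use.names = FALSE)) %in%
                           norm_term(drug_group)], n) > 0L
  ri <- rep.int(seq_len(n), lengths(cases$reactions))
  has_evt <- tabulate(ri[norm_term(unlist(cases$reactions,
                                          use.names = FALSE)) %in%
                           norm_term(event)], n) > 0L
  new_ror_table(sum(exposed & has_evt), sum(!exposed & has_evt),
                sum(exposed & !has_evt), sum(!exposed & !has_evt),
                paste(drug_group, collapse = "+"),
                paste(event, collapse = "+"))
}

new_ror_table <- function(a, b, c, d, drug_group = "target",
                          event = "event") {
  cells <- as.integer(c(a, b, c, d))
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative integers")
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 drug_group = drug_group, event = event),
            class = "ror_table")
}

#' @export
print.ror_table <- function(x, ...) {
  cat(sprintf("2x2 table [%s x %s]\n", x$drug_group, x$event))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("event", "no event"),
                              c("target", "comparator")))
  print(t(m))
  invisible(x)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' Computes `ROR = (a*d)/(b*c)` and the log-symmetric Wald interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A pair is flagged as
#' a signal when at least `min_cases` target-drug event reports exist
#' (`a >= min_cases`) and the lower CI bound exceeds one -- the standard
#' disproportionality criterion. A signal flags a pair for evaluation; it
#' does not establish causation.
#'
#' With `correction = "haldane"` (default) 0.5 is added to all four cells
#' only when any cell is zero (Haldane-Anscombe), keeping scans total over
#' sparse pairs; with `"none"` a zero cell yields non-finite estimates,
#' flagged rather than raised. A table with all four cells zero is
#' undefined and raises an error.
#'
#' @param x A `ror_table`, or a numeric vector `c(a, b, c, d)`.
#' @param correction `"haldane"` or `"none"`.
#' @param conf_level Confidence level (default 0.95, z = 1.96).
#' @param min_cases Minimum event count for the signal flag (default 3).
#' @return Object of class `ror_result`: list with `ror`, `ci_low`,
#'   `ci_high`, `se_log`, `n_cases` (the cell `a`), `is_signal`,
#'   `correction_applied`, and the input `table`.
#' @export
ror <- function(x, correction = c("haldane", "none"), conf_level = 0.95,
                min_cases = 3L) {
  if (is.numeric(x) && length(x) == 4L)
    x <- new_ror_table(x[1], x[2], x[3], x[4])
  stopifnot(inherits(x, "ror_table"))
  correction <- match.arg(correction)
  a <- x$a; b <- x$b; c <- x$c; d <- x$d
  if (a + b + c + d == 0L)
    stop("undefined result: all four cells are zero")
  if (a + c == 0L || b + d == 0L)
    stop("undefined result: a margin is zero")
  corrected <- FALSE
  if (any(c(a, b, c, d) == 0L) && correction == "haldane") {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  est <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lo <- exp(log(est) - z * se)
  hi <- exp(log(est) + z * se)
  structure(list(ror = est, ci_low = lo, ci_high = hi, se_log = se,
                 n_cases = x$a,
                 is_signal = is.finite(lo) && x$a >= min_cases && lo > 1,
                 correction_applied = corrected, conf_level = conf_level,
                 table = x),
            class = "ror_result")
}

#' @export
print.ror_result <- function(x, digits = 3, ...) {
  cat(sprintf("ROR [%s x %s]: %.*f (%.*f, %.*f), n=%d%s%s\n",
              x$table$drug_group, x$table$event,
              digits, x$ror, digits, x$ci_low, digits, x$ci_high,
              x$n_cases,
              if (x$is_signal) ", SIGNAL" else "",
              if (x$correction_applied) " [0.5 correction]" else ""))
  invisible(x)
}

#' Disproportionality scan over drug groups and tumor events
#'
#' Builds the 2x2 table and ROR for every (drug group, tumor PT) pair with
#' at least one target-drug report. Drug groups default to each study drug
#' separately plus the combined all-drug group. Pairs with fewer than
#' `min_cases` reports carry `is_signal = FALSE`. Results are ordered with
#' signals first, by descending ROR.
#'
#' @param cases Classified `report_cases` (see [classify_tae()]).
#' @param hierarchy A `meddra_hierarchy` providing the tumor-term set.
#' @param drug_groups Named list of character vectors; default per-drug
#'   plus `combined`.
#' @param events PT labels to scan; default the hierarchy's tumor terms.
#' @param min_cases Signal threshold on the cell `a` (default 3).
#' @param correction Zero-cell policy passed to [ror()].
#' @param conf_level Confidence level.
#' @return A data frame of class `ror_scan` with columns `drug_group`,
#'   `event`, `a`, `b`, `c`, `d`, `ror`, `ci_low`, `ci_high`, `n_cases`,
#'   `is_signal`, `correction_applied`.
#' @export
scan_signals <- function(cases, hierarchy = default_hierarchy(),
                         drug_groups = NULL, events = NULL,
                         min_cases = 3L, correction = "haldane",
                         conf_level = 0.95) {
  if (is.null(events)) events <- tumor_terms(hierarchy)
  if (is.null(drug_groups)) {
    drug_groups <- as.list(STUDY_DRUGS)
    names(drug_groups) <- STUDY_DRUGS
    drug_groups$combined <- STUDY_DRUGS
  }
  n <- nrow(cases)
  li <- rep.int(seq_len(n), lengths(cases$drug_name))
  dn <- norm_term(unlist(cases$drug_name, use.names = FALSE))
  ri <- rep.int(seq_len(n), lengths(cases$reactions))
  pt <- norm_term(unlist(cases$reactions, use.names = FALSE))
  evt_cases <- lapply(norm_term(events), function(e) {
    idx <- tabulate(ri[pt == e], n) > 0L
    idx
  })
  rows <- list()
  for (g in names(drug_groups)) {
    exposed <- tabulate(li[dn %in% norm_term(drug_groups[[g]])], n) > 0L
    n_exp <- sum(exposed)
    for (j in seq_along(events)) {
      has <- evt_cases[[j]]
      a <- sum(exposed & has)
      if (a < 1L) next
      b <- sum(has) - a
      tab <- new_ror_table(a, b, n_exp - a, n - n_exp - b,
                           g, events[j])
      r <- tryCatch(ror(tab, correction = correction,
                        conf_level = conf_level, min_cases = min_cases),
                    error = function(e) NULL)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        drug_group = g, event = events[j], a = tab$a, b = tab$b,
        c = tab$c, d = tab$d, ror = r$ror, ci_low = r$ci_low,
        ci_high = r$ci_high, n_cases = r$n_cases, is_signal = r$is_signal,
        correction_applied = r$correction_applied,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug_group = character(), event = character(),
               a = integer(), b = integer(), c = integer(), d = integer(),
               ror = numeric(), ci_low = numeric(), ci_high = numeric(),
               n_cases = integer(), is_signal = logical(),
               correction_applied = logical(), stringsAsFactors = FALSE)
  out <- out[order(-out$is_signal, -out$ror), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, min_cases = min_cases, conf_level = conf_level,
            class = c("ror_scan", "data.frame"))
}

#' @export
print.ror_scan <- function(x, n = 20L, ...) {
  cat(sprintf("Disproportionality scan: %d drug-event pairs, %d signal(s)\n",
              nrow(x), sum(x$is_signal)))
  df <- as.data.frame(x)
  df$ror <- round(df$ror, 2)
  df$ci_low <- round(df$ci_low, 2)
  df$ci_high <- round(df$ci_high, 2)
  print(utils::head(df[c("drug_group", "event", "a", "ror", "ci_low",
                         "ci_high", "is_signal")], n))
  if (nrow(df) > n) cat("  ...", nrow(df) - n, "more rows\n")
  invisible(x)
}

#' Wide ROR matrix export
#'
#' Reshapes a scan into a drugs-by-events matrix of ROR point estimates
#' (the heatmap layout).
#'
#' @param scan A `ror_scan`.
#' @return Numeric matrix, drug groups in rows, events in columns; `NA`
#'   where no table was computable.
#' @export
ror_matrix <- function(scan) {
  g <- unique(scan$drug_group)
  e <- unique(scan$event)
  m <- matrix(NA_real_, length(g), length(e), dimnames = list(g, e))
  m[cbind(match(scan$drug_group, g), match(scan$event, e))] <- scan$ror
  m
}
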
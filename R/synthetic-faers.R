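#' Configure the synthetic spontaneous-report generator
#'
#' Builds a validated configuration for [generate_faers()]. The generator
#' emulates a FAERS-shaped extract: per-case demographics (age, sex, weight,
#' reporter country), one suspect drug exposure with a daily dose and a
#' therapy start date, one or more MedDRA PT reactions, an event date, a
#' fatal/non-fatal outcome, injected duplicate case versions (same CASEID,
#' later FDA_DT, different PRIMARYID), injected out-of-range ages and
#' weights, a simulated delete file, and a configurable drug-by-event
#' association matrix with target reporting odds ratios.
#'
#' ## Planted-association sampling scheme
#' For every case a drug is drawn first (independently of everything else),
#' then each PT in `event_vocabulary` is drawn as an independent Bernoulli.
#' An unexposed case reports PT `e` with its background probability
#' `p0`. For a planted pair `(g, e)` with target reporting odds ratio `R`,
#' exposed cases report with probability `p1` satisfying
#' `odds(p1) = R * odds(p0)` -- an odds-scale tilt, so the planted `R` is
#' exactly the estimand of the downstream ROR in the large-sample limit.
#' A case that draws no reaction is assigned the filler PT (`filler_pt`,
#' default "Drug ineffective") so every report carries at least one
#' reaction; because the filler is assigned independently of the drug it
#' leaves every drug-event ROR untouched.
#'
#' @param n_cases Number of unique cases (>= 1).
#' @param drug_names Drug labels; must include the five study
#'   proton-pump inhibitors (esomeprazole, pantoprazole, lansoprazole,
#'   omeprazole, rabeprazole).
#' @param drug_weights Sampling weights over `drug_names`; the default
#'   mirrors the observed case mix across the five drugs.
#' @param event_vocabulary PT labels; defaults to the bundled hierarchy's
#'   term set.
#' @param tumor_terms Subset of `event_vocabulary` treated as tumor PTs.
#' @param association Data frame with columns `drug`, `event`, `ror` giving
#'   target reporting odds ratios for planted pairs (pairs not listed are
#'   null, ROR 1).
#' @param background_event_prob Per-PT baseline reporting probability in
#'   (0,1); a scalar or a named vector over the vocabulary. Default 0.002,
#'   the order of magnitude of a specific rare PT's reporting proportion in
#'   a large spontaneous-report database.
#' @param duplicate_rate Fraction in \[0,1) of cases emitted with a second
#'   version (same caseid, later fda_dt, higher primaryid).
#' @param invalid_age_rate,invalid_weight_rate Fractions in \[0,1) of cases
#'   given out-of-range ages (> 150 or < 0) or weights (> 150 kg).
#' @param delete_rate Fraction of records placed on the simulated delete
#'   file.
#' @param nonsuspect_rate Fraction of cases whose study-drug exposure is
#'   recorded with concomitant rather than suspect role.
#' @param fatal_prob Probability a tumor-event case is fatal (default 0.297).
#' @param fatal_prob_background Fatality probability for non-tumor cases.
#' @param sex_missing_rate Probability sex is missing (default 0.32).
#' @param onset_median_days,onset_sdlog Log-normal therapy-start-to-event
#'   onset distribution: median in days (default 2556) and log-sd.
#' @param dose_levels Named list per drug of `list(dose =, weight =)` daily
#'   doses in mg/day with sampling weights; defaults cover each drug's
#'   marketed strengths.
#' @param date_window Two calendar dates bounding event dates (default
#'   2004-01-01 to 2024-03-31).
#' @param country_probs Named probabilities for reporter country (name
#'   `"missing"` for absent).
#' @param filler_pt PT assigned when a case draws no reaction.
#' @param seed Integer random seed.
#' @return An object of class `faers_sim_config` (a validated list).
#' @export
faers_sim_config <- function(n_cases,
                             drug_names = STUDY_DRUGS,
                             drug_weights = c(0.36, 0.12, 0.27, 0.23, 0.02),
                             event_vocabulary = NULL,
                             tumor_terms = NULL,
                             association = NULL,
                             background_event_prob = 0.002,
                             duplicate_rate = 0.05,
                             invalid_age_rate = 0.005,
                             invalid_weight_rate = 0.005,
                             delete_rate = 0.01,
                             nonsuspect_rate = 0,
                             fatal_prob = 0.297,
                             fatal_prob_background = 0.05,
                             sex_missing_rate = 0.32,
                             onset_median_days = 2556,
                             onset_sdlog = 1.0,
                             dose_levels = NULL,
                             date_window = as.Date(c("2004-01-01",
                                                     "2024-03-31")),
                             country_probs = c(US = 0.82, JP = 0.07,
                                               GB = 0.022, OTHER = 0.08,
                                               missing = 0.008),
                             filler_pt = "Drug ineffective",
                             seed = 1L) {
  if (is.null(event_vocabulary)) {
    h <- default_hierarchy()
    event_vocabulary <- h$pt
    if (is.null(tumor_terms)) tumor_terms <- attr(h, "tumor_terms")
  }
  if (is.null(tumor_terms)) tumor_terms <- character()
  if (is.null(dose_levels)) dose_levels <- default_dose_levels(drug_names)
  if (is.null(association))
    association <- data.frame(drug = character(), event = character(),
                              ror = numeric(), stringsAsFactors = FALSE)

  if (!is.numeric(n_cases) || length(n_cases) != 1L || is.na(n_cases) ||
      n_cases < 1)
    stop_cfg("n_cases", "must be a positive integer")
  n_cases <- as.integer(n_cases)
  if (!all(STUDY_DRUGS %in% drug_names))
    stop_cfg("drug_names", "must include the five study drugs")
  if (length(drug_weights) != length(drug_names) || any(drug_weights < 0) ||
      sum(drug_weights) <= 0)
    stop_cfg("drug_weights", "must be non-negative and match drug_names")
  if (anyDuplicated(norm_term(event_vocabulary)))
    stop_cfg("event_vocabulary", "contains duplicated PT labels")
  if (!all(norm_term(tumor_terms) %in% norm_term(event_vocabulary)))
    stop_cfg("tumor_terms", "must be a subset of event_vocabulary")
  for (f in c("duplicate_rate", "invalid_age_rate", "invalid_weight_rate",
              "delete_rate", "nonsuspect_rate")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v >= 1)
      stop_cfg(f, "must be a fraction in [0, 1)")
  }
  for (f in c("fatal_prob", "fatal_prob_background", "sex_missing_rate")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_cfg(f, "must be a probability in [0, 1]")
  }
  if (any(background_event_prob <= 0) || any(background_event_prob >= 1))
    stop_cfg("background_event_prob", "must lie in (0, 1)")
  if (!is.null(names(background_event_prob)) &&
      !all(names(background_event_prob) %in% event_vocabulary))
    stop_cfg("background_event_prob",
             "has names outside the event vocabulary")
  if (nrow(association)) {
    if (!all(c("drug", "event", "ror") %in% names(association)))
      stop_cfg("association", "needs columns drug, event, ror")
    if (any(!is.finite(association$ror)) || any(association$ror <= 0))
      stop_cfg("association", "target RORs must be finite and > 0")
    if (!all(association$drug %in% drug_names))
      stop_cfg("association", "names a drug outside drug_names")
    if (!all(norm_term(association$event) %in% norm_term(event_vocabulary)))
      stop_cfg("association", "names an event outside the vocabulary")
  }
  if (!all(drug_names %in% names(dose_levels)))
    stop_cfg("dose_levels", "must provide levels for every drug")
  for (d in drug_names) {
    dl <- dose_levels[[d]]
    if (is.null(dl$dose) || any(dl$dose <= 0))
      stop_cfg("dose_levels", sprintf("doses for '%s' must be > 0", d))
    if (length(dl$weight %||% dl$dose) != length(dl$dose))
      stop_cfg("dose_levels", sprintf("weights for '%s' mismatch doses", d))
  }
  if (onset_median_days <= 0 || onset_sdlog <= 0)
    stop_cfg("onset_days_distribution", "median and log-sd must be > 0")
  date_window <- as.Date(date_window)
  if (length(date_window) != 2L || any(is.na(date_window)) ||
      date_window[1] > date_window[2])
    stop_cfg("date_window", "must be two ordered calendar dates")
  if (abs(sum(country_probs) - 1) > 1e-8 || any(country_probs < 0))
    stop_cfg("country_probs", "must be non-negative and sum to 1")
  seed <- as.integer(seed)
  if (is.na(seed)) stop_cfg("seed", "must be an integer")

  structure(list(
    n_cases = n_cases, drug_names = drug_names,
    drug_weights = drug_weights / sum(drug_weights),
    event_vocabulary = event_vocabulary, tumor_terms = tumor_terms,
    association = association,
    background_event_prob = background_event_prob,
    duplicate_rate = duplicate_rate, invalid_age_rate = invalid_age_rate,
    invalid_weight_rate = invalid_weight_rate, delete_rate = delete_rate,
    nonsuspect_rate = nonsuspect_rate, fatal_prob = fatal_prob,
    fatal_prob_background = fatal_prob_background,
    sex_missing_rate = sex_missing_rate,
    onset_median_days = onset_median_days, onset_sdlog = onset_sdlog,
    dose_levels = dose_levels, date_window = date_window,
    country_probs = country_probs, filler_pt = filler_pt, seed = seed),
    class = "faers_sim_config")
}

# marketed daily-dose strengths (mg/day) with plausible prescribing weights
default_dose_levels <- function(drug_names) {
  base <- list(
    esomeprazole = list(dose = c(20, 40, 80), weight = c(0.35, 0.55, 0.10)),
    pantoprazole = list(dose = c(20, 40, 80), weight = c(0.15, 0.60, 0.25)),
    lansoprazole = list(dose = c(15, 30, 60), weight = c(0.40, 0.45, 0.15)),
    omeprazole   = list(dose = c(10, 20, 40, 80),
                        weight = c(0.10, 0.50, 0.30, 0.10)),
    rabeprazole  = list(dose = c(10, 20, 60), weight = c(0.30, 0.60, 0.10)))
  extra <- setdiff(drug_names, names(base))
  for (d in extra) base[[d]] <- list(dose = c(20, 40), weight = c(0.5, 0.5))
  base[drug_names]
}

#' @export
print.faers_sim_config <- function(x, ...) {
  cat("Synthetic FAERS generator configuration\n")
  cat(sprintf("  cases: %d  drugs: %d  PT vocabulary: %d (%d tumor)\n",
              x$n_cases, length(x$drug_names),
              length(x$event_vocabulary), length(x$tumor_terms)))
  cat(sprintf("  planted associations: %d  duplicate rate: %.3f  seed: %d\n",
              nrow(x$association), x$duplicate_rate, x$seed))
  invisible(x)
}

# odds-scale tilt: p1 with odds(p1) = R * odds(p0)
tilt_prob <- function(p0, ror) {
  o <- ror * p0 / (1 - p0)
  o / (1 + o)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic FAERS-shaped dataset
#'
#' Draws `n_cases` unique cases under `config` (see [faers_sim_config()] for
#' the sampling scheme) and lays them out as the four FAERS-shaped
#' relational tables keyed by `primaryid` -- `demo` (demographics and
#' dates), `drug` (exposures with daily dose, therapy start date and role),
#' `reac` (one row per reaction PT) and `outc` (fatal/other outcome code) --
#' plus the simulated delete file. Output is deterministic given the
#' config's seed.
#'
#' @param config A `faers_sim_config`.
#' @return An object of class `faers_data`: a list with data frames `demo`,
#'   `drug`, `reac`, `outc`, an integer vector `deleted` of primaryids, and
#'   the generating `config`. A `truth` attribute carries per-case
#'   ground-truth (tumor-event status, onset days) for simulation studies.
#' @export
generate_faers <- function(config) {
  if (!inherits(config, "faers_sim_config"))
    stop("config must be built with faers_sim_config()")
  with_seed(config$seed, {
    n <- config$n_cases
    caseid <- 1000000L + seq_len(n)
    primaryid <- caseid * 10L + 1L

    drug <- sample(config$drug_names, n, replace = TRUE,
                   prob = config$drug_weights)
    dose <- numeric(n)
    for (d in unique(drug)) {
      i <- which(drug == d)
      dl <- config$dose_levels[[d]]
      w <- dl$weight %||% rep(1, length(dl$dose))
      dose[i] <- dl$dose[sample.int(length(dl$dose), length(i),
                                    replace = TRUE, prob = w)]
    }
    role <- ifelse(runif(n) < config$nonsuspect_rate, "C", "PS")

    sex <- ifelse(runif(n) < config$sex_missing_rate, NA_character_,
                  ifelse(runif(n) < 0.544, "male", "female"))
    age <- round(pmin(pmax(rnorm(n, 59, 13), 18), 95))
    wt <- round(pmin(pmax(rnorm(n, 75, 15), 40), 149), 1)
    cn <- names(config$country_probs)
    country <- sample(cn, n, replace = TRUE, prob = config$country_probs)
    country[country == "missing"] <- NA_character_

    win <- as.integer(config$date_window)
    event_dt <- as.Date(win[1] + floor(runif(n) * (win[2] - win[1] + 1)),
                        origin = "1970-01-01")
    onset <- pmax(round(rlnorm(n, log(config$onset_median_days),
                               config$onset_sdlog)), 1)
    start_dt <- event_dt - onset
    fda_dt <- event_dt + sample.int(180L, n, replace = TRUE) - 1L

    # reaction draws: background Bernoulli per PT, odds-tilted on planted
    # (drug, event) pairs
    vocab <- config$event_vocabulary
    J <- length(vocab)
    p0 <- config$background_event_prob
    if (is.null(names(p0))) {
      p0 <- rep_len(p0, J)
    } else {
      full <- rep(NA_real_, J)
      full[match(names(p0), vocab)] <- p0
      full[is.na(full)] <- 0.002
      p0 <- full
    }
    # per-PT Bernoulli draws, column by column so no n-by-J matrix is built
    assoc <- config$association
    jmap <- if (nrow(assoc))
      match(norm_term(assoc$event), norm_term(vocab)) else integer()
    tumor_j <- which(norm_term(vocab) %in% norm_term(config$tumor_terms))
    hits_by_pt <- vector("list", J)
    is_tae <- logical(n)
    for (j in seq_len(J)) {
      u <- runif(n)
      krows <- which(jmap == j)
      if (length(krows)) {
        thr <- rep.int(p0[j], n)
        for (k in krows)
          thr[drug == assoc$drug[k]] <- tilt_prob(p0[j], assoc$ror[k])
        idx <- which(u < thr)
      } else idx <- which(u < p0[j])
      hits_by_pt[[j]] <- idx
      if (j %in% tumor_j) is_tae[idx] <- TRUE
    }
    reac_case <- unlist(hits_by_pt, use.names = FALSE)
    reac_pt <- rep.int(vocab, lengths(hits_by_pt))
    ord <- order(reac_case)
    reac_case <- reac_case[ord]
    reac_pt <- reac_pt[ord]
    none <- which(tabulate(reac_case, n) == 0L)
    if (length(none)) {
      reac_case <- c(reac_case, none)
      reac_pt <- c(reac_pt, rep(config$filler_pt, length(none)))
    }
    fatal <- runif(n) < ifelse(is_tae, config$fatal_prob,
                               config$fatal_prob_background)

    n_bad_age <- sum(runif(n) < config$invalid_age_rate)
    if (n_bad_age) {
      i <- sample.int(n, n_bad_age)
      age[i] <- sample(c(-3, 151, 180, 250, 999), n_bad_age, replace = TRUE)
    }
    n_bad_wt <- sum(runif(n) < config$invalid_weight_rate)
    if (n_bad_wt) {
      i <- sample.int(n, n_bad_wt)
      wt[i] <- round(runif(n_bad_wt, 151, 400), 1)
    }

    dup <- which(runif(n) < config$duplicate_rate)

    demo <- data.frame(
      primaryid = primaryid, caseid = caseid, fda_dt = fda_dt, age = age,
      sex = sex, wt = wt, reporter_country = country, event_dt = event_dt,
      stringsAsFactors = FALSE)
    drug_tab <- data.frame(
      primaryid = primaryid, drugname = drug, dose_amt = dose,
      start_dt = start_dt, role = role, stringsAsFactors = FALSE)
    reac_tab <- data.frame(
      primaryid = primaryid[reac_case], pt = reac_pt,
      stringsAsFactors = FALSE)
    outc <- data.frame(
      primaryid = primaryid,
      outc_cod = ifelse(fatal, "DE", "OT"), stringsAsFactors = FALSE)

    if (length(dup)) {
      # a later-received version of the same case: same caseid and content,
      # higher primaryid, later receipt date
      pid2 <- caseid[dup] * 10L + 2L
      d2 <- demo[dup, , drop = FALSE]
      d2$primaryid <- pid2
      d2$fda_dt <- d2$fda_dt + sample(30:400, length(dup), replace = TRUE)
      demo <- rbind(demo, d2)
      g2 <- drug_tab[dup, , drop = FALSE]
      g2$primaryid <- pid2
      drug_tab <- rbind(drug_tab, g2)
      r2 <- reac_tab[reac_tab$primaryid %in% primaryid[dup], , drop = FALSE]
      r2$primaryid <- caseid[match(r2$primaryid, primaryid)] * 10L + 2L
      reac_tab <- rbind(reac_tab, r2)
      o2 <- outc[dup, , drop = FALSE]
      o2$primaryid <- pid2
      outc <- rbind(outc, o2)
    }
    rownames(demo) <- rownames(drug_tab) <- rownames(reac_tab) <-
      rownames(outc) <- NULL

    n_del <- sum(runif(nrow(demo)) < config$delete_rate)
    deleted <- if (n_del) sort(sample(demo$primaryid, n_del)) else integer()

    structure(list(demo = demo, drug = drug_tab, reac = reac_tab,
                   outc = outc, deleted = deleted, config = config),
              truth = data.frame(caseid = caseid, drug = drug,
                                 is_tae = is_tae, onset_days = onset,
                                 fatal = fatal, stringsAsFactors = FALSE),
              n_duplicated = length(dup),
              class = "faers_data")
  })
}

#' @export
print.faers_data <- function(x, ...) {
  cat("FAERS-shaped synthetic dataset\n")
  cat(sprintf("  records: %d (%d unique cases)  reactions: %d  deleted: %d\n",
              nrow(x$demo), length(unique(x$demo$caseid)), nrow(x$reac),
              length(x$deleted)))
  invisible(x)
}

#' Write a FAERS-shaped dataset to delimited text
#'
#' Writes the four relational tables as `demo`, `drug`, `reac`, `outc`
#' (tab-delimited with header by default) plus `delete.txt` (one primaryid
#' per line) under `dir`. Round-trips losslessly through [read_faers()].
#'
#' @param x A `faers_data` object.
#' @param dir Output directory (created if absent).
#' @param sep Field separator.
#' @return Invisibly, the paths written.
#' @export
write_faers <- function(x, dir, sep = "\t") {
  stopifnot(inherits(x, "faers_data"))
  if (nrow(x$demo) == 0L) stop("refusing to write an empty dataset")
  if (anyDuplicated(x$demo$primaryid))
    stop("validation error: duplicated primaryid in demo table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (sep == "\t") "tsv" else "csv"
  paths <- file.path(dir, paste0(c("demo", "drug", "reac", "outc"), ".", ext))
  names(paths) <- c("demo", "drug", "reac", "outc")
  for (nm in names(paths)) {
    tab <- x[[nm]]
    for (cc in names(tab)) if (inherits(tab[[cc]], "Date"))
      tab[[cc]] <- format(tab[[cc]], "%Y-%m-%d")
    write.table(tab, paths[[nm]], sep = sep, quote = FALSE,
                row.names = FALSE, na = "")
  }
  del <- file.path(dir, "delete.txt")
  writeLines(as.character(x$deleted), del)
  invisible(c(paths, delete = del))
}
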
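#' Synthetic reference TAE case series
#'
#' A deterministic, fully synthetic case set of 862 tumor adverse-event
#' reports whose marginal distributions mirror a realistic
#' proton-pump-inhibitor tumor case series: 256 fatal / 606 non-fatal;
#' sex 267 female / 318 male / 277 missing; reporter country dominated by
#' the US (703) with JP (60), GB (19), other (73) and missing (7); drug
#' mix esomeprazole 307, lansoprazole 234, omeprazole 202, pantoprazole
#' 104, rabeprazole 15; onset times log-normal around a median of 2,556
#' days; reports concentrated in recent five-year periods. Within each
#' fatal stratum the variables are filled independently to the stated
#' margins, so joint cross-tabulations beyond variable-by-fatal are
#' arbitrary. Used in examples and validation of the descriptive
#' machinery.
#'
#' @return A classified `report_cases` data frame with 862 rows
#'   (`is_tae` all `TRUE`).
#' @export
synthetic_tae_cases <- function() {
  strata <- list(
    fatal = list(
      n = 256,
      sex = c(female = 86, male = 93, missing = 77),
      country = c(GB = 12, JP = 7, US = 223, OTHER = 13, missing = 1),
      group = c(esomeprazole = 99, lansoprazole = 70, omeprazole = 55,
                pantoprazole = 31, rabeprazole = 1),
      period = c(`2002` = 1, `2007` = 2, `2012` = 3, `2017` = 40,
                 `2022` = 210)),
    nonfatal = list(
      n = 606,
      sex = c(female = 181, male = 225, missing = 200),
      country = c(GB = 7, JP = 53, US = 480, OTHER = 60, missing = 6),
      group = c(esomeprazole = 208, lansoprazole = 164, omeprazole = 147,
                pantoprazole = 73, rabeprazole = 14),
      period = c(`2002` = 3, `2007` = 10, `2012` = 16, `2017` = 146,
                 `2022` = 431)))
  fill <- function(counts) rep(names(counts), counts)
  parts <- lapply(names(strata), function(s) {
    st <- strata[[s]]
    n <- st$n
    # deterministic skewed spreads with the target medians
    qq <- stats::qnorm((seq_len(n) - 0.5) / n)
    age <- round(59 * exp(qq * 0.16))
    tto <- round(2556 * exp(qq * 0.9))
    sex <- fill(st$sex)
    sex[sex == "missing"] <- NA
    country <- fill(st$country)
    country[country == "missing"] <- NA
    event_dt <- as.Date(paste0(fill(st$period), "-06-15"))
    data.frame(age = age, sex = sex, reporter_country = country,
               drug = fill(st$group), event_dt = event_dt,
               tto = sample_interleave(tto),
               outcome_fatal = s == "fatal", stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  n <- nrow(df)
  out <- data.frame(
    primaryid = 100L + seq_len(n), caseid = 100L + seq_len(n),
    fda_dt = df$event_dt + 30, age = df$age, sex = df$sex,
    weight_kg = NA_real_, reporter_country = df$reporter_country,
    event_dt = df$event_dt, outcome_fatal = df$outcome_fatal,
    stringsAsFactors = FALSE)
  out$drug_name <- as.list(df$drug)
  out$dose_mgday <- rep(list(40), n)
  out$ther_start <- lapply(seq_len(n), function(i)
    df$event_dt[i] - df$tto[i])
  out$drug_role <- rep(list("PS"), n)
  out$reactions <- rep(list("Gastric cancer"), n)
  out$is_tae <- TRUE
  out$tae_terms <- rep(list("Gastric cancer"), n)
  class(out) <- c("report_cases", "data.frame")
  out
}

# deterministic shuffle so onset times are not aligned with the other
# column fills
sample_interleave <- function(x) {
  n <- length(x)
  x[order((seq_len(n) * 17L) %% n, seq_len(n))]
}
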
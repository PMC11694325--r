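# fixture builders shared across test files; everything is constructed in
# code, no stored data

# one report record in the working representation
make_record <- function(primaryid, caseid, fda_dt = "2023-01-01", age = 50,
                        sex = "male", weight = 70, country = "US",
                        event_dt = "2020-06-01", fatal = FALSE,
                        drugs = "esomeprazole", doses = 40,
                        starts = "2015-01-01", roles = "PS",
                        reactions = "Diarrhoea") {
  df <- data.frame(primaryid = as.integer(primaryid),
                   caseid = as.integer(caseid),
                   fda_dt = as.Date(fda_dt), age = as.numeric(age),
                   sex = sex, weight_kg = as.numeric(weight),
                   reporter_country = country,
                   event_dt = as.Date(event_dt), outcome_fatal = fatal,
                   stringsAsFactors = FALSE)
  df$drug_name <- list(drugs)
  df$dose_mgday <- list(doses)
  df$ther_start <- list(as.Date(rep_len(starts, length(drugs))))
  df$drug_role <- list(rep_len(roles, length(drugs)))
  df$reactions <- list(reactions)
  class(df) <- c("report_cases", "data.frame")
  df
}

bind_records <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("report_cases", "data.frame")
  out
}

# 30-record set exercising the whole exclusion cascade:
# 4 duplicate versions (2 of them date ties), 2 delete-listed records,
# 1 out-of-range age, 1 out-of-range weight -> 22 survivors
cascade_fixture <- function() {
  recs <- list()
  # distinct ages keep every case's report content unique, so only the
  # planted removals fire
  # caseids 1 and 2: two versions, later fda_dt wins
  recs <- c(recs, list(
    make_record(101, 1, "2023-01-01", age = 31),
    make_record(102, 1, "2023-03-01", age = 31),
    make_record(201, 2, "2022-05-01", age = 32),
    make_record(202, 2, "2022-07-01", age = 32)))
  # caseids 3 and 4: date ties, higher primaryid wins
  recs <- c(recs, list(
    make_record(301, 3, "2023-02-01", age = 33),
    make_record(302, 3, "2023-02-01", age = 33),
    make_record(401, 4, "2021-09-09", age = 34),
    make_record(402, 4, "2021-09-09", age = 34)))
  # caseids 5 and 6 survive dedup but sit on the delete list
  recs <- c(recs, list(make_record(501, 5, age = 35),
                       make_record(601, 6, age = 36)))
  # caseid 7: invalid age; caseid 8: invalid weight
  recs <- c(recs, list(make_record(701, 7, age = 151),
                       make_record(801, 8, weight = 160)))
  # 18 clean single-version cases
  for (i in 9:26)
    recs <- c(recs, list(make_record(i * 100 + 1, i,
                                     age = 40 + i, weight = 60 + i)))
  list(records = do.call(bind_records, recs),
       delete_ids = c(501L, 601L))
}

# quick generator config for small end-to-end tests
small_config <- function(n = 500, seed = 1, ...) {
  faers_sim_config(n, seed = seed, ...)
}

# exact two-sided Mann-Whitney p-value by exhausting all group assignments
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(i)
    sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (length(y)) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact two-sided Fisher p by hypergeometric enumeration (2x2)
fisher_enum_p <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  xs <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(xs, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
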
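#' Age bands for the risk model
#'
#' `<65` (reference), `65-75` (both boundaries inclusive), `>75`.
#'
#' @param age Age in years.
#' @return Factor with levels `<65`, `65-75`, `>75`; `NA` for missing or
#'   out-of-range ages.
#' @export
band_age <- function(age) {
  age <- as.numeric(age)
  age[!is.na(age) & (age < 0 | age > 150)] <- NA
  cut(age, breaks = c(-Inf, 65, 75, Inf), right = FALSE,
      labels = c("<65", "65-75", ">75")) -> b
  # 75 itself belongs to the middle band ("65-75" read as inclusive)
  b[!is.na(age) & age == 75] <- "65-75"
  b
}

#' Daily-dose bands
#'
#' `Low` (<= 20 mg/day, reference), `Medium` ((20, 40] mg/day), `High`
#' (> 40 mg/day). The printed integer bands (21-40) presume integer doses;
#' continuous inputs use the half-open reading, so a 20.5 mg/day dose is
#' Medium and exactly 40 is Medium.
#'
#' @param dose Daily dose in mg/day (> 0).
#' @return Factor with levels `Low`, `Medium`, `High`; `NA` for missing
#'   doses.
#' @export
band_dose <- function(dose) {
  dose <- as.numeric(dose)
  dose[!is.na(dose) & dose <= 0] <- NA
  cut(dose, breaks = c(0, 20, 40, Inf), right = TRUE,
      labels = c("Low", "Medium", "High"))
}

#' Univariate logistic regression of tumor-event occurrence
#'
#' Fits a maximum-likelihood logistic regression of the tumor-event flag on
#' one categorical exposure, reporting per-level odds ratios (Exp(Beta))
#' against the reference (first) level with Wald 95% confidence intervals
#' `exp(beta +/- z * SE)` and Wald p-values. Cases with a missing exposure
#' are excluded, not imputed; their count is reported. A level exhibiting
#' complete separation (no events or all events) is flagged non-estimable
#' rather than crashing the fit.
#'
#' Built-in exposures: `"age"` (bands `<65` ref / `65-75` / `>75`),
#' `"sex"` (`female` ref / `male`), `"group"` (primary study drug,
#' esomeprazole ref), `"dose"` (daily-dose bands, Low ref). Any other
#' string is taken as a column name in `cases`.
#'
#' @param cases Classified `report_cases` (full set: outcome is `is_tae`).
#' @param exposure One of `"age"`, `"sex"`, `"group"`, `"dose"`, or a
#'   column name.
#' @param levels Optional level ordering, reference first.
#' @param conf_level Confidence level (default 0.95).
#' @inheritParams primary_study_drug
#' @return Object of class `tae_logistic`: data frame with one row per
#'   level (`level`, `n`, `n_events`, `or`, `ci_low`, `ci_high`, `p`,
#'   `reference`, `estimable`) and attributes `variable`, `n_used`,
#'   `n_excluded`, `iterations`, `gradient_norm`, `loglik`, `null_loglik`.
#' @export
tae_logistic <- function(cases, exposure, levels = NULL, conf_level = 0.95,
                         study_drugs = STUDY_DRUGS) {
  stopifnot("is_tae" %in% names(cases))
  x <- switch(exposure,
    age = band_age(cases$age),
    sex = factor(cases$sex, levels = c("female", "male")),
    group = factor(primary_study_drug(cases, study_drugs),
                   levels = c("esomeprazole",
                              setdiff(sort(norm_term(study_drugs)),
                                      "esomeprazole"))),
    dose = band_dose(vapply(cases$dose_mgday, function(d)
      if (length(d)) d[1] else NA_real_, numeric(1))),
    {
      if (!exposure %in% names(cases))
        stop("unknown exposure: ", exposure)
      factor(cases[[exposure]])
    })
  if (!is.null(levels)) x <- factor(as.character(x), levels = levels)
  y <- cases$is_tae
  keep <- !is.na(x) & !is.na(y)
  n_excluded <- sum(!keep)
  x <- droplevels(x[keep]); y <- as.integer(y[keep])
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; logistic model is not identified")
  if (nlevels(x) < 2L)
    stop("exposure has fewer than two populated levels")

  fit <- stats::glm(y ~ x, family = stats::binomial())
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lv <- levels(x)
  # a level separates when its 2x2 margin against the outcome has a zero
  ev <- table(x, factor(y, levels = c(0, 1)))
  sep <- ev[, 1] == 0L | ev[, 2] == 0L
  idx <- paste0("x", lv[-1])
  beta <- cf[idx]; sebeta <- se[idx]
  wald_z <- beta / sebeta
  res <- data.frame(
    level = lv,
    n = as.integer(rowSums(ev)),
    n_events = as.integer(ev[, 2]),
    or = c(NA, exp(beta)),
    ci_low = c(NA, exp(beta - z * sebeta)),
    ci_high = c(NA, exp(beta + z * sebeta)),
    p = c(NA, 2 * stats::pnorm(-abs(wald_z))),
    reference = seq_along(lv) == 1L,
    estimable = !(sep | sep[1]),
    stringsAsFactors = FALSE)
  res$or[!res$estimable & !res$reference] <- NA
  res$ci_low[!res$estimable & !res$reference] <- NA
  res$ci_high[!res$estimable & !res$reference] <- NA
  res$p[!res$estimable & !res$reference] <- NA
  rownames(res) <- NULL

  # convergence metadata: score vector at the solution
  mm <- stats::model.matrix(fit)
  grad <- drop(crossprod(mm, y - stats::fitted(fit)))
  structure(res,
            variable = exposure, reference = lv[1],
            n_used = length(y), n_excluded = n_excluded,
            iterations = fit$iter,
            gradient_norm = sqrt(sum(grad^2)),
            loglik = as.numeric(stats::logLik(fit)),
            null_loglik = as.numeric(stats::logLik(
              stats::glm(y ~ 1, family = stats::binomial()))),
            conf_level = conf_level,
            class = c("tae_logistic", "data.frame"))
}

#' @export
print.tae_logistic <- function(x, digits = 3, ...) {
  cat(sprintf("Univariate logistic model: tumor event ~ %s (N = %d, %d excluded missing)\n",
              attr(x, "variable"), attr(x, "n_used"),
              attr(x, "n_excluded")))
  df <- as.data.frame(x)
  fm <- function(v) ifelse(is.na(v), "-", format(round(v, digits)))
  for (i in seq_len(nrow(df))) {
    if (df$reference[i])
      cat(sprintf("  %-10s n=%6d  (reference)\n", df$level[i], df$n[i]))
    else if (!df$estimable[i])
      cat(sprintf("  %-10s n=%6d  non-estimable (separation)\n",
                  df$level[i], df$n[i]))
    else
      cat(sprintf("  %-10s n=%6d  OR %s (%s, %s)  p=%s\n", df$level[i],
                  df$n[i], fm(df$or[i]), fm(df$ci_low[i]),
                  fm(df$ci_high[i]), format.pval(df$p[i], digits = 2)))
  }
  invisible(x)
}

#' @export
coef.tae_logistic <- function(object, ...) {
  est <- log(object$or[!object$reference])
  names(est) <- object$level[!object$reference]
  est
}

#' @export
confint.tae_logistic <- function(object, parm, level = 0.95, ...) {
  m <- cbind(low = object$ci_low, high = object$ci_high)
  rownames(m) <- object$level
  m[!object$reference, , drop = FALSE]
}

#' Dose-band risk models per drug
#'
#' One univariate logistic fit of tumor-event occurrence on daily-dose band
#' (Low reference) within the cases exposed to each drug, plus a pooled
#' `All` fit across the study drugs -- the per-drug dosage-subgroup layout.
#' A drug with fewer than two populated dose bands is skipped with a
#' warning. Raw mg/day bands are applied uniformly across drugs; mg are
#' not potency-equivalent across compounds, a documented limitation.
#'
#' @param cases Classified `report_cases`.
#' @param per_drug Also fit each drug separately (default `TRUE`).
#' @inheritParams primary_study_drug
#' @return Named list of `tae_logistic` fits (`All` plus one per drug
#'   fitted).
#' @export
dose_subgroup_fits <- function(cases, per_drug = TRUE,
                               study_drugs = STUDY_DRUGS) {
  pd <- primary_study_drug(cases, study_drugs)
  dose1 <- mapply(function(dn, ds, target) {
    i <- which(norm_term(dn) == target)
    if (length(i) && length(ds) >= i[1]) ds[i[1]] else NA_real_
  }, cases$drug_name, cases$dose_mgday, pd, USE.NAMES = FALSE)
  cases$dose_band <- band_dose(dose1)
  fits <- list()
  groups <- c(list(All = norm_term(study_drugs)),
              if (per_drug) setNames(as.list(norm_term(study_drugs)),
                                     norm_term(study_drugs)))
  for (g in names(groups)) {
    sub <- cases[pd %in% groups[[g]], , drop = FALSE]
    bands <- droplevels(sub$dose_band[!is.na(sub$dose_band)])
    if (nlevels(bands) < 2L || length(unique(sub$is_tae)) < 2L) {
      warning(sprintf("dose subgroup '%s' skipped: fewer than two populated dose bands or single-class outcome", g))
      next
    }
    fits[[g]] <- tae_logistic(sub, "dose_band",
                              levels = intersect(c("Low", "Medium", "High"),
                                                 levels(bands)))
  }
  fits
}
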
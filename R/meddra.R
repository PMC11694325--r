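#' Load a MedDRA-style term hierarchy
#'
#' Reads a compact PT -> HLT -> HLGT -> SOC hierarchy from delimited text.
#' Each Preferred Term (PT) maps to exactly one path (primary-path
#' convention); a `is_tumor` flag designates the tumor-term set used to
#' classify tumor adverse events (TAEs), and an optional `site` column maps
#' tumor PTs to anatomical sites. The package bundles a fixture covering the
#' tumor PTs of interest plus a spread of common non-tumor PTs; it stands in
#' for the licensed MedDRA dictionary and is loaded by [default_hierarchy()].
#'
#' Term matching throughout the package is case-insensitive exact string
#' match after whitespace normalization; no fuzzy matching is attempted.
#'
#' @param path Path to a tab- or comma-delimited file with columns
#'   `pt`, `hlt`, `hlgt`, `soc`, `is_tumor` (0/1) and optionally `site`.
#' @param sep Field separator, default tab.
#' @return An object of class `meddra_hierarchy`: a data frame with one row
#'   per PT and attributes `tumor_terms` (character) and a normalized lookup
#'   index.
#' @export
read_meddra <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  h <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (nrow(h) == 0L) {
    warning("empty hierarchy file: ", path)
    h <- data.frame(pt = character(), hlt = character(), hlgt = character(),
                    soc = character(), is_tumor = integer(),
                    site = character(), stringsAsFactors = FALSE)
    return(new_meddra(h))
  }
  need <- c("pt", "hlt", "hlgt", "soc", "is_tumor")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("hierarchy file missing column(s): ", paste(miss, collapse = ", "))
  if (!"site" %in% names(h)) h$site <- NA_character_
  key <- norm_term(h$pt)
  if (anyDuplicated(key)) {
    dup <- unique(h$pt[duplicated(key)])
    # duplicated PT rows are only tolerated when the full path agrees
    path_str <- paste(key, norm_term(h$hlt), norm_term(h$hlgt),
                      norm_term(h$soc))
    conflicting <- dup[vapply(norm_term(dup), function(k) {
      length(unique(path_str[key == k])) > 1L
    }, logical(1))]
    if (length(conflicting))
      stop("PT mapped to more than one hierarchy path: ",
           paste(conflicting, collapse = ", "))
    h <- h[!duplicated(key), , drop = FALSE]
  }
  new_meddra(h)
}

new_meddra <- function(h) {
  h$is_tumor <- as.integer(h$is_tumor) > 0L
  rownames(h) <- NULL
  structure(h,
            tumor_terms = h$pt[h$is_tumor],
            class = c("meddra_hierarchy", "data.frame"))
}

#' Bundled toy hierarchy
#'
#' The fixture shipped under `extdata/meddra_toy.tsv`: 49 PTs, of which 13
#' are tumor terms (the ten signal PTs -- gastric cancer, gastric
#' adenocarcinoma, renal cell carcinoma, metastatic gastric cancer, gastric
#' neoplasm, adenocarcinoma, renal neoplasm, gastric cancer stage III,
#' precancerous cells present, oesophageal cancer metastatic -- plus
#' malignant neoplasm, renal cancer and breast cancer).
#'
#' @return A `meddra_hierarchy`.
#' @export
default_hierarchy <- function() {
  read_meddra(system.file("extdata", "meddra_toy.tsv",
                          package = "pvdisprop", mustWork = TRUE))
}

#' Tumor-term set of a hierarchy
#' @param h A `meddra_hierarchy`.
#' @return Character vector of tumor PT labels.
#' @export
tumor_terms <- function(h) attr(h, "tumor_terms")

# lookup helper: returns the hierarchy row index for each term (NA if unknown)
meddra_index <- function(h, terms) match(norm_term(terms), norm_term(h$pt))

#' Map PTs to their System Organ Class
#' @param h A `meddra_hierarchy`.
#' @param terms Character vector of PT labels.
#' @return Character vector of SOC labels (`NA` for unknown PTs).
#' @export
pt_soc <- function(h, terms) h$soc[meddra_index(h, terms)]

#' Classify cases as tumor adverse events
#'
#' Flags each case whose reaction set intersects the hierarchy's tumor-term
#' set. Reaction PTs absent from the hierarchy are treated as non-tumor;
#' their count is recorded in the `n_unknown_terms` attribute rather than
#' raising an error, so a scan never aborts on vocabulary drift.
#'
#' @param cases A `report_cases` data frame (see [as_report_records()]).
#' @param hierarchy A `meddra_hierarchy`; default [default_hierarchy()].
#' @param extra_tumor_terms Optional additional PT labels to treat as tumor
#'   terms (the tumor set is configurable; the bundled set reproduces the
#'   terms of interest without guessing a full standardized MedDRA query).
#' @return `cases` with added columns `is_tae` (logical) and `tae_terms`
#'   (list of matched tumor PTs), plus attribute `n_unknown_terms`.
#' @export
classify_tae <- function(cases, hierarchy = default_hierarchy(),
                         extra_tumor_terms = character()) {
  stopifnot(is.data.frame(cases), "reactions" %in% names(cases))
  tset <- norm_term(c(tumor_terms(hierarchy), extra_tumor_terms))
  n <- nrow(cases)
  len <- lengths(cases$reactions)
  long_case <- rep.int(seq_len(n), len)
  long_pt <- unlist(cases$reactions, use.names = FALSE)
  if (length(long_pt)) {
    key <- norm_term(long_pt)
    is_t <- key %in% tset
    known <- key %in% norm_term(hierarchy$pt)
    n_unknown <- sum(!known)
    hit <- logical(n)
    hit[unique(long_case[is_t])] <- TRUE
    matched <- vector("list", n)
    matched[] <- list(character())
    if (any(is_t)) {
      m <- split(long_pt[is_t], long_case[is_t])
      matched[as.integer(names(m))] <- lapply(m, unique)
    }
  } else {
    n_unknown <- 0L
    hit <- logical(n)
    matched <- rep(list(character()), n)
  }
  cases$is_tae <- hit
  cases$tae_terms <- matched
  attr(cases, "n_unknown_terms") <- n_unknown
  cases
}
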
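# Cohort construction: outcome classification, exclusions, maternal-age
# classes, and aggregation to municipality x age-class count tables.

#' Maternal age class labels
#'
#' Nine right-closed maternal age classes used for age standardization:
#' `<=15, (15,20], (20,25], (25,30], (30,35], (35,40], (40,45], (45,50], >=50`.
#'
#' @return Character vector of length 9.
#' @export
age_class_labels <- function() {
  c("<=15", "(15,20]", "(20,25]", "(25,30]", "(30,35]",
    "(35,40]", "(40,45]", "(45,50]", ">=50")
}

#' Maternal age reporting strata labels
#'
#' Coarser three-way partition `<=20, (20,35], >35` used for summary tables
#' and stratified cluster analyses.
#'
#' @return Character vector of length 3.
#' @export
age_stratum_labels <- function() {
  c("<=20", "(20,35]", ">35")
}

#' Assign the 9-level maternal age class
#'
#' Intervals are left-open/right-closed except the open-ended extremes, so a
#' maternal age of exactly 15 falls in class 1 (`<=15`) and 20 in class 2
#' (`(15,20]`).
#'
#' @param maternal_age Integer vector of maternal ages in completed years.
#' @return Integer vector of class indices in 1..9 (`NA` stays `NA`).
#' @export
assign_age_class <- function(maternal_age) {
  if (any(maternal_age < 0, na.rm = TRUE)) {
    stop("maternal_age must be non-negative")
  }
  1L + findInterval(maternal_age, c(15, 20, 25, 30, 35, 40, 45, 50),
                    left.open = TRUE)
}

#' Assign the 3-level maternal age reporting stratum
#'
#' @param maternal_age Integer vector of maternal ages in completed years.
#' @return Factor with levels `<=20`, `(20,35]`, `>35`.
#' @export
assign_age_stratum <- function(maternal_age) {
  if (any(maternal_age < 0, na.rm = TRUE)) {
    stop("maternal_age must be non-negative")
  }
  idx <- 1L + findInterval(maternal_age, c(20, 35), left.open = TRUE)
  factor(age_stratum_labels()[idx], levels = age_stratum_labels())
}

#' Outcome group labels
#' @return Character vector of the four exclusive outcome groups.
#' @export
outcome_group_levels <- function() {
  c("LBW_pre", "LBW_term", "NBW_pre", "NBW_term")
}

#' Classify a birth into low-birthweight / preterm outcome flags
#'
#' Low birth weight (LBW) is birthweight below 2500 g irrespective of
#' gestational age; preterm birth (PTB) is gestational age below 37 completed
#' weeks. The crossing of the two binary flags defines four exclusive groups
#' (`LBW_pre`, `LBW_term`, `NBW_pre`, `NBW_term`), so the LBW total is the sum
#' of `LBW_term` and `LBW_pre` by construction. Boundary values (2500 g,
#' 37 weeks) are normal weight / term.
#'
#' Missing or non-positive inputs yield `NA` flags: such records are never
#' silently classified and should be removed with [apply_exclusions()] first.
#'
#' @param birthweight Numeric vector, grams.
#' @param gestational_age Numeric vector, completed weeks.
#' @return `data.frame` with logical columns `is_lbw`, `is_preterm` and a
#'   factor `group` with levels [outcome_group_levels()].
#' @export
classify_birth <- function(birthweight, gestational_age) {
  stopifnot(length(birthweight) == length(gestational_age))
  bad <- is.na(birthweight) | is.na(gestational_age) |
    birthweight <= 0 | gestational_age <= 0
  is_lbw <- birthweight < 2500
  is_preterm <- gestational_age < 37
  is_lbw[bad] <- NA
  is_preterm[bad] <- NA
  group <- ifelse(is_lbw,
                  ifelse(is_preterm, "LBW_pre", "LBW_term"),
                  ifelse(is_preterm, "NBW_pre", "NBW_term"))
  data.frame(is_lbw = is_lbw, is_preterm = is_preterm,
             group = factor(group, levels = outcome_group_levels()))
}

#' Apply the cohort exclusion rules
#'
#' Keeps singleton births (`plurality == 1`) with complete
#' `municipality_id`, `birthweight_g`, `gestational_weeks` and `maternal_age`.
#' Gestational ages outside the live-birth plausibility window of 20 to 45
#' completed weeks are treated as missing. A record failing both rules is
#' counted once, under "multiple". The operation is idempotent.
#'
#' @param records Birth-record `data.frame` (see [read_birth_records()]).
#' @return List with `kept` (the filtered `data.frame`) and `report`, a named
#'   integer vector with elements `multiple` and `missing`.
#' @export
apply_exclusions <- function(records) {
  req <- c("municipality_id", "birthweight_g", "gestational_weeks",
           "maternal_age", "plurality")
  miss_col <- setdiff(req, names(records))
  if (length(miss_col)) {
    stop("records is missing columns: ", paste(miss_col, collapse = ", "))
  }
  ga <- records$gestational_weeks
  ga[!is.na(ga) & (ga < 20 | ga > 45)] <- NA
  incomplete <- is.na(records$municipality_id) |
    is.na(records$birthweight_g) | records$birthweight_g <= 0 |
    is.na(ga) | is.na(records$maternal_age)
  multiple <- !is.na(records$plurality) & records$plurality > 1
  multiple <- multiple | is.na(records$plurality)
  keep <- !multiple & !incomplete
  kept <- records[keep, , drop = FALSE]
  kept$gestational_weeks <- ga[keep]
  rownames(kept) <- NULL
  list(kept = kept,
       report = c(multiple = sum(multiple),
                  missing = sum(incomplete & !multiple)))
}

#' Read a birth-record CSV
#'
#' Expected header:
#' `municipality_id,year,birthweight_g,gestational_weeks,maternal_age,plurality,sex`
#' (UTF-8, empty fields for missing values).
#'
#' @param path Path to the CSV file.
#' @return `data.frame` of birth records.
#' @export
read_birth_records <- function(path) {
  rec <- utils::read.csv(path, colClasses = c(municipality_id = "character"),
                         na.strings = c("", "NA"))
  rec
}

#' Aggregate birth records to municipality x age-class counts
#'
#' Records must already have passed [apply_exclusions()]. Every municipality
#' in `municipality_ids` (default: those present in the records) appears with
#' all 9 age classes, zero-filled. Case counts are reported for the four
#' outcome selectors; by construction
#' `n_cases_lbw == n_cases_lbwterm + n_cases_lbwpre`.
#'
#' @param records Filtered birth records.
#' @param municipality_ids Optional character vector of all municipality ids
#'   (e.g. from the geometry table). Records with an id not in this list are
#'   an error.
#' @param outcome One of `"all"` (default: four case columns) or a single
#'   selector `"LBW"`, `"PTB"`, `"LBW_term"`, `"LBW_pre"` (single `n_cases`
#'   column).
#' @return `data.frame` with columns `municipality_id`, `age_class`,
#'   `n_births` and case counts, ordered by municipality then age class.
#' @export
aggregate_counts <- function(records, municipality_ids = NULL,
                             outcome = c("all", "LBW", "PTB",
                                         "LBW_term", "LBW_pre")) {
  outcome <- match.arg(outcome)
  ids <- as.character(records$municipality_id)
  if (is.null(municipality_ids)) {
    municipality_ids <- sort(unique(ids))
  } else {
    municipality_ids <- as.character(municipality_ids)
    unknown <- setdiff(unique(ids), municipality_ids)
    if (length(unknown)) {
      stop("unknown municipality_id: ", paste(unknown, collapse = ", "))
    }
  }
  mid <- factor(ids, levels = municipality_ids)
  ac <- factor(assign_age_class(records$maternal_age), levels = 1:9)
  cl <- classify_birth(records$birthweight_g, records$gestational_weeks)
  tab <- function(sel) as.vector(t(table(mid[sel], ac[sel])))
  out <- data.frame(
    municipality_id = rep(municipality_ids, each = 9),
    age_class = rep(1:9, times = length(municipality_ids)),
    n_births = tab(rep(TRUE, length(mid))),
    stringsAsFactors = FALSE
  )
  cases <- list(
    n_cases_lbw = cl$is_lbw,
    n_cases_ptb = cl$is_preterm,
    n_cases_lbwterm = cl$group == "LBW_term",
    n_cases_lbwpre = cl$group == "LBW_pre"
  )
  if (outcome == "all") {
    for (nm in names(cases)) out[[nm]] <- tab(cases[[nm]] %in% TRUE)
  } else {
    sel <- switch(outcome,
                  LBW = cases$n_cases_lbw,
                  PTB = cases$n_cases_ptb,
                  LBW_term = cases$n_cases_lbwterm,
                  LBW_pre = cases$n_cases_lbwpre)
    out$n_cases <- tab(sel %in% TRUE)
  }
  out
}

#' Select one outcome's case column from an aggregated count table
#'
#' @param counts Output of [aggregate_counts()] with `outcome = "all"`.
#' @param outcome One of `"LBW"`, `"PTB"`, `"LBW_term"`, `"LBW_pre"`.
#' @return `data.frame` with `municipality_id`, `age_class`, `n_births`,
#'   `n_cases`.
#' @export
select_outcome <- function(counts, outcome = c("LBW", "PTB",
                                               "LBW_term", "LBW_pre")) {
  outcome <- match.arg(outcome)
  col <- switch(outcome, LBW = "n_cases_lbw", PTB = "n_cases_ptb",
                LBW_term = "n_cases_lbwterm", LBW_pre = "n_cases_lbwpre")
  data.frame(municipality_id = counts$municipality_id,
             age_class = counts$age_class,
             n_births = counts$n_births,
             n_cases = counts[[col]],
             stringsAsFactors = FALSE)
}
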
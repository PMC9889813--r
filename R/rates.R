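# Incidence computations: crude rates, direct age-standardized rates,
# pooled stratum rates, indirect expected counts, summary proportions.

#' Round half away from zero
#'
#' Display rounding matching printed epidemiological tables (`round()` in R
#' rounds halves to even). Internal computation elsewhere keeps full
#' precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Crude rate
#'
#' @param O Case count(s).
#' @param n Birth denominator(s).
#' @return `O/n`; `NA` where `n == 0` (undefined, propagated rather than 0).
#' @export
crude_rate <- function(O, n) {
  if (any(n < 0) || any(O < 0)) stop("counts must be non-negative")
  if (any(O > n)) stop("cases cannot exceed births")
  ifelse(n == 0, NA_real_, O / n)
}

#' Outcome proportion in percent
#'
#' @param count Cases.
#' @param total Births (> 0).
#' @return `100 * count / total`, rounded half-up to 2 decimals.
#' @export
outcome_proportion <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count > total)) stop("count cannot exceed total")
  round_half_up(100 * count / total, 2)
}

#' Default maternal-age reference weights
#'
#' Share of births by the 9 maternal age classes for a Japanese-style
#' national maternal age distribution; the reporting-strata sums are about
#' 2.2% (<=20), 76.6% ((20,35]) and 21.2% (>35). Used both as the direct
#' standardization reference and as the synthetic generator's default age
#' profile.
#'
#' @return Named numeric vector of length 9 summing to 1.
#' @export
default_reference_weights <- function() {
  w <- c(0.0010, 0.0210, 0.1000, 0.2800, 0.3860,
         0.1750, 0.0340, 0.0025, 0.0005)
  names(w) <- age_class_labels()
  w
}

#' Read reference weights from CSV (`age_class,weight`)
#' @param path CSV path.
#' @return Named numeric vector of length 9, normalized to sum 1.
#' @export
read_reference_weights <- function(path) {
  d <- utils::read.csv(path)
  w <- numeric(9)
  w[d$age_class] <- d$weight
  if (any(w < 0)) stop("weights must be non-negative")
  w <- w / sum(w)
  names(w) <- age_class_labels()
  w
}

#' Directly age-standardized rate for one municipality
#'
#' `asr = sum_a W_a * O_a / n_a`. Empty strata (`n_a == 0`) are imputed with
#' a very small denominator (`epsilon`, default 0.0001) and a zero numerator,
#' so they contribute a zero stratum rate rather than a division failure.
#'
#' @param n_births Length-9 vector of stratum denominators.
#' @param n_cases Length-9 vector of stratum cases.
#' @param weights Reference weights summing to 1.
#' @param epsilon Imputed denominator for empty strata.
#' @return Scalar standardized rate (cases per birth).
#' @export
direct_asr <- function(n_births, n_cases, weights = default_reference_weights(),
                       epsilon = 1e-4) {
  if (length(n_births) != length(weights) ||
      length(n_cases) != length(weights)) {
    stop("n_births and n_cases must match the weight vector length")
  }
  if (any(n_births < 0) || any(n_cases < 0)) stop("counts must be non-negative")
  if (any(n_cases > n_births)) stop("cases cannot exceed births")
  n <- ifelse(n_births == 0, epsilon, n_births)
  sum(weights * n_cases / n)
}

#' Pooled (national) age-specific rates
#'
#' @param counts Long count table with `age_class`, `n_births`, `n_cases`.
#' @return Length-9 vector `rho_a = sum_i O_ia / sum_i n_ia` (0 where the
#'   pooled denominator is empty).
#' @export
national_age_rates <- function(counts) {
  n <- tapply(counts$n_births, factor(counts$age_class, levels = 1:9), sum,
              default = 0)
  o <- tapply(counts$n_cases, factor(counts$age_class, levels = 1:9), sum,
              default = 0)
  rho <- ifelse(n > 0, o / n, 0)
  as.numeric(rho)
}

#' Indirectly standardized expected counts per municipality
#'
#' Raw expected counts `E_i = sum_a n_ia * rho_a` are calibrated by the
#' factor `sum O / sum E` so the expected total matches the observed total
#' exactly (a no-op when `rho` is derived from the same data).
#'
#' @param counts Long count table (`municipality_id`, `age_class`,
#'   `n_births`, `n_cases`).
#' @param rho Optional external per-class rates; default derived with
#'   [national_age_rates()].
#' @return `data.frame` `municipality_id`, `n_births`, `observed`, `expected`.
#' @export
indirect_expected <- function(counts, rho = NULL) {
  if (is.null(rho)) rho <- national_age_rates(counts)
  mid <- factor(counts$municipality_id,
                levels = unique(counts$municipality_id))
  e_raw <- counts$n_births * rho[counts$age_class]
  E <- as.numeric(tapply(e_raw, mid, sum, default = 0))
  O <- as.numeric(tapply(counts$n_cases, mid, sum, default = 0))
  n <- as.numeric(tapply(counts$n_births, mid, sum, default = 0))
  if (sum(E) == 0 && sum(O) > 0) {
    stop("expected total is zero while observed cases exist")
  }
  if (sum(E) > 0) E <- E * sum(O) / sum(E)
  data.frame(municipality_id = levels(mid), n_births = n,
             observed = O, expected = E, stringsAsFactors = FALSE)
}

#' Per-municipality rate surface
#'
#' Combines crude rates, directly age-standardized rates and calibrated
#' indirect expected counts into one table — the input for empirical Bayes
#' smoothing ([local_eb()]) and for cluster testing ([scan_test()],
#' [tango_mc_test()]).
#'
#' @param counts Long count table (one outcome, see [select_outcome()]).
#' @param weights Direct-standardization reference weights.
#' @param epsilon Empty-stratum denominator imputation.
#' @param rho Optional external per-class rates for the expected counts.
#' @return `data.frame` `municipality_id`, `n_births`, `observed`,
#'   `expected`, `crude_rate`, `asr`.
#' @export
rate_surface <- function(counts, weights = default_reference_weights(),
                         epsilon = 1e-4, rho = NULL) {
  ind <- indirect_expected(counts, rho)
  mid <- factor(counts$municipality_id, levels = ind$municipality_id)
  asr <- vapply(split(seq_len(nrow(counts)), mid), function(idx) {
    nb <- numeric(9); nc <- numeric(9)
    nb[counts$age_class[idx]] <- counts$n_births[idx]
    nc[counts$age_class[idx]] <- counts$n_cases[idx]
    direct_asr(nb, nc, weights, epsilon)
  }, numeric(1))
  ind$crude_rate <- crude_rate(ind$observed, ind$n_births)
  ind$asr <- as.numeric(asr)
  ind
}

#' Cohort summary table
#'
#' Counts and percentages by survey year, sex and maternal-age reporting
#' strata for the total cohort and each outcome group (LBW, PTB, LBW term,
#' LBW pre), plus mean and interquartile range of birthweight and gestational
#' age per group.
#'
#' @param records Birth records that passed [apply_exclusions()].
#' @return List of `data.frame`s: `totals`, `by_year`, `by_sex`, `by_age`,
#'   `distributions`.
#' @export
summary_table <- function(records) {
  cl <- classify_birth(records$birthweight_g, records$gestational_weeks)
  groups <- list(
    Total = rep(TRUE, nrow(records)),
    LBW = cl$is_lbw %in% TRUE,
    PTB = cl$is_preterm %in% TRUE,
    LBW_term = (cl$group == "LBW_term") %in% TRUE,
    LBW_pre = (cl$group == "LBW_pre") %in% TRUE
  )
  totals <- data.frame(group = names(groups),
                       n = vapply(groups, sum, numeric(1)),
                       stringsAsFactors = FALSE)
  totals$percent <- outcome_proportion(totals$n, totals$n[1])

  strat <- function(fac) {
    do.call(rbind, lapply(names(groups), function(g) {
      tt <- table(fac[groups[[g]]])
      data.frame(group = g, level = names(tt), n = as.numeric(tt),
                 percent = outcome_proportion(as.numeric(tt),
                                              max(1, sum(tt))),
                 stringsAsFactors = FALSE)
    }))
  }
  by_year <- if ("year" %in% names(records)) {
    strat(factor(records$year))
  } else NULL
  by_sex <- if ("sex" %in% names(records)) {
    strat(factor(records$sex))
  } else NULL
  by_age <- strat(assign_age_stratum(records$maternal_age))

  iqr_stats <- function(x, sel) {
    q <- stats::quantile(x[sel], c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    c(mean = mean(x[sel], na.rm = TRUE), q25 = q[1], q75 = q[2])
  }
  distributions <- do.call(rbind, lapply(names(groups), function(g) {
    bw <- iqr_stats(records$birthweight_g, groups[[g]])
    ga <- iqr_stats(records$gestational_weeks, groups[[g]])
    data.frame(group = g,
               birthweight_mean = bw["mean"], birthweight_q25 = bw["q25"],
               birthweight_q75 = bw["q75"],
               gestational_mean = ga["mean"], gestational_q25 = ga["q25"],
               gestational_q75 = ga["q75"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(totals = totals, by_year = by_year, by_sex = by_sex,
       by_age = by_age, distributions = distributions)
}
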
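# Synthetic municipality birth registry: planar municipality systems,
# heavy-tailed age-structured denominators, baseline outcome rates and
# planted circular risk clusters, for end-to-end testing and calibration.

#' Default age-specific baseline rates for the four outcome groups
#'
#' Per-age-class rates for the three elevated-risk exclusive groups
#' (`LBW_term`, `LBW_pre`, `NBW_pre`; `NBW_term` is the remainder). The
#' maternal-age profile of risk is J-shaped (higher at the extremes of
#' maternal age); rates are scaled so that, under the age profile `profile`,
#' the pooled shares equal `overall` — by default 5.23% LBW term, 3.00% LBW
#' pre and 1.74% preterm of normal weight, reproducing overall LBW 8.23% and
#' PTB 4.74%.
#'
#' @param profile Length-9 age profile (shares summing to 1).
#' @param overall Named overall group shares.
#' @return 9 x 3 matrix of per-class group rates.
#' @export
default_baseline_rates <- function(profile = default_reference_weights(),
                                   overall = c(LBW_term = 0.0523,
                                               LBW_pre = 0.0300,
                                               NBW_pre = 0.0174)) {
  mult <- c(1.40, 1.25, 1.05, 0.95, 0.93, 1.05, 1.25, 1.50, 1.70)
  scale <- sum(profile * mult)
  rates <- outer(mult / scale, overall)
  rownames(rates) <- age_class_labels()
  rates
}

#' Synthetic study configuration
#'
#' Full recipe for a reproducible simulated municipality birth registry.
#' Defaults describe the study conditions the generator emulates: a 15 x 15
#' planar lattice of municipalities at 10 km spacing; log-normal birth
#' denominators (median 500 births per municipality over the study window,
#' `sdlog = 1.5`, spanning roughly four orders of magnitude from small
#' islands to large cities); a national-style maternal age profile
#' ([default_reference_weights()]); baseline group rates reproducing LBW
#' 8.23% / PTB 4.74%; and optional planted circular clusters with relative
#' risks in the 1.1–2.2 range.
#'
#' Each planted cluster is a list with `center` (unit index), `rr`
#' (multiplicative relative risk), `outcome` (`"LBW"`, `"PTB"`,
#' `"LBW_term"`, `"LBW_pre"` or `"all"`), and either `radius_km` or
#' `n_units` (the cluster is the `n_units` nearest units to the center).
#'
#' @param grid_shape `(rows, cols)` of the lattice.
#' @param spacing_km Inter-centroid spacing.
#' @param jitter_km Uniform centroid jitter half-width (0 keeps the exact
#'   lattice and enables square polygons for queen contiguity).
#' @param denominator_median,denominator_sdlog Log-normal denominator law.
#' @param age_profile Length-9 shares summing to 1.
#' @param baseline_rates 9 x 3 matrix (see [default_baseline_rates()]).
#' @param planted_clusters List of cluster descriptors.
#' @param years Calendar years the records span.
#' @param seed Integer seed; fully determines the generated study.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(15, 15), spacing_km = 10,
                             jitter_km = 0,
                             denominator_median = 500,
                             denominator_sdlog = 1.5,
                             age_profile = default_reference_weights(),
                             baseline_rates = NULL,
                             planted_clusters = list(),
                             years = 2012:2016,
                             seed = 1L) {
  if (abs(sum(age_profile) - 1) > 1e-8) stop("age_profile must sum to 1")
  if (is.null(baseline_rates)) {
    baseline_rates <- default_baseline_rates(age_profile)
  }
  for (cl in planted_clusters) {
    if (is.null(cl$center) || is.null(cl$rr)) {
      stop("each planted cluster needs center and rr")
    }
    if (cl$rr <= 0) stop("planted relative risk must be positive")
  }
  structure(list(grid_shape = grid_shape, spacing_km = spacing_km,
                 jitter_km = jitter_km,
                 denominator_median = denominator_median,
                 denominator_sdlog = denominator_sdlog,
                 age_profile = age_profile,
                 baseline_rates = baseline_rates,
                 planted_clusters = planted_clusters,
                 years = years, seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic per-stage seed derived from the config seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  (as.double(seed) * 101 + stage * 7919) %% 2147483647
}

#' Generate the synthetic municipality system
#'
#' Lattice (optionally jittered) centroids in a planar km frame, with square
#' polygons when the layout is an exact lattice.
#'
#' @param config A [synthetic_config()].
#' @return List with `geos` (`municipality_id`, `x`, `y`) and `polygons`
#'   (named list of square rings, or `NULL` when jittered).
#' @export
generate_municipalities <- function(config) {
  rows <- config$grid_shape[1]; cols <- config$grid_shape[2]
  s <- config$spacing_km
  ids <- sprintf("M%04d", seq_len(rows * cols))
  gx <- rep(seq_len(cols) - 1, times = rows) * s
  gy <- rep(seq_len(rows) - 1, each = cols) * s
  polygons <- NULL
  if (config$jitter_km > 0) {
    set.seed(stage_seed(config$seed, 1))
    gx <- gx + stats::runif(length(gx), -config$jitter_km, config$jitter_km)
    gy <- gy + stats::runif(length(gy), -config$jitter_km, config$jitter_km)
  } else {
    h <- s / 2
    polygons <- lapply(seq_along(ids), function(i) {
      cbind(x = gx[i] + c(-h, h, h, -h, -h), y = gy[i] + c(-h, -h, h, h, -h))
    })
    names(polygons) <- ids
  }
  list(geos = data.frame(municipality_id = ids, x = gx, y = gy,
                         stringsAsFactors = FALSE),
       polygons = polygons)
}

#' Generate age-structured birth denominators
#'
#' Municipality sizes are log-normal (`median`, `sdlog`), rounded to
#' integers of at least 1, then split across the 9 maternal age classes by a
#' multinomial draw with the configured age profile.
#'
#' @param config A [synthetic_config()].
#' @param geos Geometry table from [generate_municipalities()].
#' @return Long `data.frame` `municipality_id`, `age_class`, `n_births`.
#' @export
generate_denominators <- function(config, geos) {
  set.seed(stage_seed(config$seed, 2))
  n_units <- nrow(geos)
  sizes <- if (config$denominator_sdlog == 0) {
    rep(config$denominator_median, n_units)
  } else {
    stats::rlnorm(n_units, log(config$denominator_median),
                  config$denominator_sdlog)
  }
  sizes <- pmax(1L, as.integer(round(sizes)))
  split_mat <- vapply(sizes, function(sz) {
    as.integer(stats::rmultinom(1, sz, config$age_profile))
  }, integer(9))
  data.frame(
    municipality_id = rep(geos$municipality_id, each = 9),
    age_class = rep(1:9, times = n_units),
    n_births = as.integer(split_mat),
    stringsAsFactors = FALSE
  )
}

cluster_members <- function(geos, cl, metric = "planar") {
  D <- distance_matrix(geos, metric)
  d <- D[cl$center, ]
  if (!is.null(cl$n_units)) {
    ids <- rownames(D)
    ord <- order(d, ids)
    ids[ord[seq_len(cl$n_units)]]
  } else {
    radius <- if (is.null(cl$radius_km)) 0 else cl$radius_km
    rownames(D)[d <= radius]
  }
}

#' Plant a multiplicative relative-risk surface
#'
#' Each planted cluster elevates the risk of its member municipalities by
#' its `rr`; overlapping clusters multiply. Clusters whose `outcome` is
#' neither `outcome` nor `"all"` are ignored. (`"LBW"` covers both LBW
#' groups; `"PTB"` covers both preterm groups when applied to group-level
#' rates.)
#'
#' @param geos Geometry table.
#' @param clusters List of planted cluster descriptors
#'   (see [synthetic_config()]).
#' @param outcome Outcome (or exclusive group) whose multiplier is wanted.
#' @param metric Distance metric.
#' @return Named per-unit multiplier vector (1.0 outside all clusters).
#' @export
plant_risk_surface <- function(geos, clusters, outcome = "all",
                               metric = "planar") {
  rr <- stats::setNames(rep(1, nrow(geos)),
                        as.character(geos$municipality_id))
  covers <- function(cl_out, out) {
    if (cl_out == "all" || out == "all" || cl_out == out) return(TRUE)
    if (cl_out == "LBW" && out %in% c("LBW_term", "LBW_pre")) return(TRUE)
    if (cl_out == "PTB" && out %in% c("LBW_pre", "NBW_pre")) return(TRUE)
    FALSE
  }
  for (cl in clusters) {
    cl_out <- if (is.null(cl$outcome)) "all" else cl$outcome
    if (!covers(cl_out, outcome)) next
    members <- cluster_members(geos, cl, metric)
    rr[members] <- rr[members] * cl$rr
  }
  rr
}

#' Simulate case counts for one outcome
#'
#' `O_ia ~ Poisson(n_ia * rho_a * RR_i)`, truncated at `n_ia` so the
#' cases-within-births invariant holds (negligible bias at realistic rates).
#'
#' @param denominators Long table from [generate_denominators()].
#' @param rates Length-9 per-class baseline rates.
#' @param risk Named per-unit relative-risk multipliers
#'   (see [plant_risk_surface()]).
#' @param seed Integer seed.
#' @return The denominator table with an `n_cases` column added.
#' @export
simulate_cases <- function(denominators, rates, risk, seed = 1L) {
  mu_rate <- rates[denominators$age_class] *
    risk[as.character(denominators$municipality_id)]
  if (any(mu_rate > 1)) stop("rate x RR exceeds 1 in some stratum")
  set.seed(seed)
  mu <- denominators$n_births * mu_rate
  out <- denominators
  out$n_cases <- pmin(denominators$n_births, stats::rpois(length(mu), mu))
  out
}

group_value_ranges <- list(
  LBW_pre  = list(bw = c(800, 2499),  ga = c(28, 36)),
  LBW_term = list(bw = c(1500, 2499), ga = c(37, 41)),
  NBW_pre  = list(bw = c(2500, 3400), ga = c(33, 36)),
  NBW_term = list(bw = c(2500, 4200), ga = c(37, 42))
)

age_class_year_range <- function(class_idx) {
  lo <- c(13, 16, 21, 26, 31, 36, 41, 46, 51)[class_idx]
  hi <- c(15, 20, 25, 30, 35, 40, 45, 50, 54)[class_idx]
  c(lo, hi)
}

#' Simulate a full synthetic study
#'
#' Runs the whole generator chain — municipality system, age-structured
#' denominators, planted risk surface, and per-stratum multinomial outcome
#' draws — and emits both the count-level truth tables and a record-level
#' birth file whose birthweight and gestational-age values are consistent
#' with each drawn outcome group, so the cohort module can be exercised
#' end to end. Fully deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @param records If `FALSE`, skip the record-level stream (counts only).
#' @return List with `geos`, `polygons`, `records` (or `NULL`),
#'   `counts` (municipality x age-class group counts with columns
#'   `n_births`, `n_lbw_term`, `n_lbw_pre`, `n_nbw_pre`), `risk`
#'   (per-group multiplier matrix), `truth` (planted cluster member ids per
#'   cluster), and `config`.
#' @export
simulate_study <- function(config, records = TRUE) {
  muni <- generate_municipalities(config)
  denom <- generate_denominators(config, muni$geos)
  grp <- c("LBW_term", "LBW_pre", "NBW_pre")
  risk <- vapply(grp, function(g) {
    plant_risk_surface(muni$geos, config$planted_clusters, g)
  }, numeric(nrow(muni$geos)))
  rownames(risk) <- as.character(muni$geos$municipality_id)
  truth <- lapply(config$planted_clusters, function(cl) {
    cluster_members(muni$geos, cl)
  })

  set.seed(stage_seed(config$seed, 3))
  n_rows <- nrow(denom)
  counts <- denom
  counts$n_lbw_term <- counts$n_lbw_pre <- counts$n_nbw_pre <- 0L
  ids <- as.character(denom$municipality_id)
  base <- config$baseline_rates
  rec_list <- if (records) vector("list", n_rows) else NULL
  for (r in seq_len(n_rows)) {
    nb <- denom$n_births[r]
    if (nb == 0) next
    a <- denom$age_class[r]
    p <- c(base[a, "LBW_term"] * risk[ids[r], "LBW_term"],
           base[a, "LBW_pre"] * risk[ids[r], "LBW_pre"],
           base[a, "NBW_pre"] * risk[ids[r], "NBW_pre"])
    if (sum(p) > 1) stop("group rates x RR exceed 1 in a stratum")
    draw <- as.integer(stats::rmultinom(1, nb, c(p, 1 - sum(p))))
    counts$n_lbw_term[r] <- draw[1]
    counts$n_lbw_pre[r] <- draw[2]
    counts$n_nbw_pre[r] <- draw[3]
    if (records) {
      group <- rep(c("LBW_term", "LBW_pre", "NBW_pre", "NBW_term"), draw)
      yr <- age_class_year_range(a)
      bw <- numeric(nb); ga <- integer(nb)
      for (g in names(group_value_ranges)) {
        sel <- group == g
        if (!any(sel)) next
        rg <- group_value_ranges[[g]]
        bw[sel] <- round(stats::runif(sum(sel), rg$bw[1], rg$bw[2]))
        ga[sel] <- sample(seq(rg$ga[1], rg$ga[2]), sum(sel), replace = TRUE)
      }
      rec_list[[r]] <- data.frame(
        municipality_id = ids[r],
        year = sample(config$years, nb, replace = TRUE),
        birthweight_g = bw,
        gestational_weeks = ga,
        maternal_age = sample(seq(yr[1], yr[2]), nb, replace = TRUE),
        plurality = 1L,
        sex = sample(c("male", "female"), nb, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  recs <- if (records) do.call(rbind, rec_list) else NULL
  list(geos = muni$geos, polygons = muni$polygons, records = recs,
       counts = counts, risk = risk, truth = truth, config = config)
}

#' Aggregate synthetic group counts to one outcome's count table
#'
#' Bookkeeping helper mapping the generator's exclusive-group counts to the
#' outcome selectors used downstream.
#'
#' @param counts `counts` table from [simulate_study()].
#' @param outcome One of `"LBW"`, `"PTB"`, `"LBW_term"`, `"LBW_pre"`.
#' @return Long count table with `n_cases`.
#' @export
synthetic_outcome_counts <- function(counts,
                                     outcome = c("LBW", "PTB", "LBW_term",
                                                 "LBW_pre")) {
  outcome <- match.arg(outcome)
  n_cases <- switch(outcome,
                    LBW = counts$n_lbw_term + counts$n_lbw_pre,
                    PTB = counts$n_lbw_pre + counts$n_nbw_pre,
                    LBW_term = counts$n_lbw_term,
                    LBW_pre = counts$n_lbw_pre)
  data.frame(municipality_id = counts$municipality_id,
             age_class = counts$age_class,
             n_births = counts$n_births,
             n_cases = n_cases,
             stringsAsFactors = FALSE)
}
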
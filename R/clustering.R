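# Cluster inference: Tango's general clustering statistic with Monte Carlo
# calibration, and the circular Poisson spatial scan (Kulldorff-Nagarwalla)
# reporting the most / second / third likely clusters.

#' Tango's general clustering statistic
#'
#' Quadratic-form contrast of observed and expected case shares under a
#' distance-decay kernel:
#' `C = sum_ij a_ij (O_i/O+ - E_i/E+)(O_j/O+ - E_j/E+)` with
#' `a_ij = exp(-d_ij / lambda)`. The exponential kernel is positive
#' semidefinite on a metric, so `C >= 0`, with `C = 0` exactly when the
#' observed shares equal the expected shares.
#'
#' @param O Observed cases per municipality.
#' @param E Expected cases per municipality.
#' @param D Symmetric distance matrix (km), zero diagonal.
#' @param lambda Kernel scale in km (> 0).
#' @return Scalar statistic.
#' @export
tango_statistic <- function(O, E, D, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  if (sum(O) <= 0 || sum(E) <= 0) stop("totals must be positive")
  z <- O / sum(O) - E / sum(E)
  A <- exp(-D / lambda)
  as.numeric(z %*% A %*% z)
}

#' Monte Carlo test of global clustering (Tango)
#'
#' Replicate case vectors are drawn multinomially with size `O+` and cell
#' probabilities `E/E+` (case-location resampling under the null of risk
#' proportional to expectation); the p-value is the standard Monte Carlo
#' rank `p = (1 + #\{C_sim >= C_obs\}) / (nsim + 1)`, with floor
#' `1/(nsim+1)`.
#'
#' @inheritParams tango_statistic
#' @param lambda Kernel scale; default (`NULL`) the median nearest-neighbor
#'   distance of `D`.
#' @param nsim Number of null replicates (>= 19 so alpha = 0.05 is
#'   resolvable).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `tango_test`: list with `statistic`, `lambda`,
#'   `p_value`, `nsim`, and the vector of null statistics `sim_stats`.
#' @export
tango_mc_test <- function(O, E, D, lambda = NULL, nsim = 999, seed = NULL) {
  if (nsim < 19) stop("nsim must be at least 19 to resolve alpha = 0.05")
  if (is.null(lambda)) lambda <- median_nn_distance(D)
  cobs <- tango_statistic(O, E, D, lambda)
  if (!is.null(seed)) set.seed(seed)
  ot <- sum(O)
  p <- E / sum(E)
  sims <- stats::rmultinom(nsim, ot, p)
  A <- exp(-D / lambda)
  Z <- sims / ot - p
  csim <- colSums(Z * (A %*% Z))
  pval <- (1 + sum(csim >= cobs)) / (nsim + 1)
  structure(list(statistic = cobs, lambda = lambda, p_value = pval,
                 nsim = nsim, sim_stats = csim),
            class = "tango_test")
}

#' @export
print.tango_test <- function(x, ...) {
  cat(sprintf(
    "Tango's general clustering test\n  C = %.6g (lambda = %.3g km)\n  Monte Carlo p = %.4g (%d replicates)\n",
    x$statistic, x$lambda, x$p_value, x$nsim))
  invisible(x)
}

#' Poisson scan log-likelihood ratio for one window
#'
#' One-sided (high-rate) likelihood ratio of the Kulldorff-Nagarwalla
#' circular scan under the Poisson model, assuming expected counts
#' calibrated so the expected total equals the observed total:
#' `llr = O_Z log(O_Z/E_Z) + (O+ - O_Z) log((O+ - O_Z)/(E+ - E_Z))` when the
#' inside rate exceeds the outside rate, else 0. Zero-count terms contribute
#' zero.
#'
#' @param o_z Observed cases in the window (vectorized).
#' @param e_z Expected cases in the window (> 0).
#' @param o_total Total observed cases.
#' @param e_total Total expected cases (defaults to `o_total`, the calibrated
#'   case).
#' @param direction `"high"` (default) or `"low"` for a low-rate scan.
#' @return Non-negative log-likelihood ratio(s).
#' @export
poisson_llr <- function(o_z, e_z, o_total, e_total = o_total,
                        direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (any(e_z <= 0)) stop("expected count in window must be positive")
  if (any(o_z < 0) || any(o_z > o_total)) stop("o_z must be in [0, o_total]")
  o_out <- o_total - o_z
  e_out <- e_total - e_z
  inside <- o_z / e_z
  outside <- ifelse(e_out > 0, o_out / e_out, Inf)
  active <- if (direction == "high") {
    e_out > 0 & inside > outside
  } else {
    e_out > 0 & inside < outside
  }
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  llr <- term(o_z, e_z) + term(o_out, e_out)
  ifelse(active, llr, 0)
}

#' Kulldorff-style relative risk (indirect form)
#'
#' `(O_Z/E_Z) / ((O+ - O_Z)/(E+ - E_Z))`: rate inside relative to the rate
#' outside the window. Reported cluster tables print the simpler `O_Z/E_Z`
#' ([reported_rr()]); this form is stored alongside for completeness.
#'
#' @param o_z,e_z Window observed and expected.
#' @param o_total,e_total Study totals.
#' @return Relative risk.
#' @export
kulldorff_rr <- function(o_z, e_z, o_total, e_total = o_total) {
  o_out <- o_total - o_z
  e_out <- e_total - e_z
  ifelse(o_out > 0 & e_out > 0, (o_z / e_z) / (o_out / e_out),
         ifelse(o_out == 0, Inf, NA_real_))
}

#' Reported relative risk of a cluster
#'
#' The observed-to-expected ratio `O_Z / E_Z`, as printed (to two decimals)
#' in cluster report tables.
#'
#' @param o_z Observed cases in the cluster.
#' @param e_z Expected cases in the cluster (> 0).
#' @return Full-precision ratio; use [round_half_up()] for display.
#' @export
reported_rr <- function(o_z, e_z) {
  if (any(e_z <= 0)) stop("expected count must be positive")
  o_z / e_z
}

scan_orderings <- function(geos, size, max_fraction, metric = NULL) {
  D <- distance_matrix(geos, metric)
  ids <- rownames(D)
  n <- length(ids)
  total <- sum(size)
  ord <- matrix(0L, n, n)
  zlen <- integer(n)
  for (i in seq_len(n)) {
    o <- order(D[i, ], ids)
    ord[, i] <- o
    zlen[i] <- max(1L, sum(cumsum(size[o]) <= max_fraction * total))
  }
  list(ids = ids, ord = ord, zlen = zlen, D = D)
}

#' Enumerate the circular scan window family
#'
#' For every municipality as a center, units are sorted by distance (ties
#' broken by ascending id) and nested windows grow one unit at a time while
#' the window's share of total births stays within `max_fraction`. Windows
#' with identical member sets reached from different centers are
#' deduplicated.
#'
#' @param geos Geometry table.
#' @param n_births Per-unit birth denominators (window size measure).
#' @param max_fraction Maximum share of total births per window, in (0, 1].
#' @param metric Distance metric override.
#' @return List of zones, each `list(center_id, member_ids)` with members
#'   ordered by distance from the center.
#' @export
enumerate_zones <- function(geos, n_births, max_fraction = 0.5,
                            metric = NULL) {
  if (max_fraction <= 0 || max_fraction > 1) {
    stop("max_fraction must be in (0, 1]")
  }
  sk <- scan_orderings(geos, n_births, max_fraction, metric)
  zones <- list()
  seen <- new.env(hash = TRUE)
  for (c_i in seq_along(sk$ids)) {
    o <- sk$ord[, c_i]
    for (len in seq_len(sk$zlen[c_i])) {
      members <- sk$ids[o[seq_len(len)]]
      key <- paste(sort(members), collapse = "|")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      zones[[length(zones) + 1L]] <- list(center_id = sk$ids[c_i],
                                          member_ids = members)
    }
  }
  zones
}

#' Circular Poisson spatial scan with Monte Carlo inference
#'
#' Computes the one-sided Poisson log-likelihood ratio for every circular
#' window (each municipality as center, nested by distance, capped at
#' `max_fraction` of total births), ranks windows by the ratio, and reports
#' the top `n_report` pairwise-disjoint windows: the most, second and third
#' likely clusters. Each reported cluster's p-value compares its ratio with
#' the maximum ratio attained in `nsim` null replicates, where replicate
#' cases are redistributed multinomially with probabilities `E/E+`
#' (conditioning on the observed total):
#' `p = (1 + #\{max LLR_sim >= llr\}) / (nsim + 1)`.
#'
#' @param O Observed cases per municipality (aligned with `geos` rows).
#' @param E Expected cases per municipality, calibrated so
#'   `sum(E) == sum(O)` (see [indirect_expected()]).
#' @param geos Geometry table.
#' @param max_fraction Window cap as share of total births, default 0.5.
#' @param nsim Null replicates, default 999; `nsim = 0` skips inference
#'   (p-values `NA`), useful when only the cluster locations are needed.
#' @param seed Optional integer seed.
#' @param n_report Number of disjoint clusters to report, default 3.
#' @param n_births Window size measure; defaults to `E` when birth
#'   denominators are not supplied.
#' @param metric Distance metric override.
#' @param direction `"high"` (default) detects elevated-risk clusters only;
#'   `"low"` detects deficits.
#' @return `data.frame` of class `scan_result` with columns `rank`
#'   (`MLC`, `SLC`, `TLC`, ...), `center_id`, `n_municipalities`, `observed`,
#'   `expected`, `relative_risk` (O/E), `kulldorff_rr`, `llr`, `p_value`,
#'   `member_ids` (semicolon-joined). The null max-LLR distribution is
#'   attached as attribute `null_maxllr`, member id vectors as attribute
#'   `members`.
#' @export
scan_test <- function(O, E, geos, max_fraction = 0.5, nsim = 999,
                      seed = NULL, n_report = 3, n_births = NULL,
                      metric = NULL, direction = c("high", "low")) {
  direction <- match.arg(direction)
  n <- nrow(geos)
  stopifnot(length(O) == n, length(E) == n)
  if (sum(O) <= 0) stop("total observed cases must be positive")
  if (abs(sum(E) - sum(O)) > 1e-6 * max(1, sum(O))) {
    stop("E must be calibrated so sum(E) == sum(O); see indirect_expected()")
  }
  if (is.null(n_births)) n_births <- E
  sk <- scan_orderings(geos, n_births, max_fraction, metric)
  ot <- sum(O)
  et <- sum(E)
  dirflag <- if (direction == "high") 1L else -1L

  # observed LLR for every nested window, per center
  ecum <- matrix(0, n, n)
  cand <- vector("list", n)
  for (c_i in seq_len(n)) {
    o <- sk$ord[, c_i]
    L <- sk$zlen[c_i]
    oc <- cumsum(O[o])[seq_len(L)]
    ec <- cumsum(E[o])
    ecum[, c_i] <- ec
    # windows with no expectation (no births in the stratum) carry no signal
    llr <- numeric(L)
    ok <- ec[seq_len(L)] > 0
    llr[ok] <- poisson_llr(oc[ok], ec[seq_len(L)][ok], ot, et, direction)
    cand[[c_i]] <- data.frame(center = c_i, len = seq_len(L),
                              observed = oc, expected = ec[seq_len(L)],
                              llr = llr)
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$llr, cand$center, cand$len), , drop = FALSE]

  # greedy non-overlap selection of the top clusters
  chosen <- list()
  used <- logical(n)
  for (r in seq_len(nrow(cand))) {
    if (length(chosen) >= n_report) break
    if (cand$llr[r] <= 0) break
    members_idx <- sk$ord[seq_len(cand$len[r]), cand$center[r]]
    if (any(used[members_idx])) next
    used[members_idx] <- TRUE
    chosen[[length(chosen) + 1L]] <- cbind(cand[r, , drop = FALSE],
                                           row = r)
  }

  null_maxllr <- numeric(0)
  if (nsim > 0) {
    if (!is.null(seed)) set.seed(seed)
    sims <- stats::rmultinom(nsim, ot, E / et)
    null_maxllr <- scan_max_llr_cpp(sims, sk$ord, sk$zlen, ecum, et, dirflag)
  }

  rank_labels <- function(k) {
    base <- c("MLC", "SLC", "TLC")
    if (k <= 3) base[seq_len(k)] else c(base, paste0("C", seq(4, k)))
  }
  if (length(chosen) == 0) {
    rep_df <- data.frame(rank = character(0), center_id = character(0),
                         n_municipalities = integer(0), observed = numeric(0),
                         expected = numeric(0), relative_risk = numeric(0),
                         kulldorff_rr = numeric(0), llr = numeric(0),
                         p_value = numeric(0), member_ids = character(0),
                         stringsAsFactors = FALSE)
    members <- list()
  } else {
    ch <- do.call(rbind, chosen)
    members <- lapply(seq_len(nrow(ch)), function(r) {
      sk$ids[sk$ord[seq_len(ch$len[r]), ch$center[r]]]
    })
    pv <- if (nsim > 0) {
      vapply(ch$llr, function(l) (1 + sum(null_maxllr >= l)) / (nsim + 1),
             numeric(1))
    } else rep(NA_real_, nrow(ch))
    rep_df <- data.frame(
      rank = rank_labels(nrow(ch)),
      center_id = sk$ids[ch$center],
      n_municipalities = ch$len,
      observed = ch$observed,
      expected = ch$expected,
      relative_risk = reported_rr(ch$observed, ch$expected),
      kulldorff_rr = kulldorff_rr(ch$observed, ch$expected, ot, et),
      llr = ch$llr,
      p_value = pv,
      member_ids = vapply(members, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  attr(rep_df, "null_maxllr") <- null_maxllr
  attr(rep_df, "members") <- members
  attr(rep_df, "nsim") <- nsim
  class(rep_df) <- c("scan_result", "data.frame")
  rep_df
}
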
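# Spatially structured (local) empirical Bayes smoothing of age-standardized
# rates toward the neighborhood mean, plus quantile classing for choropleths.

#' Local empirical Bayes smoothing of a rate surface
#'
#' Marshall-style local estimator: for each municipality the neighborhood
#' `D_i = N(i) U {i}` defines a local mean
#' `m_i = sum_j asr_j n_j / sum_j n_j` (rate-consistent pseudo-counts), a
#' weighted local variance
#' `s2_i = sum_j n_j (asr_j - m_i)^2 / sum_j n_j`, a between-area variance
#' component `A_i = max(0, s2_i - m_i / nbar_i)` (`nbar_i` the mean
#' denominator in `D_i`; negative estimates truncated to zero, i.e. full
#' shrinkage), and the shrinkage weight `w_i = A_i / (A_i + m_i / n_i)`
#' (0 when both terms vanish). The smoothed value is
#' `ebsir_i = m_i + w_i (asr_i - m_i)`, which always lies between the raw
#' rate and the neighborhood mean. Units with no neighbors keep their raw
#' value (a warning lists them).
#'
#' @param surface Rate surface (needs `municipality_id`, `asr`, `n_births`),
#'   e.g. from [rate_surface()]. Any rate column can be smoothed via `value`.
#' @param adj `adjacency` object covering all municipalities, or `NULL` for
#'   the global (whole-study-area neighborhood) variant.
#' @param value Name of the rate column to smooth (default `"asr"`).
#' @return `data.frame` `municipality_id`, `asr` (the input rate),
#'   `neighborhood_mean`, `shrinkage_weight`, `ebsir`.
#' @export
local_eb <- function(surface, adj, value = "asr") {
  ids <- as.character(surface$municipality_id)
  r <- surface[[value]]
  n <- surface$n_births
  if (any(n < 0)) stop("denominators must be non-negative")
  if (!is.null(adj)) {
    missing_ids <- setdiff(ids, names(adj$neighbors))
    if (length(missing_ids)) {
      stop("adjacency does not cover: ", paste(missing_ids, collapse = ", "))
    }
  }
  idx <- stats::setNames(seq_along(ids), ids)
  m <- w <- eb <- numeric(length(ids))
  isolated <- character(0)
  for (i in seq_along(ids)) {
    nb <- if (is.null(adj)) ids else adj$neighbors[[ids[i]]]
    if (!is.null(adj) && length(nb) == 0) isolated <- c(isolated, ids[i])
    d <- unique(c(i, idx[nb]))
    nd <- n[d]
    if (sum(nd) == 0) {           # empty neighborhood: nothing to borrow
      m[i] <- r[i]; w[i] <- 1; eb[i] <- r[i]
      next
    }
    m[i] <- sum(r[d] * nd) / sum(nd)
    s2 <- sum(nd * (r[d] - m[i])^2) / sum(nd)
    A <- max(0, s2 - m[i] / mean(nd))
    denom <- if (n[i] > 0) A + m[i] / n[i] else Inf
    w[i] <- if (A == 0 && (denom == 0 || is.infinite(denom))) 0
            else if (is.infinite(denom)) 0 else A / denom
    if (is.nan(w[i])) w[i] <- 0    # A = 0 and m_i/n_i = 0
    eb[i] <- m[i] + w[i] * (r[i] - m[i])
  }
  if (length(isolated)) {
    warning("isolated units smoothed to themselves: ",
            paste(isolated, collapse = ", "))
  }
  data.frame(municipality_id = ids, asr = r, neighborhood_mean = m,
             shrinkage_weight = w, ebsir = eb, stringsAsFactors = FALSE)
}

#' Global empirical Bayes smoothing
#'
#' Same moment estimator as [local_eb()] but with the whole study area as
#' every unit's neighborhood (Clayton–Kaldor-style global shrinkage),
#' provided for comparison with the spatially local default.
#'
#' @inheritParams local_eb
#' @return See [local_eb()].
#' @export
global_eb <- function(surface, value = "asr") {
  local_eb(surface, adj = NULL, value = value)
}

#' Quantile classes for choropleth mapping
#'
#' Class `c` holds values in `(q_{(c-1)/Q}, q_{c/Q}]`; ties at a boundary go
#' to the lower class. A constant vector maps entirely to class 1.
#'
#' @param values Numeric vector.
#' @param Q Number of classes (default 5).
#' @return Integer classes in 1..Q.
#' @export
quantile_classes <- function(values, Q = 5) {
  if (Q < 2) stop("Q must be at least 2")
  qs <- stats::quantile(values, probs = seq_len(Q - 1) / Q,
                        na.rm = TRUE, names = FALSE)
  cls <- 1L + vapply(values, function(v) sum(v > qs), integer(1))
  cls[is.na(values)] <- NA_integer_
  cls
}
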
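# Independent oracles and fixture builders used across the suite.

# brute-force Tango double sum (independent of the matrix implementation)
tango_brute <- function(O, E, D, lambda) {
  z <- O / sum(O) - E / sum(E)
  n <- length(z)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + exp(-D[i, j] / lambda) * z[i] * z[j]
    }
  }
  acc
}

# exhaustive circular-scan oracle: every center x radius window, plain loops
scan_brute_mlc <- function(O, E, geos, max_fraction = 0.5, n_births = NULL) {
  if (is.null(n_births)) n_births <- E
  D <- distance_matrix(geos)
  ids <- rownames(D)
  ot <- sum(O); et <- sum(E); tot_b <- sum(n_births)
  best <- list(llr = -1, members = NULL)
  for (i in seq_along(ids)) {
    ord <- order(D[i, ], ids)
    oz <- ez <- bz <- 0
    for (r in seq_along(ord)) {
      j <- ord[r]
      oz <- oz + O[j]; ez <- ez + E[j]; bz <- bz + n_births[j]
      if (r > 1 && bz > max_fraction * tot_b) break
      oout <- ot - oz; eout <- et - ez
      llr <- 0
      if (eout > 0 && oz / ez > oout / eout) {
        llr <- (if (oz > 0) oz * log(oz / ez) else 0) +
          (if (oout > 0) oout * log(oout / eout) else 0)
      }
      if (llr > best$llr + 1e-12) {
        best <- list(llr = llr, members = sort(ids[ord[seq_len(r)]]))
      }
    }
  }
  best
}

# random small scan instance on scattered points
random_scan_instance <- function(n, seed) {
  set.seed(seed)
  geos <- data.frame(municipality_id = sprintf("U%02d", seq_len(n)),
                     x = runif(n, 0, 100), y = runif(n, 0, 100),
                     stringsAsFactors = FALSE)
  E <- runif(n, 2, 30)
  O <- rpois(n, E)
  if (sum(O) == 0) O[1] <- 1
  E <- E * sum(O) / sum(E)
  list(geos = geos, O = O, E = E)
}

# tiny hand-made birth-record table
make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    defaults <- list(municipality_id = "A", year = 2014, birthweight_g = 3100,
                     gestational_weeks = 39, maternal_age = 30, plurality = 1,
                     sex = "female")
    defaults[names(r)] <- r
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }))
}

# square-grid geometry without the generator (for geo tests)
grid_geos <- function(rows, cols, spacing = 10) {
  ids <- sprintf("G%03d", seq_len(rows * cols))
  data.frame(municipality_id = ids,
             x = rep(seq_len(cols) - 1, times = rows) * spacing,
             y = rep(seq_len(rows) - 1, each = cols) * spacing,
             stringsAsFactors = FALSE)
}

grid_polygons <- function(geos, spacing = 10) {
  h <- spacing / 2
  polys <- lapply(seq_len(nrow(geos)), function(i) {
    cbind(geos$x[i] + c(-h, h, h, -h, -h), geos$y[i] + c(-h, -h, h, h, -h))
  })
  names(polys) <- geos$municipality_id
  polys
}
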
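# End-to-end orchestration: cohort -> rates -> smoothing -> Tango -> scan
# for each outcome x maternal-age stratum, with CSV/GeoJSON/manifest output.

#' Pipeline configuration
#'
#' @param outcomes Outcomes to analyze.
#' @param strata Maternal-age reporting strata; `"all"` plus any of
#'   [age_stratum_labels()].
#' @param adjacency `"knn"` or `"queen"` (queen needs polygons).
#' @param k Neighbors for k-NN adjacency.
#' @param max_fraction Scan window cap (share of total births).
#' @param nsim Monte Carlo replicates for both Tango's test and the scan.
#' @param n_report Clusters reported per analysis cell.
#' @param tango_lambda Tango kernel scale in km (`NULL`: median
#'   nearest-neighbor distance).
#' @param quantile_Q Number of map quantile classes.
#' @param epsilon Empty-stratum denominator imputation for direct
#'   standardization.
#' @param metric Distance metric override (`NULL` auto-detects).
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it deterministically.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outcomes = c("LBW", "PTB", "LBW_term", "LBW_pre"),
                            strata = c("all", age_stratum_labels()),
                            adjacency = c("knn", "queen"), k = 8,
                            max_fraction = 0.5, nsim = 999, n_report = 3,
                            tango_lambda = NULL, quantile_Q = 5,
                            epsilon = 1e-4, metric = NULL, seed = 1L) {
  structure(list(outcomes = outcomes, strata = strata,
                 adjacency = match.arg(adjacency), k = k,
                 max_fraction = max_fraction, nsim = nsim,
                 n_report = n_report, tango_lambda = tango_lambda,
                 quantile_Q = quantile_Q, epsilon = epsilon,
                 metric = metric, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full spatial analysis pipeline
#'
#' For each requested outcome x maternal-age stratum: aggregates the birth
#' records, computes crude and age-standardized rates with calibrated
#' expected counts, smooths the standardized rates with local empirical
#' Bayes, runs Tango's global clustering test, and runs the circular Poisson
#' spatial scan reporting the most / second / third likely clusters. The
#' whole bundle is deterministic given the configuration and seed.
#'
#' @param records Birth-record `data.frame` (exclusions are applied
#'   internally and tallied).
#' @param geos Geometry table (`municipality_id` + `x`/`y` or `lat`/`lon`).
#' @param config A [pipeline_config()].
#' @param polygons Optional named polygon list (required for queen
#'   adjacency).
#' @param weights Reference weights for direct standardization.
#' @param out_dir Optional directory; when given, writes per-cell CSVs
#'   (rate surfaces, EB surfaces, cluster reports), a summary table, and a
#'   JSON manifest.
#' @return List with `summary`, `exclusions`, `adjacency`, and `cells` — a
#'   named list (one per `outcome.stratum`) each holding `surface`, `eb`,
#'   `tango`, `scan`.
#' @export
run_pipeline <- function(records, geos, config = pipeline_config(),
                         polygons = NULL, weights = default_reference_weights(),
                         out_dir = NULL) {
  excl <- apply_exclusions(records)
  kept <- excl$kept
  ids <- as.character(geos$municipality_id)

  adj <- if (config$adjacency == "queen") {
    if (is.null(polygons)) stop("queen adjacency requires polygons")
    queen_adjacency(polygons)
  } else {
    knn_adjacency(geos, k = config$k, metric = config$metric)
  }

  summ <- summary_table(kept)
  cells <- list()
  cell_idx <- 0L
  stratum_of <- assign_age_stratum(kept$maternal_age)
  for (outcome in config$outcomes) {
    for (st in config$strata) {
      cell_idx <- cell_idx + 1L
      sel <- if (st == "all") rep(TRUE, nrow(kept)) else stratum_of == st
      sub <- kept[sel, , drop = FALSE]
      counts <- aggregate_counts(sub, municipality_ids = ids,
                                 outcome = outcome)
      surface <- rate_surface(counts, weights, config$epsilon)
      eb <- local_eb(surface, adj)
      eb$quantile_class <- quantile_classes(eb$ebsir, config$quantile_Q)
      D <- distance_matrix(geos, config$metric)
      cell_seed <- (config$seed + 1000L * cell_idx) %% 2147483647L
      tango <- tango_mc_test(surface$observed, surface$expected, D,
                             lambda = config$tango_lambda,
                             nsim = config$nsim, seed = cell_seed)
      scan <- scan_test(surface$observed, surface$expected, geos,
                        max_fraction = config$max_fraction,
                        nsim = config$nsim, seed = cell_seed + 1L,
                        n_report = config$n_report,
                        n_births = surface$n_births,
                        metric = config$metric)
      cells[[paste(outcome, st, sep = ".")]] <-
        list(outcome = outcome, stratum = st, surface = surface, eb = eb,
             tango = tango, scan = scan)
    }
  }
  result <- list(summary = summ, exclusions = excl$report,
                 adjacency = adj, cells = cells, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, geos, out_dir)
  invisible(result)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9_]+", "_", x)

write_pipeline_outputs <- function(result, geos, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$summary$totals,
                   file.path(out_dir, "summary_totals.csv"),
                   row.names = FALSE)
  for (nm in names(result$cells)) {
    cell <- result$cells[[nm]]
    tag <- sanitize_name(nm)
    utils::write.csv(cell$surface,
                     file.path(out_dir, paste0("surface_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(cell$eb,
                     file.path(out_dir, paste0("ebsir_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(render_cluster_table(cell$scan),
                     file.path(out_dir, paste0("clusters_", tag, ".csv")),
                     row.names = FALSE)
  }
  tango_df <- do.call(rbind, lapply(names(result$cells), function(nm) {
    tg <- result$cells[[nm]]$tango
    data.frame(cell = nm, statistic = tg$statistic, lambda = tg$lambda,
               p_value = tg$p_value, nsim = tg$nsim,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(tango_df, file.path(out_dir, "tango.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = result$config$seed,
    config = unclass(result$config),
    exclusions = as.list(result$exclusions),
    cells = names(result$cells),
    n_municipalities = nrow(geos)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Format a scan report like a published cluster table
#'
#' Expected counts and relative risks are rounded half-up to two decimals;
#' Monte Carlo p-values at or below 0.001 are rendered `"< 0.001"`.
#'
#' @param reports A `scan_result` from [scan_test()].
#' @return `data.frame` with display columns `rank`, `n_municipalities`,
#'   `expected`, `observed`, `relative_risk`, `p_value`, `member_ids`.
#' @export
render_cluster_table <- function(reports) {
  if (nrow(reports) == 0) {
    return(data.frame(rank = character(0), n_municipalities = integer(0),
                      expected = character(0), observed = numeric(0),
                      relative_risk = character(0), p_value = character(0),
                      member_ids = character(0), stringsAsFactors = FALSE))
  }
  fmt_p <- function(p) {
    ifelse(is.na(p), "NA",
           ifelse(p <= 0.001, "< 0.001", sprintf("%.3f", p)))
  }
  data.frame(
    rank = reports$rank,
    n_municipalities = reports$n_municipalities,
    expected = sprintf("%.2f", round_half_up(reports$expected, 2)),
    observed = reports$observed,
    relative_risk = sprintf("%.2f", round_half_up(reports$relative_risk, 2)),
    p_value = fmt_p(reports$p_value),
    member_ids = reports$member_ids,
    stringsAsFactors = FALSE
  )
}

#' Write a rate/EB surface as GeoJSON
#'
#' Point features (centroids) or Polygon features when `polygons` is given,
#' each carrying the surface columns as properties — ready for choropleth
#' rendering with the quantile classes.
#'
#' @param geos Geometry table.
#' @param properties `data.frame` keyed by `municipality_id` with the
#'   columns to attach.
#' @param path Output path.
#' @param polygons Optional named polygon list.
#' @return `path`, invisibly.
#' @export
write_surface_geojson <- function(geos, properties, path, polygons = NULL) {
  ids <- as.character(geos$municipality_id)
  prop_idx <- match(ids, properties$municipality_id)
  features <- lapply(seq_along(ids), function(i) {
    props <- as.list(properties[prop_idx[i], , drop = FALSE])
    geom <- if (!is.null(polygons)) {
      ring <- polygons[[ids[i]]]
      if (is.list(ring)) ring <- ring[[1]]
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(r) as.numeric(ring[r, ]))))
    } else if (all(c("x", "y") %in% names(geos))) {
      list(type = "Point", coordinates = c(geos$x[i], geos$y[i]))
    } else {
      list(type = "Point", coordinates = c(geos$lon[i], geos$lat[i]))
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
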
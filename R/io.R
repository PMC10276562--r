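#' Read survey points from CSV
#'
#' Expects columns `point_id`, `easting`, `northing` (metres).  A UTF-8
#' byte-order mark in the header is tolerated.
#'
#' @param path CSV file path.
#' @return data.frame with columns `point_id`, `x`, `y`.
#' @export
read_points <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8-BOM", stringsAsFactors = FALSE)
  need <- c("point_id", "easting", "northing")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  for (col in c("easting", "northing")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad)) stop(path, ": non-numeric ", col, " at row ", bad[1])
    if (anyNA(v)) stop(path, ": missing ", col, " at row ", which(is.na(v))[1])
    d[[col]] <- v
  }
  data.frame(point_id = as.character(d$point_id), x = d$easting, y = d$northing)
}

#' Read detection distances from CSV
#'
#' Expects columns `point_id`, `distance_m`; optional condition covariates
#' (`cloud`, `rain`, `wind`, `gust`) are carried through unmodelled.
#'
#' @param path CSV file path.
#' @return data.frame with at least `point_id`, `distance_m`.
#' @export
read_distances <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8-BOM", stringsAsFactors = FALSE)
  need <- c("point_id", "distance_m")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  v <- suppressWarnings(as.numeric(d$distance_m))
  bad <- which((is.na(v) & !is.na(d$distance_m)) | v < 0)
  if (length(bad))
    stop(path, ": invalid distance_m at row ", bad[1])
  d$distance_m <- v
  d$point_id <- as.character(d$point_id)
  d
}

#' Read a study region from GeoJSON or WKT
#'
#' Accepts a GeoJSON file containing a `Polygon` (or single-polygon
#' `MultiPolygon` / `Feature` / `FeatureCollection`), or a WKT `POLYGON`
#' string/file.  Coordinates must be projected metres; interior rings
#' become holes.
#'
#' @param path file path, or a WKT string.
#' @return A [region()] object.
#' @export
read_region <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "\n")
         else path
  txt_trim <- sub("^﻿", "", trimws(txt))
  if (grepl("^POLYGON", txt_trim, ignore.case = TRUE)) {
    rings <- wkt_polygon_rings(txt_trim)
  } else {
    gj <- jsonlite::fromJSON(txt_trim, simplifyVector = TRUE)
    rings <- geojson_polygon_rings(gj)
  }
  region(rings[[1]], holes = rings[-1])
}

wkt_polygon_rings <- function(txt) {
  body <- sub("^POLYGON\\s*\\(", "", txt, ignore.case = TRUE)
  body <- sub("\\)\\s*$", "", body)
  parts <- strsplit(body, "\\)\\s*,\\s*\\(")[[1]]
  parts <- gsub("[()]", "", parts)
  lapply(parts, function(p) {
    xy <- strsplit(trimws(strsplit(p, ",")[[1]]), "\\s+")
    do.call(rbind, lapply(xy, function(v) as.numeric(v[1:2])))
  })
}

geojson_polygon_rings <- function(gj) {
  if (!is.null(gj$type) && gj$type == "FeatureCollection") gj <- gj$features$geometry
  if (!is.null(gj$type) && length(gj$type) == 1 && gj$type == "Feature") gj <- gj$geometry
  type <- gj$type[1]
  coords <- gj$coordinates
  if (is.null(type) || is.null(coords)) stop("not a GeoJSON polygon")
  if (type == "MultiPolygon") {
    if (is.list(coords)) coords <- coords[[1]]
    else coords <- coords[1, , , ]   # array form
  }
  if (is.array(coords) && length(dim(coords)) == 3) {
    lapply(seq_len(dim(coords)[1]), function(i) coords[i, , ])
  } else if (is.list(coords)) {
    lapply(coords, function(r) {
      r <- if (is.list(r)) do.call(rbind, r) else r
      matrix(as.numeric(r), ncol = ncol(r))
    })
  } else stop("unsupported GeoJSON coordinate structure")
}

#' Write a region to GeoJSON
#'
#' @param region a [region()] object.
#' @param path output file.
#' @export
write_region <- function(region, path) {
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  rings <- c(list(close_ring(region$outer)),
             lapply(region$holes, close_ring))
  gj <- list(type = "Polygon",
             coordinates = lapply(rings, function(r) unname(as.matrix(r))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic survey to the standard pipeline formats
#'
#' Writes `points.csv` (`point_id`, `easting`, `northing`),
#' `distances.csv` (`point_id`, `distance_m`), `region.geojson` and
#' `truth.json` into `dir` (created if needed).
#'
#' @param survey a [simulate_survey()] object.
#' @param dir output directory.
#' @return Invisibly, the vector of paths written.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "synthetic_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, c("points.csv", "distances.csv", "region.geojson", "truth.json"))
  utils::write.csv(data.frame(point_id = survey$points$point_id,
                              easting = survey$points$x,
                              northing = survey$points$y),
                   p[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(survey$records[, c("point_id", "distance_m")],
                   p[2], row.names = FALSE, quote = FALSE)
  write_region(survey$region, p[3])
  tr <- survey$truth
  jsonlite::write_json(list(
    N_true = tr$N_true, theta = tr$theta, w_max = tr$w_max, seed = tr$seed,
    detection = tr$detection[!vapply(tr$detection, is.null, TRUE)]
  ), p[4], auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Write an abundance estimate to JSON
#'
#' @param estimate an [abundance_estimate()].
#' @param path output file.
#' @export
write_abundance_json <- function(estimate, path) {
  stopifnot(inherits(estimate, "abundance_estimate"))
  jsonlite::write_json(
    estimate[!vapply(estimate, is.null, TRUE)],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a flat key:value pipeline configuration
#'
#' Configuration files use Debian-control (DCF) `key: value` lines.
#' Numeric values are coerced; unknown keys are rejected.
#'
#' @param path DCF file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  d <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  known <- c("points", "distances", "polygon", "output_dir",
             "truncation", "target_g", "smoother", "k", "k_boundary",
             "knot_dx", "knot_dy", "nmax", "family", "cell", "n_sims",
             "seed", "key", "propagate_detection_cv")
  unknown <- setdiff(names(d), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  numeric_keys <- c("truncation", "target_g", "k", "k_boundary", "knot_dx",
                    "knot_dy", "nmax", "cell", "n_sims", "seed",
                    "propagate_detection_cv")
  for (k in intersect(numeric_keys, names(d))) {
    v <- suppressWarnings(as.numeric(d[[k]]))
    if (is.na(v)) stop("config key ", k, " must be numeric, got ", d[[k]])
    d[[k]] <- v
  }
  d
}

#' Run the full two-stage pipeline
#'
#' Orchestrates detection-function fitting (both keys, AIC selection),
#' per-point counts, the density surface model (soap and/or TPRS),
#' prediction, model-based and design-based abundance, and the
#' interval-width comparison.  Inputs are taken from files named in the
#' config, or passed directly.
#'
#' @param points data.frame (`point_id`, `x`, `y`) or path via config.
#' @param distances data.frame (`point_id`, `distance_m`) or path.
#' @param region a [region()] or path.
#' @param truncation truncation distance in metres, or `NULL` to select
#'   it from a preliminary fit at `target_g`.
#' @param target_g detection probability defining automatic truncation.
#' @param smoothers character subset of `c("soap", "tprs")`.
#' @param k TPRS basis dimension.
#' @param k_boundary soap boundary basis dimension.
#' @param knot_dx,knot_dy soap interior knot spacings, metres.
#' @param nmax soap PDE grid dimension.
#' @param family `"nb"` or `"poisson"`.
#' @param cell prediction cell size, metres.
#' @param n_sims posterior draws for model-based intervals.
#' @param seed integer seed (posterior simulation and optimizer jitter).
#' @param verbose emit stage messages.
#' @return List with `detection` (AIC table and selected fit), `counts`,
#'   `fits`, `grids`, `abundance` (named list of estimates), and
#'   `comparison` (CIW changes against the soap reference when present).
#' @export
run_pipeline <- function(points, distances, region,
                         truncation = NULL, target_g = 0.1,
                         smoothers = c("soap", "tprs"),
                         k = 127, k_boundary = 20,
                         knot_dx = 730, knot_dy = 670, nmax = 140,
                         family = "nb", cell = 200, n_sims = 10000,
                         seed = 1, verbose = FALSE) {
  say <- function(...) if (verbose) message("[soapdsm] ", ...)
  if (is.character(points)) points <- read_points(points)
  if (is.character(distances)) distances <- read_distances(distances)
  if (is.character(region)) region <- read_region(region)
  smoothers <- match.arg(smoothers, c("soap", "tprs"), several.ok = TRUE)
  family <- match.arg(family, c("nb", "poisson"))
  set.seed(as.integer(seed))

  say("stage 1: detection function")
  if (is.null(truncation)) {
    truncation <- select_truncation(distances, key = "hr", target_g = target_g)
    say("selected truncation w = ", truncation, " m")
  }
  fits_det <- list(hn = fit_detection(distances, "hn", truncation),
                   hr = fit_detection(distances, "hr", truncation))
  aic_tab <- rank_by_aic(fits_det)
  det <- fits_det[[aic_tab$key[1]]]
  say("selected key: ", det$key, " (P_a = ", round(det$p_a, 3), ")")

  counts <- counts_per_point(distances, points, truncation)

  say("stage 2: density surface models")
  fits <- list(); grids <- list(); abund <- list()
  for (sm in smoothers) {
    spec <- if (sm == "soap") {
      kg <- make_knot_grid(region, knot_dx, knot_dy)
      smoother_spec("soap", region = region, knots = kg,
                    k_boundary = k_boundary, nmax = nmax)
    } else {
      smoother_spec("tprs", k = k)
    }
    fits[[sm]] <- fit_dsm(counts, points[, c("x", "y")], det$nu, spec,
                          family = family)
    grids[[sm]] <- predict_surface(fits[[sm]], region = region, cell = cell)
    abund[[sm]] <- posterior_abundance(fits[[sm]], grids[[sm]],
                                       n_sims = n_sims, seed = seed + 1)
    say(sm, ": N = ", round(abund[[sm]]$N))
  }
  abund$distance <- design_based_abundance(counts, det, region$area_ha)
  say("distance: N = ", round(abund$distance$N))

  comparison <- list()
  if ("soap" %in% names(abund)) {
    for (other in setdiff(names(abund), "soap"))
      comparison[[other]] <- ciw_change(abund$soap, abund[[other]])
  }
  list(detection = list(table = aic_tab, fit = det, truncation = truncation),
       counts = counts, fits = fits, grids = grids,
       abundance = abund, comparison = comparison)
}
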
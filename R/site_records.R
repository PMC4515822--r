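# I/O and validation for site tables, city registries and region polygons.
# CSV dialect: UTF-8, comma separator, "." decimal, mandatory header; one row
# is one (site, medium) pair, so a site measured in both bulk precipitation
# and throughfall appears as two rows sharing site_id.

SITE_COLUMNS <- c("site_id", "latitude", "longitude", "precipitation_mm",
                  "medium", "ph", "conc_so4_ueq_l", "conc_no3_ueq_l",
                  "conc_nh4_ueq_l", "obs_years", "distance_km")
SITE_REQUIRED <- c("site_id", "latitude", "longitude", "precipitation_mm", "medium")

as_num_or_na <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read and validate a site table
#'
#' Reads a CSV of forest monitoring sites (one row per site and sampling
#' medium) and validates each row against the record invariants:
#' coordinates in range, precipitation strictly positive, medium one of
#' `bulk`/`throughfall`, pH (if present) in (0, 14), concentrations (if
#' present) non-negative. Empty cells in optional columns become `NA`, so a
#' site missing one ion still contributes to the analyses of the others.
#' Rows that fail validation are rejected individually (the rest of the file
#' is kept) and reported with their row numbers.
#'
#' @param path Path to the CSV file. Required columns: `site_id`,
#'   `latitude`, `longitude`, `precipitation_mm`, `medium`. Optional:
#'   `ph`, `conc_so4_ueq_l`, `conc_no3_ueq_l`, `conc_nh4_ueq_l`,
#'   `obs_years`, `distance_km`.
#' @param medium_filter Optional `"bulk"` or `"throughfall"` to keep only
#'   one medium.
#' @return Data frame of validated records with all columns above
#'   (missing optional columns filled with `NA`). The character vector of
#'   per-row diagnostics for rejected rows is attached as attribute
#'   `"diagnostics"` and also raised as a warning.
#' @export
read_sites <- function(path, medium_filter = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(SITE_REQUIRED, names(raw))
  if (length(missing_cols) > 0L) {
    stop("site table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(SITE_COLUMNS, names(raw))) raw[[col]] <- NA_character_

  out <- data.frame(
    site_id = trimws(raw$site_id),
    latitude = as_num_or_na(raw$latitude),
    longitude = as_num_or_na(raw$longitude),
    precipitation_mm = as_num_or_na(raw$precipitation_mm),
    medium = trimws(raw$medium),
    ph = as_num_or_na(raw$ph),
    conc_so4_ueq_l = as_num_or_na(raw$conc_so4_ueq_l),
    conc_no3_ueq_l = as_num_or_na(raw$conc_no3_ueq_l),
    conc_nh4_ueq_l = as_num_or_na(raw$conc_nh4_ueq_l),
    obs_years = as.character(raw$obs_years),
    distance_km = as_num_or_na(raw$distance_km),
    stringsAsFactors = FALSE
  )

  diag <- character(0)
  keep <- rep(TRUE, nrow(out))
  flag <- function(i, msg) {
    diag <<- c(diag, sprintf("row %d (site_id '%s'): %s", i, out$site_id[i], msg))
    keep[i] <<- FALSE
  }
  for (i in seq_len(nrow(out))) {
    if (is.na(out$latitude[i]) || abs(out$latitude[i]) > 90)
      flag(i, "latitude missing, non-numeric or outside [-90, 90]")
    if (is.na(out$longitude[i]) || abs(out$longitude[i]) > 180)
      flag(i, "longitude missing, non-numeric or outside [-180, 180]")
    if (is.na(out$precipitation_mm[i]) || out$precipitation_mm[i] <= 0)
      flag(i, "precipitation must be a number > 0")
    if (!out$medium[i] %in% c("bulk", "throughfall"))
      flag(i, "medium must be 'bulk' or 'throughfall'")
    if (!is.na(out$ph[i]) && (out$ph[i] <= 0 || out$ph[i] >= 14))
      flag(i, "ph outside (0, 14)")
    for (col in c("conc_so4_ueq_l", "conc_no3_ueq_l", "conc_nh4_ueq_l")) {
      if (!is.na(out[[col]][i]) && out[[col]][i] < 0)
        flag(i, paste(col, "is negative"))
    }
    if (!is.na(out$distance_km[i]) && out$distance_km[i] <= 0)
      flag(i, "distance_km must be > 0 when given")
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (length(diag) > 0L) {
    warning(sprintf("rejected %d row(s):\n%s", length(diag),
                    paste(diag, collapse = "\n")))
  }
  if (!is.null(medium_filter)) {
    medium_filter <- match.arg(medium_filter, c("bulk", "throughfall"))
    out <- out[out$medium == medium_filter, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "diagnostics") <- diag
  out
}

#' Read a large-city registry
#'
#' Reads a CSV of city centers and keeps those whose nonagricultural
#' population strictly exceeds `min_population` -- the registry used for
#' nearest-city distances ("large city" means nonagricultural population
#' above half a million).
#'
#' @param path CSV with columns `name`, `latitude`, `longitude`,
#'   `nonag_population`.
#' @param min_population Inclusion threshold (persons); strict inequality.
#'   Default 500000.
#' @return Data frame of retained cities. An empty result raises a warning,
#'   not an error. Duplicate city names at distinct coordinates are kept,
#'   with a warning.
#' @export
read_cities <- function(path, min_population = 5e5) {
  raw <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  needed <- c("name", "latitude", "longitude", "nonag_population")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("city registry is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    name = trimws(raw$name),
    latitude = as_num_or_na(raw$latitude),
    longitude = as_num_or_na(raw$longitude),
    nonag_population = as_num_or_na(raw$nonag_population),
    stringsAsFactors = FALSE
  )
  bad <- is.na(out$latitude) | abs(out$latitude) > 90 |
    is.na(out$longitude) | abs(out$longitude) > 180 | is.na(out$nonag_population)
  if (any(bad)) {
    warning(sprintf("rejected %d malformed city row(s)", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[out$nonag_population > min_population, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no cities exceed the population threshold; distances will be undefined")
  }
  dup <- duplicated(out$name) | duplicated(out$name, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate city name(s) at distinct coordinates retained: ",
            paste(unique(out$name[dup]), collapse = ", "))
  }
  out
}

# ---- Region polygons ------------------------------------------------------

EARTH_RADIUS_KM <- 6371.0088

# A region is a list of polygons; each polygon is a list of rings
# (first = outer boundary, rest = holes); each ring a two-column matrix
# (longitude, latitude) in WGS84 decimal degrees, closed or open.
# Ring edges are interpreted as straight segments in the Lambert cylindrical
# equal-area plane (x = lon in radians, y = sin(lat)), which makes area,
# membership tests and equal-area sampling mutually exact on the sphere.

lambert_xy <- function(lonlat) {
  cbind(x = lonlat[, 1] * pi / 180, y = sin(lonlat[, 2] * pi / 180))
}

close_ring <- function(m) {
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ]) else m
}

ring_area_km2 <- function(ring) {
  p <- lambert_xy(close_ring(ring))
  n <- nrow(p)
  i <- seq_len(n - 1)
  abs(sum(p[i, 1] * p[i + 1, 2] - p[i + 1, 1] * p[i, 2]) / 2) * EARTH_RADIUS_KM^2
}

#' Construct a region polygon
#'
#' @param rings List of two-column (longitude, latitude) matrices; the first
#'   is the outer boundary, any others are holes. Alternatively use
#'   [region_from_rect()].
#' @return Object of class `acid_region`.
#' @export
region_polygon <- function(rings) {
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2, nrow(r) >= 3)
    if (any(abs(r[, 1]) > 180) || any(abs(r[, 2]) > 90)) {
      stop("region vertices must be WGS84 decimal degrees")
    }
    close_ring(r)
  })
  reg <- structure(list(polygons = list(rings)), class = "acid_region")
  if (region_area_km2(reg) <= 0) stop("region has non-positive area")
  reg
}

#' Rectangular region from longitude/latitude bounds
#'
#' @param lon,lat Numeric length-2 vectors of bounds in decimal degrees.
#' @return Object of class `acid_region`.
#' @export
region_from_rect <- function(lon, lat) {
  lon <- sort(lon); lat <- sort(lat)
  region_polygon(list(cbind(
    c(lon[1], lon[2], lon[2], lon[1], lon[1]),
    c(lat[1], lat[1], lat[2], lat[2], lat[1])
  )))
}

#' Area of a region polygon
#'
#' Spherical area computed by the shoelace formula in the Lambert cylindrical
#' equal-area plane (exact for the region's edge convention); holes subtract.
#'
#' @param region An `acid_region`.
#' @return Area in square kilometres.
#' @export
region_area_km2 <- function(region) {
  stopifnot(inherits(region, "acid_region"))
  sum(vapply(region$polygons, function(rings) {
    a <- vapply(rings, ring_area_km2, numeric(1))
    a[1] - sum(a[-1])
  }, numeric(1)))
}

# All rings stacked with NA separators, in Lambert coordinates, for
# crossing-parity point-in-polygon tests (handles holes and multi-parts).
region_bnd <- function(region) {
  parts <- list()
  for (rings in region$polygons) {
    for (r in rings) parts[[length(parts) + 1L]] <- lambert_xy(r)
  }
  sep <- matrix(NA_real_, 1, 2)
  do.call(rbind, Reduce(function(acc, p) c(acc, list(sep, p)),
                        parts[-1], list(parts[[1]])))
}

# Membership of (lon, lat) points in the region (crossing parity).
region_contains <- function(region, lon, lat) {
  mgcv::in.out(region_bnd(region), lambert_xy(cbind(lon, lat)))
}

region_bbox_lambert <- function(region) {
  bnd <- region_bnd(region)
  bnd <- bnd[stats::complete.cases(bnd), , drop = FALSE]
  list(x = range(bnd[, 1]), y = range(bnd[, 2]))
}

#' Read a region polygon from GeoJSON
#'
#' Accepts a GeoJSON `Polygon` or `MultiPolygon` geometry (bare geometry,
#' `Feature`, or single-feature `FeatureCollection`) in WGS84 coordinates.
#'
#' @param path Path to a GeoJSON file.
#' @return Object of class `acid_region`.
#' @export
read_region <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(g$type, "FeatureCollection")) {
    if (length(g$features) != 1L) stop("expected a single-feature FeatureCollection")
    g <- g$features[[1]]
  }
  if (identical(g$type, "Feature")) g <- g$geometry
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  polys <- switch(g$type,
    Polygon = list(lapply(g$coordinates, ring_mat)),
    MultiPolygon = lapply(g$coordinates, function(p) lapply(p, ring_mat)),
    stop("unsupported GeoJSON geometry type: ", g$type)
  )
  reg <- structure(list(polygons = lapply(polys, function(rings) {
    lapply(rings, close_ring)
  })), class = "acid_region")
  if (region_area_km2(reg) <= 0) stop("region has non-positive area")
  reg
}

#' Write a region polygon to GeoJSON
#'
#' @param region An `acid_region`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region <- function(region, path) {
  coords <- lapply(region$polygons, function(rings) {
    lapply(rings, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
  })
  g <- if (length(coords) == 1L) {
    list(type = "Polygon", coordinates = coords[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = coords)
  }
  jsonlite::write_json(g, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- Report bundle --------------------------------------------------------

#' Write a pipeline report
#'
#' Serializes a completed pipeline bundle (see [run_pipeline()]) as
#' `report.json` (fits, summaries, critical radius, island area, resolved
#' configuration; numeric fields at full double precision) plus a flat
#' `sites_derived.csv` with per-site fluxes and assigned distances. Sections
#' that were not computed are written as explicit nulls.
#'
#' @param bundle Pipeline result list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create report directory: ", dir)
  json <- bundle
  json$sites <- NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", dataframe = "columns")
  if (!is.null(bundle$sites)) {
    df <- bundle$sites
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) {
      ifelse(is.na(x), "", sprintf("%.17g", x))
    })
    utils::write.csv(df, file.path(dir, "sites_derived.csv"),
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Read back a pipeline report
#'
#' Inverse of [write_report()]: numeric fields round-trip at full precision.
#'
#' @param dir Directory written by [write_report()].
#' @return List with the report sections and, if present, the per-site table
#'   under `$sites`.
#' @export
read_report <- function(dir) {
  out <- jsonlite::fromJSON(file.path(dir, "report.json"),
                            simplifyDataFrame = TRUE)
  csv <- file.path(dir, "sites_derived.csv")
  if (file.exists(csv)) {
    df <- utils::read.csv(csv, colClasses = "character", fileEncoding = "UTF-8")
    for (col in setdiff(names(df), c("site_id", "medium", "obs_years",
                                     "nearest_city"))) {
      df[[col]] <- as_num_or_na(df[[col]])
    }
    out$sites <- df
  }
  out
}
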
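# Headline computations: the potential acid load curve around a city, the
# critical radius at which it crosses the critical load, the area covered by
# the union of all city discs within a region, and the bulk/throughfall and
# emission-equivalent budget arithmetic.
#
# Potential acid load (PAL) is the proton load realized after complete
# nitrification of deposited ammonium: PAL = H+ deposition + 2 x NH4+
# deposition (each NH4+ yields two protons, one of which replaces an acid
# proton neutralized in the atmosphere). With both fluxes following
# power-law distance decays, PAL(r) = a_H r^b_H + 2 a_N r^b_N.

#' Build a potential-acid-load curve from two flux fits
#'
#' @param fit_h Power-law fit (or list with `a`, `b`) of the hydrogen-ion
#'   deposition flux (keq/ha/yr) against distance; conventionally from
#'   throughfall, the closer proxy for total deposition.
#' @param fit_nh4 Power-law fit of the ammonium deposition flux.
#' @param critical_load Critical acid load in keq/ha/yr; default 2, the
#'   maximum critical load for acid-sensitive forest soils in the study
#'   region.
#' @return Object of class `acid_load_curve`.
#' @export
acid_load_curve <- function(fit_h, fit_nh4, critical_load = 2) {
  pick <- function(f) {
    stopifnot(is.numeric(f$a), is.numeric(f$b), f$a >= 0)
    list(a = f$a, b = f$b)
  }
  stopifnot(critical_load > 0)
  structure(list(h = pick(fit_h), nh4 = pick(fit_nh4),
                 critical_load = critical_load),
            class = "acid_load_curve")
}

#' Potential acid load at distance r
#'
#' PAL(r) = a_H r^b_H + 2 a_N r^b_N (keq/ha/yr); strictly decreasing in r
#' when both exponents are negative.
#'
#' @param r Distance(s) from the city center, km (at or above the
#'   [DISTANCE_FLOOR_KM]).
#' @param curve An [acid_load_curve()].
#' @return Potential acid load(s) in keq/ha/yr.
#' @export
potential_acid_load <- function(r, curve) {
  stopifnot(inherits(curve, "acid_load_curve"), all(r > 0))
  curve$h$a * r^curve$h$b + 2 * curve$nh4$a * r^curve$nh4$b
}

#' Critical radius of an urban acid island
#'
#' Solves PAL(r) = critical load by bisection on a fixed bracket. The curve
#' must be strictly decreasing over the bracket (each non-zero term needs a
#' negative exponent). If the load is not exceeded even at the inner edge of
#' the bracket there is no island: the radius is reported as 0 and flagged.
#'
#' @param curve An [acid_load_curve()].
#' @param bracket Search interval in km; default `c(1, 10000)`.
#' @param tol Convergence tolerance on the load, keq/ha/yr; default 1e-9.
#' @return List with `radius_km`, `no_island` (logical) and `pal_at_radius`.
#'   When one amplitude is zero the bisection agrees with the closed form
#'   `(a_eff / CL)^(-1/b)` (with `a_eff = 2a` for the ammonium term).
#' @export
critical_radius <- function(curve, bracket = c(1, 10000), tol = 1e-9) {
  stopifnot(inherits(curve, "acid_load_curve"), bracket[1] > 0,
            bracket[2] > bracket[1])
  for (term in list(curve$h, curve$nh4)) {
    if (term$a > 0 && term$b >= 0) {
      stop("potential acid load is not decreasing: non-negative exponent")
    }
  }
  if (curve$h$a == 0 && curve$nh4$a == 0) stop("both amplitudes are zero")
  cl <- curve$critical_load
  lo <- bracket[1]; hi <- bracket[2]
  f <- function(r) potential_acid_load(r, curve) - cl
  if (abs(f(lo)) <= tol) {
    return(list(radius_km = lo, no_island = FALSE,
                pal_at_radius = potential_acid_load(lo, curve)))
  }
  if (f(lo) < 0) {
    warning("critical load is not exceeded anywhere in the bracket: no acid island")
    return(list(radius_km = 0, no_island = TRUE,
                pal_at_radius = potential_acid_load(lo, curve)))
  }
  if (f(hi) >= 0) {
    stop("critical load still exceeded at the outer bracket edge; widen the bracket")
  }
  # bisection in log-r: PAL is a sum of exponentials in log r; the bracket
  # is contracted to relative machine precision, so the radius is resolved
  # far below 1e-6 km and the load residual far below `tol`
  llo <- log(lo); lhi <- log(hi)
  for (i in 1:100) {
    mid <- (llo + lhi) / 2
    fm <- f(exp(mid))
    if (abs(fm) < tol && (lhi - llo) < 1e-13) break
    if (fm > 0) llo <- mid else lhi <- mid
  }
  r <- exp(mid)
  list(radius_km = r, no_island = FALSE,
       pal_at_radius = potential_acid_load(r, curve))
}

# ---- Acid-island area -----------------------------------------------------

#' Area of the union of city discs within a region
#'
#' Estimates the area of the union of geodesic discs of a common radius
#' around every registry city, clipped to a region polygon, together with
#' the fraction of the region covered. Two estimators are provided and
#' should agree within Monte Carlo error:
#'
#' * `"mc"`: Monte Carlo -- points sampled uniformly over the region in the
#'   Lambert cylindrical equal-area plane (exactly equal-area on the
#'   sphere); a point counts when its haversine distance to any city is at
#'   most the radius. Requires `seed`; the standard error of the area is
#'   returned.
#' * `"projected_union"`: deterministic quadrature of the same indicator on
#'   a regular grid of equal-area cells in the projected plane (cells of
#'   `cell_km^2` each); the union of the projected buffers is measured by
#'   counting covered cells.
#'
#' @param cities City registry data frame (`name`, `latitude`, `longitude`).
#' @param radius_km Disc radius in km, > 0.
#' @param region An `acid_region`.
#' @param method `"mc"` or `"projected_union"`.
#' @param n_points Monte Carlo sample size (default 1e6; a warning is issued
#'   below 1e4).
#' @param seed RNG seed, required for `"mc"`.
#' @param cell_km Grid cell edge (km) for `"projected_union"`; default 2.
#' @return List with `union_area_km2`, `region_area_km2`, `fraction`,
#'   `method`, `n` (points or cells evaluated) and, for `"mc"`,
#'   `se_km2` (one Monte Carlo standard error of the union area).
#' @export
buffer_union_area <- function(cities, radius_km, region,
                              method = c("mc", "projected_union"),
                              n_points = 1e6, seed = NULL, cell_km = 2) {
  method <- match.arg(method)
  stopifnot(radius_km > 0, inherits(region, "acid_region"), nrow(cities) >= 1)
  reg_area <- region_area_km2(region)
  if (reg_area <= 0) stop("region has zero area")
  bb <- region_bbox_lambert(region)
  bnd <- region_bnd(region)

  covered <- function(lon, lat) {
    hit <- rep(FALSE, length(lon))
    for (i in seq_len(nrow(cities))) {
      todo <- which(!hit)
      if (length(todo) == 0L) break
      hit[todo] <- haversine_km(lat[todo], lon[todo],
                                cities$latitude[i], cities$longitude[i]) <= radius_km
    }
    hit
  }

  if (method == "mc") {
    if (is.null(seed)) stop("Monte Carlo area estimation requires a seed")
    if (n_points < 1e4) warning("fewer than 1e4 Monte Carlo points; the estimate will be noisy")
    set.seed(seed)
    got <- 0L; hits <- 0L
    bbox_area <- diff(bb$x) * diff(bb$y) * EARTH_RADIUS_KM^2
    batch <- ceiling(min(n_points, 5e5) / max(reg_area / bbox_area, 1e-3))
    while (got < n_points) {
      xs <- stats::runif(batch, bb$x[1], bb$x[2])
      ys <- stats::runif(batch, bb$y[1], bb$y[2])
      inside <- mgcv::in.out(bnd, cbind(xs, ys))
      xs <- xs[inside]; ys <- ys[inside]
      if (length(xs) == 0L) next
      take <- seq_len(min(length(xs), n_points - got))
      lon <- xs[take] * 180 / pi
      lat <- asin(ys[take]) * 180 / pi
      hits <- hits + sum(covered(lon, lat))
      got <- got + length(take)
    }
    p <- hits / n_points
    list(union_area_km2 = p * reg_area, region_area_km2 = reg_area,
         fraction = p, method = "mc", n = n_points,
         se_km2 = reg_area * sqrt(p * (1 - p) / n_points))
  } else {
    # equal-area cells: dx (lon radians) sized to cell_km at the bbox
    # mid-latitude, dy (sin lat) chosen so dx * dy * R^2 = cell_km^2 exactly
    mid_lat <- asin(mean(bb$y))
    dx <- cell_km / (EARTH_RADIUS_KM * cos(mid_lat))
    dy <- cell_km^2 / (EARTH_RADIUS_KM^2 * dx)
    xs <- seq(bb$x[1] + dx / 2, bb$x[2], by = dx)
    ys <- seq(bb$y[1] + dy / 2, bb$y[2], by = dy)
    hits <- 0; n_cells <- 0
    for (y in ys) {   # row-wise to bound memory
      pts <- cbind(xs, y)
      inside <- mgcv::in.out(bnd, pts)
      if (!any(inside)) next
      lon <- xs[inside] * 180 / pi
      lat <- rep(asin(y) * 180 / pi, sum(inside))
      n_cells <- n_cells + sum(inside)
      hits <- hits + sum(covered(lon, lat))
    }
    area <- hits * cell_km^2
    list(union_area_km2 = area, region_area_km2 = reg_area,
         fraction = area / reg_area, method = "projected_union",
         n = n_cells)
  }
}

#' Spherical-cap area of a single geodesic disc
#'
#' Exact area of one unclipped disc of radius `r` km on the sphere:
#' 2 pi R^2 (1 - cos(r / R)). Reference value for the area estimators.
#'
#' @param radius_km Disc radius in km.
#' @return Area in km^2.
#' @export
spherical_cap_area_km2 <- function(radius_km) {
  2 * pi * EARTH_RADIUS_KM^2 * (1 - cos(radius_km / EARTH_RADIUS_KM))
}

#' Export acid-island discs as GeoJSON
#'
#' Writes the geodesic disc around each city as a polygon ring (WGS84) in a
#' single MultiPolygon. Rings of overlapping islands are written as-is; the
#' island area itself comes from [buffer_union_area()], not from these
#' rings.
#'
#' @param cities City registry data frame.
#' @param radius_km Disc radius in km.
#' @param path Output GeoJSON path.
#' @param n_vertices Vertices per ring (default 180).
#' @return `path`, invisibly.
#' @export
islands_geojson <- function(cities, radius_km, path, n_vertices = 180) {
  bearings <- seq(0, 360, length.out = n_vertices + 1)
  polys <- lapply(seq_len(nrow(cities)), function(i) {
    ring <- geosphere::destPoint(
      cbind(cities$longitude[i], cities$latitude[i]),
      b = bearings, d = radius_km * 1000, a = EARTH_RADIUS_KM * 1000, f = 0)
    list(lapply(seq_len(nrow(ring)), function(j) c(ring[j, 1], ring[j, 2])))
  })
  g <- list(type = "Feature",
            properties = list(radius_km = radius_km),
            geometry = list(type = "MultiPolygon", coordinates = polys))
  jsonlite::write_json(g, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- Budget arithmetic ----------------------------------------------------

#' Throughfall/bulk enrichment ratios
#'
#' Ratio of the geometric-mean throughfall flux to the geometric-mean bulk
#' flux, per ion. Ratios above 1 reflect canopy-captured dry deposition
#' (net of canopy exchange); nitrogen compounds typically show weaker
#' enrichment than sulfate because of foliar uptake.
#'
#' @param bulk,throughfall Named numeric vectors of geometric-mean fluxes
#'   (keq/ha/yr), names from `so4`, `no3`, `nh4`; or summary tables from
#'   [summary_table()] (flux rows are extracted per medium).
#' @return Named numeric vector of ratios for the ions present in both
#'   media; ions missing from either side are `NA`.
#' @export
enrichment_ratios <- function(bulk, throughfall) {
  extract <- function(x, medium) {
    if (is.data.frame(x)) {
      sel <- x$kind == "flux" & x$quantity %in% c("so4", "no3", "nh4") &
        x$medium == medium
      stats::setNames(x$geometric_mean[sel], x$quantity[sel])
    } else x
  }
  b <- extract(bulk, "bulk"); t <- extract(throughfall, "throughfall")
  ions <- c("so4", "no3", "nh4")
  out <- stats::setNames(rep(NA_real_, length(ions)), ions)
  for (ion in ions) {
    if (!is.na(b[ion] %||% NA) && !is.na(t[ion] %||% NA) && b[[ion]] > 0) {
      out[ion] <- t[[ion]] / b[[ion]]
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Emission-equivalent acidity arithmetic
#'
#' Converts national precursor emissions into charge equivalents and forms
#' two summary quantities: the acidification-capacity ratio of sulfur to
#' oxidized nitrogen, and the fraction of that acidity that ammonia could
#' neutralize. Sulfur dioxide carries 2 eq per mol S (S = 32.06 g/mol);
#' oxidized and reduced nitrogen carry 1 eq per mol N (N = 14.007 g/mol).
#'
#' @param so2_tgs SO2 emission, Tg S per year (>= 0).
#' @param nox_tgn NOx emission, Tg N per year (> 0 for the ratio).
#' @param nh3_tgn NH3 emission, Tg N per year, or `NA` to skip the
#'   neutralization fraction.
#' @param m_s,m_n Molar masses of S and N (g/mol).
#' @return List with `eq_so2`, `eq_nox`, `eq_nh3` (Teq/yr), `acid_ratio`
#'   (eq SO2 / eq NOx) and `neutralization_fraction`
#'   (eq NH3 / (eq SO2 + eq NOx), possibly above 1).
#' @export
#' @examples
#' emission_acidity(14.4, 5.0, 12.7)
emission_acidity <- function(so2_tgs, nox_tgn, nh3_tgn = NA,
                             m_s = 32.06, m_n = 14.007) {
  stopifnot(so2_tgs >= 0, nox_tgn >= 0, is.na(nh3_tgn) || nh3_tgn >= 0)
  if (nox_tgn == 0) stop("NOx emission must be > 0 for the acidity ratio")
  eq_so2 <- 2 * so2_tgs / m_s
  eq_nox <- nox_tgn / m_n
  eq_nh3 <- if (is.na(nh3_tgn)) NA_real_ else nh3_tgn / m_n
  list(eq_so2 = eq_so2, eq_nox = eq_nox, eq_nh3 = eq_nh3,
       acid_ratio = eq_so2 / eq_nox,
       neutralization_fraction =
         if (is.na(nh3_tgn)) NA_real_ else eq_nh3 / (eq_so2 + eq_nox))
}
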
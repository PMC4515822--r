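# Seeded synthetic study generator. Emulates the statistical structure the
# analysis assumes: monitoring sites scattered around large cities, ion
# concentrations following y = a * x^b with multiplicative lognormal noise,
# pH following c + d ln(x) with additive gaussian noise, throughfall
# enriched over bulk by a deterministic per-ion multiplier (applied before
# noise, so the enrichment-ratio oracle is exact in expectation).

#' Synthetic study configuration
#'
#' Ground-truth parameters for the generator. The defaults emulate the
#' observed study conditions: 33 sites measured simultaneously in bulk
#' precipitation and throughfall, pH available at 28 sites and sulfate at 30
#' (so per-ion n is 28/30/33), bulk concentration decays whose geometric
#' means over log-uniform distances on [2, 300] km land near 101, 19 and 48
#' ueq/L for sulfate, nitrate and ammonium, bulk pH near 5.5 with a +0.3
#' throughfall offset, throughfall/bulk enrichment 1.82/1.56/1.34, annual
#' precipitation uniform on 1200-2200 mm, and lognormal noise with
#' sigma_log = 0.3.
#'
#' @param seed Integer seed; mandatory (no implicit randomness).
#' @param n_cities Number of large cities placed in the region.
#' @param n_sites Number of sites (each yields one bulk + one throughfall
#'   row).
#' @param region An `acid_region`; default a southern-China-sized rectangle
#'   (lon 104-122, lat 22-32).
#' @param distance_range_km Site-city distance law: log-uniform on this
#'   interval (km), giving the leverage across decades of x that power-law
#'   fitting needs.
#' @param conc_a,conc_b Named vectors (`so4`, `no3`, `nh4`): bulk
#'   concentration amplitude (ueq/L at 1 km) and exponent.
#' @param ph_c,ph_d Bulk pH curve intercept (pH at 1 km) and slope per
#'   ln(km).
#' @param ph_offset_throughfall Added to the throughfall pH intercept.
#' @param enrichment Named vector: throughfall/bulk concentration
#'   multiplier per ion.
#' @param sigma_log Lognormal noise SD for concentrations.
#' @param sigma_ph Gaussian noise SD for pH.
#' @param precip_range Annual precipitation interval (mm/yr), uniform.
#' @param n_ph,n_so4 Number of sites with pH / sulfate reported (missing
#'   sites drawn at random; nitrate and ammonium are always complete).
#' @param ph_clip pH values are clipped to this interval, guarding the
#'   pH-to-hydrogen-ion domain; clipping events are counted in the truth
#'   record.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_cities = 5,
                             n_sites = 33,
                             region = region_from_rect(c(104, 122), c(22, 32)),
                             distance_range_km = c(2, 300),
                             conc_a = c(so4 = 320, no3 = 42, nh4 = 125),
                             conc_b = c(so4 = -0.35, no3 = -0.25, nh4 = -0.30),
                             ph_c = 4.7, ph_d = 0.25,
                             ph_offset_throughfall = 0.3,
                             enrichment = c(so4 = 1.82, no3 = 1.56, nh4 = 1.34),
                             sigma_log = 0.3, sigma_ph = 0.3,
                             precip_range = c(1200, 2200),
                             n_ph = 28, n_so4 = 30,
                             ph_clip = c(3, 9)) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  stopifnot(all(conc_a > 0), sigma_log >= 0, sigma_ph >= 0,
            inherits(region, "acid_region"),
            distance_range_km[1] > 0,
            distance_range_km[2] > distance_range_km[1],
            n_ph <= n_sites, n_so4 <= n_sites,
            all(sort(names(conc_a)) == c("nh4", "no3", "so4")),
            all(sort(names(enrichment)) == c("nh4", "no3", "so4")))
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic study
#'
#' Places cities uniformly in the region, scatters sites at log-uniform
#' distances and uniform bearings from randomly chosen cities (re-drawing
#' positions that fall outside the region), and fills in chemistry from the
#' configured ground-truth curves evaluated at each site's distance to its
#' *nearest* city (another city may be closer than the one it was placed
#' around, exactly as in the real assignment). The site table leaves
#' `distance_km` empty so the proximity step is exercised downstream.
#'
#' @param config A [synthetic_config()].
#' @return List with `sites` (site table in the [read_sites()] schema),
#'   `cities`, `region`, and `truth`: the generating parameters plus the
#'   implied throughfall flux curves (at the mean precipitation), the true
#'   potential-acid-load curve, its critical radius at a load of 2
#'   keq/ha/yr, and the pH clipping count.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  set.seed(cf$seed)

  bb <- region_bbox_lambert(cf$region)
  draw_in_region <- function(n) {
    lon <- numeric(0); lat <- numeric(0)
    tries <- 0L
    while (length(lon) < n) {
      tries <- tries + 1L
      if (tries > 1000L) stop("region too small: cannot place points inside it")
      xs <- stats::runif(n, bb$x[1], bb$x[2])
      ys <- stats::runif(n, bb$y[1], bb$y[2])
      ok <- mgcv::in.out(region_bnd(cf$region), cbind(xs, ys))
      lon <- c(lon, xs[ok] * 180 / pi)
      lat <- c(lat, asin(ys[ok]) * 180 / pi)
    }
    cbind(lon = lon[seq_len(n)], lat = lat[seq_len(n)])
  }

  city_pos <- draw_in_region(cf$n_cities)
  cities <- data.frame(
    name = sprintf("City%02d", seq_len(cf$n_cities)),
    latitude = city_pos[, "lat"],
    longitude = city_pos[, "lon"],
    nonag_population = round(stats::runif(cf$n_cities, 6e5, 8e6))
  )

  # site placement: city + log-uniform distance + uniform bearing,
  # redrawn until the site lands inside the region
  lr <- log(cf$distance_range_km)
  site_lon <- numeric(cf$n_sites); site_lat <- numeric(cf$n_sites)
  for (i in seq_len(cf$n_sites)) {
    for (try in 1:1000) {
      ci <- sample.int(cf$n_cities, 1)
      d_km <- exp(stats::runif(1, lr[1], lr[2]))
      brg <- stats::runif(1, 0, 360)
      p <- geosphere::destPoint(
        cbind(cities$longitude[ci], cities$latitude[ci]),
        b = brg, d = d_km * 1000, a = EARTH_RADIUS_KM * 1000, f = 0)
      if (region_contains(cf$region, p[1], p[2])) break
      if (try == 1000) stop("region too small for the requested distance range")
    }
    site_lon[i] <- p[1]; site_lat[i] <- p[2]
  }

  # chemistry is driven by the distance to the *nearest* city
  x <- vapply(seq_len(cf$n_sites), function(i) {
    nearest_city(site_lat[i], site_lon[i], cities)$distance_km
  }, numeric(1))

  precip <- stats::runif(cf$n_sites, cf$precip_range[1], cf$precip_range[2])
  miss_ph <- sample.int(cf$n_sites, cf$n_sites - cf$n_ph)
  miss_so4 <- sample.int(cf$n_sites, cf$n_sites - cf$n_so4)

  clip_count <- 0L
  make_rows <- function(medium) {
    enr <- if (medium == "throughfall") cf$enrichment else
      c(so4 = 1, no3 = 1, nh4 = 1)
    conc <- sapply(c("so4", "no3", "nh4"), function(ion) {
      cf$conc_a[[ion]] * enr[[ion]] * x^cf$conc_b[[ion]] *
        exp(stats::rnorm(cf$n_sites, 0, cf$sigma_log))
    })
    c0 <- cf$ph_c + if (medium == "throughfall") cf$ph_offset_throughfall else 0
    ph <- c0 + cf$ph_d * log(x) + stats::rnorm(cf$n_sites, 0, cf$sigma_ph)
    clip_count <<- clip_count + sum(ph < cf$ph_clip[1] | ph > cf$ph_clip[2])
    ph <- pmin(pmax(ph, cf$ph_clip[1]), cf$ph_clip[2])
    ph[miss_ph] <- NA_real_
    conc[miss_so4, "so4"] <- NA_real_
    data.frame(
      site_id = sprintf("S%03d", seq_len(cf$n_sites)),
      latitude = site_lat, longitude = site_lon,
      precipitation_mm = precip, medium = medium,
      ph = ph,
      conc_so4_ueq_l = conc[, "so4"],
      conc_no3_ueq_l = conc[, "no3"],
      conc_nh4_ueq_l = conc[, "nh4"],
      obs_years = "synthetic",
      distance_km = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  sites <- rbind(make_rows("bulk"), make_rows("throughfall"))
  rownames(sites) <- NULL

  # implied throughfall flux curves at the mean precipitation (the
  # precipitation draw adds bounded multiplicative spread around these)
  p_mean <- mean(cf$precip_range)
  c_tf <- cf$ph_c + cf$ph_offset_throughfall
  truth_h <- list(a = 10^(6 - c_tf) * p_mean * 1e-5, b = -cf$ph_d * log(10))
  truth_nh4 <- list(a = cf$conc_a[["nh4"]] * cf$enrichment[["nh4"]] *
                      p_mean * 1e-5, b = cf$conc_b[["nh4"]])
  truth_curve <- acid_load_curve(truth_h, truth_nh4, critical_load = 2)
  truth_radius <- tryCatch(
    suppressWarnings(critical_radius(truth_curve)$radius_km),
    error = function(e) NA_real_)

  list(sites = sites, cities = cities, region = cf$region,
       truth = list(config = cf, flux_h_throughfall = truth_h,
                    flux_nh4_throughfall = truth_nh4,
                    pal_curve = truth_curve,
                    critical_radius_km = truth_radius,
                    ph_clipped = clip_count))
}

#' Write a generated study to disk
#'
#' Writes `sites.csv` and `cities.csv` (the [read_sites()]/[read_cities()]
#' dialects), `region.geojson`, and `truth.txt` (flat key = value sidecar of
#' the scalar ground-truth parameters).
#'
#' @param study Result of [generate_synthetic()].
#' @param dir Output directory.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_synthetic <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sites = file.path(dir, "sites.csv"),
             cities = file.path(dir, "cities.csv"),
             region = file.path(dir, "region.geojson"),
             truth = file.path(dir, "truth.txt"))
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) ifelse(is.na(x), "", sprintf("%.17g", x)))
    df
  }
  utils::write.csv(fmt(study$sites), paths["sites"], row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  utils::write.csv(fmt(study$cities), paths["cities"], row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  write_region(study$region, paths["region"])
  tr <- study$truth; cf <- tr$config
  kv <- c(
    seed = cf$seed, n_cities = cf$n_cities, n_sites = cf$n_sites,
    sigma_log = cf$sigma_log, sigma_ph = cf$sigma_ph,
    ph_c = cf$ph_c, ph_d = cf$ph_d,
    ph_offset_throughfall = cf$ph_offset_throughfall,
    conc_a_so4 = cf$conc_a[["so4"]], conc_b_so4 = cf$conc_b[["so4"]],
    conc_a_no3 = cf$conc_a[["no3"]], conc_b_no3 = cf$conc_b[["no3"]],
    conc_a_nh4 = cf$conc_a[["nh4"]], conc_b_nh4 = cf$conc_b[["nh4"]],
    enrichment_so4 = cf$enrichment[["so4"]],
    enrichment_no3 = cf$enrichment[["no3"]],
    enrichment_nh4 = cf$enrichment[["nh4"]],
    precip_min = cf$precip_range[1], precip_max = cf$precip_range[2],
    flux_h_a = tr$flux_h_throughfall$a, flux_h_b = tr$flux_h_throughfall$b,
    flux_nh4_a = tr$flux_nh4_throughfall$a,
    flux_nh4_b = tr$flux_nh4_throughfall$b,
    critical_radius_km = tr$critical_radius_km,
    ph_clipped = tr$ph_clipped
  )
  writeLines(sprintf("%s = %.17g", names(kv), as.numeric(kv)), paths["truth"])
  invisible(paths)
}

#' Read a ground-truth sidecar
#'
#' @param path Path to a `truth.txt` written by [write_synthetic()].
#' @return Named numeric vector.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                  vapply(parts, `[[`, character(1), 1))
}

#' Paths to the packaged synthetic fixture
#'
#' A small committed study (5 cities, 33 bulk + 33 throughfall rows,
#' rectangular region, truth sidecar) generated by [generate_synthetic()]
#' at seed 20150727 and shipped with the package for end-to-end tests and
#' examples.
#'
#' @return Named character vector with elements `sites`, `cities`,
#'   `region`, `truth`.
#' @export
packaged_fixture <- function() {
  dir <- system.file("extdata", "synthetic", package = "acidisland",
                     mustWork = TRUE)
  c(sites = file.path(dir, "sites.csv"),
    cities = file.path(dir, "cities.csv"),
    region = file.path(dir, "region.geojson"),
    truth = file.path(dir, "truth.txt"))
}
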
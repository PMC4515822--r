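# In-code fixture builders: small site tables and city registries written to
# temporary CSV files in the package's own dialect.

write_site_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

site_rows <- function(n = 3, medium = "bulk", ...) {
  base <- data.frame(
    site_id = sprintf("T%02d", seq_len(n)),
    latitude = seq(25, 26, length.out = n),
    longitude = seq(110, 111, length.out = n),
    precipitation_mm = rep(1500, n),
    medium = medium,
    ph = rep(5.5, n),
    conc_so4_ueq_l = rep(100, n),
    conc_no3_ueq_l = rep(20, n),
    conc_nh4_ueq_l = rep(50, n),
    obs_years = "2010",
    distance_km = NA_real_,
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

city_df <- function(name, lat, lon, pop = 1e6) {
  data.frame(name = name, latitude = lat, longitude = lon,
             nonag_population = pop, stringsAsFactors = FALSE)
}

# deterministic power-law sample: y = a * x^b * exp(eps)
power_law_sample <- function(n, a, b, sigma, seed,
                             x_range = c(2, 300)) {
  set.seed(seed)
  x <- exp(stats::runif(n, log(x_range[1]), log(x_range[2])))
  y <- a * x^b * exp(stats::rnorm(n, 0, sigma))
  list(x = x, y = y)
}
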
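test_that("generation is deterministic under a fixed seed and requires one", {
  expect_error(synthetic_config(), "seed")
  cfg <- synthetic_config(seed = 42)
  s1 <- generate_synthetic(cfg)
  s2 <- generate_synthetic(cfg)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$cities, s2$cities)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic(s1, d1); write_synthetic(s2, d2)
  expect_identical(readLines(file.path(d1, "sites.csv")),
                   readLines(file.path(d2, "sites.csv")))
  # different seed, different draw
  s3 <- generate_synthetic(synthetic_config(seed = 43))
  expect_false(identical(s1$sites$conc_so4_ueq_l, s3$sites$conc_so4_ueq_l))
})

test_that("generated tables honour the configured per-ion sample sizes", {
  st <- generate_synthetic(synthetic_config(seed = 7))
  for (m in c("bulk", "throughfall")) {
    sub <- st$sites[st$sites$medium == m, ]
    expect_equal(nrow(sub), 33)
    expect_equal(sum(!is.na(sub$ph)), 28)
    expect_equal(sum(!is.na(sub$conc_so4_ueq_l)), 30)
    expect_equal(sum(!is.na(sub$conc_no3_ueq_l)), 33)
    expect_equal(sum(!is.na(sub$conc_nh4_ueq_l)), 33)
  }
  # the same sites are missing pH in both media (simultaneous sampling)
  miss_b <- st$sites$site_id[st$sites$medium == "bulk" & is.na(st$sites$ph)]
  miss_t <- st$sites$site_id[st$sites$medium == "throughfall" & is.na(st$sites$ph)]
  expect_setequal(miss_b, miss_t)
  expect_true(all(is.na(st$sites$distance_km)))
  expect_true(all(st$sites$precipitation_mm >= 1200 &
                    st$sites$precipitation_mm <= 2200))
})

test_that("noise-free generation lets the fits recover the truth exactly", {
  # fixed precipitation too: flux = conc x precip, so random rain volumes
  # would re-introduce spread in the flux cells
  cfg <- synthetic_config(seed = 99, sigma_log = 0, sigma_ph = 0,
                          n_ph = 33, n_so4 = 33,
                          precip_range = c(1700, 1700))
  st <- generate_synthetic(cfg)
  sites <- assign_distances(st$sites, st$cities)
  res <- suppressWarnings(fit_all(sites))   # exact fits trip lm's perfect-fit warning
  expect_true(all(res$table$available))
  expect_equal(res$table$r_squared, rep(1, 18), tolerance = 1e-9)
  row <- res$table[res$table$medium == "bulk" & res$table$quantity == "so4" &
                     res$table$kind == "concentration", ]
  expect_equal(row$a, 320, tolerance = 1e-8)
  expect_equal(row$b, -0.35, tolerance = 1e-8)
})

test_that("estimates converge to the truth as the noise shrinks", {
  err <- vapply(c(0.3, 0.1, 0.01), function(sg) {
    cfg <- synthetic_config(seed = 555, sigma_log = sg, sigma_ph = sg,
                            n_sites = 60, n_ph = 60, n_so4 = 60)
    st <- generate_synthetic(cfg)
    sites <- assign_distances(st$sites, st$cities)
    fit <- suppressWarnings(fit_all(sites))$table
    row <- fit[fit$medium == "bulk" & fit$quantity == "nh4" &
                 fit$kind == "concentration", ]
    abs(row$b - (-0.30)) + abs(log(row$a / 125))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("the packaged fixture loads cleanly and drives the whole pipeline", {
  fx <- packaged_fixture()
  sites <- read_sites(fx["sites"])
  expect_length(attr(sites, "diagnostics"), 0)
  expect_equal(nrow(sites), 66)
  cities <- read_cities(fx["cities"])
  expect_equal(nrow(cities), 5)
  region <- read_region(fx["region"])
  expect_gt(region_area_km2(region), 0)
  truth <- read_truth(fx["truth"])
  expect_equal(unname(truth["n_sites"]), 33)
  res <- fit_all(assign_distances(sites, cities))
  expect_equal(sum(res$table$available), 18)
  cfg <- pipeline_config(fx["sites"], fx["cities"], fx["region"],
                         area_method = "projected_union", cell_km = 5)
  bundle <- suppressMessages(run_pipeline(cfg))
  expect_true(is.finite(bundle$critical_radius_km))
  expect_gt(bundle$critical_radius_km, 0)
})

test_that("the estimated critical radius tracks the generating acid-load curve", {
  # ground truth stated in flux units; precipitation held fixed so the
  # throughfall fluxes follow the target power laws exactly (up to noise)
  p_fix <- 1600
  truth_h <- list(a = 40, b = -0.8)
  truth_n <- list(a = 30, b = -0.6)
  cfg_for <- function(seed) synthetic_config(
    seed = seed, n_sites = 33, n_ph = 33, n_so4 = 33,
    precip_range = c(p_fix, p_fix),
    enrichment = c(so4 = 1, no3 = 1, nh4 = 1),
    ph_offset_throughfall = 0,
    # pH curve equivalent to H+ flux = 40 r^-0.8 at fixed precipitation
    ph_c = 6 - log10(truth_h$a * 1e5 / p_fix),
    ph_d = -truth_h$b / log(10),
    conc_a = c(so4 = 320, no3 = 42, nh4 = truth_n$a * 1e5 / p_fix),
    conc_b = c(so4 = -0.35, no3 = -0.25, nh4 = truth_n$b),
    sigma_log = 0.3, sigma_ph = 0.3 / log(10),
    ph_clip = c(0.5, 13.5))
  true_curve <- acid_load_curve(truth_h, truth_n, critical_load = 2)
  true_radius <- critical_radius(true_curve)$radius_km

  radius_from <- function(sites, idx) {
    tryCatch({
      sub <- sites[sites$medium == "throughfall", ][idx, ]
      fh <- fit_power_law(sub$distance_km,
                          ph_to_h(sub$ph) * sub$precipitation_mm * 1e-5)
      fn <- fit_power_law(sub$distance_km,
                          sub$conc_nh4_ueq_l * sub$precipitation_mm * 1e-5)
      suppressWarnings(
        critical_radius(acid_load_curve(fh, fn, critical_load = 2))$radius_km)
    }, error = function(e) NA_real_)
  }

  n_rep <- 200; n_boot <- 99
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    st <- generate_synthetic(cfg_for(1000 + r))
    sites <- assign_distances(st$sites, st$cities)
    boot <- vapply(seq_len(n_boot), function(b) {
      radius_from(sites, sample.int(33, 33, replace = TRUE))
    }, numeric(1))
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    covered[r] <- ci[1] <= true_radius && true_radius <= ci[2]
  }
  expect_gte(mean(covered), 0.90)
})
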
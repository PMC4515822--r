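test_that("the potential acid load is H+ flux plus twice the ammonium flux", {
  curve <- acid_load_curve(list(a = 1, b = -1), list(a = 0.5, b = -1))
  expect_equal(potential_acid_load(1, curve), 2)
  expect_equal(potential_acid_load(4, curve), 0.5)
  # ammonium term absent: reduces to the hydrogen-ion term
  h_only <- acid_load_curve(list(a = 3, b = -0.7), list(a = 0, b = -1))
  r <- c(1.5, 10, 88)
  expect_equal(potential_acid_load(r, h_only), 3 * r^-0.7)
  # identity against independently evaluated power laws
  set.seed(8)
  for (i in 1:20) {
    ah <- runif(1, 0.1, 5); bh <- runif(1, -1.2, -0.1)
    an <- runif(1, 0.1, 5); bn <- runif(1, -1.2, -0.1)
    cv <- acid_load_curve(list(a = ah, b = bh), list(a = an, b = bn))
    rr <- exp(runif(5, 0, log(500)))
    expect_equal(potential_acid_load(rr, cv),
                 ah * rr^bh + 2 * an * rr^bn, tolerance = 1e-12)
  }
})

test_that("the potential acid load is monotone decreasing for negative exponents", {
  set.seed(17)
  grid <- exp(seq(log(1), log(5000), length.out = 400))
  for (i in 1:20) {
    cv <- acid_load_curve(list(a = runif(1, 0.01, 10), b = runif(1, -1.5, -0.05)),
                          list(a = runif(1, 0.01, 10), b = runif(1, -1.5, -0.05)))
    expect_true(all(diff(potential_acid_load(grid, cv)) < 0))
  }
})

test_that("bisection critical radius matches algebra and closed forms", {
  # PAL(r) = 2/r crosses CL = 2 at exactly 1 km
  cv <- acid_load_curve(list(a = 1, b = -1), list(a = 0.5, b = -1),
                        critical_load = 2)
  expect_equal(critical_radius(cv)$radius_km, 1, tolerance = 1e-6)
  # single ammonium term: r* = (2a/CL)^(-1/b), with the factor 2 on NH4+
  cv2 <- acid_load_curve(list(a = 0, b = -1), list(a = 4, b = -0.5),
                         critical_load = 2)
  expect_equal(critical_radius(cv2)$radius_km, 16, tolerance = 1e-6)
  # single hydrogen term closed form on random curves (amplitude anchored so
  # the crossing lies inside the [1, 10000] km solver bracket)
  set.seed(23)
  for (i in 1:20) {
    b <- runif(1, -1.4, -0.2); cl <- runif(1, 0.5, 2)
    r_star <- exp(runif(1, log(2), log(4000)))
    a <- cl * r_star^-b
    cv3 <- acid_load_curve(list(a = a, b = b), list(a = 0, b = -1),
                           critical_load = cl)
    expect_equal(critical_radius(cv3)$radius_km, (a / cl)^(-1 / b),
                 tolerance = 1e-6)
    expect_equal(critical_radius(cv3)$radius_km, r_star, tolerance = 1e-6)
  }
})

test_that("critical radius error and degenerate cases behave as specified", {
  # load never exceeded: no island, radius 0, flagged
  low <- acid_load_curve(list(a = 0.1, b = -0.5), list(a = 0.1, b = -0.5),
                         critical_load = 5)
  expect_warning(res <- critical_radius(low), "no acid island")
  expect_equal(res$radius_km, 0)
  expect_true(res$no_island)
  # load exceeded everywhere in the bracket: bracket error
  high <- acid_load_curve(list(a = 1000, b = -0.01), list(a = 0, b = -1),
                          critical_load = 0.5)
  expect_error(critical_radius(high), "bracket")
  # non-decreasing curve rejected
  up <- acid_load_curve(list(a = 1, b = 0.2), list(a = 1, b = -0.5))
  expect_error(critical_radius(up), "not decreasing")
})

test_that("raising the critical load never enlarges the island", {
  set.seed(31)
  for (i in 1:15) {
    # anchor the curve so PAL = 2 is crossed at a radius inside the bracket
    bh <- runif(1, -1, -0.3); bn <- runif(1, -1, -0.3)
    r2 <- exp(runif(1, log(2), log(300)))
    u <- runif(1, 0.2, 1.8)
    ah <- u * r2^-bh; an <- (2 - u) / 2 * r2^-bn
    r_at <- function(cl) critical_radius(acid_load_curve(
      list(a = ah, b = bh), list(a = an, b = bn), critical_load = cl))$radius_km
    expect_equal(r_at(2), r2, tolerance = 1e-6)
    expect_lte(r_at(2), r_at(1) + 1e-9)
  }
})

test_that("an isolated island matches the spherical-cap area within 0.1 percent", {
  reg <- region_from_rect(c(110, 113), c(27, 30))
  city <- city_df("Solo", 28.5, 111.5)
  cap <- spherical_cap_area_km2(67)
  got <- buffer_union_area(city, 67, reg, method = "projected_union",
                           cell_km = 0.67)
  expect_lt(abs(got$union_area_km2 - cap) / cap, 0.001)
  # the flat-disc approximation is itself within 0.1% at this radius
  expect_lt(abs(cap - pi * 67^2) / cap, 0.001)
})

test_that("union area is idempotent for coincident cities and additive for disjoint ones", {
  reg <- region_from_rect(c(104, 116), c(22, 30))
  one <- city_df("A", 26, 107)
  two_same <- city_df(c("A", "A2"), c(26, 26), c(107, 107))
  # disjoint twin placed an integer number of grid columns east so the
  # quadrature sees an identical relative geometry
  a1 <- buffer_union_area(one, 60, reg, method = "projected_union", cell_km = 2)
  a2 <- buffer_union_area(two_same, 60, reg, method = "projected_union", cell_km = 2)
  expect_equal(a2$union_area_km2, a1$union_area_km2)
  far <- city_df(c("A", "B"), c(26, 26), c(107, 113))
  a3 <- buffer_union_area(far, 60, reg, method = "projected_union", cell_km = 2)
  expect_equal(a3$union_area_km2, 2 * a1$union_area_km2, tolerance = 0.005)
  # union monotone in radius
  a4 <- buffer_union_area(far, 80, reg, method = "projected_union", cell_km = 2)
  expect_gt(a4$union_area_km2, a3$union_area_km2)
})

test_that("Monte Carlo and grid-quadrature areas agree within Monte Carlo error", {
  set.seed(47)
  for (i in 1:3) {
    n_city <- sample(1:10, 1)
    reg <- region_from_rect(c(105, 112), c(24, 29))
    cities <- city_df(sprintf("C%d", seq_len(n_city)),
                      runif(n_city, 24.5, 28.5), runif(n_city, 105.5, 111.5))
    radius <- runif(1, 40, 90)
    mc <- buffer_union_area(cities, radius, reg, method = "mc",
                            n_points = 2e5, seed = 100 + i)
    gr <- buffer_union_area(cities, radius, reg, method = "projected_union",
                            cell_km = 2)
    expect_lt(abs(mc$union_area_km2 - gr$union_area_km2), 3 * mc$se_km2)
    expect_equal(mc$fraction, mc$union_area_km2 / mc$region_area_km2)
    expect_lte(gr$union_area_km2, gr$region_area_km2)
  }
  # determinism and the seed requirement
  reg <- region_from_rect(c(105, 112), c(24, 29))
  cities <- city_df("C1", 26, 108)
  m1 <- buffer_union_area(cities, 70, reg, method = "mc", n_points = 5e4, seed = 9)
  m2 <- buffer_union_area(cities, 70, reg, method = "mc", n_points = 5e4, seed = 9)
  expect_identical(m1$union_area_km2, m2$union_area_km2)
  expect_error(buffer_union_area(cities, 70, reg, method = "mc", seed = NULL),
               "seed")
  expect_warning(buffer_union_area(cities, 70, reg, method = "mc",
                                   n_points = 5e3, seed = 1), "1e4")
})

test_that("enrichment ratios reproduce the throughfall/bulk flux contrasts", {
  bulk <- c(so4 = 1.55, no3 = 0.30, nh4 = 0.73)
  tf <- c(so4 = 2.83, no3 = 0.47, nh4 = 0.98)
  r <- enrichment_ratios(bulk, tf)
  expect_equal(unname(r["so4"]), 2.83 / 1.55)
  expect_equal(unname(r["nh4"]), 0.98 / 0.73)
  expect_equal(unname(enrichment_ratios(bulk, bulk)), rep(1, 3))
  # invariant to a common rescaling of both media
  expect_equal(enrichment_ratios(bulk * 3.1, tf * 3.1), r)
  # missing ion yields NA, others unaffected
  r2 <- enrichment_ratios(bulk[c("so4", "nh4")], tf)
  expect_true(is.na(r2["no3"]))
  expect_equal(r2["so4"], r["so4"])
})

test_that("emission-equivalent arithmetic converts Tg to charge equivalents", {
  res <- emission_acidity(14.4, 5.0, 12.7)
  expect_equal(res$eq_so2, 2 * 14.4 / 32.06)
  expect_equal(res$eq_nox, 5.0 / 14.007)
  expect_equal(res$acid_ratio, 2.516541484716157, tolerance = 1e-12)
  expect_equal(res$neutralization_fraction, 0.7223005930797428, tolerance = 1e-12)
  # constructed equality: NOx dosed to exactly match the sulfur equivalents
  x <- 3.3
  expect_equal(emission_acidity(x, x * 2 * 14.007 / 32.06)$acid_ratio, 1)
  expect_error(emission_acidity(1, 0), "> 0")
  expect_true(is.na(emission_acidity(1, 1)$neutralization_fraction))
})
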
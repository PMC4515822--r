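# Distance-decay regressions. Two empirical forms describe how precipitation
# chemistry changes with distance x (km) to the nearest large city:
#   power law    y  = a * x^b        (ion concentrations and fluxes; b < 0
#                                     means an increase toward the city)
#   logarithmic  pH = c + d * ln(x)  (d > 0 means pH falls toward the city)
# The primary estimator is OLS on (ln x, ln y): deposition data are positive
# and right-skewed, so errors are treated as multiplicative lognormal. An
# optional nonlinear least-squares refinement on the original scale is
# provided; each fit reports R^2 on its own fitting scale.

#' Fit a power-law distance-decay curve y = a * x^b
#'
#' @param x Distances in km, strictly positive.
#' @param y Response (concentration in ueq/L or flux in keq/ha/yr); values
#'   that are not strictly positive are rejected with a message before
#'   fitting (the log transform requires y > 0).
#' @param method `"loglog_ols"` (default): OLS of ln y on ln x, `a =
#'   exp(intercept)`, `b = slope`, with R^2 and the two-sided t-test of
#'   slope = 0 on the log-log scale. `"nls"`: nonlinear least squares on the
#'   original scale initialized from the log-log fit; R^2 is then
#'   1 - SSres/SStot on the original scale, while the p-value is still the
#'   log-log slope test.
#' @return Object of class `power_law_fit`: list with `a`, `b`, `n`,
#'   `r_squared`, `p_value`, `sigma_log` (residual SD on the log scale),
#'   `se_log_a`, `se_b` (log-log standard errors), `method`.
#' @export
fit_power_law <- function(x, y, method = c("loglog_ols", "nls")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (any(x <= 0)) stop("all distances must be > 0")
  pos <- y > 0
  if (any(!pos)) {
    message(sprintf("[fit] rejected %d non-positive response value(s)", sum(!pos)))
  }
  x <- x[pos]; y <- y[pos]
  n <- length(x)
  if (n < 3) stop("power-law fit needs at least 3 positive observations")
  if (stats::sd(log(x)) == 0) stop("degenerate design: no variation in log(x)")

  fit <- stats::lm(log(y) ~ log(x))
  sm <- summary(fit)
  cf <- sm$coefficients
  out <- list(
    a = exp(unname(cf[1, 1])),
    b = unname(cf[2, 1]),
    n = n,
    r_squared = sm$r.squared,
    p_value = unname(cf[2, 4]),
    sigma_log = sm$sigma,
    se_log_a = unname(cf[1, 2]),
    se_b = unname(cf[2, 2]),
    method = method
  )
  if (method == "nls") {
    nf <- stats::nls(y ~ a * x^b, start = list(a = out$a, b = out$b),
                     control = stats::nls.control(warnOnly = TRUE))
    cn <- stats::coef(nf)
    out$a <- unname(cn["a"]); out$b <- unname(cn["b"])
    out$r_squared <- 1 - sum(stats::resid(nf)^2) / sum((y - mean(y))^2)
  }
  if (out$a <= 0) stop("fitted amplitude is not positive")
  structure(out, class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit (%s): y = %.4g * x^%.4g  [n = %d, R2 = %.3f, p = %.3g]\n",
              x$method, x$a, x$b, x$n, x$r_squared, x$p_value))
  invisible(x)
}

#' Fit a logarithmic pH-distance curve pH = c + d * ln(x)
#'
#' OLS of pH on ln(distance). A positive `d` is the acid-island pattern:
#' pH declines toward the city.
#'
#' @param x Distances in km, strictly positive.
#' @param ph pH values.
#' @return Object of class `log_fit`: list with `c`, `d`, `n`, `r_squared`,
#'   `p_value` (two-sided t-test of d = 0), `se_c`, `se_d`.
#' @export
fit_log_curve <- function(x, ph) {
  stopifnot(length(x) == length(ph))
  ok <- is.finite(x) & is.finite(ph)
  x <- x[ok]; ph <- ph[ok]
  if (any(x <= 0)) stop("all distances must be > 0")
  n <- length(x)
  if (n < 3) stop("logarithmic fit needs at least 3 observations")
  if (stats::sd(log(x)) == 0) stop("degenerate design: no variation in log(x)")
  fit <- stats::lm(ph ~ log(x))
  sm <- summary(fit)
  cf <- sm$coefficients
  structure(list(
    c = unname(cf[1, 1]),
    d = unname(cf[2, 1]),
    n = n,
    r_squared = sm$r.squared,
    p_value = unname(cf[2, 4]),
    se_c = unname(cf[1, 2]),
    se_d = unname(cf[2, 2])
  ), class = "log_fit")
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf("log fit: pH = %.4g + %.4g ln(x)  [n = %d, R2 = %.3f, p = %.3g]\n",
              x$c, x$d, x$n, x$r_squared, x$p_value))
  invisible(x)
}

#' Fit the full distance-decay table
#'
#' One logarithmic pH fit per medium plus one power-law fit per
#' medium x ion (hydrogen ion, sulfate, nitrate, ammonium) x kind
#' (concentration, flux) -- 18 curves when every cell has data. Each site
#' contributes to a cell only where its value is non-missing, so per-ion n
#' may differ. Cells with fewer than 3 usable observations are recorded as
#' unavailable rather than aborting the table.
#'
#' @param sites Site table with assigned `distance_km` (see
#'   [assign_distances()]).
#' @param method Power-law fitting method, passed to [fit_power_law()].
#' @param alpha Significance level for flagging fits (default 0.05).
#' @return List with `table` (data frame: `medium`, `quantity`, `kind`, `n`,
#'   `a`, `b`, `r_squared`, `p_value`, `significant`, `available`, `note`;
#'   for pH rows `a`/`b` hold `c`/`d`) and `fits` (named list of fit
#'   objects, names `medium.quantity.kind`).
#' @export
fit_all <- function(sites, method = "loglog_ols", alpha = 0.05) {
  if (is.null(sites$distance_km) || all(is.na(sites$distance_km))) {
    stop("sites must carry assigned distances; run assign_distances() first")
  }
  cells <- rbind(
    data.frame(quantity = "ph", kind = "ph"),
    expand.grid(quantity = c("h", "so4", "no3", "nh4"),
                kind = c("concentration", "flux"),
                stringsAsFactors = FALSE)
  )
  fits <- list()
  rows <- list()
  for (m in c("bulk", "throughfall")) {
    sub <- sites[sites$medium == m, , drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      q <- cells$quantity[i]; k <- cells$kind[i]
      key <- paste(m, q, k, sep = ".")
      val <- if (q == "ph") sub$ph else site_quantity(sub, q, k)
      use <- !is.na(val) & !is.na(sub$distance_km)
      f <- tryCatch({
        if (q == "ph") fit_log_curve(sub$distance_km[use], val[use])
        else fit_power_law(sub$distance_km[use], val[use], method = method)
      }, error = function(e) e)
      if (inherits(f, "error")) {
        rows[[key]] <- data.frame(
          medium = m, quantity = q, kind = k, n = sum(use),
          a = NA_real_, b = NA_real_, r_squared = NA_real_,
          p_value = NA_real_, significant = NA, available = FALSE,
          note = conditionMessage(f))
      } else {
        fits[[key]] <- f
        isph <- inherits(f, "log_fit")
        rows[[key]] <- data.frame(
          medium = m, quantity = q, kind = k, n = f$n,
          a = if (isph) f$c else f$a, b = if (isph) f$d else f$b,
          r_squared = f$r_squared, p_value = f$p_value,
          significant = f$p_value < alpha, available = TRUE, note = "")
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, fits = fits)
}
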
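#' Convert pH to hydrogen-ion concentration
#'
#' The hydrogen-ion activity implied by a pH value, expressed in
#' micro-equivalents per litre: \eqn{[H^+] = 10^{6 - pH}} ueq/L.
#'
#' @param ph Numeric vector of pH values, each in (0, 14).
#' @return Hydrogen-ion concentration(s) in ueq/L; strictly positive and
#'   strictly decreasing in `ph`.
#' @seealso [h_to_ph()] for the inverse.
#' @export
#' @examples
#' ph_to_h(6)   # 1 ueq/L
#' ph_to_h(4)   # 100 ueq/L
ph_to_h <- function(ph) {
  stopifnot(is.numeric(ph))
  if (any(!is.finite(ph) | ph <= 0 | ph >= 14)) {
    stop("ph must lie in the open interval (0, 14)")
  }
  10^(6 - ph)
}

#' Convert hydrogen-ion concentration to pH
#'
#' @param h Hydrogen-ion concentration(s) in ueq/L, strictly positive.
#' @return pH value(s); exact inverse of [ph_to_h()] to floating-point
#'   precision.
#' @export
h_to_ph <- function(h) {
  stopifnot(is.numeric(h))
  if (any(!is.finite(h) | h <= 0)) stop("h must be strictly positive")
  6 - log10(h)
}

#' Volume-weighted mean concentration
#'
#' Event concentrations averaged with weights proportional to the collected
#' water volume: VWM = sum(v_i c_i) / sum(v_i). The result is invariant under
#' rescaling all volumes by a common factor and is bounded by the
#' concentration extremes.
#'
#' @param volume Water volumes (L, or any common unit such as mm of
#'   precipitation), strictly positive.
#' @param conc Concentrations (ueq/L), non-negative, same length as `volume`.
#' @return The volume-weighted mean concentration in the units of `conc`.
#' @export
#' @examples
#' volume_weighted_mean(c(1, 1), c(10, 30))  # 20
#' volume_weighted_mean(c(3, 1), c(10, 30))  # 15
volume_weighted_mean <- function(volume, conc) {
  if (length(volume) == 0L) stop("empty sample list")
  if (length(volume) != length(conc)) stop("volume and conc lengths differ")
  if (any(!is.finite(volume) | volume <= 0)) stop("volumes must be > 0")
  if (any(!is.finite(conc) | conc < 0)) stop("concentrations must be >= 0")
  sum(volume * conc) / sum(volume)
}

#' Volume-weighted mean pH
#'
#' Within-site aggregation of event pH. The default mode (`"h_space"`)
#' converts each pH to hydrogen-ion concentration, volume-weights in that
#' space, and converts back -- the chemically meaningful average of an
#' intensity defined on a log scale. The alternative (`"ph_space"`) weights
#' the pH values directly, as some monitoring programmes report. The mode
#' used is recorded in the result's `"mode"` attribute.
#'
#' @param volume Water volumes, strictly positive.
#' @param ph pH values, each in (0, 14).
#' @param mode `"h_space"` (default) or `"ph_space"`.
#' @return Volume-weighted pH (length 1) with attribute `mode`.
#' @export
volume_weighted_ph <- function(volume, ph, mode = c("h_space", "ph_space")) {
  mode <- match.arg(mode)
  out <- if (mode == "h_space") {
    h_to_ph(volume_weighted_mean(volume, ph_to_h(ph)))
  } else {
    if (any(!is.finite(ph) | ph <= 0 | ph >= 14)) stop("ph must lie in (0, 14)")
    volume_weighted_mean(volume, ph)
  }
  structure(out, mode = mode)
}

#' Convert a concentration to an annual deposition flux
#'
#' Deposition flux is the product of the volume-weighted mean concentration
#' and the annual precipitation: F = C x P x 1e-5, which maps ueq/L times
#' mm/yr onto keq/ha/yr (1 mm of water over 1 ha is 1e4 L; 1 keq is 1e9 ueq).
#'
#' @param conc Concentration in ueq/L, non-negative.
#' @param precip_mm Annual precipitation in mm/yr, strictly positive.
#' @return Flux in keq/ha/yr; linear in both arguments.
#' @export
#' @examples
#' conc_to_flux(100, 1000)  # 1 keq/ha/yr
conc_to_flux <- function(conc, precip_mm) {
  if (any(!is.finite(precip_mm) | precip_mm <= 0)) stop("precipitation must be > 0")
  if (any(!is.finite(conc) | conc < 0)) stop("concentration must be >= 0")
  conc * precip_mm * 1e-5
}

#' Geometric mean of positive values
#'
#' exp(mean(log(x))) over the strictly positive, non-missing entries.
#' Zero or negative values are excluded with a warning (no pseudo-count is
#' added) and `n` is reduced accordingly.
#'
#' @param x Numeric vector.
#' @return List with `geometric_mean` and `n` (values actually used).
#' @export
geometric_mean <- function(x) {
  x <- x[!is.na(x)]
  bad <- x <= 0
  if (any(bad)) {
    warning(sprintf("excluded %d non-positive value(s) from geometric mean", sum(bad)))
    x <- x[!bad]
  }
  if (length(x) == 0L) stop("no positive values to summarize")
  list(geometric_mean = exp(mean(log(x))), n = length(x))
}

# Internal: per-site value of one quantity/kind for summary and fitting.
# For quantity "ph" the pH itself is used (site-level pH values are summarized
# and regressed as reported, not re-transformed); for "h" the hydrogen-ion
# concentration derived from pH; ions use their concentration columns.
site_quantity <- function(sites, quantity = c("ph", "h", "so4", "no3", "nh4"),
                          kind = c("concentration", "flux")) {
  quantity <- match.arg(quantity)
  kind <- match.arg(kind)
  val <- switch(quantity,
    ph  = sites$ph,
    h   = ifelse(is.na(sites$ph), NA_real_, 10^(6 - sites$ph)),
    so4 = sites$conc_so4_ueq_l,
    no3 = sites$conc_no3_ueq_l,
    nh4 = sites$conc_nh4_ueq_l
  )
  if (kind == "flux") {
    if (quantity == "ph") stop("pH has no flux; use quantity = 'h'")
    val <- ifelse(is.na(val), NA_real_, val * sites$precipitation_mm * 1e-5)
  }
  val
}

#' Geometric-mean summary for one medium/quantity/kind cell
#'
#' Summarizes one quantity over the sites of one medium. Per-ion sample
#' sizes may differ because each site contributes only where its value is
#' non-missing. pH is summarized on the pH scale directly; fluxes are
#' computed per site (concentration x precipitation) before summarizing.
#'
#' @param sites Validated site table (see [read_sites()]).
#' @param quantity One of `"ph"`, `"h"`, `"so4"`, `"no3"`, `"nh4"`.
#' @param kind `"concentration"` or `"flux"`.
#' @param medium `"bulk"` or `"throughfall"`.
#' @return List with `geometric_mean`, `n`, `quantity`, `kind`, `medium`.
#' @export
chem_summary <- function(sites, quantity, kind = "concentration",
                         medium = c("bulk", "throughfall")) {
  medium <- match.arg(medium)
  sub <- sites[sites$medium == medium, , drop = FALSE]
  gm <- geometric_mean(site_quantity(sub, quantity, kind))
  c(gm, list(quantity = quantity, kind = kind, medium = medium))
}

#' Geometric-mean summary table over all media and quantities
#'
#' One row per (medium, quantity, kind): pH plus concentration and flux of
#' hydrogen ion, sulfate, nitrate and ammonium, for bulk and throughfall.
#'
#' @param sites Validated site table.
#' @return Data frame with columns `medium`, `quantity`, `kind`,
#'   `geometric_mean`, `n`.
#' @export
summary_table <- function(sites) {
  cells <- rbind(
    data.frame(quantity = "ph", kind = "concentration"),
    expand.grid(quantity = c("h", "so4", "no3", "nh4"),
                kind = c("concentration", "flux"),
                stringsAsFactors = FALSE)
  )
  out <- do.call(rbind, lapply(c("bulk", "throughfall"), function(m) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      s <- tryCatch(
        chem_summary(sites, cells$quantity[i], cells$kind[i], m),
        error = function(e) NULL
      )
      if (is.null(s)) {
        data.frame(medium = m, quantity = cells$quantity[i], kind = cells$kind[i],
                   geometric_mean = NA_real_, n = 0L)
      } else {
        data.frame(medium = m, quantity = s$quantity, kind = s$kind,
                   geometric_mean = s$geometric_mean, n = s$n)
      }
    }))
  }))
  rownames(out) <- NULL
  out
}
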
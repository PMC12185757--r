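#' Estimate the Porod plateau of a desmeared curve
#'
#' At momentum transfers large compared with the inverse droplet size,
#' scattering from a sharp interface follows \eqn{I \to K Q^{-4}} (Porod
#' law), so \eqn{I Q^4} reaches a plateau \eqn{K}. The plateau is taken as
#' the (inverse-variance weighted, when uncertainties are present) mean of
#' \eqn{I Q^4} over the fit range, with its standard error. A local log-log
#' slope check guards against fitting outside the Porod regime: a slope
#' outside \eqn{-4 \pm 0.3} warns, \eqn{|slope + 4| > 1} errors.
#'
#' @param curve A desmeared `scattering_curve` with intensity in
#'   \eqn{cm^{-1}}.
#' @param fit_range Length-2 q-interval. `NULL` picks the highest half-decade
#'   window of the curve where the slope check passes — the plateau is
#'   approached from below as \eqn{Qr} grows, so the highest passing window
#'   is the least biased.
#' @return A one-row tibble: `plateau`, `plateau_se`
#'   (\eqn{cm^{-1}\mathrm{\AA}^{-4}}), `slope`, `q_min`, `q_max`, `n`.
#' @export
porod_plateau <- function(curve, fit_range = NULL) {
  ok <- !curve$masked
  if (is.null(fit_range)) {
    fit_range <- find_porod_window(curve)
  }
  fit_range <- sort(fit_range)
  sel <- ok & curve$q >= fit_range[1] & curve$q <= fit_range[2]
  if (sum(sel) < 5L) abort("Fewer than 5 usable points in the Porod fit range.",
                           class = "scatterprint_format_error")
  lq <- log(curve$q[sel]); li <- log(curve$intensity[sel])
  slope <- coef(lm(li ~ lq))[[2]]
  if (abs(slope + 4) > 1) {
    abort(sprintf("Local log-log slope %.2f is not Porod-like (expected about -4): not in a Porod regime.",
                  slope), class = "scatterprint_porod_error")
  }
  if (abs(slope + 4) > 0.3) {
    warn(sprintf("Porod fit-range slope %.2f is outside -4 +- 0.3; plateau may be biased.", slope))
  }
  iq4 <- curve$intensity[sel] * curve$q[sel]^4
  w <- curve$sigma[sel]
  if (all(is.finite(w)) && all(w > 0)) {
    wts <- 1 / (w * curve$q[sel]^4)^2
    plateau <- weighted.mean(iq4, wts)
    se <- sqrt(1 / sum(wts))
  } else {
    plateau <- mean(iq4)
    se <- sd(iq4) / sqrt(length(iq4))
  }
  tibble::tibble(plateau = plateau, plateau_se = se, slope = slope,
                 q_min = fit_range[1], q_max = fit_range[2], n = sum(sel))
}

# Highest half-decade window whose local log-log slope is within -4 +- 0.3.
find_porod_window <- function(curve) {
  ok <- !curve$masked
  q <- curve$q[ok]; i <- curve$intensity[ok]
  if (length(q) < 5L) abort("Too few points to locate a Porod window.",
                            class = "scatterprint_format_error")
  starts <- rev(q[q * 10^0.5 <= max(q)])
  for (q0 in starts) {
    sel <- q >= q0 & q <= q0 * 10^0.5
    if (sum(sel) < 5L) next
    slope <- coef(lm(log(i[sel]) ~ log(q[sel])))[[2]]
    if (abs(slope + 4) <= 0.3) return(c(q0, q0 * 10^0.5))
  }
  abort("No half-decade window with a Porod-like slope (-4 +- 0.3) found.",
        class = "scatterprint_porod_error")
}

#' Specific surface area and equivalent droplet radius from a Porod plateau
#'
#' Applies \eqn{S_v = K / (2\pi(\Delta\rho)^2)}: with intensity in
#' \eqn{cm^{-1}} and both \eqn{Q} and \eqn{\Delta\rho} in \eqn{\mathrm{\AA}}
#' units, \eqn{Q^4/\Delta\rho^2} is dimensionless and the surface per unit
#' *sample* volume comes out directly in \eqn{cm^{-1}}. Dividing by the
#' dispersed-phase volume fraction gives the specific surface area per unit
#' volume of dispersed material, and the sphere relation \eqn{r = 3/S}
#' converts it to an equivalent droplet radius.
#'
#' @param plateau Porod plateau \eqn{K = \lim I Q^4},
#'   \eqn{cm^{-1}\mathrm{\AA}^{-4}} scale. May be the tibble returned by
#'   [porod_plateau()].
#' @param delta_rho Scattering-length-density contrast,
#'   \eqn{\mathrm{\AA}^{-2}}; default oil vs water,
#'   \eqn{9.47\times10^{-6} - 8.7\times10^{-6}}.
#' @param dispersed_volume_fraction Volume fraction of the dispersed phase in
#'   (0, 1\]; see [fat_volume_fraction()].
#' @return One-row tibble: `plateau`, `delta_rho`,
#'   `surface_per_sample_volume` (\eqn{cm^{-1}}), `specific_surface_area`
#'   (\eqn{cm^{-1}}, per unit dispersed volume), `equivalent_radius_um`,
#'   `dispersed_volume_fraction`.
#' @examples
#' # a plateau that implies S = 3600 1/cm at phi = 0.1 gives r = 8.3 um
#' specific_surface(3600 * 0.1 * 2 * pi * (0.77e-6)^2, 0.77e-6, 0.1)
#' @export
specific_surface <- function(plateau, delta_rho = 9.47e-6 - 8.7e-6,
                             dispersed_volume_fraction = 1) {
  if (is.data.frame(plateau)) plateau <- plateau$plateau
  if (delta_rho == 0) abort("`delta_rho` must be non-zero.", class = "scatterprint_domain_error")
  phi <- dispersed_volume_fraction
  if (!is.finite(phi) || phi <= 0 || phi > 1) {
    abort("`dispersed_volume_fraction` must lie in (0, 1].", class = "scatterprint_domain_error")
  }
  sv <- plateau / (2 * pi * delta_rho^2)
  s <- sv / phi
  tibble::tibble(
    plateau = plateau,
    delta_rho = delta_rho,
    surface_per_sample_volume = sv,
    specific_surface_area = s,
    equivalent_radius_um = equivalent_radius(s),
    dispersed_volume_fraction = phi
  )
}

#' Equivalent sphere radius from a specific surface area
#'
#' For spheres, surface area over volume is \eqn{3/r}, so
#' \eqn{r = 3/S}.
#'
#' @param S Specific surface area, \eqn{cm^{-1}} (per unit volume of
#'   dispersed material).
#' @return Radius in micrometres.
#' @examples
#' equivalent_radius(3600) # 8.3 um
#' equivalent_radius(5900) # 5.1 um
#' @export
equivalent_radius <- function(S) {
  if (any(!is.finite(S) | S <= 0)) abort("`S` must be > 0.", class = "scatterprint_domain_error")
  (3 / S) * 1e4  # cm -> um
}

#' Dispersed-phase volume fraction from a fat mass fraction
#'
#' Converts a label fat content in % w/w to an oil volume fraction using an
#' oil density of 0.92 g/mL and a product density of 1.0 g/mL by default.
#'
#' @param fat Fat content, % w/w.
#' @param oil_density,product_density Densities in g/mL.
#' @return Volume fraction in \[0, 1\].
#' @export
fat_volume_fraction <- function(fat, oil_density = 0.92, product_density = 1.0) {
  if (any(fat < 0 | fat > 100)) abort("`fat` must be in [0, 100] % w/w.",
                                      class = "scatterprint_domain_error")
  (fat / 100) * product_density / oil_density
}
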
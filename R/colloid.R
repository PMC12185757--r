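#' Cumulant polydispersity analysis of a DLS correlation function
#'
#' Recovers the field correlation \eqn{|g_1|} from the measured intensity
#' correlation via the Siegert relation
#' \eqn{g_2 = baseline + \beta |g_1|^2}, then fits a polynomial cumulant
#' expansion \eqn{\ln|g_1| = c_0 - a_1 t + a_2 t^2 - \ldots} over the window
#' where \eqn{|g_1| >} `g1_min` (limiting noise amplification in the log).
#' The polydispersity index is \eqn{PDI = 2a_2/a_1^2}, which for a Gaussian
#' distribution of decay rates equals \eqn{\sigma^2/\mu^2}. By default the
#' fit carries one order beyond the reported cumulants (`order = 3`): for
#' skewed rate distributions the truncated quadratic systematically
#' underestimates \eqn{a_2}, and absorbing the third cumulant removes that
#' bias; `order = 2` gives the plain quadratic fit. Negative \eqn{a_2}
#' estimates are floored at zero with a flag.
#'
#' @param data Tibble with columns `lag` (s) and `g2`.
#' @param baseline Long-time value of `g2` (1 for a normalised correlation
#'   function).
#' @param coherence Siegert coherence factor \eqn{\beta}.
#' @param g1_min Lower `|g1|` cut for the fit window.
#' @param order Polynomial order of the cumulant fit (2 or 3).
#' @return Object of class `cumulant_fit` with `a1` (1/s), `a2`
#'   (1/s\eqn{^2}), `pdi`, `floored`, `fit_window`, `n`; has
#'   [tidy()]/[glance()] methods.
#' @export
cumulant_pdi <- function(data, baseline = 1, coherence = 1, g1_min = 0.1,
                         order = 3) {
  if (!order %in% c(2, 3)) abort("`order` must be 2 or 3.", class = "scatterprint_domain_error")
  lag <- data$lag; g2 <- data$g2
  g1sq <- (g2 - baseline) / coherence
  g1 <- sqrt(pmax(g1sq, 0))
  use <- g1 > g1_min & lag > 0
  if (sum(use) < 10L) {
    # noisy/short data: relax the window rather than fail outright
    use <- g1 > 0 & lag > 0
    if (sum(use) < 10L) abort("Fewer than 10 usable lag points above the |g1| cut.",
                              class = "scatterprint_fit_error")
    warn("Fewer than 10 points above `g1_min`; fit window extended to all positive |g1|.")
  }
  t <- lag[use]; lg <- log(g1[use])
  fit <- if (order == 3) lm(lg ~ t + I(t^2) + I(t^3)) else lm(lg ~ t + I(t^2))
  a1 <- -coef(fit)[[2]]
  a2 <- coef(fit)[[3]]
  if (a1 <= 0) abort("Correlation function does not decay (a1 <= 0).",
                     class = "scatterprint_fit_error")
  floored <- a2 < 0
  pdi <- max(2 * a2 / a1^2, 0)
  structure(list(a1 = a1, a2 = max(a2, 0), pdi = pdi, floored = floored,
                 fit_window = range(t), n = sum(use), fit = fit),
            class = "cumulant_fit")
}

#' @export
print.cumulant_fit <- function(x, ...) {
  cat(sprintf("<cumulant_fit> a1 = %.4g 1/s, a2 = %.4g 1/s^2, PDI = %.4g%s (n = %d)\n",
              x$a1, x$a2, x$pdi, if (x$floored) " [a2 floored at 0]" else "", x$n))
  invisible(x)
}

#' @rdname cumulant_pdi
#' @param x A `cumulant_fit`.
#' @param ... Unused.
#' @export
tidy.cumulant_fit <- function(x, ...) {
  tibble::tibble(term = c("a1", "a2", "pdi"),
                 estimate = c(x$a1, x$a2, x$pdi))
}

#' @rdname cumulant_pdi
#' @export
glance.cumulant_fit <- function(x, ...) {
  tibble::tibble(pdi = x$pdi, a1 = x$a1, a2 = x$a2, floored = x$floored,
                 window_min = x$fit_window[1], window_max = x$fit_window[2],
                 n = x$n)
}

#' Hydrodynamic radius from a diffusion coefficient (Stokes-Einstein)
#'
#' \eqn{r = k_B T / (6\pi\eta D)}, reported in \eqn{\mathrm{\AA}}.
#'
#' @param D Translational diffusion coefficient, \eqn{m^2 s^{-1}}.
#' @param temperature Kelvin.
#' @param viscosity Medium viscosity, Pa s (water at 25 C: 8.9e-4).
#' @return Hydrodynamic radius, \eqn{\mathrm{\AA}}.
#' @export
stokes_einstein_radius <- function(D, temperature = 298.15, viscosity = 8.9e-4) {
  if (any(c(D, temperature, viscosity) <= 0)) {
    abort("All inputs must be > 0.", class = "scatterprint_domain_error")
  }
  kb <- 1.380649e-23
  (kb * temperature / (6 * pi * viscosity * D)) * 1e10
}

#' Zeta potential from electrophoretic mobility (Henry's equation)
#'
#' \eqn{\zeta = 3 U_E \eta / (2 \varepsilon f(\kappa r_p))}, reported in mV.
#' `epsilon` is the *absolute* permittivity \eqn{\varepsilon_0\varepsilon_r}
#' (water at 25 C: about 6.95e-10 F/m). The Smoluchowski high-ionic-strength
#' limit is \eqn{f = 1.5}, in which case \eqn{\zeta = U_E\eta/\varepsilon}.
#'
#' @param mobility Electrophoretic mobility \eqn{U_E},
#'   \eqn{m^2 V^{-1} s^{-1}}.
#' @param viscosity Pa s.
#' @param epsilon Absolute permittivity, F/m.
#' @param henry_factor Henry's function value in \[1, 1.5\].
#' @return Zeta potential, mV.
#' @export
henry_zeta <- function(mobility, viscosity = 8.9e-4, epsilon = 6.95e-10,
                       henry_factor = 1.5) {
  if (viscosity <= 0 || epsilon <= 0) abort("`viscosity` and `epsilon` must be > 0.",
                                            class = "scatterprint_domain_error")
  if (henry_factor < 1 || henry_factor > 1.5) {
    abort("`henry_factor` must lie in [1, 1.5].", class = "scatterprint_domain_error")
  }
  (3 * mobility * viscosity / (2 * epsilon * henry_factor)) * 1e3
}

#' Convert a mass fraction to molarity
#'
#' \eqn{M = (w/100)\,\rho_{sol} \times 1000 / M_w} in mol/L, reported in mM.
#' With the molar mass of NaCl (58.44 g/mol) this maps label salt contents
#' of 0.03-0.25 % w/w to about 5-43 mM.
#'
#' @param w Mass fraction, % w/w, in \[0, 100\].
#' @param molar_mass g/mol (default NaCl, 58.44).
#' @param solution_density g/mL.
#' @return Molarity, mM.
#' @examples
#' mass_fraction_to_molarity(0.25) # ~43 mM
#' @export
mass_fraction_to_molarity <- function(w, molar_mass = 58.44, solution_density = 1.0) {
  if (any(w < 0 | w > 100)) abort("`w` must be in [0, 100] % w/w.",
                                  class = "scatterprint_domain_error")
  if (molar_mass <= 0 || solution_density <= 0) {
    abort("`molar_mass` and `solution_density` must be > 0.",
          class = "scatterprint_domain_error")
  }
  (w / 100) * solution_density * 1000 / molar_mass * 1000
}
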
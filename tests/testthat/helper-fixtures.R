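# shared fixture builders (everything generated in code; no binary files)

power_law_curve <- function(A = 1, p = 4, q_range = c(2e-4, 6e-3), n = 150, ...) {
  q <- exp(seq(log(q_range[1]), log(q_range[2]), length.out = n))
  scattering_curve(q, A * q^(-p), ...)
}

# reference polydisperse-sphere curve used across smearing/porod tests
sphere_fixture <- function(radius_um = 0.5, pd = 0.2, phi = 0.05,
                           drho = 7.7e-7, q_range = c(3e-4, 5e-3), n = 150) {
  m <- emulsion_model(porod_sphere(radius_um, pd, phi, drho),
                      q_range = q_range, n_points = n)
  generate_emulsion_curve(m, technique = "USAXS")
}

# analytic lognormal moments for the planted size distribution (independent
# of the package's quadrature): E[r^k] = r0^k exp(k^2 s^2 / 2)
lognormal_specific_surface_cm <- function(radius_um, sdlog) {
  r0 <- radius_um * 1e4
  mean_r2 <- r0^2 * exp(2 * sdlog^2)
  mean_r3 <- r0^3 * exp(4.5 * sdlog^2)
  # S per unit dispersed volume = <4 pi r^2> / <(4/3) pi r^3>, A^-1 -> cm^-1
  (mean_r2 / mean_r3 * 3) * 1e8
}

rms_log <- function(a, b) sqrt(mean((log(a) - log(b))^2))
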
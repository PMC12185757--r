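# --- sphere form factor machinery ---------------------------------------

# orientationally averaged sphere form factor amplitude squared
sphere_F2 <- function(qr) {
  small <- qr < 1e-4
  out <- numeric(length(qr))
  out[small] <- (1 - qr[small]^2 / 10)^2
  x <- qr[!small]
  out[!small] <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  out
}

# Intensity (cm^-1) of a lognormal polydisperse sphere population.
#   radius_um: median radius of the lognormal, micrometres
#   polydispersity: sdlog of the lognormal (0.2 = "20% spread")
#   volume_fraction: dispersed-phase volume fraction
#   delta_rho: contrast, A^-2
# I(q) = n_d (drho)^2 <V^2 F^2> with n_d = phi / <V>, in A^-1, times 1e8
# for cm^-1. Above q r_min > 30 the lognormal average of the oscillatory
# form factor is replaced by its smooth Porod asymptote
# 8 pi^2 <r^2> n_d drho^2 / q^4, which the polydispersity average converges
# to; this avoids needing ever-denser quadrature at WAXS-scale q.
poly_sphere_intensity <- function(q, radius_um, polydispersity, volume_fraction,
                                  delta_rho, n_nodes = 501) {
  r0 <- radius_um * 1e4  # A
  s <- max(polydispersity, 0)
  if (s > 0) {
    z <- seq(-5, 5, length.out = n_nodes)
    w <- dnorm(z)
    w <- w / sum(w)
    r <- r0 * exp(s * z)
  } else {
    r <- r0
    w <- 1
  }
  V <- 4 / 3 * pi * r^3
  mean_V <- sum(w * V)
  mean_r2 <- sum(w * r^2)
  nd <- volume_fraction / mean_V            # A^-3
  r_lo <- min(r)
  asym <- q * r_lo > 30
  I <- numeric(length(q))
  if (any(!asym)) {
    I[!asym] <- vapply(q[!asym], function(qi) sum(w * V^2 * sphere_F2(qi * r)),
                       numeric(1))
  }
  I[asym] <- 8 * pi^2 * mean_r2 / q[asym]^4
  nd * delta_rho^2 * I * 1e8                # cm^-1
}

# --- model components ----------------------------------------------------

#' Components of a synthetic emulsion scattering model
#'
#' Building blocks for [emulsion_model()]: a sharp-interface polydisperse
#' sphere population (Porod scatterer), a power law, a Gaussian correlation
#' peak (e.g. the 2L lamellar peak at 0.15 \eqn{\mathrm{\AA}^{-1}} or WAXS
#' polymorph reflections), the broad amorphous water halo near 2
#' \eqn{\mathrm{\AA}^{-1}}, and a flat background.
#'
#' @param radius_um Median droplet radius, micrometres.
#' @param polydispersity Lognormal sdlog of the radius (0.2 = 20% spread).
#' @param volume_fraction Dispersed-phase volume fraction.
#' @param delta_rho Contrast, \eqn{\mathrm{\AA}^{-2}}.
#' @param amplitude Component amplitude (intensity units).
#' @param exponent Power-law exponent p in \eqn{I = A Q^{-p}}, in \[0, 5\].
#' @param position Peak centre, \eqn{\mathrm{\AA}^{-1}}.
#' @param width Gaussian sigma, \eqn{\mathrm{\AA}^{-1}}.
#' @return A component list for [emulsion_model()].
#' @name emulsion_components
NULL

#' @rdname emulsion_components
#' @export
porod_sphere <- function(radius_um = 0.5, polydispersity = 0.2,
                         volume_fraction = 0.05, delta_rho = 7.7e-7) {
  list(type = "porod_sphere", radius_um = radius_um, polydispersity = polydispersity,
       volume_fraction = volume_fraction, delta_rho = delta_rho)
}

#' @rdname emulsion_components
#' @export
power_law <- function(amplitude, exponent) {
  list(type = "power_law", amplitude = amplitude, exponent = exponent)
}

#' @rdname emulsion_components
#' @export
gaussian_peak <- function(position, width, amplitude) {
  list(type = "gaussian_peak", position = position, width = width, amplitude = amplitude)
}

#' @rdname emulsion_components
#' @export
water_halo <- function(position = 2, width = 0.3, amplitude = 1) {
  list(type = "gaussian_peak", position = position, width = width, amplitude = amplitude)
}

#' @rdname emulsion_components
#' @export
flat_background <- function(amplitude) {
  list(type = "flat_background", amplitude = amplitude)
}

#' Define a synthetic emulsion scattering model
#'
#' @param ... Components built with [porod_sphere()], [power_law()],
#'   [gaussian_peak()], [water_halo()], [flat_background()].
#' @param q_range Length-2 q-interval, \eqn{\mathrm{\AA}^{-1}}.
#' @param n_points Number of log-spaced q points.
#' @param noise Relative (multiplicative lognormal) counting-noise level;
#'   0 for a noise-free curve.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An `emulsion_model` list.
#' @export
emulsion_model <- function(..., q_range = c(3e-4, 3), n_points = 400,
                           noise = 0, seed = 1L) {
  components <- list(...)
  problems <- character()
  for (k in seq_along(components)) {
    cmp <- components[[k]]
    if (is.null(cmp$type)) problems <- c(problems, sprintf("component %d: no type", k))
    if (identical(cmp$type, "power_law") &&
        (cmp$exponent < 0 || cmp$exponent > 5)) {
      problems <- c(problems, sprintf("component %d: exponent outside [0, 5]", k))
    }
    amp <- cmp$amplitude
    if (!is.null(amp) && amp < 0) problems <- c(problems, sprintf("component %d: negative amplitude", k))
    pos <- cmp$position
    if (!is.null(pos) && (pos < q_range[1] || pos > q_range[2])) {
      problems <- c(problems, sprintf("component %d: peak position outside q_range", k))
    }
  }
  if (noise < 0) problems <- c(problems, "negative noise level")
  if (length(problems) > 0) {
    abort(paste0("Invalid emulsion model: ", paste(problems, collapse = "; ")),
          class = "scatterprint_validation_error")
  }
  structure(list(components = components, q_range = sort(q_range),
                 n_points = n_points, noise = noise, seed = as.integer(seed)),
            class = "emulsion_model")
}

component_intensity <- function(cmp, q) {
  switch(cmp$type,
    porod_sphere = poly_sphere_intensity(q, cmp$radius_um, cmp$polydispersity,
                                         cmp$volume_fraction, cmp$delta_rho),
    power_law = cmp$amplitude * q^(-cmp$exponent),
    gaussian_peak = cmp$amplitude * exp(-(q - cmp$position)^2 / (2 * cmp$width^2)),
    flat_background = rep(cmp$amplitude, length(q)),
    abort(paste0("Unknown component type: ", cmp$type), class = "scatterprint_validation_error")
  )
}

#' Generate a synthetic emulsion scattering curve
#'
#' Sums the model components on a log-spaced q-grid, applies multiplicative
#' lognormal counting noise with the model's seed, and optionally forwards
#' the result through [slit_smear()] to emulate Bonse-Hart USAXS geometry.
#'
#' @param model An [emulsion_model()].
#' @param smear `FALSE` for pinhole data, or a slit length
#'   (\eqn{\mathrm{\AA}^{-1}}) to produce a slit-smeared curve.
#' @inheritParams scattering_curve
#' @return A `scattering_curve`; the model is attached as attribute
#'   `truth` for parameter-recovery tests.
#' @export
generate_emulsion_curve <- function(model, smear = FALSE,
                                    technique = c("SAXS", "USAXS", "WAXS", "merged"),
                                    sample_id = NA_character_) {
  technique <- match.arg(technique)
  q <- exp(seq(log(model$q_range[1]), log(model$q_range[2]),
               length.out = model$n_points))
  I <- Reduce(`+`, lapply(model$components, component_intensity, q = q))
  sigma <- NULL
  if (model$noise > 0) {
    I <- withr::with_seed(model$seed, I * exp(stats::rnorm(length(q), 0, model$noise)))
    sigma <- I * model$noise
  }
  out <- scattering_curve(q, I, sigma = sigma, technique = technique,
                          smeared = FALSE, sample_id = sample_id)
  if (!isFALSE(smear)) {
    L <- if (isTRUE(smear)) 0.015 else smear
    out <- slit_smear(out, slit_length = L)
  }
  attr(out, "truth") <- model
  out
}

#' Generate a linked set of sample curves and a composition table
#'
#' Emulates the correlation structure seen in commercial emulsion products:
#' the total fat drives the low-Q (droplet) scattering amplitude and — for
#' cream-category samples — the 0.15 \eqn{\mathrm{\AA}^{-1}} lamellar peak,
#' while the carbohydrate content drives the mid-Q intensity. Compositions
#' are drawn within the ranges of commercial products (fat 1.0-36,
#' carbohydrate 0-13, protein 0.1-5.0 % w/w), split into milk/yoghurt/cream
#' categories. The exact link functions are recorded in the `truth`
#' attribute so tests can assert recovery.
#'
#' @param n_samples Number of samples (>= 4).
#' @param noise Relative intensity noise per curve (0 = deterministic link).
#' @param seed Integer seed.
#' @param q_range,n_points Grid passed to each curve.
#' @return List with `curves` (named list of `scattering_curve`s),
#'   `composition` (a tibble accepted by downstream validation), and
#'   `truth` (the planted link description).
#' @export
generate_sample_set <- function(n_samples = 29, noise = 0, seed = 1L,
                                q_range = c(3e-4, 3), n_points = 300) {
  if (n_samples < 4L) abort("`n_samples` must be >= 4.", class = "scatterprint_domain_error")
  materials <- c("almond", "casein", "coconut", "fava bean", "linseed",
                 "oat", "pea", "rice", "soy")
  withr::with_seed(seed, {
    n_milk <- max(1L, round(n_samples * 12 / 29))
    n_yog <- max(1L, round(n_samples * 8 / 29))
    n_cream <- max(1L, n_samples - n_milk - n_yog)
    n_milk <- n_samples - n_yog - n_cream
    category <- c(rep("milk", n_milk), rep("yoghurt", n_yog), rep("cream", n_cream))
    # compositions span the commercial-product ranges as an evenly spaced
    # panel, randomly assigned to samples: creams are the high-fat products
    fat <- numeric(n_samples)
    is_cream <- category == "cream"
    shuffle <- function(x) x[sample.int(length(x))]
    fat[is_cream] <- shuffle(seq(3, 36, length.out = sum(is_cream)))
    fat[!is_cream] <- shuffle(seq(1, 2.8, length.out = sum(!is_cream)))
    carbohydrate <- shuffle(seq(0, 13, length.out = n_samples))
    protein <- stats::runif(n_samples, 0.1, 5)
    material <- sample(materials, n_samples, replace = TRUE)
    label <- sub("^(.)", "\\U\\1", material, perl = TRUE)
    composition <- tibble::tibble(
      number = seq_len(n_samples),
      sample = sprintf("%s %s - %d", label, category, seq_len(n_samples)),
      fat = fat, carbohydrate = carbohydrate,
      protein = protein, category = category, material = material
    )
    # planted monotone links: fat sets the droplet volume fraction (low-Q
    # intensity), carbohydrate a broad mid-Q feature, fat the lamellar peak
    # for creams
    link <- list(
      low_q = function(fat) fat_volume_fraction(fat),
      mid_q = function(carb) 0.2 * (0.2 + carb),
      lamellar = function(fat, category) ifelse(category == "cream", 0.05 * fat, 0)
    )
    curve_seeds <- sample.int(1e6, n_samples)
    curves <- purrr::pmap(list(composition$sample, composition$fat,
                               composition$carbohydrate, composition$category,
                               curve_seeds),
      function(id, fat, carb, cat, sd_i) {
        lam_amp <- link$lamellar(fat, cat)
        cmps <- list(
          porod_sphere(radius_um = 0.5, polydispersity = 0.2,
                       volume_fraction = link$low_q(fat), delta_rho = 7.7e-7),
          # broad carbohydrate/protein network feature between 0.01 and
          # 0.1 1/A; localised so it does not leak into the USAXS regime
          gaussian_peak(position = 0.05, width = 0.03, amplitude = link$mid_q(carb)),
          water_halo(position = 2, width = 0.3, amplitude = 0.5),
          flat_background(0.01)
        )
        if (lam_amp > 0) {
          cmps <- c(cmps, list(gaussian_peak(0.15, 0.01, lam_amp)))
        }
        model <- do.call(emulsion_model,
                         c(cmps, list(q_range = q_range, n_points = n_points,
                                      noise = noise, seed = sd_i)))
        generate_emulsion_curve(model, technique = "merged", sample_id = id)
      })
    names(curves) <- composition$sample
    list(curves = curves, composition = composition, truth = link)
  })
}

#' Generate a synthetic DLS intensity correlation function
#'
#' Builds \eqn{g_2(\tau)} for a lognormal distribution of hydrodynamic radii:
#' the scattering vector follows from the optics
#' (\eqn{q = 4\pi n \sin(\theta/2)/\lambda}), each size decays at
#' \eqn{\Gamma = D q^2} with \eqn{D} from Stokes-Einstein, the field
#' correlation \eqn{g_1} is the intensity-weighted (\eqn{r^6}, Rayleigh
#' limit) sum of exponentials, and \eqn{g_2 = 1 + \beta|g_1|^2} (Siegert)
#' with additive Gaussian noise. Defaults emulate a He-Ne (633 nm)
#' backscatter instrument at 25 C.
#'
#' @param median_radius Median radius of the lognormal, \eqn{\mathrm{\AA}}.
#' @param spread Lognormal sdlog (0 = monodisperse).
#' @param temperature Kelvin.
#' @param viscosity Pa s.
#' @param wavelength Laser wavelength, nm.
#' @param angle Scattering angle, degrees.
#' @param ri_medium Refractive index of the medium.
#' @param coherence Siegert coherence factor \eqn{\beta}.
#' @param noise Additive Gaussian noise sd on g2.
#' @param seed Integer seed.
#' @param lags Lag times, s; default 200 log-spaced points over
#'   \eqn{10^{-7}}-1 s.
#' @return Tibble with `lag`, `g2`; attributes `truth` (planted parameters,
#'   including the intensity-weighted mean decay rate `gamma_mean` and its
#'   relative variance `gamma_relvar`) and `q_m` (scattering vector, 1/m).
#' @export
generate_dls_correlation <- function(median_radius = 1500, spread = 0.3,
                                     temperature = 298.15, viscosity = 8.9e-4,
                                     wavelength = 633, angle = 173,
                                     ri_medium = 1.33, coherence = 1,
                                     noise = 0, seed = 1L,
                                     lags = 10^seq(-7, 0, length.out = 200)) {
  if (median_radius <= 0 || spread < 0) abort("Distribution parameters must be positive.",
                                              class = "scatterprint_domain_error")
  if (wavelength <= 0 || angle <= 0 || angle > 180 || ri_medium <= 0) {
    abort("Invalid optics parameters.", class = "scatterprint_domain_error")
  }
  q_m <- 4 * pi * ri_medium * sin(angle * pi / 360) / (wavelength * 1e-9)  # 1/m
  kb <- 1.380649e-23
  if (spread > 0) {
    z <- seq(-5, 5, length.out = 201)
    w <- dnorm(z); w <- w / sum(w)
    r <- median_radius * exp(spread * z)     # A
  } else {
    r <- median_radius; w <- 1
  }
  wi <- w * r^6                              # Rayleigh intensity weighting
  wi <- wi / sum(wi)
  D <- kb * temperature / (6 * pi * viscosity * r * 1e-10)  # m^2/s
  gamma <- D * q_m^2                          # 1/s
  g1 <- vapply(lags, function(t) sum(wi * exp(-gamma * t)), numeric(1))
  g2 <- 1 + coherence * g1^2
  if (noise > 0) {
    g2 <- withr::with_seed(seed, g2 + stats::rnorm(length(g2), 0, noise))
  }
  gm <- sum(wi * gamma)
  gv <- sum(wi * (gamma - gm)^2)
  out <- tibble::tibble(lag = lags, g2 = g2)
  attr(out, "truth") <- list(median_radius = median_radius, spread = spread,
                             gamma_mean = gm, gamma_relvar = gv / gm^2,
                             coherence = coherence)
  attr(out, "q_m") <- q_m
  out
}
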
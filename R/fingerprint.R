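#' Resample a curve onto a logarithmically spaced q-grid
#'
#' Interpolates \eqn{\ln I} linearly in \eqn{\ln Q} onto `n_points`
#' log-spaced nodes between the curve's first and last q. Interpolation in
#' log-log space is the natural choice here because the downstream quantity
#' is \eqn{d\ln I/d\ln Q} and scattering curves are viewed log-log; linear-I
#' interpolation is available via `log_domain = FALSE`. Masked (non-positive)
#' stretches are bridged and flagged in a `gap` column.
#'
#' @param curve A `scattering_curve` spanning at least one decade.
#' @param n_points Number of grid nodes (>= 10); 100 is the conventional
#'   resolution for fingerprint maps.
#' @param log_domain Interpolate `ln I` (default) or raw `I`.
#' @return Tibble with `q` (constant-ratio grid), `intensity`, `gap`.
#' @export
resample_loglog <- function(curve, n_points = 100, log_domain = TRUE) {
  ok <- !curve$masked
  if (sum(ok) < 2L) abort("All-masked curve: nothing to resample.",
                          class = "scatterprint_nodata_error")
  if (n_points < 10L) abort("`n_points` must be >= 10.", class = "scatterprint_domain_error")
  if (max(curve$q) / min(curve$q) < 10) {
    abort("Curve spans less than one decade in q.", class = "scatterprint_range_error")
  }
  grid <- exp(seq(log(min(curve$q)), log(max(curve$q)), length.out = n_points))
  grid[1] <- min(curve$q); grid[n_points] <- max(curve$q)
  y <- if (log_domain) {
    exp(approx(log(curve$q[ok]), log(curve$intensity[ok]), xout = log(grid),
               rule = 2, ties = "ordered")$y)
  } else {
    approx(log(curve$q[ok]), curve$intensity[ok], xout = log(grid),
           rule = 2, ties = "ordered")$y
  }
  # a node is a gap if it falls strictly inside a masked stretch
  gap <- vapply(grid, function(g) {
    j <- findInterval(g, curve$q, rightmost.closed = TRUE)
    j >= 1 && j < nrow(curve) && curve$masked[j] && curve$masked[j + 1]
  }, logical(1))
  tibble::tibble(q = grid, intensity = y, gap = gap)
}

#' Log-log gradients between neighbouring grid points
#'
#' \eqn{g_i = (\ln I_{i+1} - \ln I_i) / (\ln Q_{i+1} - \ln Q_i)}, assigned to
#' the geometric midpoint of each pair. Both the signed value and its modulus
#' are returned.
#'
#' @param gridded Tibble from [resample_loglog()] (columns `q`, `intensity`),
#'   or any tibble with positive `q` and `intensity`.
#' @return Tibble with `q` (geometric midpoints, n-1 rows), `gradient`,
#'   `modulus`.
#' @export
loglog_gradient <- function(gridded) {
  ok <- is.finite(gridded$intensity) & gridded$intensity > 0
  if (sum(ok) < 2L) abort("Fewer than 2 positive points: no gradient defined.",
                          class = "scatterprint_nodata_error")
  q <- gridded$q; i <- gridded$intensity
  g <- diff(log(i)) / diff(log(q))
  tibble::tibble(q = sqrt(q[-length(q)] * q[-1]), gradient = g, modulus = abs(g))
}

#' Normalise intensities to \[0, 1\] per sample
#'
#' Rescales \eqn{\ln I} so its minimum maps to 0 and its maximum to 1
#' (log-domain normalisation matches the displayed dynamic range of a
#' log-log scattering plot and makes the result invariant under intensity
#' scaling).
#'
#' @param gridded Tibble with an `intensity` column.
#' @return The tibble with `intensity` replaced by normalised values.
#' @export
normalize_intensity <- function(gridded) {
  i <- gridded$intensity
  ok <- is.finite(i) & i > 0
  li <- log(i[ok])
  rng <- range(li)
  if (diff(rng) <= 0) abort("Constant intensity: zero normalisation range.",
                            class = "scatterprint_normalization_error")
  out <- gridded
  out$intensity[ok] <- (li - rng[1]) / diff(rng)
  out$intensity[!ok] <- NA_real_
  out
}

#' Classify a log-log gradient into a scattering regime
#'
#' Gradients near \eqn{-4} indicate surface (Porod) scattering from sharp
#' interfaces; between \eqn{-3} and \eqn{-1}, mass-fractal structures; near
#' zero, a plateau; \eqn{\ge 1}, the rising flank of a correlation peak.
#'
#' @param g Signed gradient value(s).
#' @return Character vector of labels: `porod_surface` (g <= -3.5),
#'   `smeared_surface_or_steep` (-3.5 < g <= -3), `mass_fractal`
#'   (-3 < g <= -1), `plateau` (-1 < g < 1), `rising_peak_flank` (g >= 1).
#' @export
classify_regime <- function(g) {
  if (any(!is.finite(g))) abort("Gradient must be finite.", class = "scatterprint_domain_error")
  dplyr::case_when(
    g <= -3.5 ~ "porod_surface",
    g <= -3 ~ "smeared_surface_or_steep",
    g <= -1 ~ "mass_fractal",
    g < 1 ~ "plateau",
    TRUE ~ "rising_peak_flank"
  )
}

#' Build a structural-fingerprint matrix from full-range curves
#'
#' Each sample's merged (desmeared USAXS + SAXS + WAXS) curve is resampled
#' onto a common log-spaced q-grid; two layers are stored: the per-sample
#' \[0, 1\]-normalised log intensity and the signed log-log gradient with its
#' modulus. For rendering, gradient moduli are shown on a linear temperature
#' scale from 0 (black) to 4 (white), values above 4 clipped — the stored
#' values are never clipped.
#'
#' @param curves Named list of `scattering_curve`s spanning a common q-range
#'   (names are the sample ids; unnamed lists fall back to each curve's
#'   `sample_id` attribute).
#' @param n_points Grid resolution (default 100).
#' @return A `fingerprint_matrix`: list with `q_grid` (length `n_points`),
#'   `q_mid` (length `n_points - 1`), `samples`, matrices
#'   `normalized_intensity` (samples x n), `gradient` and `gradient_modulus`
#'   (samples x n-1), and `colour_scale = c(0, 4)`.
#' @export
build_fingerprint <- function(curves, n_points = 100) {
  if (is.null(names(curves)) || any(!nzchar(names(curves)))) {
    names(curves) <- vapply(curves, function(cv) {
      id <- attr(cv, "sample_id")
      if (is.null(id) || is.na(id)) "" else id
    }, character(1))
  }
  if (any(!nzchar(names(curves)))) {
    names(curves)[!nzchar(names(curves))] <-
      paste0("sample_", which(!nzchar(names(curves))))
  }
  rng <- vapply(curves, function(cv) range(cv$q), numeric(2))
  ref <- rng[, 1]
  bad <- names(curves)[abs(log(rng[1, ] / ref[1])) > 0.01 | abs(log(rng[2, ] / ref[2])) > 0.01]
  if (length(bad) > 0) {
    abort(paste0("Curves do not span a common q-range: ", paste(bad, collapse = ", ")),
          class = "scatterprint_range_error")
  }
  # order rows by trailing sample number when ids carry one (e.g. "... - 23")
  num <- suppressWarnings(as.numeric(sub(".*?([0-9]+)\\s*$", "\\1", names(curves))))
  if (!any(is.na(num))) curves <- curves[order(num)]
  layers <- purrr::map(curves, function(cv) {
    grd <- resample_loglog(cv, n_points = n_points)
    list(norm = normalize_intensity(grd)$intensity, grad = loglog_gradient(grd))
  })
  q_grid <- resample_loglog(curves[[1]], n_points = n_points)$q
  grad <- do.call(rbind, purrr::map(layers, ~ .x$grad$gradient))
  structure(list(
    q_grid = q_grid,
    q_mid = layers[[1]]$grad$q,
    samples = names(curves),
    normalized_intensity = do.call(rbind, purrr::map(layers, "norm")),
    gradient = grad,
    gradient_modulus = abs(grad),
    colour_scale = c(0, 4)
  ), class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d samples x %d log-Q points (%.3g-%.3g 1/A)\n",
              length(x$samples), length(x$q_grid), min(x$q_grid), max(x$q_grid)))
  invisible(x)
}

#' Tidy a fingerprint matrix into long form
#'
#' @param x A `fingerprint_matrix`.
#' @param ... Unused.
#' @return Long tibble with `sample`, `layer`, `q`, `value`.
#' @export
tidy.fingerprint_matrix <- function(x, ...) {
  long <- function(mat, qs, layer) {
    tibble::tibble(
      sample = rep(x$samples, each = length(qs)),
      layer = layer,
      q = rep(qs, times = length(x$samples)),
      value = as.vector(t(mat))
    )
  }
  dplyr::bind_rows(
    long(x$normalized_intensity, x$q_grid, "normalized_intensity"),
    long(x$gradient_modulus, x$q_mid, "gradient_modulus")
  )
}

#' Heat-map rendering of a fingerprint matrix
#'
#' Draws the samples-by-log-Q heat map: the gradient-modulus layer on a
#' linear temperature scale from 0 (black) to 4 (white), values above 4
#' clipped to white, or the normalised-intensity layer on \[0, 1\].
#'
#' @param object A `fingerprint_matrix`.
#' @param layer `"gradient"` (modulus) or `"intensity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fingerprint_matrix <- function(object, layer = c("gradient", "intensity"), ...) {
  layer <- match.arg(layer)
  dat <- tidy(object)
  if (layer == "gradient") {
    dat <- dplyr::filter(dat, .data$layer == "gradient_modulus")
    lims <- object$colour_scale
    lab <- "|d ln I / d ln Q|"
  } else {
    dat <- dplyr::filter(dat, .data$layer == "normalized_intensity")
    lims <- c(0, 1)
    lab <- "normalised I"
  }
  dat$sample <- factor(dat$sample, levels = rev(object$samples))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$q, y = .data$sample, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10(expand = c(0, 0)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = lims,
                                 oob = scales::squish, name = lab) +
    ggplot2::labs(x = expression(Q ~ (ring(A)^-1)), y = NULL)
}

#' @rdname autoplot.fingerprint_matrix
#' @param x A `fingerprint_matrix`.
#' @param y Unused.
#' @export
plot.fingerprint_matrix <- function(x, y, ...) print(autoplot(x, ...))

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
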
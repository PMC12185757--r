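#' Read the intensity of a curve at a probe Q
#'
#' Log-log interpolation between the neighbouring grid points; at a grid
#' point the stored intensity is returned exactly.
#'
#' @param curve A `scattering_curve`.
#' @param q_probe Probe position, \eqn{\mathrm{\AA}^{-1}}, inside the curve
#'   range.
#' @return Interpolated intensity.
#' @export
intensity_at_q <- function(curve, q_probe) {
  lo <- min(curve$q); hi <- max(curve$q)
  if (any(q_probe < lo * (1 - 1e-9) | q_probe > hi * (1 + 1e-9))) {
    abort("`q_probe` lies outside the curve's q-range.", class = "scatterprint_range_error")
  }
  loglog_interp(curve, pmin(pmax(q_probe, lo), hi), rule = 2)
}

# all permutations of 1..n as an (n! x n) matrix, built iteratively
all_permutations <- function(n) {
  p <- matrix(1L, 1, 1)
  for (k in 2:n) {
    m <- nrow(p)
    p <- do.call(rbind, lapply(seq_len(k), function(pos) {
      cbind(p, k)[, append(seq_len(k - 1), k, after = pos - 1), drop = FALSE]
    }))
  }
  p
}

#' Spearman rank correlation with an exact small-n p-value
#'
#' The coefficient uses midranks for ties. The two-sided p-value under the
#' null of no correlation is computed by exact enumeration of all n!
#' permutations of one variable for n <= `exact_max`, and by the t
#' approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of
#' freedom otherwise.
#'
#' @param x,y Equal-length numeric vectors, n >= 4, neither constant.
#' @param method `"auto"` (exact for n <= `exact_max`), `"exact"`, or
#'   `"t_approx"`.
#' @param exact_max Largest n for which the exact enumeration is used.
#' @return One-row tibble: `rho`, `p_value`, `method`, `n`.
#' @examples
#' spearman_correlation(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_correlation <- function(x, y, method = c("auto", "exact", "t_approx"),
                                 exact_max = 9) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.",
                            class = "scatterprint_format_error")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 4L) abort("Need at least 4 complete pairs.", class = "scatterprint_format_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Constant input: Spearman correlation undefined.",
          class = "scatterprint_undefined_error")
  }
  rho <- cor(x, y, method = "spearman")
  if (method == "auto") method <- if (n <= exact_max) "exact" else "t_approx"
  if (method == "exact") {
    rx <- rank(x); ry <- rank(y)
    perms <- all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    num <- as.vector(ry_perm %*% rx) - n * mean(rx) * mean(ry)
    den <- (n - 1) * sd(rx) * sd(ry)
    rho_perm <- num / den
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, method = method, n = n)
}

#' Ordinary least-squares straight-line fit
#'
#' @param x,y Equal-length numeric vectors, n >= 3, `x` not constant.
#' @return Object of class `line_fit` wrapping the `lm` fit, with
#'   [tidy()]/[glance()] methods; `$slope`, `$intercept` and `$residuals`
#'   are available directly.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.",
                                    class = "scatterprint_format_error")
  if (length(x) < 3L) abort("Need at least 3 points.", class = "scatterprint_format_error")
  if (sd(x) == 0) abort("Constant `x`: singular fit.", class = "scatterprint_singular_error")
  fit <- lm(y ~ x)
  # summary.lm warns on exact fits; zero residuals are a legitimate case here
  s <- suppressWarnings(summary(fit))
  structure(list(
    slope = coef(fit)[[2]],
    intercept = coef(fit)[[1]],
    residuals = unname(stats::residuals(fit)),
    sigma = s$sigma,
    slope_se = s$coefficients[2, 2],
    fit = fit
  ), class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("<line_fit> y = %.4g + %.4g x (residual SE %.4g, n = %d)\n",
              x$intercept, x$slope, x$sigma, length(x$residuals)))
  invisible(x)
}

#' @rdname linear_fit
#' @param x A `line_fit`.
#' @param ... Unused.
#' @export
tidy.line_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = s[, 2])
}

#' @rdname linear_fit
#' @export
glance.line_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 n = length(x$residuals))
}

#' Correlate intensity read-outs with product composition
#'
#' For each probe, reads the intensity of every sample's curve at the probe
#' Q, pairs it with the requested composition variable, and reports the
#' Spearman correlation with p-value plus a straight-line fit. The default
#' probes are the conventional ones for emulsion products: total fat against
#' USAXS intensity at \eqn{3\times10^{-4}} \eqn{\mathrm{\AA}^{-1}},
#' carbohydrate against SAXS intensity at 0.10 \eqn{\mathrm{\AA}^{-1}}, and
#' total fat against the solid-fat lamellar peak at 0.15
#' \eqn{\mathrm{\AA}^{-1}}.
#'
#' For a peak probe (such as the lamellar 0.15 read-out), a logical
#' `baseline_subtract` column in `probes` switches the correlated quantity
#' to the intensity above the local rolling baseline (as used by
#' [find_peaks()]); the raw interpolated intensity is always kept in the
#' `pairs` tables, so both variants are available.
#'
#' @param curves Named list of `scattering_curve`s; names must match
#'   `composition$sample`.
#' @param composition Composition tibble (see [read_composition_table()]).
#' @param probes Tibble with columns `q` and `variable` (optionally
#'   `baseline_subtract`).
#' @return Tibble with one row per probe: `q_probe`, `variable`, `rho`,
#'   `p_value`, `method`, `n`, `slope`, `intercept`, and a list-column
#'   `pairs` of the underlying (composition, intensity) tables.
#' @export
correlate_composition <- function(curves, composition,
                                  probes = tibble::tibble(
                                    q = c(0.0003, 0.10, 0.15),
                                    variable = c("fat", "carbohydrate", "fat"))) {
  ids <- intersect(names(curves), composition$sample)
  if (length(ids) < 4L) abort("Fewer than 4 samples shared between curves and composition.",
                              class = "scatterprint_format_error")
  if (!"baseline_subtract" %in% names(probes)) probes$baseline_subtract <- FALSE
  purrr::pmap_dfr(probes, function(q, variable, baseline_subtract) {
    pairs <- purrr::map_dfr(ids, function(id) {
      raw <- intensity_at_q(curves[[id]], q)
      val <- raw
      if (isTRUE(baseline_subtract)) {
        base <- local_baseline_at(curves[[id]], q)
        val <- max(raw - base, 0)
      }
      tibble::tibble(sample = id,
                     composition = composition[[variable]][composition$sample == id],
                     intensity = val, intensity_raw = raw)
    })
    sp <- spearman_correlation(pairs$composition, pairs$intensity)
    lf <- linear_fit(pairs$composition, pairs$intensity)
    tibble::tibble(q_probe = q, variable = variable, rho = sp$rho,
                   p_value = sp$p_value, method = sp$method, n = sp$n,
                   slope = lf$slope, intercept = lf$intercept,
                   pairs = list(pairs))
  })
}
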
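#' Convert a Bragg peak position to a real-space d-spacing
#'
#' @param q Peak position(s), \eqn{\mathrm{\AA}^{-1}}, > 0.
#' @return d-spacing \eqn{d = 2\pi/q} in \eqn{\mathrm{\AA}}.
#' @examples
#' q_to_dspacing(0.15) # ~42 A lamellar repeat
#' q_to_dspacing(1.37) # 4.6 A, beta (triclinic)
#' @export
q_to_dspacing <- function(q) {
  if (any(!is.finite(q) | q <= 0)) abort("`q` must be > 0.", class = "scatterprint_domain_error")
  2 * pi / q
}

#' Reference Bragg positions for triglyceride polymorphs
#'
#' The catalogue holds the characteristic WAXS chain-packing reflections of
#' the three triglyceride polymorphs — alpha (hexagonal), beta-prime
#' (orthorhombic, two reported variant sets) and beta (triclinic) — plus the
#' first-order 2L lamellar SAXS peak near 0.15 \eqn{\mathrm{\AA}^{-1}}.
#' Q positions are authoritative; d-spacings are recomputed as \eqn{2\pi/Q}
#' (literature d-values are sometimes transcribed with small discrepancies,
#' e.g. 4.15 vs \eqn{2\pi/1.53 = 4.11}).
#'
#' @return Tibble with columns `polymorph`, `variant`, `q`, `d`.
#' @export
polymorph_catalogue <- function() {
  entries <- list(
    alpha_hexagonal = list(`1` = 1.53),
    beta_prime_orthorhombic = list(`1` = c(1.50, 1.65), `2` = c(1.47, 1.58, 1.69)),
    beta_triclinic = list(`1` = c(1.37, 1.65, 1.70)),
    lamellar_2L = list(`1` = 0.15)
  )
  purrr::imap_dfr(entries, function(variants, poly) {
    purrr::imap_dfr(variants, function(qs, var) {
      tibble::tibble(polymorph = poly, variant = as.integer(var), q = qs,
                     d = 2 * pi / qs)
    })
  })
}

# rolling-min-then-mean baseline (log domain) interpolated at a probe q
local_baseline_at <- function(curve, q_probe, baseline_window = NULL) {
  sel <- !curve$masked
  q <- curve$q[sel]; i <- curve$intensity[sel]
  if (is.null(baseline_window)) {
    spacing <- mean(diff(q))
    baseline_window <- min(max(5L, as.integer(ceiling(0.15 / spacing))),
                           max(5L, length(q) %/% 3))
  }
  base_log <- roll_stat(roll_stat(log(i), baseline_window, min),
                        baseline_window, mean)
  exp(approx(log(q), base_log, xout = log(q_probe), rule = 2, ties = "ordered")$y)
}

# rolling window statistic with partial edge windows
roll_stat <- function(x, k, fun) {
  n <- length(x)
  h <- k %/% 2
  vapply(seq_len(n), function(i) {
    fun(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Detect peaks above a rolling baseline
#'
#' The baseline is estimated in log intensity by a rolling minimum followed
#' by a rolling mean over `baseline_window` points. A rolling-minimum
#' baseline tracks any feature broader than its window, so the window must
#' sit between the two width scales present in WAXS data: wider than the
#' crystal reflections (FWHM a few times 0.01 \eqn{\mathrm{\AA}^{-1}}),
#' narrower than the amorphous water halo centred near 2
#' \eqn{\mathrm{\AA}^{-1}} (FWHM about 0.7 \eqn{\mathrm{\AA}^{-1}}), which
#' is then absorbed into the baseline rather than reported. Local maxima
#' whose height above the baseline exceeds `min_prominence` times the local
#' baseline are reported, with the position refined by a 3-point parabola in
#' (q, log I) and an interpolated FWHM.
#'
#' @param curve A `scattering_curve`.
#' @param region Length-2 q-interval to search (default: whole curve).
#' @param min_prominence Minimum peak height as a fraction of the local
#'   baseline intensity.
#' @param baseline_window Width of the baseline window in points. Default:
#'   the number of points spanning 0.15 \eqn{\mathrm{\AA}^{-1}} (at least 5,
#'   at most a third of the region), between the crystal-peak and
#'   water-halo width scales.
#' @return Tibble with `q_position`, `d_spacing`, `height_above_baseline`,
#'   `width` (FWHM, \eqn{\mathrm{\AA}^{-1}}); zero rows when nothing exceeds
#'   the prominence threshold.
#' @export
find_peaks <- function(curve, region = range(curve$q), min_prominence = 0.2,
                       baseline_window = NULL) {
  region <- sort(region)
  if (region[1] < min(curve$q) * (1 - 1e-9) || region[2] > max(curve$q) * (1 + 1e-9)) {
    abort("`region` extends outside the curve's q-range.", class = "scatterprint_range_error")
  }
  sel <- curve$q >= region[1] & curve$q <= region[2] & !curve$masked
  q <- curve$q[sel]; i <- curve$intensity[sel]
  if (length(q) < 10L) abort("Fewer than 10 usable points in `region`.",
                             class = "scatterprint_format_error")
  if (is.null(baseline_window)) {
    spacing <- mean(diff(q))
    baseline_window <- min(max(5L, as.integer(ceiling(0.15 / spacing))),
                           max(5L, length(q) %/% 3))
  }
  li <- log(i)
  base_log <- roll_stat(roll_stat(li, baseline_window, min), baseline_window, mean)
  baseline <- exp(base_log)
  excess <- i - baseline
  is_max <- c(FALSE, diff(sign(diff(i))) < 0, FALSE) &
    excess > min_prominence * baseline
  idx <- which(is_max)
  idx <- idx[idx > 1 & idx < length(q)]
  if (length(idx) == 0) {
    return(tibble::tibble(q_position = numeric(), d_spacing = numeric(),
                          height_above_baseline = numeric(), width = numeric()))
  }
  rows <- purrr::map_dfr(idx, function(j) {
    # 3-point parabolic refinement in (q, log I)
    x <- q[(j - 1):(j + 1)]; y <- li[(j - 1):(j + 1)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
    q_pk <- if (a < 0) -b / (2 * a) else x[2]
    if (q_pk < x[1] || q_pk > x[3]) q_pk <- x[2]
    height <- excess[j]
    # FWHM of the excess-above-baseline profile around the peak
    half <- height / 2
    lo <- j; while (lo > 1 && excess[lo] > half) lo <- lo - 1
    hi <- j; while (hi < length(q) && excess[hi] > half) hi <- hi + 1
    q_lo <- if (lo < j) approx(excess[c(lo, lo + 1)], q[c(lo, lo + 1)], xout = half)$y else q[lo]
    q_hi <- if (hi > j) approx(excess[c(hi - 1, hi)], q[c(hi - 1, hi)], xout = half)$y else q[hi]
    tibble::tibble(q_position = q_pk, d_spacing = 2 * pi / q_pk,
                   height_above_baseline = height,
                   width = max(q_hi - q_lo, mean(diff(q)), na.rm = TRUE))
  })
  dplyr::arrange(rows, .data$q_position)
}

#' Assign triglyceride polymorphs to detected peak positions
#'
#' Each peak is matched against every catalogue reflection within
#' `tolerance`; a polymorph variant is flagged `supported` when *all* of its
#' catalogue positions are matched by some peak. Because 1.65
#' \eqn{\mathrm{\AA}^{-1}} occurs in both the beta and beta-prime sets,
#' several polymorphs can be supported simultaneously; the ambiguity is
#' surfaced rather than resolved. Unmatched peaks are labelled
#' `"unassigned"`.
#'
#' @param peaks Numeric vector of peak positions, or a tibble from
#'   [find_peaks()] with a `q_position` column.
#' @param catalogue Reference positions; default [polymorph_catalogue()].
#' @param tolerance Match tolerance, \eqn{\mathrm{\AA}^{-1}}. Default 0.03
#'   (about half the gap between the closest catalogue entries 1.47/1.50).
#' @return Tibble with one row per (peak, candidate) pair: `q_position`,
#'   `d_spacing`, `polymorph`, `variant`, `catalogue_q`, `match_distance`,
#'   `supported`.
#' @examples
#' assign_polymorph(c(1.37, 1.65, 1.70)) # beta (triclinic) supported
#' @export
assign_polymorph <- function(peaks, catalogue = polymorph_catalogue(), tolerance = 0.03) {
  if (tolerance < 0) abort("`tolerance` must be >= 0.", class = "scatterprint_domain_error")
  if (is.data.frame(peaks)) peaks <- peaks$q_position
  if (length(peaks) == 0) {
    return(tibble::tibble(q_position = numeric(), d_spacing = numeric(),
                          polymorph = character(), variant = integer(),
                          catalogue_q = numeric(), match_distance = numeric(),
                          supported = logical()))
  }
  # which variant sets are fully matched by the peak list
  support <- catalogue |>
    dplyr::group_by(.data$polymorph, .data$variant) |>
    dplyr::summarise(
      supported = all(vapply(.data$q, function(qq) any(abs(peaks - qq) <= tolerance), logical(1))),
      .groups = "drop"
    )
  purrr::map_dfr(peaks, function(pk) {
    hits <- catalogue[abs(catalogue$q - pk) <= tolerance, ]
    if (nrow(hits) == 0) {
      return(tibble::tibble(q_position = pk, d_spacing = 2 * pi / pk,
                            polymorph = "unassigned", variant = NA_integer_,
                            catalogue_q = NA_real_, match_distance = NA_real_,
                            supported = FALSE))
    }
    hits |>
      dplyr::left_join(support, by = c("polymorph", "variant")) |>
      dplyr::transmute(q_position = pk, d_spacing = 2 * pi / pk,
                       polymorph = .data$polymorph, variant = .data$variant,
                       catalogue_q = .data$q,
                       match_distance = abs(.data$q - pk),
                       supported = .data$supported)
  })
}
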
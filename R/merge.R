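# Log-log interpolation of a curve at arbitrary q, bridging masked points.
loglog_interp <- function(curve, q_out, rule = 1) {
  ok <- !curve$masked
  if (sum(ok) < 2L) abort("Curve has fewer than 2 unmasked points.",
                          class = "scatterprint_nodata_error")
  res <- approx(log(curve$q[ok]), log(curve$intensity[ok]), xout = log(q_out),
                rule = rule, ties = "ordered")
  exp(res$y)
}

# Interpolation of intensity linearly in log q (works with non-positive I).
logq_interp <- function(curve, q_out, rule = 1) {
  res <- approx(log(curve$q), curve$intensity, xout = log(q_out),
                rule = rule, ties = "ordered")
  res$y
}

#' Scale and merge a low-Q curve onto a high-Q curve
#'
#' Multi-configuration measurements (USAXS vs SAXS, SAXS at two detector
#' distances) are stitched by scaling the low-Q curve onto the high-Q curve:
#' the multiplicative factor minimising the squared log-intensity mismatch
#' over the overlap window is applied to the low-Q intensities, and the output
#' keeps the high-Q points inside the overlap. The default window,
#' 0.0052-0.0055 \eqn{\mathrm{\AA}^{-1}}, is where a Bonse-Hart USAXS range
#' meets a typical long-distance SAXS configuration.
#'
#' @param low_q,high_q `scattering_curve`s covering adjacent q-ranges; same
#'   intensity-unit flag.
#' @param overlap Length-2 numeric q-interval over which to fit the scale.
#' @return A merged `scattering_curve` spanning the union of the ranges, with
#'   attribute `scale_factor` (the factor applied to `low_q`).
#' @export
merge_curves <- function(low_q, high_q, overlap = c(0.0052, 0.0055)) {
  if (!identical(attr(low_q, "units"), attr(high_q, "units"))) {
    abort("Curves have different intensity-unit flags; merge is ill-defined.",
          class = "scatterprint_merge_error")
  }
  overlap <- sort(overlap)
  in_lo <- low_q$q >= overlap[1] & low_q$q <= overlap[2] & !low_q$masked
  in_hi <- high_q$q >= overlap[1] & high_q$q <= overlap[2] & !high_q$masked
  if (max(low_q$q) < min(high_q$q) || sum(in_lo) < 2L || sum(in_hi) < 2L) {
    abort("Fewer than 2 usable points from each curve inside the overlap window.",
          class = "scatterprint_merge_error")
  }
  q_ref <- low_q$q[in_lo]
  i_lo <- low_q$intensity[in_lo]
  i_hi <- loglog_interp(high_q, q_ref, rule = 2)
  if (any(i_lo <= 0) || any(i_hi <= 0)) {
    abort("Non-positive intensities in the overlap window; cannot fit a log-space scale.",
          class = "scatterprint_scaling_error")
  }
  # least squares in log space: log s = mean(log I_hi - log I_lo)
  scale_factor <- exp(mean(log(i_hi) - log(i_lo)))
  keep_lo <- low_q$q < overlap[1]
  merged <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(low_q)[keep_lo, ],
                  intensity = .data$intensity * scale_factor,
                  sigma = .data$sigma * scale_factor),
    tibble::as_tibble(high_q)[high_q$q >= overlap[1], ]
  )
  merged <- dplyr::arrange(merged, .data$q)
  merged <- merged[!duplicated(merged$q), ]
  out <- scattering_curve(merged$q, merged$intensity, sigma = merged$sigma,
                          technique = "merged",
                          smeared = attr(high_q, "smeared"),
                          slit_length = if (isTRUE(attr(high_q, "smeared"))) attr(high_q, "slit_length") else NULL,
                          sample_id = attr(high_q, "sample_id"),
                          units = attr(high_q, "units"))
  attr(out, "scale_factor") <- scale_factor
  out
}

#' Subtract a measured background from a sample curve
#'
#' Computes `intensity = sample - factor * background`, with the background
#' interpolated linearly in log q onto the sample grid. Uncertainties are
#' combined in quadrature where both are present. Points that become
#' non-positive are masked, not deleted, so later log-space stages treat them
#' as gaps.
#'
#' @param sample,background `scattering_curve`s; the background q-range must
#'   cover the sample's.
#' @param factor Transmission/thickness scale applied to the background.
#' @return A `scattering_curve` with the sample's metadata.
#' @export
subtract_background <- function(sample, background, factor = 1) {
  if (min(background$q) > min(sample$q) * (1 + 1e-9) ||
      max(background$q) < max(sample$q) * (1 - 1e-9)) {
    abort("Background q-range does not cover the sample q-range.",
          class = "scatterprint_coverage_error")
  }
  bg <- logq_interp(background, sample$q, rule = 2)
  intensity <- sample$intensity - factor * bg
  sigma <- sample$sigma
  if (any(is.finite(background$sigma))) {
    bg_sig <- approx(log(background$q), background$sigma, xout = log(sample$q),
                     rule = 2, ties = "ordered")$y
    sigma <- sqrt(ifelse(is.finite(sigma), sigma^2, 0) + (factor * bg_sig)^2)
  }
  out <- tibble::tibble(
    q = sample$q,
    intensity = intensity,
    sigma = sigma,
    masked = !is.finite(intensity) | intensity <= 0
  )
  new_scattering_curve(out, technique = attr(sample, "technique"),
                       smeared = attr(sample, "smeared"),
                       slit_length = attr(sample, "slit_length"),
                       sample_id = attr(sample, "sample_id"),
                       units = attr(sample, "units"))
}
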
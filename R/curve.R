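#' Construct a 1D scattering curve
#'
#' A scattering curve is a tibble with columns `q` (momentum transfer,
#' \eqn{\mathrm{\AA}^{-1}}, strictly increasing and positive), `intensity`
#' (scattered intensity, absolute \eqn{cm^{-1}} or arbitrary units) and
#' optionally `sigma` (per-point uncertainty, same units as the intensity).
#' Points with non-positive or non-finite intensity are retained but flagged
#' in a logical `masked` column, so that downstream log-space operations can
#' bridge them as gaps instead of failing.
#'
#' Metadata (technique, smearing geometry, intensity-unit flag, sample id)
#' travels as attributes rather than columns, mirroring how reduced-SAS file
#' headers carry it.
#'
#' @param q Momentum transfer values, \eqn{\mathrm{\AA}^{-1}}.
#' @param intensity Scattered intensities, one per `q`.
#' @param sigma Optional per-point uncertainties.
#' @param technique One of `"USAXS"`, `"SAXS"`, `"WAXS"`, `"merged"`.
#' @param smeared Logical; `TRUE` for slit-smeared (Bonse-Hart) data.
#' @param slit_length Slit half-length \eqn{L} in \eqn{\mathrm{\AA}^{-1}};
#'   required when `smeared = TRUE`.
#' @param sample_id Free-text sample identifier.
#' @param units `"absolute"` (\eqn{cm^{-1}}) or `"arbitrary"`.
#'
#' @return A tibble of class `scattering_curve`, sorted by `q`.
#' @examples
#' sc <- scattering_curve(q = c(0.01, 0.02, 0.04), intensity = c(100, 25, 6))
#' curve_meta(sc)
#' @export
scattering_curve <- function(q, intensity, sigma = NULL,
                             technique = c("SAXS", "USAXS", "WAXS", "merged"),
                             smeared = FALSE, slit_length = NULL,
                             sample_id = NA_character_,
                             units = c("absolute", "arbitrary")) {
  technique <- match.arg(technique)
  units <- match.arg(units)
  if (length(q) != length(intensity)) {
    abort("`q` and `intensity` must have equal length.", class = "scatterprint_format_error")
  }
  if (length(q) < 2L) {
    abort("A scattering curve needs at least 2 points.", class = "scatterprint_format_error")
  }
  keep <- is.finite(q)
  q <- q[keep]; intensity <- intensity[keep]
  if (!is.null(sigma)) sigma <- sigma[keep]
  ord <- order(q)
  q <- q[ord]; intensity <- intensity[ord]
  if (!is.null(sigma)) sigma <- sigma[ord]
  if (any(q <= 0)) abort("All q must be > 0.", class = "scatterprint_format_error")
  if (any(diff(q) <= 0)) abort("q values must be strictly increasing (duplicates present).",
                               class = "scatterprint_format_error")
  if (isTRUE(smeared) && (is.null(slit_length) || slit_length <= 0)) {
    abort("`slit_length` must be > 0 when `smeared = TRUE`.", class = "scatterprint_format_error")
  }
  out <- tibble::tibble(
    q = as.numeric(q),
    intensity = as.numeric(intensity),
    sigma = if (is.null(sigma)) NA_real_ else as.numeric(sigma),
    masked = !is.finite(intensity) | intensity <= 0
  )
  new_scattering_curve(out, technique = technique, smeared = isTRUE(smeared),
                       slit_length = slit_length, sample_id = sample_id, units = units)
}

new_scattering_curve <- function(df, technique, smeared, slit_length, sample_id, units) {
  structure(df,
            class = c("scattering_curve", class(tibble::tibble())),
            technique = technique, smeared = smeared,
            slit_length = if (is.null(slit_length)) NA_real_ else slit_length,
            sample_id = sample_id, units = units)
}

#' Coerce a data frame to a scattering curve
#'
#' @param data Data frame with columns `q` and `intensity` (optionally `sigma`).
#' @inheritParams scattering_curve
#' @return A `scattering_curve` tibble.
#' @export
as_scattering_curve <- function(data, technique = c("SAXS", "USAXS", "WAXS", "merged"),
                                smeared = FALSE, slit_length = NULL,
                                sample_id = NA_character_,
                                units = c("absolute", "arbitrary")) {
  if (!all(c("q", "intensity") %in% names(data))) {
    abort("`data` needs columns `q` and `intensity`.", class = "scatterprint_format_error")
  }
  scattering_curve(data$q, data$intensity, sigma = data[["sigma"]],
                   technique = technique, smeared = smeared, slit_length = slit_length,
                   sample_id = sample_id, units = match.arg(units))
}

#' Curve metadata
#'
#' @param curve A `scattering_curve`.
#' @return One-row tibble with technique, smearing geometry, units and sample id.
#' @export
curve_meta <- function(curve) {
  tibble::tibble(
    sample_id = attr(curve, "sample_id"),
    technique = attr(curve, "technique"),
    smeared = attr(curve, "smeared"),
    slit_length = attr(curve, "slit_length"),
    units = attr(curve, "units"),
    n = nrow(curve),
    q_min = min(curve$q),
    q_max = max(curve$q)
  )
}

#' @export
print.scattering_curve <- function(x, ...) {
  m <- curve_meta(x)
  cat(sprintf("<scattering_curve> %s%s, %d points, q %.3g-%.3g 1/A, %s units\n",
              m$technique, if (m$smeared) " (slit-smeared)" else "",
              m$n, m$q_min, m$q_max, m$units))
  NextMethod()
}

#' Read a 1D reduced scattering curve from a text file
#'
#' Accepts the common reduced-SAS export dialects: whitespace- or
#' comma-separated numeric columns with `#` comment lines. Column meaning is
#' auto-detected unless given: 2 columns are (q, I), 3 are (q, I, sigma);
#' extra columns are ignored with a warning. Rows with non-finite q are
#' dropped; the result is sorted by q.
#'
#' @param path File path.
#' @param dialect Optional character vector naming the columns in file order,
#'   from `"q"`, `"intensity"`, `"sigma"`, `"skip"`. `NULL` auto-detects.
#' @inheritParams scattering_curve
#' @return A `scattering_curve`.
#' @export
read_curve <- function(path, dialect = NULL,
                       technique = c("SAXS", "USAXS", "WAXS", "merged"),
                       smeared = FALSE, slit_length = NULL,
                       sample_id = NA_character_,
                       units = c("absolute", "arbitrary")) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "scatterprint_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(data_lines) == 0L) {
    abort(paste0("No data rows in ", path), class = "scatterprint_format_error")
  }
  sep <- if (grepl(",", data_lines[1])) "," else ""
  raw <- tryCatch(
    read.table(path, comment.char = "#", sep = sep, header = FALSE,
               colClasses = "character", blank.lines.skip = TRUE,
               strip.white = TRUE),
    error = function(e) abort(paste0("Unreadable curve file ", path, ": ", conditionMessage(e)),
                              class = "scatterprint_io_error")
  )
  if (ncol(raw) < 2L) {
    abort(paste0("Curve file ", path, " has fewer than 2 columns."),
          class = "scatterprint_format_error")
  }
  num <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  bad <- which(!is.na(raw[[1]]) & nzchar(raw[[1]]) & is.na(num[[1]]) |
                 !is.na(raw[[2]]) & nzchar(raw[[2]]) & is.na(num[[2]]))
  if (length(bad) > 0) {
    abort(sprintf("Non-numeric data in %s (data row %d: '%s').",
                  path, bad[1], paste(unlist(raw[bad[1], ]), collapse = " ")),
          class = "scatterprint_format_error")
  }
  if (is.null(dialect)) {
    dialect <- switch(min(ncol(raw), 3L), NULL, c("q", "intensity"), c("q", "intensity", "sigma"))
    if (ncol(raw) > 3L) {
      warn(sprintf("%s: %d columns found; using the first three as (q, I, sigma).",
                   path, ncol(raw)))
    }
  }
  cols <- setNames(seq_along(dialect), dialect)
  q <- num[[cols[["q"]]]]
  intensity <- num[[cols[["intensity"]]]]
  sigma <- if ("sigma" %in% names(cols)) num[[cols[["sigma"]]]] else NULL
  keep <- is.finite(q)
  if (sum(keep) < 2L) {
    abort(paste0("Fewer than 2 valid data rows in ", path), class = "scatterprint_format_error")
  }
  scattering_curve(q[keep], intensity[keep], sigma = sigma[keep],
                   technique = technique, smeared = smeared, slit_length = slit_length,
                   sample_id = sample_id, units = match.arg(units))
}

#' Write a scattering curve to a plain-text file
#'
#' Writes full double precision so that `read_curve(write_curve(x))`
#' round-trips exactly.
#'
#' @param curve A `scattering_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  m <- curve_meta(curve)
  header <- c(
    sprintf("# sample_id: %s", m$sample_id),
    sprintf("# technique: %s", m$technique),
    sprintf("# smeared: %s", m$smeared),
    sprintf("# slit_length: %.17g", m$slit_length),
    sprintf("# units: %s", m$units),
    "# columns: q intensity sigma"
  )
  has_sigma <- any(is.finite(curve$sigma))
  body <- if (has_sigma) {
    sprintf("%.17g %.17g %.17g", curve$q, curve$intensity, curve$sigma)
  } else {
    sprintf("%.17g %.17g", curve$q, curve$intensity)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Convert scattering angle to momentum transfer
#'
#' \eqn{Q = (4\pi/\lambda)\,\sin(\theta/2)} with the full scattering angle
#' \eqn{\theta} in degrees and wavelength \eqn{\lambda} in \eqn{\mathrm{\AA}}.
#'
#' @param theta Scattering angle(s), degrees, in \[0, 180\].
#' @param wavelength Radiation wavelength, \eqn{\mathrm{\AA}} (Cu K-alpha: 1.54).
#' @return Momentum transfer, \eqn{\mathrm{\AA}^{-1}}.
#' @examples
#' q_from_angle(28.4, 1.54) # about 2 1/A
#' @export
q_from_angle <- function(theta, wavelength = 1.54) {
  if (wavelength <= 0) abort("`wavelength` must be > 0.", class = "scatterprint_domain_error")
  if (any(theta < 0 | theta > 180)) {
    abort("`theta` must lie in [0, 180] degrees.", class = "scatterprint_domain_error")
  }
  (4 * pi / wavelength) * sin(theta * pi / 360)
}

#' Read a product composition table
#'
#' Expects a CSV with header columns `number`, `sample`, `fat`,
#' `carbohydrate`, `protein`, `category`, `material`; mass fractions in
#' percent w/w.
#'
#' @param path CSV file path.
#' @return A tibble with one row per product.
#' @export
read_composition_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path), class = "scatterprint_io_error")
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(trimws(first))) {
    warn(paste0("Empty composition table: ", path))
    return(tibble::tibble(number = integer(), sample = character(),
                          fat = numeric(), carbohydrate = numeric(), protein = numeric(),
                          category = character(), material = character()))
  }
  df <- read.table(path, sep = ",", header = TRUE, strip.white = TRUE,
                   stringsAsFactors = FALSE)
  names(df) <- tolower(trimws(names(df)))
  required <- c("number", "sample", "fat", "carbohydrate", "protein", "category", "material")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("Composition table missing column(s): ", paste(missing, collapse = ", ")),
          class = "scatterprint_schema_error")
  }
  out <- tibble::as_tibble(df[required])
  out$number <- as.integer(out$number)
  for (col in c("fat", "carbohydrate", "protein")) {
    v <- as.numeric(out[[col]])
    if (any(!is.finite(v) | v < 0 | v > 100)) {
      abort(sprintf("Column '%s' has mass fractions outside [0, 100] %% w/w.", col),
            class = "scatterprint_validation_error")
    }
    out[[col]] <- v
  }
  if (any(out$fat + out$carbohydrate + out$protein > 100)) {
    abort("fat + carbohydrate + protein exceeds 100% w/w for some rows.",
          class = "scatterprint_validation_error")
  }
  out
}
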
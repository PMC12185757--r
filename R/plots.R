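#' Log-log plot of one or more scattering curves
#'
#' @param object A `scattering_curve`.
#' @param ... Further `scattering_curve`s to overlay.
#' @return A ggplot object (log-log axes; masked points dropped).
#' @export
autoplot.scattering_curve <- function(object, ...) {
  curves <- c(list(object), purrr::keep(list(...), inherits, "scattering_curve"))
  ids <- purrr::imap_chr(curves, function(cv, i) {
    id <- attr(cv, "sample_id")
    if (is.null(id) || is.na(id)) paste0(attr(cv, "technique"), " ", i) else id
  })
  dat <- purrr::map2_dfr(curves, ids, function(cv, id) {
    dplyr::mutate(dplyr::filter(tibble::as_tibble(cv), !.data$masked), sample = id)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$q, y = .data$intensity,
                                    colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ (ring(A)^-1)), y = expression(I ~ (cm^-1)))
}

#' @rdname autoplot.scattering_curve
#' @param x A `scattering_curve`.
#' @param y Unused.
#' @export
plot.scattering_curve <- function(x, y, ...) print(autoplot(x, ...))
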
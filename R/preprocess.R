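#' Standard normal variate (SNV) normalisation
#'
#' Transforms each spectrum (row) to zero mean and unit standard deviation
#' (`n - 1` denominator), removing per-sample multiplicative scatter and
#' additive offset. SNV is invariant to `a * x + b` for `a > 0`.
#'
#' @param spectra A spectra tibble.
#' @return A spectra tibble on the same grid with SNV-corrected rows.
#' @export
#' @examples
#' sp <- generate_spectra(synthetic_config())
#' snv(sp)
snv <- function(spectra) {
  spectra <- as_spectra(spectra)
  m <- spectra_matrix(spectra)
  if (ncol(m) < 2) abort_size("SNV needs at least 2 channels per spectrum")
  mu <- rowMeans(m)
  sdev <- apply(m, 1, stats::sd)
  bad <- which(sdev == 0)
  if (length(bad) > 0) {
    abort_degenerate(sprintf(
      "constant spectrum (zero spread), cannot SNV-normalise: %s",
      paste(spectra$sample_id[bad], collapse = ", ")))
  }
  set_spectra_matrix(spectra, (m - mu) / sdev)
}

#' Savitzky-Golay first-derivative filtering
#'
#' Applies a Savitzky-Golay local-polynomial first-derivative filter to each
#' spectrum, in absorbance-per-channel units. Output length equals input
#' length; boundary values come from the polynomial fits on the edge
#' windows, so a strictly linear spectrum yields its exact slope everywhere.
#' Defaults (window 11, polynomial order 2) are standard chemometric
#' practice.
#'
#' @param spectra A spectra tibble.
#' @param window Odd filter window length in channels; must be at least
#'   `polyorder + 2` and no longer than the spectrum.
#' @param polyorder Polynomial order (`>= 1`).
#' @return A spectra tibble of first derivatives on the same grid.
#' @export
sg_derivative <- function(spectra, window = 11L, polyorder = 2L) {
  spectra <- as_spectra(spectra)
  check_sg_params(window, polyorder)
  m <- spectra_matrix(spectra)
  if (ncol(m) < window) {
    abort_size(sprintf("window (%d) exceeds channel count (%d)", window, ncol(m)))
  }
  d <- t(apply(m, 1, function(r) {
    signal::sgolayfilt(r, p = polyorder, n = window, m = 1, ts = 1)
  }))
  set_spectra_matrix(spectra, d)
}

check_sg_params <- function(window, polyorder) {
  if (polyorder < 1) abort_config("`polyorder` must be >= 1")
  if (window %% 2 == 0 || window < polyorder + 2) {
    abort_config("`window` must be odd and at least `polyorder + 2`")
  }
  invisible(TRUE)
}

#' One-pass preprocessing pipeline
#'
#' Applies the standard preprocessing for this workflow in a fixed order:
#' SNV first, then the Savitzky-Golay first derivative. Running the
#' derivative stage more than once would change the signal's meaning, so the
#' pipeline is single-pass by construction: call it once on raw spectra.
#'
#' @inheritParams sg_derivative
#' @param apply_snv Apply SNV before the derivative?
#' @param derivative Apply the first-derivative filter?
#' @return A preprocessed spectra tibble.
#' @export
#' @examples
#' synthetic_config() |>
#'   generate_spectra() |>
#'   preprocess()
preprocess <- function(spectra, apply_snv = TRUE, derivative = TRUE,
                       window = 11L, polyorder = 2L) {
  spectra <- as_spectra(spectra)
  if (apply_snv) spectra <- snv(spectra)
  if (derivative) spectra <- sg_derivative(spectra, window, polyorder)
  spectra
}

#' Per-class mean and standard-deviation spectra
#'
#' Summarises each class by its channel-wise mean and sample standard
#' deviation (`n - 1`), the usual population-overview figure for a
#' two-class spectral dataset.
#'
#' @param spectra A spectra tibble with at least two samples per class.
#' @return A long tibble with columns `label`, `wavenumber`, `mean`, `sd`.
#' @export
class_summary <- function(spectra) {
  spectra <- as_spectra(spectra)
  wn <- spectra_wavenumbers(spectra)
  m <- spectra_matrix(spectra)
  labs <- spectra_labels(spectra)
  purrr::map_dfr(sort(unique(labs)), function(cl) {
    rows <- m[labs == cl, , drop = FALSE]
    if (nrow(rows) < 2) {
      abort_size(sprintf("class %d has fewer than 2 samples", cl))
    }
    tibble::tibble(
      label = cl,
      wavenumber = wn,
      mean = unname(colMeans(rows)),
      sd = unname(apply(rows, 2, stats::sd))
    )
  })
}

#' Plot class mean spectra with a +/- 1 sd ribbon
#'
#' @param spectra A spectra tibble.
#' @return A ggplot object.
#' @export
plot_class_summary <- function(spectra) {
  s <- class_summary(spectra)
  s$class <- factor(s$label, levels = c(1, 2), labels = c("cancerous", "normal"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$wavenumber, y = .data$mean,
                                  colour = .data$class, fill = .data$class)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "absorbance, log(1/R) (a.u.)")
}
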
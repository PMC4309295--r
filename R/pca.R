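#' Principal component exploration of a spectra set
#'
#' Column-mean-centred PCA (no variance scaling, the usual choice for
#' spectra) retaining the first `n_components` components. Component signs
#' follow a fixed convention -- the largest-magnitude element of each
#' loading is positive -- so scores are reproducible across runs.
#'
#' @param spectra A spectra tibble.
#' @param n_components Number of components to retain; at most
#'   `min(N - 1, K)`.
#' @return A `spectra_pca` object: `scores` (tibble with `sample_id`,
#'   `label`, `PC1` ...), `explained_fraction` (per retained component),
#'   `loadings` (`n_components` x K matrix), `wavenumbers`, `center`, and
#'   `all_variances` (all K eigenvalues, for completeness checks).
#' @export
#' @examples
#' sp <- generate_spectra(synthetic_config())
#' fit <- pca_spectra(preprocess(sp), n_components = 3)
#' glance(fit)
pca_spectra <- function(spectra, n_components = 3L) {
  spectra <- as_spectra(spectra)
  m <- spectra_matrix(spectra)
  n_max <- min(nrow(m) - 1L, ncol(m))
  if (n_components < 1 || n_components > n_max) {
    abort_size(sprintf("`n_components` must be in 1..%d (min(N - 1, K))", n_max))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| element positive
  for (j in seq_len(n_components)) {
    piv <- which.max(abs(rot[, j]))
    if (rot[piv, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vars <- pc$sdev^2
  out <- list(
    scores = dplyr::bind_cols(
      tibble::tibble(sample_id = spectra$sample_id, label = spectra$label),
      tibble::as_tibble(scores, .name_repair = "minimal")
    ),
    explained_fraction = vars[seq_len(n_components)] / sum(vars),
    loadings = t(rot),
    wavenumbers = spectra_wavenumbers(spectra),
    center = pc$center,
    all_variances = vars
  )
  class(out) <- "spectra_pca"
  out
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(sprintf(
    "PCA of %d spectra, %d components retained (%.1f%% of variance)\n",
    nrow(x$scores), length(x$explained_fraction),
    100 * sum(x$explained_fraction)))
  invisible(x)
}

#' Tidiers for `spectra_pca` objects
#'
#' `tidy()` returns per-component statistics (explained variance fractions),
#' `glance()` a one-row model summary.
#'
#' @param x A `spectra_pca` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy spectra_pca
#' @export
tidy.spectra_pca <- function(x, ...) {
  m <- length(x$explained_fraction)
  tibble::tibble(
    component = seq_len(m),
    variance = x$all_variances[seq_len(m)],
    explained_fraction = x$explained_fraction,
    cumulative_fraction = cumsum(x$explained_fraction)
  )
}

#' @rdname tidy.spectra_pca
#' @method glance spectra_pca
#' @export
glance.spectra_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_channels = length(x$wavenumbers),
    n_components = length(x$explained_fraction),
    total_explained_fraction = sum(x$explained_fraction)
  )
}

#' Score plot of the first two principal components
#'
#' @param object A `spectra_pca` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectra_pca
#' @export
autoplot.spectra_pca <- function(object, ...) {
  sc <- object$scores
  sc$class <- factor(sc$label, levels = c(1, 2),
                     labels = c("cancerous", "normal"))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_fraction[2]))
}

#' Write PCA scores to CSV
#'
#' The scores table (`sample_id`, `label`, PC columns) is written as plain
#' CSV; explained-variance fractions go into a `#`-prefixed header comment.
#'
#' @param x A `spectra_pca` object.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_pca_scores <- function(x, path) {
  hdr <- sprintf("# explained_fraction: %s",
                 paste(format(x$explained_fraction, digits = 10), collapse = ", "))
  writeLines(hdr, path)
  readr::write_csv(x$scores, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(x)
}
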
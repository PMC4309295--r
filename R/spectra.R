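#' Build a spectra tibble
#'
#' The central container of the package is an ordinary wide tibble with one
#' row per spectrum: a `sample_id` character column, an integer `label`
#' column (1 = cancerous, 2 = normal) and one numeric absorbance column per
#' wavenumber, named by the wavenumber in cm^-1 (e.g. `"4000"`, `"4004"`,
#' ...). Absorbance is on the log(1/R) scale, R being diffuse reflectance.
#' All verbs in the package take such a tibble first and return one, so
#' pipelines chain with the pipe.
#'
#' @param wavenumbers Strictly increasing numeric vector of wavenumbers
#'   (cm^-1).
#' @param absorbance Numeric matrix, one row per sample, `length(wavenumbers)`
#'   columns, log(1/R) absorbance units.
#' @param labels Integer vector of class codes, one per sample, drawn from
#'   `{1, 2}` (1 = cancerous, 2 = normal).
#' @param sample_ids Character vector of unique sample identifiers; generated
#'   as `"s001"`, `"s002"`, ... when omitted.
#'
#' @return A `spectra_tbl`: a tibble with columns `sample_id`, `label`, then
#'   one column per wavenumber.
#' @export
#' @examples
#' wn <- seq(4000, 4040, by = 4)
#' x <- matrix(rnorm(22), nrow = 2)
#' new_spectra(wn, x, labels = c(1L, 2L))
new_spectra <- function(wavenumbers, absorbance, labels, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%03d", seq_len(nrow(absorbance)))
  }
  out <- tibble::tibble(
    sample_id = as.character(sample_ids),
    label = as.integer(labels)
  )
  ab <- tibble::as_tibble(absorbance, .name_repair = "minimal")
  names(ab) <- format_wavenumber(wavenumbers)
  out <- dplyr::bind_cols(out, ab)
  validate_spectra(out)
}

format_wavenumber <- function(wn) {
  format(wn, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

#' Coerce a data frame to a spectra tibble
#'
#' Checks the invariants of the container: `sample_id` and `label` columns
#' followed by numeric wavenumber columns in strictly increasing order, no
#' non-finite absorbance values, labels in `{1, 2}`, unique sample ids.
#'
#' @param x A data frame shaped as described in [new_spectra()].
#' @return The validated tibble, classed `spectra_tbl`.
#' @export
as_spectra <- function(x) {
  validate_spectra(tibble::as_tibble(x))
}

validate_spectra <- function(x) {
  if (!all(c("sample_id", "label") %in% names(x))) {
    rlang::abort("spectra tibble needs `sample_id` and `label` columns",
      class = "nirspa_input_error")
  }
  wn <- spectra_wavenumbers(x)
  if (length(wn) < 1 || anyNA(wn)) {
    rlang::abort("wavenumber column names must parse as numbers",
      class = "nirspa_input_error")
  }
  if (any(diff(wn) <= 0)) {
    rlang::abort("wavenumbers must be strictly increasing",
      class = "nirspa_input_error")
  }
  m <- spectra_matrix(x)
  if (!all(is.finite(m))) {
    rlang::abort("absorbance values must all be finite",
      class = "nirspa_input_error")
  }
  if (!all(x$label %in% c(1L, 2L))) {
    rlang::abort("labels must be drawn from {1, 2} (1 = cancer, 2 = normal)",
      class = "nirspa_input_error")
  }
  if (anyDuplicated(x$sample_id)) {
    rlang::abort("sample ids must be unique", class = "nirspa_input_error")
  }
  class(x) <- unique(c("spectra_tbl", class(x)))
  x
}

#' Accessors for a spectra tibble
#'
#' `spectra_wavenumbers()` returns the numeric wavenumber grid,
#' `spectra_matrix()` the samples-by-channels absorbance matrix (rownames =
#' sample ids), `spectra_labels()` the integer class codes.
#'
#' @param x A spectra tibble.
#' @return A numeric vector, matrix, or integer vector respectively.
#' @export
spectra_wavenumbers <- function(x) {
  chan <- setdiff(names(x), c("sample_id", "label"))
  suppressWarnings(as.numeric(chan))
}

#' @rdname spectra_wavenumbers
#' @export
spectra_matrix <- function(x) {
  chan <- setdiff(names(x), c("sample_id", "label"))
  m <- as.matrix(x[chan])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

#' @rdname spectra_wavenumbers
#' @export
spectra_labels <- function(x) {
  as.integer(x$label)
}

# Rebuild a spectra tibble from x with a replaced absorbance matrix (same
# grid) -- used by the per-spectrum transforms.
set_spectra_matrix <- function(x, m) {
  chan <- setdiff(names(x), c("sample_id", "label"))
  x[chan] <- tibble::as_tibble(m, .name_repair = "minimal")
  x
}

#' Read and write spectra as delimited text
#'
#' The on-disk form is a plain CSV whose header row carries `sample_id`,
#' `label`, then the wavenumbers; one row per spectrum. The round trip is
#' lossless to full double precision.
#'
#' @param path File path.
#' @return `read_spectra()` returns a spectra tibble; `write_spectra()`
#'   returns `x` invisibly.
#' @export
read_spectra <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  x$label <- as.integer(x$label)
  as_spectra(x)
}

#' @rdname read_spectra
#' @param x A spectra tibble.
#' @export
write_spectra <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' @export
print.spectra_tbl <- function(x, ...) {
  wn <- spectra_wavenumbers(x)
  cat(sprintf(
    "# NIR spectra: %d samples x %d channels (%s-%s cm^-1), %d cancerous / %d normal\n",
    nrow(x), length(wn), format_wavenumber(min(wn)), format_wavenumber(max(wn)),
    sum(x$label == 1L), sum(x$label == 2L)))
  NextMethod()
}
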
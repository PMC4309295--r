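#' Configuration for the synthetic NIR spectrum generator
#'
#' Describes a two-class population of log(1/R) NIR spectra on a uniform
#' wavenumber grid. Each spectrum is a sum of broad Gaussian bands shared by
#' both classes, plus (for class 1, cancerous) a set of class-difference
#' bands, distorted by a per-sample multiplicative scatter ramp and additive
#' offset, with i.i.d. Gaussian noise on top. The defaults emulate the study
#' conditions of a colorectal-tissue NIR screen: a 4000-10000 cm^-1 grid at
#' 4 cm^-1 spacing (1501 channels), broad overlapping bands, strong
#' inter-channel collinearity, a small number of class-informative bands,
#' and three subsets of 26 cancerous + 36 normal spectra.
#'
#' @param wavenumber_start,wavenumber_end,step Grid limits and spacing in
#'   cm^-1; endpoints inclusive.
#' @param shared_bands Data frame with columns `center` (cm^-1), `width`
#'   (Gaussian sd, cm^-1) and `amplitude` (absorbance a.u.): bands common to
#'   both classes.
#' @param class_delta_bands Same shape: bands added to class 1 (cancerous)
#'   spectra only, i.e. the planted class signal. May have zero rows.
#' @param scatter_slope_sd,scatter_offset_sd Standard deviations of the
#'   per-sample multiplicative ramp slope and additive offset
#'   (dimensionless / a.u.); both zero gives scatter-free spectra.
#' @param noise_sd Standard deviation of i.i.d. additive Gaussian channel
#'   noise (absorbance a.u.).
#' @param n_per_class_per_subset Data frame with columns `subset`,
#'   `cancerous`, `normal`: per-subset class counts. The generator pools all
#'   subsets; [split_subsets()] recovers them.
#' @param seed Integer seed making generation deterministic.
#'
#' @return A `synthetic_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(noise_sd = 0.002)
#' cfg$n_per_class_per_subset
synthetic_config <- function(wavenumber_start = 4000,
                             wavenumber_end = 10000,
                             step = 4,
                             shared_bands = default_shared_bands(),
                             class_delta_bands = default_delta_bands(),
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.05,
                             noise_sd = 0.005,
                             n_per_class_per_subset = default_subset_counts(),
                             seed = 1L) {
  cfg <- list(
    wavenumber_start = wavenumber_start,
    wavenumber_end = wavenumber_end,
    step = step,
    shared_bands = tibble::as_tibble(shared_bands),
    class_delta_bands = tibble::as_tibble(class_delta_bands),
    scatter_slope_sd = scatter_slope_sd,
    scatter_offset_sd = scatter_offset_sd,
    noise_sd = noise_sd,
    n_per_class_per_subset = tibble::as_tibble(n_per_class_per_subset),
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

#' @rdname synthetic_config
#' @export
default_shared_bands <- function() {
  tibble::tibble(
    center    = c(4400, 5200, 6000, 7100, 8600),
    width     = c(250, 350, 400, 500, 600),
    amplitude = c(0.90, 0.70, 0.50, 0.45, 0.30)
  )
}

#' @rdname synthetic_config
#' @export
default_delta_bands <- function() {
  tibble::tibble(
    center    = c(4065, 4173, 5758),
    width     = c(40, 40, 40),
    amplitude = c(0.030, 0.025, 0.020)
  )
}

#' @rdname synthetic_config
#' @export
default_subset_counts <- function() {
  tibble::tibble(
    subset = c("training", "validation", "test"),
    cancerous = c(26L, 26L, 26L),
    normal = c(36L, 36L, 36L)
  )
}

validate_synthetic_config <- function(cfg) {
  if (!isTRUE(cfg$wavenumber_end > cfg$wavenumber_start)) {
    abort_config("`wavenumber_end` must exceed `wavenumber_start`")
  }
  if (!isTRUE(cfg$step > 0)) abort_config("`step` must be positive")
  for (nm in c("shared_bands", "class_delta_bands")) {
    b <- cfg[[nm]]
    if (nrow(b) > 0) {
      if (!all(c("center", "width", "amplitude") %in% names(b))) {
        abort_config(sprintf("`%s` needs center/width/amplitude columns", nm))
      }
      if (any(b$width <= 0)) abort_config(sprintf("`%s` widths must be positive", nm))
    }
  }
  if (!isTRUE(cfg$noise_sd >= 0)) abort_config("`noise_sd` must be non-negative")
  if (!isTRUE(cfg$scatter_slope_sd >= 0) || !isTRUE(cfg$scatter_offset_sd >= 0)) {
    abort_config("scatter standard deviations must be non-negative")
  }
  cnt <- cfg$n_per_class_per_subset
  if (!all(c("cancerous", "normal") %in% names(cnt)) || nrow(cnt) < 1) {
    abort_config("`n_per_class_per_subset` needs cancerous/normal columns")
  }
  if (any(cnt$cancerous <= 0) || any(cnt$normal <= 0)) {
    abort_config("`n_per_class_per_subset` counts must be positive")
  }
  cfg
}

#' Wavenumber grid and noise-free class-difference spectrum of a config
#'
#' `synthetic_grid()` returns the inclusive uniform grid;
#' `class_difference_spectrum()` evaluates the planted class-1-minus-class-2
#' mean difference on it (zero everywhere when no delta bands are planted).
#'
#' @param config A [synthetic_config()].
#' @return Numeric vector over the grid.
#' @export
synthetic_grid <- function(config) {
  seq(config$wavenumber_start, config$wavenumber_end, by = config$step)
}

#' @rdname synthetic_grid
#' @export
class_difference_spectrum <- function(config) {
  eval_bands(config$class_delta_bands, synthetic_grid(config))
}

# Sum of Gaussian bands evaluated on a wavenumber grid.
eval_bands <- function(bands, wn) {
  out <- numeric(length(wn))
  if (is.null(bands) || nrow(bands) == 0) return(out)
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amplitude[i] *
      exp(-(wn - bands$center[i])^2 / (2 * bands$width[i]^2))
  }
  out
}

#' Generate synthetic two-class NIR spectra
#'
#' Draws all subsets' samples pooled into one spectra tibble: each spectrum
#' is `(shared bands + class-1 delta bands) * (1 + slope * t) + offset +
#' noise`, with `t` the grid coordinate normalised to `[0, 1]`, `slope` and
#' `offset` per-sample Gaussian scatter draws, and `noise` i.i.d. Gaussian
#' per channel. Deterministic given `config$seed`. Use [split_subsets()] to
#' recover training/validation/test subsets.
#'
#' @param config A [synthetic_config()].
#' @return A spectra tibble with all cancerous samples followed by all
#'   normal samples.
#' @export
#' @examples
#' sp <- generate_spectra(synthetic_config())
#' dim(spectra_matrix(sp))
generate_spectra <- function(config) {
  config <- validate_synthetic_config(config)
  wn <- synthetic_grid(config)
  t_norm <- (wn - min(wn)) / (max(wn) - min(wn))
  n1 <- sum(config$n_per_class_per_subset$cancerous)
  n2 <- sum(config$n_per_class_per_subset$normal)
  labels <- c(rep(1L, n1), rep(2L, n2))
  base1 <- eval_bands(config$shared_bands, wn) + eval_bands(config$class_delta_bands, wn)
  base2 <- eval_bands(config$shared_bands, wn)
  with_seed(config$seed, {
    n <- n1 + n2
    slopes <- stats::rnorm(n, 0, config$scatter_slope_sd)
    offsets <- stats::rnorm(n, 0, config$scatter_offset_sd)
    m <- matrix(0, nrow = n, ncol = length(wn))
    for (i in seq_len(n)) {
      base <- if (labels[i] == 1L) base1 else base2
      m[i, ] <- base * (1 + slopes[i] * t_norm) + offsets[i]
    }
    if (config$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(n * length(wn), 0, config$noise_sd),
                      nrow = n)
    }
    new_spectra(wn, m, labels)
  })
}

#' Split pooled spectra into stratified subsets
#'
#' Randomly partitions a pooled spectra tibble into disjoint subsets with
#' exactly the requested per-class counts (stratified by class), e.g. into
#' the training / validation / test design of 26 cancerous + 36 normal
#' spectra each. Deterministic given `seed`.
#'
#' @param spectra A spectra tibble.
#' @param counts Data frame with columns `cancerous` and `normal` (and
#'   optionally `subset` names), one row per subset. Requested counts must
#'   not exceed availability per class.
#' @param seed Integer seed for the random assignment.
#' @return A named list of spectra tibbles, one per row of `counts`
#'   (`training`, `validation`, `test` when three unnamed subsets are
#'   requested).
#' @export
#' @examples
#' sp <- generate_spectra(synthetic_config())
#' subs <- split_subsets(sp, seed = 42)
#' vapply(subs, nrow, integer(1))
split_subsets <- function(spectra, counts = default_subset_counts(), seed = 1L) {
  spectra <- as_spectra(spectra)
  counts <- tibble::as_tibble(counts)
  if (!all(c("cancerous", "normal") %in% names(counts))) {
    abort_input("`counts` needs `cancerous` and `normal` columns")
  }
  nms <- if ("subset" %in% names(counts)) {
    as.character(counts$subset)
  } else if (nrow(counts) == 3) {
    c("training", "validation", "test")
  } else {
    sprintf("subset_%d", seq_len(nrow(counts)))
  }
  avail1 <- which(spectra$label == 1L)
  avail2 <- which(spectra$label == 2L)
  if (sum(counts$cancerous) > length(avail1) || sum(counts$normal) > length(avail2)) {
    abort_size(sprintf(
      "requested %d cancerous / %d normal but only %d / %d available",
      sum(counts$cancerous), sum(counts$normal), length(avail1), length(avail2)))
  }
  with_seed(seed, {
    ord1 <- sample(avail1)
    ord2 <- sample(avail2)
    out <- vector("list", nrow(counts))
    at1 <- 0L; at2 <- 0L
    for (i in seq_len(nrow(counts))) {
      take1 <- ord1[seq_len(counts$cancerous[i]) + at1]
      take2 <- ord2[seq_len(counts$normal[i]) + at2]
      at1 <- at1 + counts$cancerous[i]
      at2 <- at2 + counts$normal[i]
      idx <- sort(c(take1, take2))
      out[[i]] <- as_spectra(spectra[idx, , drop = FALSE])
    }
    names(out) <- nms
    out
  })
}

#' Bayes accuracy of the generating model
#'
#' For a scatter-free configuration (`scatter_slope_sd = scatter_offset_sd =
#' 0`) the two classes are Gaussian with a common isotropic covariance
#' `noise_sd^2 * I` and mean difference equal to the planted delta-band
#' spectrum `d`. The optimal classifier then has closed-form accuracy
#' `pi1 * Phi(D/2 - log(pi2/pi1)/D) + pi2 * Phi(D/2 + log(pi2/pi1)/D)` with
#' `D = ||d|| / noise_sd` and class priors `pi1`, `pi2` taken from the
#' configured class counts. Used as the analytic reference that fitted
#' classifiers are compared against on large synthetic test sets.
#'
#' @param config A [synthetic_config()] with both scatter sds zero.
#' @param priors Optional length-2 vector of class priors (cancerous,
#'   normal); defaults to the configured class counts. Supply `c(.5, .5)`
#'   when scoring against a balanced test set.
#' @return Bayes accuracy as a fraction in `[0.5, 1]`.
#' @export
bayes_accuracy <- function(config, priors = NULL) {
  config <- validate_synthetic_config(config)
  if (config$scatter_slope_sd != 0 || config$scatter_offset_sd != 0) {
    abort_config("closed-form Bayes accuracy requires both scatter sds to be zero")
  }
  if (is.null(priors)) {
    n1 <- sum(config$n_per_class_per_subset$cancerous)
    n2 <- sum(config$n_per_class_per_subset$normal)
    priors <- c(n1, n2) / (n1 + n2)
  }
  pi1 <- priors[1] / sum(priors)
  pi2 <- 1 - pi1
  d <- class_difference_spectrum(config)
  nd <- sqrt(sum(d^2))
  if (nd == 0) return(max(pi1, pi2))
  if (config$noise_sd == 0) return(1)
  D <- nd / config$noise_sd
  lr <- log(pi2 / pi1)
  pi1 * stats::pnorm(D / 2 - lr / D) + pi2 * stats::pnorm(D / 2 + lr / D)
}
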
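# Small in-code fixtures shared across tests.

# Random two-class spectra tibble on an arbitrary grid (no band structure;
# used for structural / oracle checks, not for signal recovery).
random_spectra <- function(n1, n2, k, seed, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm((n1 + n2) * k, sd = sd), nrow = n1 + n2)
  new_spectra(seq(4000, by = 4, length.out = k), m,
              labels = c(rep(1L, n1), rep(2L, n2)))
}

# Spectra tibble from an explicit matrix on a unit grid.
spectra_from_matrix <- function(m, labels) {
  new_spectra(seq(4000, by = 4, length.out = ncol(m)), m, labels = labels)
}

# Small planted-band generator configuration on a short grid (251 channels),
# scatter-free so selection behaviour can be read off directly: three
# narrow informative bands far apart between two broad shared bands.
recovery_config <- function(noise_sd, seed,
                            counts = default_subset_counts()) {
  synthetic_config(
    wavenumber_start = 4000, wavenumber_end = 5000, step = 4,
    shared_bands = tibble::tibble(
      center = c(4300, 4700), width = c(200, 250), amplitude = c(0.8, 0.6)),
    class_delta_bands = tibble::tibble(
      center = c(4100, 4500, 4900), width = c(8, 8, 8),
      amplitude = c(0.030, 0.025, 0.020)),
    scatter_slope_sd = 0, scatter_offset_sd = 0,
    noise_sd = noise_sd,
    n_per_class_per_subset = counts,
    seed = seed)
}

# Channel indices within +/- `win` channels of the planted delta-band
# centres of a config.
planted_neighbourhood <- function(config, win = 3L) {
  wn <- synthetic_grid(config)
  centres <- vapply(config$class_delta_bands$center,
                    function(cc) which.min(abs(wn - cc)), integer(1))
  unique(unlist(lapply(centres, function(ci) {
    seq(max(1L, ci - win), min(length(wn), ci + win))
  })))
}
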
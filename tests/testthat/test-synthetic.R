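test_that("default grid has inclusive endpoints at 4 cm^-1 spacing", {
  cfg <- synthetic_config()
  wn <- synthetic_grid(cfg)
  expect_length(wn, 1501)
  expect_equal(wn[1], 4000)
  expect_equal(wn[length(wn)], 10000)
  sp <- generate_spectra(cfg)
  expect_equal(ncol(spectra_matrix(sp)), 1501)
  expect_equal(nrow(sp), 3 * (26 + 36))
})

test_that("generation is deterministic and noise-free spectra collapse by class", {
  cfg <- synthetic_config(seed = 42)
  expect_identical(generate_spectra(cfg), generate_spectra(cfg))

  quiet <- synthetic_config(noise_sd = 0, scatter_slope_sd = 0,
                            scatter_offset_sd = 0, seed = 1)
  sp <- generate_spectra(quiet)
  m <- spectra_matrix(sp)
  labs <- spectra_labels(sp)
  rows1 <- which(labs == 1L)
  expect_equal(m[rows1[1], ], m[rows1[2], ])

  nosig <- synthetic_config(class_delta_bands = tibble::tibble(
    center = numeric(0), width = numeric(0), amplitude = numeric(0)),
    noise_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0)
  m0 <- spectra_matrix(generate_spectra(nosig))
  l0 <- spectra_labels(generate_spectra(nosig))
  expect_equal(colMeans(m0[l0 == 1L, ]), colMeans(m0[l0 == 2L, ]))
})

test_that("planted signal appears only inside the delta-band supports", {
  cfg <- synthetic_config(noise_sd = 0, scatter_slope_sd = 0,
                          scatter_offset_sd = 0)
  sp <- generate_spectra(cfg)
  m <- spectra_matrix(sp)
  labs <- spectra_labels(sp)
  diff_mean <- colMeans(m[labs == 1L, ]) - colMeans(m[labs == 2L, ])
  wn <- synthetic_grid(cfg)
  support <- rep(FALSE, length(wn))
  for (i in seq_len(nrow(cfg$class_delta_bands))) {
    b <- cfg$class_delta_bands[i, ]
    support <- support | abs(wn - b$center) <= 8 * b$width
  }
  expect_true(all(abs(diff_mean[!support]) < 1e-12))
  expect_true(max(abs(diff_mean[support])) > 0.01)
  expect_equal(unname(diff_mean), class_difference_spectrum(cfg))
})

test_that("broad bands over a fine grid give strongly collinear neighbours", {
  cfg <- synthetic_config(noise_sd = 0)  # scatter on: between-sample variation
  m <- spectra_matrix(generate_spectra(cfg))
  adj <- vapply(seq_len(ncol(m) - 1),
                function(j) stats::cor(m[, j], m[, j + 1]), numeric(1))
  expect_true(min(adj) > 0.99)
})

test_that("invalid configurations are refused with a configuration error", {
  expect_error(synthetic_config(wavenumber_end = 3000),
               class = "nirspa_config_error")
  expect_error(synthetic_config(step = 0), class = "nirspa_config_error")
  expect_error(synthetic_config(noise_sd = -1), class = "nirspa_config_error")
  expect_error(synthetic_config(shared_bands = tibble::tibble(
    center = 5000, width = 0, amplitude = 1)), class = "nirspa_config_error")
})

test_that("stratified split yields disjoint subsets with exact class counts", {
  cfg <- synthetic_config()  # pooled 78 cancerous + 108 normal
  sp <- generate_spectra(cfg)
  expect_equal(sum(sp$label == 1L), 78)
  expect_equal(sum(sp$label == 2L), 108)
  subs <- split_subsets(sp, seed = 9)
  expect_named(subs, c("training", "validation", "test"))
  for (s in subs) {
    expect_equal(nrow(s), 62)
    expect_equal(sum(s$label == 1L), 26)
    expect_equal(sum(s$label == 2L), 36)
  }
  ids <- unlist(lapply(subs, function(s) s$sample_id))
  expect_equal(anyDuplicated(ids), 0L)
  expect_identical(split_subsets(sp, seed = 9), subs)
  expect_false(identical(split_subsets(sp, seed = 10), subs))
  expect_error(
    split_subsets(sp, tibble::tibble(cancerous = 100, normal = 10)),
    class = "nirspa_size_error")
})

test_that("a singleton subset request works at the boundary", {
  sp <- random_spectra(1, 1, 5, seed = 1)
  one <- split_subsets(sp, tibble::tibble(cancerous = 1, normal = 1), seed = 1)
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]), 2)
})

test_that("closed-form Bayes accuracy matches a Monte Carlo oracle", {
  cfg <- recovery_config(noise_sd = 0.01, seed = 1,
                         counts = tibble::tibble(cancerous = 30, normal = 30))
  analytic <- bayes_accuracy(cfg)
  # Monte Carlo: draw from the generating model, classify with the true
  # parameters (likelihood ratio on the known mean difference)
  set.seed(99)
  n <- 4000
  d <- class_difference_spectrum(cfg)
  base2 <- rep(0, length(d))
  lab <- sample(c(1L, 2L), n, replace = TRUE)
  correct <- 0
  proj_sd <- cfg$noise_sd * sqrt(sum(d^2))
  for (i in seq_len(n)) {
    mu <- if (lab[i] == 1L) sum(d * d) else 0
    u <- rnorm(1, mu, proj_sd)  # sufficient statistic d'x (shifted)
    pred <- if (u > sum(d * d) / 2) 1L else 2L
    correct <- correct + (pred == lab[i])
  }
  expect_equal(analytic, correct / n, tolerance = 0.02)
  expect_error(bayes_accuracy(synthetic_config()),
               class = "nirspa_config_error")
})
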
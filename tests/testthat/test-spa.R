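test_that("class-mean centring zeroes each class's column means", {
  sp <- random_spectra(4, 5, 7, seed = 31)
  cen <- center_by_class_mean(sp)
  labs <- spectra_labels(sp)
  for (cl in 1:2) {
    expect_true(all(abs(colMeans(cen[labs == cl, , drop = FALSE])) < 1e-10))
  }
  # single class: identical to ordinary column centring
  one <- spectra_from_matrix(matrix(rnorm(12), 4), rep(1L, 4))
  expect_equal(center_by_class_mean(one),
               scale(spectra_matrix(one), scale = FALSE),
               ignore_attr = TRUE)
  # two singleton classes: all zeros
  two <- spectra_from_matrix(matrix(rnorm(10), 2), c(1L, 2L))
  expect_true(all(center_by_class_mean(two) == 0))
})

test_that("chains follow the orthogonal-projection construction", {
  # orthogonal columns with norms 3, 2, 1: projections leave them unchanged,
  # so selection is by norm
  m <- diag(c(3, 2, 1))
  ch <- build_chains(m, l_max = 1, n_classes = 2)$chains
  expect_equal(nrow(ch), 3)
  ch <- build_chains(rbind(m, 0), l_max = 2, n_classes = 2)
  expect_equal(ch$chains[1, ], c(1L, 2L))
  expect_equal(ch$chains[3, ], c(3L, 1L))

  # a duplicated column has zero residual and is never selected while
  # independent columns remain
  set.seed(5)
  base <- matrix(rnorm(24), nrow = 6, ncol = 4)
  dup <- cbind(base, base[, 2])
  ch <- build_chains(dup, l_max = 4, n_classes = 2)
  expect_false(5L %in% ch$chains[2, seq_len(4)][-4])
  expect_false(2L %in% ch$chains[5, seq_len(4)][-4])
})

test_that("chains stop early with a truncation flag when residuals vanish", {
  set.seed(3)
  t <- rnorm(6)
  m <- cbind(t, 2 * t, -t)  # rank 1: only the initialiser survives
  ch <- build_chains(m, l_max = 3, n_classes = 2)
  expect_equal(ch$lengths, c(1L, 1L, 1L))
  expect_true(all(ch$truncated))
})

test_that("the chain-length bound N - C is enforced", {
  sp <- random_spectra(3, 3, 8, seed = 1)
  cen <- center_by_class_mean(sp)
  expect_error(build_chains(cen, l_max = 5, n_classes = 2),
               regexp = "N - C", class = "nirspa_size_error")
  expect_silent(build_chains(cen, l_max = 4, n_classes = 2))
})

test_that("chain construction matches the brute-force QR oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:9, 1)
    k <- sample(4:8, 1)
    m <- matrix(rnorm(n * k), n, k)
    l_max <- min(3, n - 2)
    ch <- build_chains(m, l_max, n_classes = 2)
    for (init in seq_len(k)) {
      expect_equal(ch$chains[init, seq_len(ch$lengths[init])],
                   oracle_chain(m, init, l_max))
    }
  }
})

test_that("pooled covariance matches the hand-computed formula", {
  # class 1 = {0, 2}, class 2 = {10, 14}: S = (2 + 8) / 2 = 5
  sp <- spectra_from_matrix(cbind(c(0, 2, 10, 14), 0 * 1:4 + rnorm(4)),
                            c(1L, 1L, 2L, 2L))
  S <- pooled_covariance(sp, 1)
  expect_equal(S[1, 1], 5)
  # one class only: ordinary sample covariance (denominator N - 1)
  one <- spectra_from_matrix(matrix(rnorm(20), 5), rep(1L, 5))
  expect_equal(pooled_covariance(one, 1:4),
               stats::cov(spectra_matrix(one)), ignore_attr = TRUE)
  # symmetric
  sp2 <- random_spectra(5, 5, 6, seed = 8)
  S2 <- pooled_covariance(sp2, c(1, 3, 5))
  expect_equal(S2, t(S2), tolerance = 1e-12)
})

test_that("zero within-class scatter makes the pooled covariance singular", {
  m <- rbind(c(1, 2), c(1, 2), c(3, 4), c(3, 4))
  sp <- spectra_from_matrix(m, c(1L, 1L, 2L, 2L))
  expect_error(fit_lda(sp, 1:2), class = "nirspa_singular_error")
})

test_that("squared Mahalanobis distance reduces to its closed forms", {
  expect_equal(mahalanobis_sq(c(1, 0), c(0, 0), diag(2)), 1)
  expect_equal(mahalanobis_sq(c(3, 4), c(3, 4), diag(2)), 0)
  expect_equal(mahalanobis_sq(c(2, 0), c(0, 0), solve(diag(c(4, 1)))), 1)
  expect_error(mahalanobis_sq(c(1, 2, 3), c(0, 0), diag(2)),
               class = "nirspa_size_error")
  # property: S = sigma^2 I reduces to Euclidean distance / sigma^2
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(4); mu <- rnorm(4); s2 <- runif(1, 0.1, 5)
    expect_equal(mahalanobis_sq(x, mu, diag(4) / s2),
                 sum((x - mu)^2) / s2, tolerance = 1e-10)
  }
})

test_that("the per-sample risk has its documented fixed points", {
  m <- rbind(c(-1, 0), c(-1.5, 0.5), c(1, 0), c(1.5, 0.5))
  sp <- spectra_from_matrix(m, c(1L, 1L, 2L, 2L))
  model <- fit_lda(sp, 1:2)
  # at the true class mean: numerator zero
  expect_equal(risk_g(model$class_means[1, ], 1L, model), 0)
  # exact midpoint of the two class means: ratio 1 by symmetry
  mid <- colMeans(model$class_means)
  expect_equal(risk_g(mid, 1L, model), 1, tolerance = 1e-12)
  expect_equal(risk_g(mid, 2L, model), 1, tolerance = 1e-12)
  # at the wrong class mean the denominator degenerates
  expect_error(risk_g(model$class_means[2, ], 1L, model),
               class = "nirspa_degenerate_error")
})

test_that("the cost function averages per-sample risks over validation", {
  train <- random_spectra(5, 5, 4, seed = 41)
  model <- fit_lda(train, 1:3)
  # validation samples sitting exactly at their true class means: cost 0
  val_m <- rbind(model$class_means[1, ], model$class_means[2, ])
  val <- new_spectra(spectra_wavenumbers(train)[1:3], val_m, c(1L, 2L))
  # build a validation tibble on the full grid with the means in place
  full <- matrix(0, 2, 4)
  full[, 1:3] <- val_m
  val_full <- new_spectra(spectra_wavenumbers(train), full, c(1L, 2L))
  expect_equal(spa_cost(val_full, 1:3, train), 0)

  # a single validation sample: cost equals its own risk
  v1 <- random_spectra(1, 1, 4, seed = 42)[1, ]
  v1 <- as_spectra(v1)
  expect_equal(spa_cost(v1, 1:3, train),
               risk_g(spectra_matrix(v1)[1, 1:3], 1L, model))

  # small fixed instance against the independent loop-based oracle
  tr <- random_spectra(4, 4, 5, seed = 43)
  va <- random_spectra(3, 3, 5, seed = 44)
  for (sub in list(1L, c(2L, 4L), c(1L, 3L, 5L))) {
    expect_equal(spa_cost(va, sub, tr),
                 oracle_cost(spectra_matrix(tr), spectra_labels(tr),
                             spectra_matrix(va), spectra_labels(va), sub),
                 tolerance = 1e-10)
  }
})

test_that("variable selection enumerates chain prefixes like the oracle", {
  # K = 8 toy instance
  tr <- random_spectra(5, 5, 8, seed = 51)
  va <- random_spectra(4, 4, 8, seed = 52)
  sel <- select_variables(tr, va, l_max = 3)
  ref <- oracle_select(spectra_matrix(tr), spectra_labels(tr),
                       spectra_matrix(va), spectra_labels(va), l_max = 3)
  expect_equal(sel$selected, ref$subset)
  expect_equal(min(sel$cost_curve$cost), ref$cost, tolerance = 1e-10)
  # cost curve covers sizes 1..L with non-negative best costs
  expect_equal(sel$cost_curve$n_variables, 1:3)
  expect_true(all(sel$cost_curve$cost >= 0))

  # degenerate enumeration: L = 1 returns the single best channel by cost
  sel1 <- select_variables(tr, va, l_max = 1)
  costs1 <- vapply(seq_len(8), function(j) spa_cost(va, j, tr), numeric(1))
  expect_equal(sel1$selected, which.min(costs1))
})

test_that("LDA fitting stores per-class means and refits identically", {
  tr <- random_spectra(6, 6, 5, seed = 61)
  model <- fit_lda(tr, c(2L, 4L))
  m <- spectra_matrix(tr)[, c(2, 4)]
  labs <- spectra_labels(tr)
  expect_equal(model$class_means[1, ], colMeans(m[labs == 1, ]),
               ignore_attr = TRUE)
  expect_equal(model$class_means[2, ], colMeans(m[labs == 2, ]),
               ignore_attr = TRUE)
  expect_equal(fit_lda(tr, c(2L, 4L)), model)
  # selecting more variables than N - C permits: singular covariance
  wide <- random_spectra(3, 3, 10, seed = 62)
  expect_error(fit_lda(wide, 1:10), class = "nirspa_singular_error")
})

test_that("prediction assigns the nearest class mean, ties to class 1", {
  m <- rbind(c(0, 0), c(0.5, 0.5), c(10, 10), c(10.5, 9.5))
  tr <- spectra_from_matrix(m, c(1L, 1L, 2L, 2L))
  model <- fit_lda(tr, 1:2)
  probe <- spectra_from_matrix(rbind(model$class_means[1, ], c(4, 4),
                                     c(9, 9)), c(1L, 1L, 2L))
  expect_equal(suppressMessages(predict(model, probe)), c(1L, 1L, 2L))
  # equidistant probe: smaller class code, with a logged message
  mid <- colMeans(model$class_means)
  probe_mid <- spectra_from_matrix(rbind(mid), 1L)
  expect_message(p <- predict(model, probe_mid), regexp = "equidistant")
  expect_equal(p, 1L)
  # grid mismatch
  bad <- random_spectra(1, 1, 3, seed = 1)
  expect_error(predict(model, bad), class = "nirspa_size_error")
})
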
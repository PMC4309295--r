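#' Fit a PLS-DA model (NIPALS PLS1 on a dummy class variable)
#'
#' The full-spectrum baseline classifier: partial least squares regression
#' of the mean-centred spectra on the mean-centred dummy class code
#' (1 = cancerous, 2 = normal), by the NIPALS algorithm for a univariate
#' response. A prediction threshold between the two codes (default 1.5, the
#' midpoint) turns the continuous output into a class assignment.
#'
#' @param train Training spectra tibble (labels supply the dummy variable).
#' @param n_lv Number of latent variables, in `1..min(N - 1, K)`.
#' @param threshold Decision threshold, strictly between 1 and 2.
#' @return A `pls_da` model: weights `W`, loadings `P`, response loadings
#'   `q`, `regression_vector`, centring terms, `scores` on the training
#'   set, `n_lv`, `threshold`.
#' @export
#' @examples
#' cfg <- synthetic_config(wavenumber_end = 5000, seed = 3)
#' subs <- split_subsets(generate_spectra(cfg), seed = 3)
#' fit <- fit_pls(preprocess(subs$training), n_lv = 2)
#' glance(fit)
fit_pls <- function(train, n_lv, threshold = 1.5) {
  train <- as_spectra(train)
  x <- spectra_matrix(train)
  y <- as.numeric(spectra_labels(train))
  n <- nrow(x)
  if (n < 2) abort_size("PLS needs at least 2 training samples")
  if (n_lv < 1 || n_lv > min(n - 1, ncol(x))) {
    abort_size(sprintf("`n_lv` must be in 1..%d (min(N - 1, K))",
                       min(n - 1, ncol(x))))
  }
  if (!(threshold > 1 && threshold < 2)) {
    abort_config("`threshold` must lie strictly between the class codes 1 and 2")
  }
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  E <- sweep(x, 2, x_mean)
  f <- y - y_mean
  K <- ncol(x)
  W <- matrix(0, K, n_lv)
  P <- matrix(0, K, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) abort_degenerate(sprintf(
      "residual covariance vanished at latent variable %d; reduce `n_lv`", a))
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    p <- drop(crossprod(E, tt)) / tt2
    qa <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, p)
    f <- f - tt * qa
    W[, a] <- w; P[, a] <- p; Tm[, a] <- tt; q[a] <- qa
  }
  # b maps centred x to centred y: b = W (P'W)^-1 q
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(
    n_lv = n_lv,
    x_weights = W,
    x_loadings = P,
    y_loadings = q,
    scores = Tm,
    regression_vector = b,
    x_mean = x_mean,
    y_mean = y_mean,
    threshold = threshold,
    wavenumbers = spectra_wavenumbers(train),
    n_train = n
  ), class = "pls_da")
}

#' @export
print.pls_da <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d latent variables over %d channels, threshold %.2f\n",
              x$n_lv, length(x$wavenumbers), x$threshold))
  invisible(x)
}

#' Predict class membership with a PLS-DA model
#'
#' Computes the continuous PLS prediction and thresholds it: class 1
#' (cancerous) if the prediction is below the threshold, class 2 otherwise.
#' A prediction exactly at the threshold goes to class 2 (the "at or above"
#' convention) and is reported via a message.
#'
#' @param object A `pls_da` model.
#' @param spectra A spectra tibble on the model's wavenumber grid.
#' @param type `"class"` for labels, `"response"` for the continuous
#'   prediction.
#' @param ... Unused.
#' @return Integer labels or a numeric vector.
#' @export
predict.pls_da <- function(object, spectra, type = c("class", "response"), ...) {
  type <- match.arg(type)
  spectra <- as_spectra(spectra)
  wn <- spectra_wavenumbers(spectra)
  if (length(wn) != length(object$wavenumbers) ||
      any(wn != object$wavenumbers)) {
    abort_size("spectra are not on the model's wavenumber grid")
  }
  x <- spectra_matrix(spectra)
  yhat <- unname(drop(sweep(x, 2, object$x_mean) %*% object$regression_vector)) +
    object$y_mean
  if (type == "response") return(yhat)
  at <- yhat == object$threshold
  if (any(at)) {
    message(sprintf("%d prediction(s) exactly at the threshold; assigned class 2",
                    sum(at)))
  }
  ifelse(yhat < object$threshold, 1L, 2L)
}

#' Choose the number of latent variables by 5-fold cross-validation
#'
#' Reproduces the stated fold design: the training set is split into five
#' cancellation groups, the first four holding a fixed per-class quota
#' (`floor(n_class / 5)` each, i.e. 5 cancerous + 7 normal for the
#' 26 + 36 design) and the fifth the remainder. Fold membership within the
#' quotas is randomised by `seed`. Each group is held out once; the
#' misclassification ratio over all held-out predictions is recorded per
#' candidate LV count and the count with the smallest ratio is chosen, ties
#' going to fewer LVs.
#'
#' @param train Training spectra tibble.
#' @param max_lv Largest LV count to try.
#' @param seed Integer seed for fold membership.
#' @param threshold Decision threshold passed to [fit_pls()].
#' @return A `plsda_cv` object: tibble `results` (`n_lv`, `mcr`), chosen
#'   `n_lv`, and the fold assignment.
#' @export
cross_validate_lvs <- function(train, max_lv = 10L, seed = 1L, threshold = 1.5) {
  train <- as_spectra(train)
  labs <- spectra_labels(train)
  n1 <- sum(labs == 1L); n2 <- sum(labs == 2L)
  q1 <- n1 %/% 5L; q2 <- n2 %/% 5L
  if (q1 < 1 || q2 < 1) {
    abort_size(sprintf(
      "5-fold design needs at least 5 samples per class; have %d cancerous / %d normal",
      n1, n2))
  }
  fold <- integer(length(labs))
  with_seed(seed, {
    ord1 <- sample(which(labs == 1L))
    ord2 <- sample(which(labs == 2L))
    for (k in 1:4) {
      fold[ord1[seq_len(q1) + (k - 1L) * q1]] <- k
      fold[ord2[seq_len(q2) + (k - 1L) * q2]] <- k
    }
    fold[fold == 0L] <- 5L
  })
  # cap by the smallest training complement: N - largest fold - 1
  cap <- min(max_lv, nrow(train) - max(table(fold)) - 1L)
  lv_grid <- seq_len(max(1L, cap))
  errs <- integer(length(lv_grid))
  for (k in 1:5) {
    tr <- as_spectra(train[fold != k, , drop = FALSE])
    ho <- as_spectra(train[fold == k, , drop = FALSE])
    for (ai in seq_along(lv_grid)) {
      fit <- fit_pls(tr, n_lv = lv_grid[ai], threshold = threshold)
      pred <- suppressMessages(predict(fit, ho))
      errs[ai] <- errs[ai] + sum(pred != spectra_labels(ho))
    }
  }
  mcr <- errs / nrow(train)
  chosen <- lv_grid[which.min(mcr)]  # which.min takes the first: fewer LVs on ties
  structure(list(
    results = tibble::tibble(n_lv = lv_grid, mcr = mcr),
    n_lv = chosen,
    fold = fold,
    seed = as.integer(seed)
  ), class = "plsda_cv")
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat(sprintf("PLS-DA 5-fold CV: chose %d LV(s), misclassification ratio %.3f\n",
              x$n_lv, x$results$mcr[x$results$n_lv == x$n_lv]))
  invisible(x)
}

#' @rdname tidy.pls_da
#' @method tidy plsda_cv
#' @export
tidy.plsda_cv <- function(x, ...) x$results

#' Latent-variable loadings on the wavenumber axis
#'
#' Returns the X-loading vector of each latent variable paired with the
#' wavenumber grid, the long format used to inspect which spectral regions
#' each LV draws on.
#'
#' @param model A `pls_da` model.
#' @return A tibble with columns `lv`, `wavenumber`, `loading`.
#' @export
pls_loadings <- function(model) {
  purrr::map_dfr(seq_len(model$n_lv), function(a) {
    tibble::tibble(lv = a, wavenumber = model$wavenumbers,
                   loading = model$x_loadings[, a])
  })
}

#' Tidiers for `pls_da` models
#'
#' `tidy()` returns the regression vector per wavenumber; `glance()` a
#' one-row summary.
#'
#' @param x A `pls_da` model (or `plsda_cv` result for `tidy.plsda_cv`).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pls_da
#' @export
tidy.pls_da <- function(x, ...) {
  tibble::tibble(wavenumber = x$wavenumbers,
                 coefficient = x$regression_vector)
}

#' @rdname tidy.pls_da
#' @method glance pls_da
#' @export
glance.pls_da <- function(x, ...) {
  tibble::tibble(
    n_lv = x$n_lv,
    n_channels = length(x$wavenumbers),
    n_train = x$n_train,
    threshold = x$threshold
  )
}

#' Plot PLS-DA latent-variable loadings
#'
#' @param object A `pls_da` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pls_da
#' @export
autoplot.pls_da <- function(object, ...) {
  ld <- pls_loadings(object)
  ld$lv <- factor(ld$lv)
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$wavenumber, y = .data$loading,
                                   colour = .data$lv)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "loading", colour = "LV")
}
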
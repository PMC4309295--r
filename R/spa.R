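#' Centre spectra on their class means
#'
#' Subtracts from every spectrum the mean spectrum of its own class. The
#' chain-building phase of the successive projections algorithm (SPA) runs
#' on this matrix so that between-class differences do not drive the
#' collinearity structure; per-class column means of the result are zero.
#'
#' @param train A spectra tibble.
#' @return A numeric N x K matrix in input row order.
#' @export
center_by_class_mean <- function(train) {
  train <- as_spectra(train)
  m <- spectra_matrix(train)
  labs <- spectra_labels(train)
  for (cl in unique(labs)) {
    rows <- labs == cl
    m[rows, ] <- sweep(m[rows, , drop = FALSE], 2,
                       colMeans(m[rows, , drop = FALSE]))
  }
  m
}

#' Build SPA variable chains by successive orthogonal projections
#'
#' Phase 1 of SPA-LDA. For each of the K variables (columns) as an
#' initialiser, a chain of up to `l_max` variables is grown: at every step
#' all remaining columns are projected onto the orthogonal complement of the
#' span of the columns already in the chain, and the column with the largest
#' residual norm is appended. Selected variables are therefore minimally
#' collinear. The chain length is capped at `N - C` (training samples minus
#' classes), the degrees of freedom left after class-mean centring.
#'
#' If at some step every remaining column has (numerically) zero residual
#' norm the chain stops early and is flagged as truncated.
#'
#' @param centered Class-mean-centred matrix from [center_by_class_mean()].
#' @param l_max Maximum chain length.
#' @param n_classes Number of classes C used for the `N - C` bound.
#' @return A `spa_chains` object: integer matrix `chains` (K rows, `l_max`
#'   columns, NA-padded), `lengths`, and logical `truncated` per chain.
#' @export
build_chains <- function(centered, l_max, n_classes = 2L) {
  centered <- as.matrix(centered)
  n <- nrow(centered)
  k <- ncol(centered)
  bound <- n - n_classes
  if (l_max < 1 || l_max > bound) {
    abort_size(sprintf(
      "`l_max` must be in 1..%d (N - C = %d - %d); got %d",
      bound, n, n_classes, l_max))
  }
  norms0 <- colSums(centered^2)
  tol <- 1e-12 * max(norms0)
  chains <- matrix(NA_integer_, nrow = k, ncol = l_max)
  lengths <- integer(k)
  truncated <- logical(k)
  for (init in seq_len(k)) {
    x <- centered
    chain <- init
    v <- x[, init]
    while (length(chain) < l_max) {
      vv <- sum(v^2)
      if (vv <= tol) { truncated[init] <- TRUE; break }
      # project all columns onto the orthogonal complement of v (the
      # residual of the last selected column); previously selected columns
      # are already residualised, so spans accumulate correctly
      x <- x - v %*% (crossprod(v, x) / vv)
      norms <- colSums(x^2)
      norms[chain] <- -Inf
      j <- which.max(norms)  # ties: smallest index, deterministic
      if (norms[j] <= tol) { truncated[init] <- TRUE; break }
      chain <- c(chain, j)
      v <- x[, j]
    }
    chains[init, seq_along(chain)] <- chain
    lengths[init] <- length(chain)
  }
  structure(list(chains = chains, lengths = lengths, truncated = truncated,
                 l_max = l_max),
            class = "spa_chains")
}

#' @export
print.spa_chains <- function(x, ...) {
  cat(sprintf("SPA chains: %d initialisers, chain length <= %d (%d truncated)\n",
              nrow(x$chains), x$l_max, sum(x$truncated)))
  invisible(x)
}

#' Pooled within-class covariance matrix
#'
#' `S = sum over classes of the within-class scatter, divided by N - C`,
#' computed on the training set over the selected variables only and shared
#' by all classes in the Mahalanobis classifier. With a single class this
#' reduces to the ordinary sample covariance (denominator `N - 1`).
#'
#' @param train A spectra tibble.
#' @param selected Integer indices of the selected variables (columns of the
#'   absorbance matrix).
#' @return A symmetric matrix of order `length(selected)`.
#' @export
pooled_covariance <- function(train, selected) {
  train <- as_spectra(train)
  m <- spectra_matrix(train)[, selected, drop = FALSE]
  labs <- spectra_labels(train)
  n <- nrow(m)
  cl <- sort(unique(labs))
  if (n - length(cl) < 1) {
    abort_size("need at least one more training sample than classes")
  }
  S <- matrix(0, ncol(m), ncol(m))
  for (c_i in cl) {
    rows <- m[labs == c_i, , drop = FALSE]
    S <- S + crossprod(sweep(rows, 2, colMeans(rows)))
  }
  S / (n - length(cl))
}

#' Squared Mahalanobis distance
#'
#' `(x - mean) %*% S_inv %*% (x - mean)`, the covariance-weighted squared
#' distance used throughout the LDA classifier and its risk function.
#'
#' @param x,mean Conforming numeric vectors.
#' @param S_inv Inverse pooled covariance (symmetric).
#' @return A non-negative scalar.
#' @export
mahalanobis_sq <- function(x, mean, S_inv) {
  x <- as.numeric(x); mean <- as.numeric(mean)
  if (length(x) != length(mean) || length(x) != nrow(S_inv)) {
    abort_size("dimension mismatch in Mahalanobis distance")
  }
  d <- x - mean
  drop(d %*% S_inv %*% d)
}

# Squared Mahalanobis distances of all rows of V to each class mean.
# Returns an n x C matrix; columns ordered as `means` rows.
mahal_all <- function(V, means, S_inv) {
  out <- matrix(0, nrow(V), nrow(means))
  for (ci in seq_len(nrow(means))) {
    d <- sweep(V, 2, means[ci, ])
    out[, ci] <- rowSums((d %*% S_inv) * d)
  }
  out
}

#' Misclassification risk of one validation sample
#'
#' `g_n`: the ratio of the squared Mahalanobis distance of a validation
#' sample to its true class centre over the distance to the nearest wrong
#' class centre (means and pooled covariance from the training set). Small
#' `g_n` means the sample sits close to its own class and far from the
#' others; zero at the true class mean.
#'
#' @param x_val Validation sample over the model's selected variables.
#' @param true_label Its class code.
#' @param model A fitted [fit_lda()] model.
#' @return Non-negative scalar risk.
#' @export
risk_g <- function(x_val, true_label, model) {
  cl <- model$class_labels
  if (length(cl) < 2) abort_size("risk requires at least 2 classes")
  ti <- match(true_label, cl)
  if (is.na(ti)) abort_input(sprintf("label %s not among model classes", true_label))
  d2 <- vapply(seq_along(cl), function(ci) {
    mahalanobis_sq(x_val, model$class_means[ci, ], model$S_inv)
  }, numeric(1))
  denom <- min(d2[-ti])
  if (denom == 0) {
    abort_degenerate("validation sample coincides with a wrong-class mean; risk ratio undefined")
  }
  d2[ti] / denom
}

#' Validation-set average risk of a variable subset
#'
#' The SPA-LDA cost `G_cost`: the mean of [risk_g()] over all validation
#' samples, with class means and pooled covariance estimated on the
#' training set restricted to `subset`. Phase 2 of SPA-LDA minimises this
#' over all candidate subsets.
#'
#' @param validation Validation spectra tibble (never used for means or S).
#' @param subset Integer variable indices (non-empty).
#' @param train Training spectra tibble.
#' @return Non-negative scalar `G_cost`.
#' @export
spa_cost <- function(validation, subset, train) {
  if (length(subset) < 1) abort_size("`subset` must be non-empty")
  model <- fit_lda(train, subset)
  validation <- as_spectra(validation)
  V <- spectra_matrix(validation)[, subset, drop = FALSE]
  labs <- spectra_labels(validation)
  d2 <- mahal_all(V, model$class_means, model$S_inv)
  ti <- match(labs, model$class_labels)
  g <- vapply(seq_len(nrow(V)), function(n) {
    denom <- min(d2[n, -ti[n]])
    if (denom == 0) {
      abort_degenerate(sprintf(
        "validation sample %s coincides with a wrong-class mean", validation$sample_id[n]))
    }
    d2[n, ti[n]] / denom
  }, numeric(1))
  mean(g)
}

#' Select variables by minimising the validation cost over all chain prefixes
#'
#' Phase 2 of SPA-LDA. Every chain from [build_chains()] contributes one
#' candidate subset per prefix length 1..L (the first `m` variables in
#' selection order), giving up to K x L candidates; each is scored by
#' [spa_cost()] on the validation set and the global minimiser is returned.
#' Ties are broken toward fewer variables, then the lexicographically
#' smallest index sequence, so the output is deterministic. Candidates with
#' a singular pooled covariance are skipped (infinite cost); if every
#' candidate is singular the selection fails hard.
#'
#' @param train,validation Spectra tibbles; chains are built on the
#'   training set only and cost evaluated on the validation set only.
#' @param l_max Maximum subset size (chain length), at most `N_train - C`.
#' @return A list: `selected` (integer indices), `cost_curve` (tibble with
#'   `n_variables`, best `cost` per size and the achieving `subset`),
#'   `chains`, and `n_candidates` evaluated.
#' @export
select_variables <- function(train, validation, l_max) {
  train <- as_spectra(train)
  validation <- as_spectra(validation)
  labs <- spectra_labels(train)
  n_classes <- length(unique(labs))
  centered <- center_by_class_mean(train)
  chains <- build_chains(centered, l_max, n_classes = n_classes)
  # unique prefixes across chains
  total <- sum(chains$lengths)
  prefixes <- vector("list", total)
  keys <- character(total)
  at <- 0L
  for (i in seq_len(nrow(chains$chains))) {
    for (m in seq_len(chains$lengths[i])) {
      at <- at + 1L
      # a candidate is the *set* of the first m chain variables; canonical
      # (sorted) order makes duplicates and cost evaluation unambiguous
      sub <- sort(chains$chains[i, seq_len(m)])
      keys[at] <- paste(sub, collapse = ",")
      prefixes[[at]] <- sub
    }
  }
  prefixes <- prefixes[!duplicated(keys)]
  # fast candidate scoring on precomputed matrices: pooled covariance from
  # the class-centred training matrix, means indexed from the full grid
  train_m <- spectra_matrix(train)
  cls <- sort(unique(labs))
  means_full <- do.call(rbind, lapply(cls, function(cl) {
    colMeans(train_m[labs == cl, , drop = FALSE])
  }))
  val_m <- spectra_matrix(validation)
  val_ti <- match(spectra_labels(validation), cls)
  denom_df <- nrow(train_m) - length(cls)
  costs <- vapply(prefixes, function(sub) {
    S <- crossprod(centered[, sub, drop = FALSE]) / denom_df
    rc <- tryCatch(rcond(S), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-12) return(Inf)
    S_inv <- solve(S)
    d2 <- mahal_all(val_m[, sub, drop = FALSE],
                    means_full[, sub, drop = FALSE], S_inv)
    g <- vapply(seq_len(nrow(d2)), function(n) {
      denom <- min(d2[n, -val_ti[n]])
      if (denom == 0) {
        abort_degenerate("validation sample coincides with a wrong-class mean")
      }
      d2[n, val_ti[n]] / denom
    }, numeric(1))
    mean(g)
  }, numeric(1))
  if (all(!is.finite(costs))) {
    rlang::abort(
      "every candidate subset has a singular pooled covariance; cannot select variables",
      class = "nirspa_singular_error")
  }
  sizes <- lengths(prefixes)
  lex <- vapply(prefixes, function(s) paste(sprintf("%08d", s), collapse = ""),
                character(1))
  pick <- function(idx) {
    idx <- idx[costs[idx] == min(costs[idx])]
    idx <- idx[sizes[idx] == min(sizes[idx])]
    idx[order(lex[idx])][1]
  }
  best <- pick(which(is.finite(costs)))
  curve <- purrr::map_dfr(sort(unique(sizes)), function(m) {
    idx <- which(sizes == m & is.finite(costs))
    if (length(idx) == 0) {
      return(tibble::tibble(n_variables = m, cost = Inf, subset = list(integer(0))))
    }
    b <- pick(idx)
    tibble::tibble(n_variables = m, cost = costs[b], subset = list(prefixes[[b]]))
  })
  list(selected = prefixes[[best]], cost_curve = curve, chains = chains,
       n_candidates = length(prefixes))
}

#' Fit the pooled-covariance Mahalanobis LDA on selected variables
#'
#' Stores the per-class mean vectors and the pooled covariance (and its
#' inverse) over the selected variables. The pooled covariance must be
#' invertible, which requires fewer variables than `N_train - C + 1`; a
#' singular matrix is a hard error, never silently regularised.
#'
#' @param train Training spectra tibble.
#' @param selected Integer variable indices.
#' @return A `spa_lda` model object.
#' @export
fit_lda <- function(train, selected) {
  train <- as_spectra(train)
  m <- spectra_matrix(train)[, selected, drop = FALSE]
  labs <- spectra_labels(train)
  cl <- sort(unique(labs))
  means <- do.call(rbind, lapply(cl, function(c_i) {
    colMeans(m[labs == c_i, , drop = FALSE])
  }))
  S <- pooled_covariance(train, selected)
  S_inv <- safe_inverse(S)
  structure(list(
    selected = as.integer(selected),
    wavenumbers = spectra_wavenumbers(train),
    selected_wavenumbers = spectra_wavenumbers(train)[selected],
    class_labels = cl,
    class_means = means,
    S = S,
    S_inv = S_inv,
    n_train = nrow(m)
  ), class = "spa_lda")
}

#' Fit a full SPA-LDA model
#'
#' Runs both phases of SPA-LDA -- chain construction on the class-mean
#' centred training set, validation-cost minimisation over all chain
#' prefixes -- then fits the Mahalanobis LDA on the winning subset.
#'
#' @inheritParams select_variables
#' @return A `spa_lda` model additionally carrying `cost_curve` and the
#'   selection metadata.
#' @export
#' @examples
#' cfg <- synthetic_config(wavenumber_end = 5000, seed = 7)
#' subs <- split_subsets(generate_spectra(cfg), seed = 7)
#' fit <- spa_lda(preprocess(subs$training), preprocess(subs$validation), l_max = 5)
#' tidy(fit)
spa_lda <- function(train, validation, l_max = 10L) {
  sel <- select_variables(train, validation, l_max)
  model <- fit_lda(train, sel$selected)
  model$cost_curve <- sel$cost_curve
  model$n_candidates <- sel$n_candidates
  model
}

#' @export
print.spa_lda <- function(x, ...) {
  cat(sprintf(
    "SPA-LDA model: %d selected variables (%s cm^-1), %d classes, %d training samples\n",
    length(x$selected),
    paste(format_wavenumber(x$selected_wavenumbers), collapse = ", "),
    length(x$class_labels), x$n_train))
  invisible(x)
}

#' Classify spectra with a fitted SPA-LDA model
#'
#' Each spectrum is assigned the class whose Mahalanobis distance (pooled
#' covariance) to its mean is smallest. Exact ties go to the smaller class
#' code and are reported via a message.
#'
#' @param object A `spa_lda` model.
#' @param spectra A spectra tibble on the model's wavenumber grid.
#' @param ... Unused.
#' @return Integer vector of predicted class codes.
#' @export
predict.spa_lda <- function(object, spectra, ...) {
  spectra <- as_spectra(spectra)
  wn <- spectra_wavenumbers(spectra)
  if (length(wn) != length(object$wavenumbers) ||
      any(wn != object$wavenumbers)) {
    abort_size("spectra are not on the model's wavenumber grid")
  }
  V <- spectra_matrix(spectra)[, object$selected, drop = FALSE]
  d2 <- mahal_all(V, object$class_means, object$S_inv)
  ties <- apply(d2, 1, function(r) sum(r == min(r)) > 1)
  if (any(ties)) {
    message(sprintf(
      "%d sample(s) equidistant from several class means; assigned the smaller class code",
      sum(ties)))
  }
  object$class_labels[apply(d2, 1, which.min)]
}

#' Tidiers for `spa_lda` models
#'
#' `tidy()` lists the selected variables with their wavenumbers and class
#' mean values; `glance()` gives a one-row summary including the minimum
#' validation cost when the model was fitted via [spa_lda()].
#'
#' @param x A `spa_lda` model.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy spa_lda
#' @export
tidy.spa_lda <- function(x, ...) {
  out <- tibble::tibble(
    index = x$selected,
    wavenumber = x$selected_wavenumbers
  )
  for (ci in seq_along(x$class_labels)) {
    out[[paste0("mean_class_", x$class_labels[ci])]] <- x$class_means[ci, ]
  }
  out
}

#' @rdname tidy.spa_lda
#' @method glance spa_lda
#' @export
glance.spa_lda <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    n_classes = length(x$class_labels),
    n_train = x$n_train,
    min_cost = if (!is.null(x$cost_curve)) min(x$cost_curve$cost) else NA_real_
  )
}

#' Plot the SPA-LDA validation cost curve
#'
#' Best validation cost per subset size, with the selected size marked.
#'
#' @param object A `spa_lda` model fitted via [spa_lda()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spa_lda
#' @export
autoplot.spa_lda <- function(object, ...) {
  if (is.null(object$cost_curve)) {
    abort_input("model has no cost curve; fit it with spa_lda()")
  }
  cc <- object$cost_curve
  sel <- cc[cc$n_variables == length(object$selected), ]
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$n_variables, y = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = sel, colour = "red", size = 3) +
    ggplot2::labs(x = "number of variables", y = expression(G[cost]))
}
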
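#' Configuration for the end-to-end diagnostic pipeline
#'
#' Bundles the synthetic-data configuration, preprocessing choices, model
#' complexity limits and named seeds that drive one full reproducible run:
#' generate, split, preprocess, PCA, SPA-LDA, PLS-DA, evaluate, compare.
#'
#' @param synthetic A [synthetic_config()].
#' @param apply_snv,derivative,window,polyorder Preprocessing settings, see
#'   [preprocess()].
#' @param l_max Maximum SPA-LDA subset size.
#' @param max_lv Largest PLS-DA latent-variable count tried in
#'   cross-validation.
#' @param split_seed,cv_seed Seeds for subset splitting and CV fold
#'   membership (generation uses `synthetic$seed`).
#' @param n_pca_components Components retained in the PCA report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            apply_snv = TRUE, derivative = TRUE,
                            window = 11L, polyorder = 2L,
                            l_max = 10L, max_lv = 10L,
                            split_seed = 2L, cv_seed = 3L,
                            n_pca_components = 3L) {
  cfg <- list(
    synthetic = validate_synthetic_config(synthetic),
    apply_snv = apply_snv, derivative = derivative,
    window = as.integer(window), polyorder = as.integer(polyorder),
    l_max = as.integer(l_max), max_lv = as.integer(max_lv),
    split_seed = as.integer(split_seed), cv_seed = as.integer(cv_seed),
    n_pca_components = as.integer(n_pca_components)
  )
  check_sg_params(cfg$window, cfg$polyorder)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full diagnostic workflow on synthetic spectra
#'
#' Executes the study workflow end to end: generate two-class spectra,
#' split them into training / validation / test subsets, preprocess each
#' subset in one pass, report PCA scores of the preprocessed training set,
#' fit SPA-LDA (chains on training, cost on validation) and PLS-DA (LV
#' count by 5-fold CV on training), and evaluate both on all three subsets.
#' The test set enters only this final evaluation -- it never touches
#' variable selection, cross-validation or fitting. Bit-reproducible given
#' the configured seeds.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all intermediate tables
#'   (spectra, preprocessed spectra, PCA scores, both model reports, the
#'   comparison table) and a run log are written there as plain text.
#' @return A list: `subsets`, `preprocessed`, `pca`, `spa` model, `pls`
#'   model, `cv`, `reports` (per classifier) and `comparison`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(synthetic_config(wavenumber_end = 5000, seed = 11))
#' res <- run_pipeline(cfg)
#' res$comparison
#' }
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }

  say("generate: seed %d", config$synthetic$seed)
  pooled <- stage("generate", generate_spectra(config$synthetic))
  say("split: seed %d", config$split_seed)
  subsets <- stage("split", split_subsets(
    pooled, config$synthetic$n_per_class_per_subset, seed = config$split_seed))
  say("preprocess: snv=%s derivative=%s window=%d polyorder=%d",
      config$apply_snv, config$derivative, config$window, config$polyorder)
  prep <- stage("preprocess", purrr::map(subsets, preprocess,
    apply_snv = config$apply_snv, derivative = config$derivative,
    window = config$window, polyorder = config$polyorder))
  pca_fit <- stage("pca", pca_spectra(prep$training, config$n_pca_components))
  say("pca: first %d components explain %.1f%% of variance",
      config$n_pca_components, 100 * sum(pca_fit$explained_fraction))
  spa_fit <- stage("spa_lda", spa_lda(prep$training, prep$validation,
                                      l_max = config$l_max))
  say("spa_lda: selected %d variable(s) at %s cm^-1",
      length(spa_fit$selected),
      paste(format_wavenumber(spa_fit$selected_wavenumbers), collapse = ", "))
  cv <- stage("pls_cv", cross_validate_lvs(prep$training, config$max_lv,
                                           seed = config$cv_seed))
  say("pls_da: cross-validation chose %d LV(s)", cv$n_lv)
  pls_fit <- stage("pls_fit", fit_pls(prep$training, n_lv = cv$n_lv))
  spa_report <- stage("evaluate", evaluate_classifier(spa_fit, prep))
  pls_report <- stage("evaluate", evaluate_classifier(pls_fit, prep))
  comparison <- compare_reports(spa_report, pls_report)
  for (i in seq_len(nrow(comparison))) {
    say("%s: SPA-LDA sens %.1f%% spec %.1f%% | PLS-DA sens %.1f%% spec %.1f%%",
        comparison$subset[i],
        comparison$sensitivity_a[i], comparison$specificity_a[i],
        comparison$sensitivity_b[i], comparison$specificity_b[i])
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    for (nm in names(subsets)) {
      write_spectra(subsets[[nm]], p(sprintf("%s_raw.csv", nm)))
      write_spectra(prep[[nm]], p(sprintf("%s_preprocessed.csv", nm)))
    }
    write_pca_scores(pca_fit, p("pca_scores.csv"))
    jsonlite::write_json(list(
      selected_indices = spa_fit$selected,
      selected_wavenumbers = spa_fit$selected_wavenumbers,
      cost_curve = spa_fit$cost_curve[c("n_variables", "cost")],
      class_means = spa_fit$class_means,
      pooled_covariance = spa_fit$S
    ), p("spa_lda_report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(
      n_lv = pls_fit$n_lv,
      threshold = pls_fit$threshold,
      cv = cv$results,
      regression_vector = pls_fit$regression_vector
    ), p("pls_da_report.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(tibble::as_tibble(comparison), p("comparison.csv"),
                     progress = FALSE)
    writeLines(log_lines, p("run_log.txt"))
  }

  list(subsets = subsets, preprocessed = prep, pca = pca_fit,
       spa = spa_fit, pls = pls_fit, cv = cv,
       reports = list(spa_lda = spa_report, pls_da = pls_report),
       comparison = comparison, log = log_lines)
}
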
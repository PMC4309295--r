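# Run code with a local RNG state so package functions are deterministic
# given an explicit seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

abort_size <- function(msg) rlang::abort(msg, class = "nirspa_size_error")
abort_config <- function(msg) rlang::abort(msg, class = "nirspa_config_error")
abort_degenerate <- function(msg) rlang::abort(msg, class = "nirspa_degenerate_error")
abort_singular <- function(msg) rlang::abort(msg, class = "nirspa_singular_error")
abort_input <- function(msg) rlang::abort(msg, class = "nirspa_input_error")

# Invert a covariance matrix, refusing near-singular input rather than
# regularizing it. The reciprocal condition estimate is reported so the
# caller can see how close to singular the matrix is.
safe_inverse <- function(S, tol = 1e-12, what = "pooled covariance") {
  S <- as.matrix(S)
  rc <- tryCatch(rcond(S), error = function(e) 0)
  if (!is.finite(rc) || rc < tol) {
    abort_singular(sprintf(
      "%s matrix is numerically singular (reciprocal condition estimate %.3g); refusing to invert",
      what, rc))
  }
  solve(S)
}
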
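#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators are pure
#' functions of their arguments and never perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if
      (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic substream seed: one stream per parameter so that adding a
# parameter never perturbs another parameter's draws. Kept below 2^31 - 1.
stream_seed <- function(root, i) {
  as.integer(((as.numeric(root) %% 2147483647) + i * 1000003) %% 2147483646) + 1L
}

#' Round to two significant figures
#'
#' Report-time rendering rule: raw results keep full precision, rendered
#' tables round monetary and share figures to two significant figures.
#'
#' @param x numeric vector.
#' @return `x` rounded to two significant figures.
#' @export
render_2sf <- function(x) signif(x, 2)

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("hbp_usage_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("hbp_validation_error", "error")))
}
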
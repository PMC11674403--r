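#' @useDynLib twindyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif cov cor sd lm resid anova pf pchisq qchisq qf
#'   kmeans fft optim optimHess rbinom coef BIC approx model.matrix
#'   as.formula na.exclude quantile
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible substream seed from a label
#'
#' A stable 31-bit polynomial hash of `label`, mixed with a global seed. Used to
#' fan one cohort seed out to per-subject simulation streams so that results do
#' not depend on iteration order.
#'
#' @param seed global integer seed.
#' @param label character scalar (e.g. a subject id).
#' @return An integer in `[0, 2^31)`.
#' @keywords internal
substream_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Canonical electrophysiological frequency bands
#'
#' The five canonical bands used throughout: delta (1-3 Hz), theta (4-7 Hz),
#' alpha (8-12 Hz), beta (13-25 Hz) and gamma (30-45 Hz).
#'
#' @return A named list of band definitions from [band_definition()].
#' @export
#' @examples
#' canonical_bands()$alpha
canonical_bands <- function() {
  list(
    delta = band_definition("delta", 1, 3),
    theta = band_definition("theta", 4, 7),
    alpha = band_definition("alpha", 8, 12),
    beta  = band_definition("beta", 13, 25),
    gamma = band_definition("gamma", 30, 45)
  )
}

#' Define a frequency band
#'
#' @param name band label.
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!(is.numeric(low_hz) && is.numeric(high_hz) &&
        low_hz > 0 && high_hz > low_hz)) {
    stop("band edges must satisfy 0 < low_hz < high_hz", call. = FALSE)
  }
  structure(list(name = as.character(name), low_hz = low_hz,
                 high_hz = high_hz),
            class = "band_definition")
}
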
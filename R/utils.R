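#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib prophagecomp, .registration = TRUE
NULL

#' Derive a reproducible substream seed from a master seed and a stream name
#'
#' All stochastic stages draw their seed from one master seed through named
#' substreams, so that stages are independently reproducible and adding a new
#' stage never perturbs another stage's random numbers.
#'
#' @param master integer master seed.
#' @param stream character stream name, e.g. `"enrichment.bootstrap"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(master) %% 2147483647 * 48271 + h) %% 2147483646)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
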
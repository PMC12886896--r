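# internal helpers shared across modules

#' @importFrom stats median rnorm runif rpois rnbinom var pnorm pt phyper
#'   p.adjust t.test setNames
#' @importFrom utils head
NULL

# Derive a reproducible 31-bit integer seed from a base seed plus arbitrary
# string/numeric tags (stage name, sample id, ...).  Polynomial rolling hash
# modulo the Mersenne prime 2^31 - 1 keeps every derived seed a valid R seed.
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  tags <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                       character(1)), collapse = "|")
  for (code in utf8ToInt(tags)) h <- (h * 31 + code) %% m
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state so generators are pure
# functions of their seed and never disturb the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fixed float formatting used for all text outputs (hash-stable manifests)
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(format(v, scientific = FALSE))
    formatC(signif(v, 6), format = "g", digits = 6)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) stop(sprintf(...), call. = FALSE)
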
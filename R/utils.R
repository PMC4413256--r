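#' @importFrom rlang %||% abort warn inform
#' @importFrom stats plogis qlogis rbinom rpois rnorm runif rbeta var sd
#'   median cor cor.test fisher.test p.adjust binom.test wilcox.test
#'   optim lm lm.fit pt pchisq qnorm quantile setNames complete.cases
#'   ks.test optimize coef
#' @importFrom utils head tail
NULL

# Internal: stop unless a condition holds, with a formatted message.
stopf <- function(cond, fmt, ...) {
  if (!cond) abort(sprintf(fmt, ...))
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x > 0

is_fraction <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1

# Draw a reproducible sub-seed stream: k seeds derived from one master seed,
# kept below .Machine$integer.max so they are valid R seeds.
derive_seeds <- function(seed, k) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, k)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Run code with a local RNG seed, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  force(code)
}
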
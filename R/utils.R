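#' Run code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state so simulation helpers never clobber the
#' session RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a stable child seed for a pipeline stage from the global seed.
# Keeps everything below 2^31 - 1 so R's integer seeds stay valid.
child_seed <- function(seed, stage) {
  offsets <- c(
    generate = 104729L, preprocess = 1299709L, fit = 15485863L,
    bounds = 32452843L, evaluate = 49979687L, subset = 67867967L
  )
  if (!stage %in% names(offsets)) stop("unknown pipeline stage: ", stage)
  as.integer((as.numeric(seed) + offsets[[stage]]) %% 2147483647)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config(field, "must be a single non-missing number")
  }
  if (x < lower || x > upper) {
    stop_config(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  invisible(x)
}
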
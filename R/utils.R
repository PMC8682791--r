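# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# population (denominator n) standard deviation; the convention used for the
# cV statistic and the DAPI decondensation proxy
pop_sd <- function(x) {
  n <- length(x)
  if (n < 2L) stop("population SD needs at least 2 values")
  sqrt(sum((x - mean(x))^2) / n)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# wrap a generated dataset with its ground truth record
sim_truth <- function(generator, seed, params) {
  structure(list(generator = generator, seed = seed, params = params),
            class = "sim_truth")
}

assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single number", name)
  if (strict && x <= lower) stopf("`%s` must be > %g", name, lower)
  if (!strict && x < lower) stopf("`%s` must be >= %g", name, lower)
  invisible(x)
}
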
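#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations (signature-score control sampling, the
#' simulator) never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# stop() with a consistent condition class so callers can distinguish
# configuration errors from runtime failures
config_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("scatlaskit_config_error", "error")))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error("'%s' must be a single finite number", name)
  if (strict_min && x <= min) config_error("'%s' must be > %s", name, format(min))
  if (!strict_min && x < min) config_error("'%s' must be >= %s", name, format(min))
  invisible(x)
}

#' @importFrom methods as is new
#' @importFrom stats var setNames rnbinom rgamma p.adjust pnorm chisq.test
#'   fisher.test rmultinom sd cor ave
#' @importFrom utils write.table read.delim head
NULL
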
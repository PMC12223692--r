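#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's `.Random.seed`,
#' so library functions are reproducible without clobbering user RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a named substream seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed split into named
#' substreams (simulate / split / embed / init / bootstrap / ...), so that
#' e.g. changing the bootstrap count never perturbs the simulated cohort.
#'
#' @param root integer root seed.
#' @param name substream name.
#' @return an integer seed strictly below 2^31.
#' @export
substreamSeed <- function(root, name) {
  streams <- c(simulate = 1L, split = 2L, embed = 3L, init = 4L,
               bootstrap = 5L, dropout = 6L, scenario = 7L, semisynthetic = 8L)
  off <- streams[[match.arg(name, names(streams))]]
  as.integer((abs(as.integer(root)) %% 1000003L) * 1009L + off)
}

# clamp away from 0/1 before taking logs
.clampProb <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

.isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == as.integer(x)

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
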
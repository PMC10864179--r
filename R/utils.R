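`%||%` <- function(a, b) if (is.null(a)) b else a

# Signalled conditions carry subclasses so callers (and the CLI) can map them
# to exit codes: usage errors vs data/format errors.
msaforge_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "msaforge_error", "error")))
}
format_error <- function(msg) msaforge_error(msg, "msaforge_format_error")
usage_error <- function(msg) msaforge_error(msg, "msaforge_usage_error")
io_error <- function(msg) msaforge_error(msg, "msaforge_io_error")
undefined_error <- function(msg) msaforge_error(msg, "msaforge_undefined_error")

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' generators never leak global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}
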
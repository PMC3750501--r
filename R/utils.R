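# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the previous global RNG state,
#' so seeded package functions do not disturb the caller's random stream.
#' With `seed = NULL` the current stream is used unchanged.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# collect-all validation: accumulate messages, then stop once
check_collector <- function() {
  msgs <- character()
  list(
    add = function(ok, msg) if (!isTRUE(ok)) msgs[[length(msgs) + 1L]] <<- msg,
    fail_if_any = function(prefix = "invalid input") {
      if (length(msgs))
        stop(paste0(prefix, ":\n", paste0("  - ", msgs, collapse = "\n")),
             call. = FALSE)
    },
    messages = function() msgs
  )
}

.log_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

#' Package logging level
#'
#' Messages at or above `getOption("specmap.log_level", "WARN")` are emitted
#' via [message()].
#' @noRd
sm_log <- function(level, fmt, ...) {
  thr <- .log_levels[[toupper(getOption("specmap.log_level", "WARN"))]]
  if (.log_levels[[level]] >= thr)
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

# Frobenius norm
fnorm <- function(m) sqrt(sum(m^2))

vnorm <- function(v) sqrt(sum(v^2))
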
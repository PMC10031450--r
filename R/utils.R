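#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# All character offsets in this package are 0-based, half-open [start, end)
# over code points; R's substr is 1-based and inclusive, hence the shift.
slice_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

pghd_log <- function(level, msg, json = FALSE) {
  if (isTRUE(json)) {
    message(jsonlite::toJSON(list(level = level, message = msg),
                             auto_unbox = TRUE))
  } else {
    message(sprintf("[%s] %s", level, msg))
  }
  invisible(NULL)
}

# Runs expr with the global RNG seeded by `seed`, restoring the caller's RNG
# state afterwards so generation never leaks into user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
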
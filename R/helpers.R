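# Internal utilities shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
abort <- function(msg, class = "pbtksim_error", ...) {
  stop(structure(
    class = c(class, "pbtksim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Parse a ";"-separated numeric list field (e.g. pKa lists) stored in a CSV.
parse_num_list <- function(s) {
  if (is.null(s) || length(s) == 0L) return(numeric(0))
  if (is.numeric(s)) return(s[is.finite(s)])
  s <- trimws(as.character(s))
  if (length(s) == 1L && (is.na(s) || !nzchar(s))) return(numeric(0))
  out <- suppressWarnings(as.numeric(strsplit(paste(s, collapse = ";"), ";")[[1]]))
  out[is.finite(out)]
}

format_num_list <- function(x) {
  if (length(x) == 0L) return("")
  paste(vapply(x, function(v) sprintf("%.17g", v), character(1)), collapse = ";")
}
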
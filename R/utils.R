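# internal helpers: seeded evaluation and logging

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL evaluates in the current
# stream (so an outer with_seed() governs determinism).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  expr
}

# leveled, timestamped logging to stderr and (optionally) a file
dmqa_log <- function(msg, level = "INFO", logfile = NULL, verbose = TRUE) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  if (isTRUE(verbose)) message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
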
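# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state so fixture construction is
# byte-stable and never disturbs the caller's random stream.
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

# Append timestamped entries to an in-package audit log (a character vector
# carried in an environment). Manual curation steps of the original workflow
# (consensus tie-breaks, excluded columns, reference choices) are replaced by
# automatic rules, so every such decision is recorded here.
new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$entries <- character(0)
  env
}

log_note <- function(log, ...) {
  if (is.null(log)) return(invisible(NULL))
  log$entries <- c(log$entries, paste0(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
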
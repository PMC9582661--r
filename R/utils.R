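# Internal helpers: classed errors and seeded evaluation.

# Classed conditions let the CLI map failures onto distinct exit codes:
# usage errors (bad arguments), format errors (unparseable/inconsistent
# files), numeric errors (mathematically degenerate input).
srd_abort <- function(message, class = "srd_usage_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "srd_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

abort_usage   <- function(...) srd_abort(paste0(...), "srd_usage_error")
abort_format  <- function(...) srd_abort(paste0(...), "srd_format_error")
abort_numeric <- function(...) srd_abort(paste0(...), "srd_numeric_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a deterministic RNG state, restoring the caller's
# stream afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-task seed derivation from a master seed. Kept strictly
# below 2^31 - 1 so the result is a valid R integer seed.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (v in idx) h <- (h * 48271 + as.double(v) + 1) %% 2147483647
  as.integer(h)
}

is_square_matrix <- function(M) is.matrix(M) && nrow(M) == ncol(M)

check_dissimilarity <- function(M, what = "dissimilarity matrix") {
  if (!is_square_matrix(M) || !is.numeric(M))
    abort_usage(what, " must be a square numeric matrix")
  if (any(!is.finite(M)))
    abort_numeric(what, " contains non-finite entries")
  if (max(abs(M - t(M))) > 1e-9)
    abort_usage(what, " must be symmetric")
  if (any(diag(M) != 0))
    abort_usage(what, " must have a zero diagonal")
  if (any(M < 0))
    abort_usage(what, " must be non-negative")
  invisible(M)
}
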
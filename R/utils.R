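# Internal helpers: seed streams and argument checks.

# Deterministically derive an independent sub-seed from a master seed and an
# integer stream id, using a Lehmer-style mix kept inside 32-bit range.
# Distinct streams (data, init, shuffle, train masks, test masks, ...) get
# distinct ids so e.g. conditions can share data order while drawing
# different dropout masks.
sub_seed <- function(master, id) {
  master <- as.double(master %% 2147483647)
  id <- as.double(id %% 2147483647)
  s <- (master * 48271 + id * 16807 + 12345) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` with the given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop_bad("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok)
    stop_bad("'%s' must be a single number in [%g, %g%s", name, lo, hi,
             if (open_hi) ")" else "]")
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
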
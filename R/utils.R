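## internal helpers: validation and seed splitting

.stopv <- function(...) stop(..., call. = FALSE)

.checkNumber <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopv(name, " must be a single finite number")
  if (positive && x <= 0) .stopv(name, " must be > 0")
  if (nonneg && x < 0) .stopv(name, " must be >= 0")
  invisible(x)
}

# Counter-based seed splitting: each (stream, counter) pair maps to a stable
# 31-bit seed, so enlarging a cohort never reshuffles existing subjects.
# Simple multiplicative mixing kept within exact double-precision integers.
.splitSeed <- function(master, counter) {
  master <- as.numeric(master) %% 2147483647
  lo <- master %% 65536
  hi <- master %/% 65536
  h <- (lo * 40503 + hi * 30269 + as.numeric(counter) * 2654435 + 1013904) %%
    2147483629
  as.integer(h)
}

# run expr under a locally derived seed without disturbing the global stream
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic numeric formatting that survives a CSV round trip bit-exactly
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}
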
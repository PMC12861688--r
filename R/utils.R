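# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream untouched.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Parse a "chrom:start-end" region string into list(chrom, start, end)
# (1-based inclusive coordinates as typed; callers convert as needed).
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4) {
    stop("cannot parse region '", region, "' (expected chrom:start-end)")
  }
  num <- function(x) as.integer(gsub(",", "", x, fixed = TRUE))
  list(chrom = m[2], start = num(m[3]), end = num(m[4]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)
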
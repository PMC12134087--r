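# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. A NULL seed leaves the RNG alone.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage seed from a master seed, kept within 32-bit integer range.
deriveSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

asUTC <- function(t) {
  stopifnot(inherits(t, "POSIXct"))
  attr(t, "tzone") <- "UTC"
  t
}

parseTimestamps <- function(s) {
  s <- trimws(as.character(s))
  out <- as.POSIXct(rep(NA_real_, length(s)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    todo <- is.na(out) & !is.na(s) & nzchar(s)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(s[todo], format = fmt, tz = "UTC")
  }
  out
}

formatTimestamps <- function(t) {
  format(asUTC(t), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

HOUR <- 3600
DAY <- 86400
YEAR_DAYS <- 365
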
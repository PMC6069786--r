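# Internal helpers shared across modules.

# reverse cumulative sum: out[i] = sum(x[i:n]); column-wise for matrices
.revcumsum <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n <= 1L) return(x)
    out <- x[n:1L, , drop = FALSE]
    for (j in seq_len(ncol(out))) out[, j] <- cumsum(out[, j])
    out[n:1L, , drop = FALSE]
  } else {
    rev(cumsum(rev(x)))
  }
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the user's stream.
.withSeed <- function(seed, code) {
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

# Deterministic 31-bit hash of a string; used to derive independent
# per-cohort seeds from a master seed without any RNG draw.
.stableHash <- function(x) {
  h <- 0
  for (k in utf8ToInt(as.character(x))) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

.deriveSeed <- function(master, tag) {
  as.integer((as.numeric(master) * 7919 + .stableHash(tag)) %% 2147483647)
}

.calibrationError <- function(msg) {
  stop(errorCondition(msg,
    class = c("calibrationError", "gliomaScreenError")))
}

.convergenceError <- function(msg) {
  stop(errorCondition(msg,
    class = c("convergenceError", "gliomaScreenError")))
}

.inputError <- function(msg) {
  stop(errorCondition(msg, class = c("inputError", "gliomaScreenError")))
}

#' Format a percentage the way cohort tables print it
#'
#' Percentages are shown to one decimal place, or two when the value is
#' below 10 (so a 23/311 mutation rate prints as \code{"7.40"}). Missing
#' values must be excluded from \code{denom} by the caller.
#'
#' @param count Numerator count(s).
#' @param denom Denominator (missing values excluded).
#' @return Character vector of formatted percentages (no \code{"\%"} sign).
#' @examples
#' formatPercent(159, 424) # "37.5"
#' formatPercent(23, 311)  # "7.40"
#' @export
formatPercent <- function(count, denom) {
  pct <- 100 * count / denom
  ifelse(is.finite(pct) & pct < 10, sprintf("%.2f", pct), sprintf("%.1f", pct))
}
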
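`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integer percentage of a count
#'
#' `100 * k / n`, rounded half away from zero to the requested number
#' of digits -- the rounding used throughout the package's reports
#' (54.5% prints as 55, -54.5% as -55).
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimal digits to keep (default 0).
#' @return Numeric percentage.
#' @examples
#' percent_of(1301, 9273)  # 14
#' @export
percent_of <- function(k, n, digits = 0) {
  round_half_up(100 * k / n, digits)
}

## round half away from zero at `digits`; used wherever a percentage is
## reported as an integer (54.5 -> 55, not banker's 54)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## 32-bit FNV-1a over the characters of a string, done in double arithmetic
## (R has no native unsigned 32-bit integer). Used to stamp run reports with
## a config fingerprint and to split one user seed into per-stage streams.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in as.integer(utf8ToInt(s)) %% 256L) {
    ## xor with a byte only touches the low 8 bits
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    ## multiply by the FNV prime mod 2^32, split to avoid overflow
    lo <- h %% 2^16
    hi <- (h - lo) / 2^16
    h <- (lo * 16777619 + ((hi * 16777619) %% 2^16) * 2^16) %% 2^32
  }
  h
}

## one user-facing integer seed -> independent per-stage streams
derive_seed <- function(seed, stream) {
  as.integer(fnv1a32(paste0(seed, "/", stream)) %% 2147483647)
}

config_hash <- function(x) {
  s <- paste(
    vapply(x, function(v) paste(format(v, digits = 15), collapse = ","),
           character(1)),
    collapse = ";"
  )
  h <- fnv1a32(s)
  paste0(format(as.hexmode(as.integer(h %/% 2^16)), width = 4),
         format(as.hexmode(as.integer(h %% 2^16)), width = 4))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stopf("configuration error: `%s` must be a proportion in [0, 1], got %s",
          name, format(x))
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
    stopf("configuration error: `%s` must be a positive number, got %s",
          name, format(x))
  invisible(x)
}
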
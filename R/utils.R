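#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed error
#' @noRd
mr_stop <- function(msg, class = "mregle_error", ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Run an expression under a temporary RNG state
#'
#' Restores the caller's RNG state afterwards so generators are pure
#' functions of (parameters, seed).
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Derive a child seed from a base seed and a stream index
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1009) %% 2147483647L)
}

#' Type-7 percentile (linear interpolation between order statistics)
#'
#' Used consistently for QC cutoffs and the 90th-percentile scale factor.
#' @noRd
pctl <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

#' FNV-1a 32-bit hash of a character vector
#'
#' Pure-R implementation of the Fowler-Noll-Vo 1a hash; byte-for-byte
#' identical across platforms and languages, which is what makes the
#' train/validation/test split reproducible anywhere.
#' @noRd
fnv1a32 <- function(ids) {
  vapply(ids, function(id) {
    bytes <- as.integer(charToRaw(id))
    h <- 2166136261
    for (b in bytes) {
      h <- bitwXor_dbl(h, b)
      ## h * 16777619 mod 2^32, split to stay inside double precision
      h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

## XOR for doubles holding 32-bit unsigned values
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Survival probability of a chi-squared distribution with underflow guard
#'
#' Computes the upper-tail probability on the log scale internally and
#' floors the returned double at the smallest positive normal number so
#' extreme statistics never collapse to zero.
#' @noRd
chisq_sf <- function(x, df) {
  logp <- stats::pchisq(x, df = df, lower.tail = FALSE, log.p = TRUE)
  p <- exp(logp)
  pmax(p, .Machine$double.xmin)
}

#' log10 upper-tail chi-squared probability
#' @noRd
chisq_log10sf <- function(x, df) {
  stats::pchisq(x, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
}
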
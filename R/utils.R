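# internal helpers: error signalling, seed substreams, config hashing

#' @noRd
wp_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "wantpower_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package flows from a single root seed through named
#' substreams so that each stage (cohort simulation, splitting, resampling)
#' is independently reproducible.
#'
#' @param seed integer root seed.
#' @param stream character substream name.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- fnv1a(paste0(stream, ":", format(seed)))
  as.integer(h %% 2147483629)
}

# FNV-1a 32-bit over UTF-8 bytes, done in double arithmetic (exact below 2^53)
#' @noRd
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor for doubles representing 32-bit unsigned ints
#' @noRd
bitwXor_dbl <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    ab <- a %% 2
    bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2
    b <- (b - bb) / 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

# evaluate expr with a local RNG state; global .Random.seed is restored
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Hash a configuration object
#'
#' Stable FNV-1a hash of the canonical JSON serialisation of a list; used to
#' stamp output artifacts so runs with identical configurations are
#' recognisable.
#'
#' @param config a list.
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- fnv1a(as.character(js))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
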
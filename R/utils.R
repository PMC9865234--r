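# Internal helpers: seeded evaluation, seed derivation, config hashing.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Polynomial string hash with modulus 2^31 - 1; all intermediates stay well
# below 2^53 so double arithmetic is exact.
string_hash31 <- function(x) {
  stopifnot(length(x) == 1L, is.character(x))
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

#' Derive a stage seed from a global seed
#'
#' Hash-chains a global integer seed with any number of string/number labels
#' (stage name, participant id, session, ...) into a reproducible seed in
#' `[1, 2^31 - 2]`. Used so that one run-level seed deterministically fixes
#' every stochastic stage, independent of evaluation order.
#'
#' @param seed Integer global seed.
#' @param ... Labels identifying the stage (coerced to character).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  as.integer(string_hash31(key) %% 2147483645 + 1)
}

# Short hexadecimal fingerprint of an R object (via its JSON serialization);
# embedded in artifacts so outputs of different configurations cannot be
# silently mixed.
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", string_hash31(as.character(js)))
}

# Unit-variance band-limited Gaussian noise: white noise low-passed with a
# zero-lag 2nd-order Butterworth filter and rescaled to unit SD. The caller's
# RNG state is consumed (callers wrap in with_seed).
bandlimited_noise <- function(n, fs, cutoff_hz) {
  stopifnot(n > 0, cutoff_hz > 0, cutoff_hz < fs / 2)
  w <- stats::rnorm(n + 2L * ceiling(fs))  # pad to absorb filter edge effects
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  s <- signal::filtfilt(bf, w)
  s <- s[(ceiling(fs) + 1L):(ceiling(fs) + n)]
  sdv <- stats::sd(s)
  if (sdv < .Machine$double.eps) return(rep(0, n))
  (s - mean(s)) / sdv
}

`%||%` <- function(a, b) if (is.null(a)) b else a
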
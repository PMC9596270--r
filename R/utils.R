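#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (0.005 -> 0.01), the
#' convention used by the published Celeb-DF agreement tables, as opposed to
#' the IEEE round-half-even rule of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)  # 0.13, 0.14
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-9 guard keeps decimal ties (e.g. 2.675) from falling just below
  # the halfway point in binary floating point
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# condition helpers: every user-facing failure carries a subclass so drivers
# can map it to an exit status
stop_format <- function(msg, ...) {
  abort(msg, class = c("emotransfer_format_error", "emotransfer_error"), ...)
}
stop_identity <- function(msg, ...) {
  abort(msg, class = c("emotransfer_identity_error", "emotransfer_error"), ...)
}
stop_contract <- function(msg, ...) {
  abort(msg, class = c("emotransfer_contract_error", "emotransfer_error"), ...)
}
stop_config <- function(msg, ...) {
  abort(msg, class = c("emotransfer_config_error", "emotransfer_error"), ...)
}

# Deterministic string hash onto [0, 2^31 - 2], used to derive per-video RNG
# substreams from one root seed. Polynomial rolling hash mod the Mersenne
# prime 2^31 - 1; plain double arithmetic stays exact below 2^53.
hash_seed <- function(root, ...) {
  key <- paste(c(root, ...), collapse = "/")
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% m
  as.integer(h)
}

# run fn with a temporary RNG state seeded from a substream hash
with_substream <- function(root, ..., fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(hash_seed(root, ...))
  fn()
}
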
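# Internal helpers shared across modules.

#' Derive a reproducible RNG stream seed from a base seed and string labels
#'
#' Cohort simulations key their RNG stream per (family, variant, seed) so
#' results do not depend on execution order. The derived seed is a
#' deterministic 31-bit integer.
#'
#' @param seed integer base seed.
#' @param ... character labels (family id, variant id, stage name, ...).
#' @return a single integer in [0, 2^31 - 2].
#' @export
streamSeed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double integer range
  h <- 5381
  for (lab in list(...)) {
    bytes <- utf8ToInt(paste0(as.character(lab), "\x1f"))
    for (b in bytes) h <- (h * 33 + b) %% m
  }
  as.integer((abs(seed) %% m * 69069 + h) %% m)
}

.setStream <- function(seed, ...) {
  set.seed(streamSeed(seed, ...), kind = "Mersenne-Twister")
}

# Structured condition helpers ------------------------------------------------

.famsegError <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "famseg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

.validationError <- function(msg, ids = character()) {
  .famsegError(msg, "famseg_validation_error", ids = ids)
}

.domainError <- function(msg) .famsegError(msg, "famseg_domain_error")

.checkProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    .domainError(sprintf("%s must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

.checkFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    .domainError(sprintf("%s must be TRUE or FALSE", name))
  }
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' Preferred over the Wald interval because the success probabilities this
#' package estimates (chance sharing of a rare allele) are close to zero.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(low, high)`.
#' @export
wilsonInterval <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}
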
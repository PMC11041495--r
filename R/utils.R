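# Internal helpers shared across modules.

# Classed errors so callers (and the CLI) can distinguish user/config errors
# from programming errors.
rr_stop <- function(msg, class = "reidrisk_error", call. = FALSE) {
  stop(structure(
    class = c(class, "reidrisk_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

rr_config_error <- function(msg) rr_stop(msg, "reidrisk_config_error")
rr_validation_error <- function(msg) rr_stop(msg, "reidrisk_validation_error")
rr_degenerate_error <- function(msg) rr_stop(msg, "reidrisk_degenerate_error")

#' Derive a child seed from a master seed
#'
#' Deterministic mixing of a master seed with an index and a stream label, so
#' that every randomised stage of the pipeline draws from its own reproducible
#' stream. The result always fits in a 32-bit signed integer.
#'
#' @param seed master seed (integer).
#' @param index integer index of the child stream.
#' @param salt character stream label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index = 0L, salt = "") {
  h <- 0
  if (nzchar(salt)) {
    for (ch in utf8ToInt(salt)) h <- (h * 131 + ch) %% 2147483629
  }
  # all arithmetic in doubles, exact far below 2^53
  as.integer((abs(seed) %% 2147483629 * 48271 + index * 1009 + h) %% 2147483629)
}

# Run an expression under a local RNG state with the given seed; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Coerce a covariance specification (scalar variance or full matrix) to a
# d x d matrix, checking symmetry and (semi)definiteness.
as_cov <- function(spec, dim, positive = FALSE, what = "covariance") {
  if (is.numeric(spec) && length(spec) == 1L) {
    if (spec < 0 || (positive && spec <= 0)) {
      rr_validation_error(sprintf("%s variance must be %s", what,
                                  if (positive) "positive" else "non-negative"))
    }
    return(diag(spec, dim))
  }
  m <- as.matrix(spec)
  if (nrow(m) != dim || ncol(m) != dim) {
    rr_validation_error(sprintf("%s matrix must be %d x %d", what, dim, dim))
  }
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    rr_validation_error(sprintf("%s matrix must be symmetric", what))
  }
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lo <- if (positive) 1e-12 * max(abs(ev), 1) else -1e-8 * max(abs(ev), 1)
  if (min(ev) < lo) {
    rr_validation_error(sprintf("%s matrix must be positive %sdefinite", what,
                                if (positive) "" else "semi"))
  }
  m
}

sym <- function(m) (m + t(m)) / 2

# log-determinant and inverse of a symmetric positive definite matrix
chol_logdet <- function(m) 2 * sum(log(diag(chol(m))))
chol_inv <- function(m) chol2inv(chol(m))

`%||%` <- function(a, b) if (is.null(a)) b else a
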
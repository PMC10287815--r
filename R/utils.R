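is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Least-squares slope of y on x (first-order polynomial fit).
ls_slope <- function(x, y) {
  stop_unless(length(x) == length(y) && length(x) >= 2,
              "need >= 2 paired points for a first-order fit")
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop("degenerate segment: strain is constant", call. = FALSE)
  sum((x - mx) * (y - mean(y))) / sxx
}

# Run `expr` under a local RNG state seeded with `seed` when non-NULL;
# otherwise advance the caller's RNG stream.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
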
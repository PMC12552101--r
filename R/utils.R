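# internal helpers shared across modules

#' @keywords internal
ve_stop <- function(code, msg, ...) {
  stop(structure(
    list(message = sprintf("%s: %s", code, sprintf(msg, ...)),
         call = sys.call(-1)),
    class = c(paste0("velode_", gsub("-", "_", code)), "velode_error",
              "error", "condition")
  ))
}

#' @keywords internal
ve_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

# numerically safe sigmoid
sigmoid <- function(x) 1 / (1 + exp(-x))

# softplus log(1+e^x), stable for large |x|
softplus <- function(x) {
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  out
}

# fractional part, result in [0, 1)
frac01 <- function(x) x - floor(x)

# derive a reproducible child seed from a base seed and a stream label;
# kept below 2^31 so it is a valid R integer seed
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# row-broadcast multiply of an n x p matrix by a length-p vector
rowmult <- function(M, v) sweep(M, 2L, v, "*")

# Pearson correlation that returns NA for degenerate input instead of warning
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
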
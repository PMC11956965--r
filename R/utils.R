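# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Typed error conditions. Every validation failure in the package raises one
# of these classes so callers (and the CLI) can react without string matching.
seqtime_error <- function(msg, class) {
  stop(structure(
    class = c(class, "seqtime_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error     <- function(msg) seqtime_error(msg, "seqtime_config_error")
validation_error <- function(msg) seqtime_error(msg, "seqtime_validation_error")
format_error     <- function(msg) seqtime_error(msg, "seqtime_format_error")
io_error         <- function(msg) seqtime_error(msg, "seqtime_io_error")

assert_that <- function(ok, msg, error = validation_error) {
  if (!isTRUE(ok)) error(msg)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# Centered rolling mean with edge shrinkage: the mean is taken over the
# available frames when the window sticks out past either end, so edges are
# never padded or dropped. For an even window w the extra frame goes to the
# right (left = floor((w-1)/2), right = w-1-left).
roll_mean_center <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Per-row z-score over the whole session; zero-variance rows map to zeros.
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- sqrt(rowMeans(m * m) - mu^2)
  sd <- sd * sqrt(ncol(m) / (ncol(m) - 1))
  out <- (m - mu) / sd
  out[sd <= .Machine$double.eps^0.5, ] <- 0
  out
}

fmt_num <- function(x) sprintf("%.17g", x)
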
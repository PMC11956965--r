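# Independent brute-force oracles. These deliberately share no code with
# the package: explicit loops and textbook formulas only.

# Conditioning chain: centered rolling mean with edge shrinkage, session
# z-score, hard floor at floor_z.
condition_oracle <- function(raw, smooth_window = 10, floor_z = 2) {
  out <- raw
  left <- (smooth_window - 1) %/% 2
  right <- smooth_window - 1 - left
  for (nr in seq_len(nrow(raw))) {
    x <- raw[nr, ]
    sm <- numeric(length(x))
    for (i in seq_along(x)) {
      lo <- max(1, i - left); hi <- min(length(x), i + right)
      sm[i] <- mean(x[lo:hi])
    }
    s <- sd(sm)
    z <- if (is.na(s) || s == 0) rep(0, length(sm)) else (sm - mean(sm)) / s
    z[z < floor_z] <- 0
    out[nr, ] <- z
  }
  out
}

# Plug-in mutual information from paired observations.
mi_oracle <- function(x, y) {
  total <- 0
  for (xv in unique(x)) for (yv in unique(y)) {
    pxy <- mean(x == xv & y == yv)
    if (pxy > 0)
      total <- total + pxy * log2(pxy / (mean(x == xv) * mean(y == yv)))
  }
  total
}
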
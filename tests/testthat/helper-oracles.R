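# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition (plain loops, direct moment
# sums, exhaustive enumeration) rather than calling the package's vectorized
# implementations.

emaOracle <- function(x, N) {
  alpha <- 2 / (N + 1)
  y <- numeric(length(x))
  y[1] <- x[1]
  for (n in seq_along(x)[-1]) y[n] <- alpha * x[n] + (1 - alpha) * y[n - 1]
  y
}

macdOracle <- function(x, nShort = 12, nLong = 26) {
  emaOracle(x, nShort) - emaOracle(x, nLong)
}

skewOracle <- function(v) {
  m <- sum(v) / length(v)
  m2 <- sum((v - m)^2) / length(v)
  m3 <- sum((v - m)^3) / length(v)
  m3 / m2^1.5
}

kurtOracle <- function(v) {
  m <- sum(v) / length(v)
  m2 <- sum((v - m)^2) / length(v)
  m4 <- sum((v - m)^4) / length(v)
  m4 / m2^2 - 3
}

confusionOracle <- function(est, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(est)) {
    if (est[i] && truth[i]) tp <- tp + 1L
    else if (est[i] && !truth[i]) fp <- fp + 1L
    else if (!est[i] && truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(accuracy = (tp + tn) / length(est),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

# all load sequences of length n satisfying the protocol constraints
enumerateValidOrders <- function(n) {
  stopifnot(n %% 2 == 0)
  half <- n %/% 2
  combos <- expand.grid(rep(list(c("low", "high")), n),
                        stringsAsFactors = FALSE)
  ok <- apply(combos, 1, function(lab) {
    if (sum(lab == "high") != half) return(FALSE)
    fh <- sum(lab[seq_len(half)] == "high")
    if (abs(fh - half / 2) > 0.5) return(FALSE)
    all(rle(lab)$lengths <= 2)
  })
  unname(apply(combos[ok, , drop = FALSE], 1, paste, collapse = ","))
}

# a trial fixture: 14 channels x 66 samples at 2 Hz with given values on
# one channel (zeros elsewhere)
makeTrial <- function(values = NULL, channel = 1L, load = "low",
                      nch = 14L, base = 0) {
  m <- matrix(base, nch, 66L)
  if (!is.null(values)) m[channel, seq_along(values)] <- values
  new("FnirsTrial", hbo2 = m, hhb = -m / 3, load = load, index = 1L,
      onset = 100, fs = 2)
}

randomRecording <- function(n = 40L, seed = 1, nch = 16L) {
  set.seed(seed)
  fnirsRecording(matrix(rnorm(nch * n), nch), matrix(rnorm(nch * n), nch),
                 montage = channelMontage(seq_len(nch),
                                          if (nch == 16L) c(8L, 10L)
                                          else integer(0)))
}
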
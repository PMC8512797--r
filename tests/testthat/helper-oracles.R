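# Independent brute-force oracles and small fixtures, kept deliberately
# naive (explicit loops) so they share no code with the implementation.

oracleIntensity <- function(values) {
  s <- 0
  for (v in values) s <- s + v
  log10(s / length(values))
}

oracleEntropy <- function(values) {
  tot <- 0
  for (v in values) tot <- tot + v^2
  e <- 0
  for (v in values) {
    p2 <- v^2 / tot
    if (p2 > 0) e <- e - p2 * log2(p2)
  }
  e
}

oracleCoV <- function(values) {
  n <- length(values)
  m <- 0
  for (v in values) m <- m + v
  m <- m / n
  ss <- 0
  for (v in values) ss <- ss + (v - m)^2
  100 * sqrt(ss / (n - 1)) / m
}

# a fully populated r x c grid (no missing electrode)
fullLayout <- function(r, c) gridLayout(r, c, missing = NULL)

# recording with explicitly given per-channel sample vectors (list of
# numeric vectors, canonical channel order)
toyRecording <- function(channels, layout, fs = 1000) {
  emgRecording(do.call(cbind, channels), samplingRate = fs, layout = layout)
}

# map with given per-channel values on an n-channel single-column grid
toyMap <- function(values, normalized = FALSE) {
  activationMap(values, fullLayout(length(values), 1),
                normalized = normalized)
}
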
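# Independent brute-force implementation of the diversity chain with
# explicit loops. Deliberately naive: used only as an oracle for the
# vectorised package code.

oracle_trapz <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1)) {
    s <- s + (t[i + 1] - t[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

oracle_overlap <- function(t, zi, zj) {
  1 - 2 * oracle_trapz(t, zi * zj) /
    (oracle_trapz(t, zi * zi) + oracle_trapz(t, zj * zj))
}

# Z: list of per-species intensity vectors on grid t
oracle_qpd <- function(t, Z, q) {
  S <- length(Z)
  ints <- numeric(S)
  for (i in seq_len(S)) ints[i] <- oracle_trapz(t, Z[[i]])
  p <- ints / sum(ints)
  O <- matrix(0, S, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i != j) O[i, j] <- oracle_overlap(t, Z[[i]], Z[[j]])
    }
  }
  Q <- 0
  for (i in seq_len(S)) for (j in seq_len(S)) Q <- Q + O[i, j] * p[i] * p[j]
  if (Q == 0) return(0)
  if (abs(q - 1) < 1e-6) {
    s <- 0
    for (i in seq_len(S)) {
      for (j in seq_len(S)) {
        s <- s + O[i, j] / Q * p[i] * p[j] * log(p[i] * p[j])
      }
    }
    exp(-s / 2)
  } else {
    s <- 0
    for (i in seq_len(S)) {
      for (j in seq_len(S)) {
        s <- s + O[i, j] / Q * (p[i] * p[j])^q
      }
    }
    s^(1 / (2 * (1 - q)))
  }
}
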
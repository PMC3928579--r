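# Brute-force oracles, deliberately naive and independent of the package
# internals: direct neighbourhood gathering, exhaustive threshold sweeps,
# all-pairs distances.

oracle_median3d <- function(vol, mask = c(3, 3, 3)) {
  d <- dim(vol)
  clampi <- function(v, n) pmin(pmax(v, 1L), n)  # replicate border
  out <- array(NA_real_, d)
  hm <- (mask[1] - 1) / 2; hn <- (mask[2] - 1) / 2; hi <- (mask[3] - 1) / 2
  for (i in seq_len(d[3])) for (n in seq_len(d[2])) for (m in seq_len(d[1])) {
    nb <- vol[clampi(m + (-hm:hm), d[1]),
              clampi(n + (-hn:hn), d[2]),
              clampi(i + (-hi:hi), d[3])]
    s <- sort(as.vector(nb))
    out[m, n, i] <- s[(length(s) + 1) / 2]
  }
  out
}

oracle_otsu <- function(values) {
  sb <- rep(-Inf, 255)
  for (t in 0:254) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values)
    sb[t + 1] <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }
  top <- max(sb)
  mean((0:254)[sb >= top - 1e-8 * top])  # mean over tied maximizing cuts
}

oracle_rpe_argmax <- function(vol) {
  d <- dim(vol)
  out <- matrix(NA_real_, d[2], d[3])
  for (i in seq_len(d[3])) for (n in seq_len(d[2])) {
    col <- vol[, n, i]
    if (max(col) > 0) out[n, i] <- which.max(col)
  }
  out
}

oracle_boundary <- function(bits) {
  # boundary dual to 8-connected foreground: background 4-adjacency
  M <- nrow(bits); N <- ncol(bits)
  out <- matrix(FALSE, M, N)
  for (a in seq_len(M)) for (b in seq_len(N)) {
    if (!bits[a, b]) next
    edge <- FALSE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      aa <- a + d[1]; bb <- b + d[2]
      if (aa < 1 || aa > M || bb < 1 || bb > N || !bits[aa, bb]) edge <- TRUE
    }
    out[a, b] <- edge
  }
  out
}

oracle_min_boundary_distance <- function(cup, disk) {
  cb <- which(oracle_boundary(cup), arr.ind = TRUE)
  db <- which(oracle_boundary(disk), arr.ind = TRUE)
  best <- Inf
  for (a in seq_len(nrow(cb))) for (b in seq_len(nrow(db))) {
    d <- sqrt(sum((cb[a, ] - db[b, ])^2))
    if (d < best) best <- d
  }
  best
}

# half-up rounding used when comparing against printed 2-dp tables
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

disc_matrix <- function(N, I, center, r) {
  (row(matrix(0, N, I)) - center[1])^2 +
    (col(matrix(0, N, I)) - center[2])^2 <= r^2
}
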
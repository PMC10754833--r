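# Independent oracles, deliberately coded from first principles and kept
# free of the package's own implementation paths.

# plain mean binary cross-entropy, elementwise loop
oracle_bce <- function(z, p, eps = 1e-7) {
  z <- as.numeric(z); p <- as.numeric(p)
  tot <- 0
  for (i in seq_along(z)) {
    pi <- min(max(p[i], eps), 1 - eps)
    tot <- tot - (z[i] * log(pi) + (1 - z[i]) * log(1 - pi))
  }
  tot / length(z)
}

# squared Pearson correlation via explicit sums
oracle_r2 <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num^2 / (dx2 * dy2)
}

# single GRU cell written directly from the gate equations
oracle_gru_cell <- function(x, a_prev, w) {
  sigma <- function(v) 1 / (1 + exp(-v))
  gamma_u <- sigma(as.vector(w$Wz %*% x) + as.vector(w$Uz %*% a_prev) + w$bz)
  gamma_r <- sigma(as.vector(w$Wr %*% x) + as.vector(w$Ur %*% a_prev) + w$br)
  a_cand <- tanh(as.vector(w$Wh %*% x) +
                 gamma_r * as.vector(w$Uh %*% a_prev) + w$bh)
  list(a = gamma_u * a_cand + (1 - gamma_u) * a_prev,
       update = gamma_u, reset = gamma_r, candidate = a_cand)
}

# random GRU cell weight set
random_cell_weights <- function(h, din) {
  list(Wz = matrix(rnorm(h * din), h, din),
       Wr = matrix(rnorm(h * din), h, din),
       Wh = matrix(rnorm(h * din), h, din),
       Uz = matrix(rnorm(h * h), h, h),
       Ur = matrix(rnorm(h * h), h, h),
       Uh = matrix(rnorm(h * h), h, h),
       bz = rnorm(h), br = rnorm(h), bh = rnorm(h))
}

zero_cell_weights <- function(h, din) {
  list(Wz = matrix(0, h, din), Wr = matrix(0, h, din),
       Wh = matrix(0, h, din),
       Uz = matrix(0, h, h), Ur = matrix(0, h, h), Uh = matrix(0, h, h),
       bz = rep(0, h), br = rep(0, h), bh = rep(0, h))
}
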
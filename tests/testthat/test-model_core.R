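test_that("one_hot_encode maps alleles to unit pairs", {
  expect_equal(one_hot_encode(c(0, 1, 1)),
               cbind(c(1, 0, 0), c(0, 1, 1)), ignore_attr = TRUE)
  expect_identical(dim(one_hot_encode(numeric(0))), c(0L, 2L))
  x <- rbinom(20, 1, 0.5)
  expect_equal(apply(one_hot_encode(x), 1, which.max) - 1, x)
  expect_error(one_hot_encode(c(0, 2)), "0 or 1")
})

test_that("GRU gates are exactly 0.5 at zero weights and the update gate
           carries state", {
  h <- 5
  w0 <- zero_cell_weights(h, 3)
  out <- gru_cell(rnorm(3), rnorm(h), w0)
  expect_identical(out$update, rep(0.5, h))
  expect_identical(out$reset, rep(0.5, h))
  expect_identical(out$candidate, rep(0, h))

  # forcing the update gate to 0 reduces the state update to a_t = a_(t-1)
  w0$bz <- rep(-1e9, h)
  a_prev <- rnorm(h)
  out2 <- gru_cell(rnorm(3), a_prev, w0)
  expect_identical(out2$update, rep(0, h))
  expect_identical(out2$a, a_prev)
})

test_that("gru_cell agrees with the independent cell oracle", {
  set.seed(101)
  for (i in 1:25) {
    h <- sample(2:6, 1); din <- sample(2:5, 1)
    w <- random_cell_weights(h, din)
    x <- rnorm(din); a <- rnorm(h)
    got <- gru_cell(x, a, w)
    want <- oracle_gru_cell(x, a, w)
    expect_equal(got$a, want$a, tolerance = 1e-12)
    expect_equal(got$update, want$update, tolerance = 1e-12)
    expect_equal(got$candidate, want$candidate, tolerance = 1e-12)
  }
})

test_that("sequential_features identity configuration passes input through", {
  F <- 6
  W <- matrix(0, F, 2); W[1, 1] <- 1; W[2, 2] <- 1
  wts <- list(W = W, b = rep(0, F), gamma = rep(1, F), beta = rep(0, F))
  enc <- one_hot_encode(c(0, 1, 1, 0))
  out <- sequential_features(enc, wts, slope = 1, normalize = FALSE)
  expect_equal(out[1, , 1:2], enc, ignore_attr = TRUE)
  expect_true(all(out[1, , 3:F] == 0))
})

test_that("sequential_features batch statistics and eval determinism", {
  set.seed(55)
  B <- 16; T <- 10; F <- 7
  enc <- array(rbinom(B * T, 1, 0.5), c(B, T, 1))
  enc <- array(c(1 - enc, enc), c(B, T, 2))
  wts <- list(W = matrix(rnorm(F * 2), F, 2), b = rnorm(F),
              gamma = rep(1, F), beta = rep(0, F))
  out <- sequential_features(enc, wts, train = TRUE)
  flat <- matrix(out, B * T, F)
  expect_equal(colMeans(flat), rep(0, F), tolerance = 1e-8)
  bs <- attr(out, "batch_stats")
  # normalised variance is var/(var + eps): unit up to the eps floor
  expect_equal(apply(flat, 2, function(v) mean(v^2)),
               bs$var / (bs$var + 1e-5), tolerance = 1e-10)
  wts$running_mean <- rnorm(F); wts$running_var <- runif(F, 0.5, 2)
  e1 <- sequential_features(enc, wts, train = FALSE)
  e2 <- sequential_features(enc, wts, train = FALSE)
  expect_identical(e1, e2)
})

test_that("compiled generator forward equals the R reference implementation", {
  set.seed(77)
  for (i in 1:5) {
    cfg <- generator_config(hidden_units = sample(3:6, 1),
                            num_layers = sample(1:3, 1),
                            feature_size = sample(3:6, 1),
                            leaky_slope = 0.1)
    B <- sample(2:4, 1); T <- sample(4:8, 1)
    obs_pos <- sort(sample(1000, T))
    tgt_pos <- sort(sample(setdiff(1:1000, obs_pos), sample(2:6, 1)))
    an <- target_anchors(obs_pos, tgt_pos)
    U <- length(tgt_pos)
    theta <- init_generator_theta(cfg, U)
    net <- grud:::grud_net_create(T, cfg$feature_size, cfg$hidden_units,
                                  cfg$num_layers, U,
                                  an$left - 1L, an$right - 1L,
                                  cfg$leaky_slope)
    grud:::grud_net_set_theta(net, theta)
    X <- matrix(rbinom(B * T, 1, 0.5), B, T)
    storage.mode(X) <- "double"
    p_cpp <- grud:::grud_net_forward(net, X, TRUE)$p_alt

    w <- unpack_generator_params(theta, cfg, U)
    enc <- array(c(1 - X, X), c(B, T, 2))
    feats <- sequential_features(enc, list(W = w$feature.W, b = w$feature.b,
                                           gamma = w$feature.gamma,
                                           beta = w$feature.beta),
                                 slope = cfg$leaky_slope, train = TRUE)
    logits <- bigru_impute(feats, w, an$left, an$right, cfg)
    p_ref <- generator_softmax(logits)[, , 2]
    expect_equal(p_cpp, matrix(p_ref, B, U), tolerance = 1e-12)
  }
})

test_that("zero-function layers leave skip-connected output unchanged", {
  set.seed(13)
  cfg3 <- generator_config(hidden_units = 4, num_layers = 3,
                           feature_size = 5)
  cfg1 <- generator_config(hidden_units = 4, num_layers = 1,
                           feature_size = 5)
  U <- 3; T <- 6
  obs_pos <- seq(10, 60, by = 10); tgt_pos <- c(15, 35, 55)
  an <- target_anchors(obs_pos, tgt_pos)
  theta1 <- init_generator_theta(cfg1, U)
  w1 <- unpack_generator_params(theta1, cfg1, U)
  # build a 3-layer parameter set whose layers 2 and 3 are all zero
  w3 <- unpack_generator_params(init_generator_theta(cfg3, U), cfg3, U)
  for (nm in names(w3)) {
    if (grepl("^gru\\.(forward|backward)\\.1\\.", nm) ||
        !startsWith(nm, "gru.")) w3[[nm]] <- w1[[nm]]
    else w3[[nm]] <- w3[[nm]] * 0
  }
  B <- 4
  X <- matrix(rbinom(B * T, 1, 0.5), B, T)
  enc <- array(c(1 - X, X), c(B, T, 2))
  fw <- list(W = w1$feature.W, b = w1$feature.b, gamma = w1$feature.gamma,
             beta = w1$feature.beta)
  feats <- sequential_features(enc, fw, train = TRUE)
  l3 <- bigru_impute(feats, w3, an$left, an$right, cfg3)
  l1 <- bigru_impute(feats, w1, an$left, an$right, cfg1)
  expect_equal(l3, l1, tolerance = 1e-12)
})

test_that("generator_softmax closed forms and shift invariance", {
  expect_equal(generator_softmax(matrix(c(0, 0), 1)), matrix(0.5, 1, 2))
  expect_equal(generator_softmax(matrix(c(log(3), 0), 1)),
               matrix(c(0.75, 0.25), 1), tolerance = 1e-12)
  set.seed(3)
  lg <- matrix(rnorm(20), 10, 2)
  expect_equal(generator_softmax(lg), generator_softmax(lg + 7.3),
               tolerance = 1e-12)
  expect_error(generator_softmax(matrix(c(NaN, 0), 1)), "NaN")
  # rows sum to one even for extreme logits
  lg2 <- matrix(c(1e4, -1e4, 500, 499), 2, 2, byrow = TRUE)
  expect_equal(rowSums(generator_softmax(lg2)), c(1, 1), tolerance = 1e-12)
})

test_that("generator_loss closed forms", {
  # exact prediction -> loss below clipping noise
  z <- matrix(c(1, 0, 1), 1)
  expect_lt(generator_loss(z, z, maf = rep(0.5, 3), gamma = 2), 1e-6)
  # single variant, z = 1, zhat = 0.5, MAF = 0.5: unit weight, loss = ln 2
  for (g in c(-1, 0, 1, 2.5))
    expect_equal(generator_loss(1, 0.5, maf = 0.5, gamma = g), log(2),
                 tolerance = 1e-12)
  expect_error(generator_loss(1, 0.5, maf = 0, gamma = -1), "weight")
  expect_equal(generator_loss(1, 0.5, maf = 0, gamma = -1, weight_cap = 10),
               10 * log(2), tolerance = 1e-12)
})

test_that("generator_loss with gamma 0 equals the brute-force BCE oracle", {
  set.seed(9)
  for (i in 1:100) {
    B <- sample(1:5, 1); U <- sample(1:8, 1)
    z <- matrix(rbinom(B * U, 1, 0.5), B, U)
    p <- matrix(runif(B * U), B, U)
    maf <- runif(U, 0, 0.5)
    got <- generator_loss(z, p, maf, gamma = 0)
    want <- mean(sapply(seq_len(B), function(b) oracle_bce(z[b, ], p[b, ])))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("per-site loss weight scales contributions linearly", {
  set.seed(21)
  z <- matrix(rbinom(40, 1, 0.5), 5, 8)
  p <- matrix(runif(40, 0.1, 0.9), 5, 8)
  maf <- runif(8, 0.05, 0.5)
  base <- generator_loss(z, p, maf, gamma = 1)
  # doubling one site's MAF (gamma = 1) doubles that site's contribution
  for (j in c(1, 4, 8)) {
    maf2 <- maf; maf2[j] <- 2 * maf[j]
    site_j <- generator_loss(z[, j, drop = FALSE], p[, j, drop = FALSE],
                             maf[j], gamma = 1) / 8  # its share of the mean
    expect_equal(generator_loss(z, p, maf2, gamma = 1), base + site_j,
                 tolerance = 1e-10)
  }
})

test_that("discriminator forward: symmetry, normalisation, shapes", {
  U <- 12
  wz <- list(W1 = matrix(0, 8, U), b1 = rep(0, 8),
             W2 = matrix(0, 2, 8), b2 = rep(0, 2))
  y <- matrix(runif(5 * U), 5, U)
  out <- discriminator_forward(y, wz)
  expect_equal(out$p_real, rep(0.5, 5))

  set.seed(41)
  w <- init_discriminator_params(U, hidden = 6)
  out2 <- discriminator_forward(y, w)
  expect_true(all(out2$p_real >= 0 & out2$p_real <= 1))
  expect_equal(rowSums(out2$p), rep(1, 5), tolerance = 1e-12)
  # real rows (exact 0/1) and generated rows produce identically shaped scores
  real <- matrix(rbinom(5 * U, 1, 0.5), 5, U)
  expect_length(discriminator_forward(real, w)$p_real, 5L)
  expect_error(discriminator_forward(y[, 1:5], w), "match")
})

test_that("discriminator_loss closed forms and oracle equality", {
  expect_lt(discriminator_loss(c(1, 0), c(1, 0)), 1e-6)
  expect_equal(discriminator_loss(1, 0.5), log(2), tolerance = 1e-12)
  set.seed(17)
  for (i in 1:50) {
    n <- sample(2:20, 1)
    p <- rbinom(n, 1, 0.5)
    q <- runif(n)
    expect_equal(discriminator_loss(p, q), oracle_bce(p, q),
                 tolerance = 1e-10)
  }
})

test_that("total_loss is the plain sum", {
  expect_identical(total_loss(0.3, 0.2), 0.5)
  expect_identical(total_loss(0, 0), 0)
  expect_identical(total_loss(2 * 0.3, 2 * 0.2), 2 * total_loss(0.3, 0.2))
})

test_that("allele probability slices always sum to one", {
  set.seed(59)
  for (i in 1:10) {
    cfg <- generator_config(hidden_units = 5, num_layers = 2, feature_size = 4)
    T <- 8; U <- 5; B <- 3
    an <- target_anchors(1:T * 10, sort(sample(setdiff(1:80, 1:T * 10), U)))
    net <- grud:::grud_net_create(T, 4, 5, 2, U, an$left - 1L, an$right - 1L,
                                  0.01)
    grud:::grud_net_set_theta(net, init_generator_theta(cfg, U) * 10)
    X <- matrix(rbinom(B * T, 1, 0.5), B, T); storage.mode(X) <- "double"
    p <- grud:::grud_net_forward(net, X, TRUE)$p_alt
    expect_true(all(p >= 0 & p <= 1))
    lo <- grud:::grud_net_forward(net, X, TRUE, want_logits = TRUE)
    pr <- generator_softmax(aperm(lo$logits, c(2, 3, 1)))
    expect_equal(apply(pr, c(1, 2), sum), matrix(1, B, U), tolerance = 1e-6)
  }
})

test_that("compiled backward matches finite differences", {
  set.seed(42)
  cfg <- generator_config(hidden_units = 4, num_layers = 2, feature_size = 5,
                          leaky_slope = 0.1)
  B <- 3; T <- 6; U <- 4
  an <- target_anchors(c(10, 20, 30, 40, 50, 60), c(5, 25, 26, 65))
  theta <- init_generator_theta(cfg, U)
  net <- grud:::grud_net_create(T, cfg$feature_size, cfg$hidden_units,
                                cfg$num_layers, U, an$left - 1L,
                                an$right - 1L, cfg$leaky_slope)
  X <- matrix(rbinom(B * T, 1, 0.5), B, T); storage.mode(X) <- "double"
  Z <- matrix(rbinom(B * U, 1, 0.5), B, U); storage.mode(Z) <- "double"
  wv <- runif(U, 0.5, 2)
  lossfun <- function(th) {
    grud:::grud_net_set_theta(net, th)
    bn <- grud:::grud_net_get_bn(net)
    p <- grud:::grud_net_forward(net, X, TRUE)$p_alt
    grud:::grud_net_set_bn(net, bn$mean, bn$var, bn$batches)
    grud:::generator_loss_grad(Z, p, wv)$loss
  }
  grud:::grud_net_set_theta(net, theta)
  p <- grud:::grud_net_forward(net, X, TRUE)$p_alt
  ana <- grud:::grud_net_backward(net, grud:::generator_loss_grad(Z, p, wv)$dp)
  eps <- 1e-6
  idx <- sort(sample(length(theta), 60))
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (lossfun(tp) - lossfun(tm)) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - ana[idx]) / pmax(1e-4, abs(num) + abs(ana[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("eval-mode forward is deterministic across calls", {
  set.seed(71)
  cfg <- generator_config(hidden_units = 4, num_layers = 2, feature_size = 4)
  T <- 5; U <- 3
  an <- target_anchors(1:T * 10, c(15, 25, 35))
  net <- grud:::grud_net_create(T, 4, 4, 2, U, an$left - 1L, an$right - 1L,
                                0.01)
  grud:::grud_net_set_theta(net, init_generator_theta(cfg, U))
  X <- matrix(rbinom(2 * T, 1, 0.5), 2, T); storage.mode(X) <- "double"
  grud:::grud_net_forward(net, X, TRUE)  # populate running statistics
  p1 <- grud:::grud_net_forward(net, X, FALSE)$p_alt
  p2 <- grud:::grud_net_forward(net, X, FALSE)$p_alt
  expect_identical(p1, p2)
})
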
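#' Generator architecture configuration
#'
#' Defaults follow the published architecture: GRU cells with 40 hidden
#' units, 8 stacked layers per direction, and a sequential feature layer of
#' size 50. `gamma` selects the MAF-weighted loss variant: `gamma = 0`
#' weights all unobserved variants equally ("Equivalent"), `gamma > 0`
#' up-weights common variants ("Higher"), `gamma < 0` up-weights rare
#' variants ("Lower"); see [generator_loss()].
#'
#' @param hidden_units GRU hidden state size per direction.
#' @param num_layers number of stacked GRU layers per direction.
#' @param feature_size output size of the sequential feature layer.
#' @param leaky_slope negative slope of the leaky ReLU activations.
#' @param gamma exponent of the per-variant loss weight `(2 * MAF)^gamma`.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(hidden_units = 40L, num_layers = 8L,
                             feature_size = 50L, leaky_slope = 0.01,
                             gamma = 0) {
  stopifnot(hidden_units >= 1, num_layers >= 1, feature_size >= 1,
            is.finite(gamma), leaky_slope >= 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 num_layers = as.integer(num_layers),
                 feature_size = as.integer(feature_size),
                 leaky_slope = leaky_slope,
                 gamma = gamma),
            class = "generator_config")
}

# ---------------------------------------------------------------------------
# Flat parameter vector layout (must mirror src/grud_net.cpp exactly).
# Column-major within each tensor; R arrays share arma's memory order.

gen_param_shapes <- function(config, n_unobserved) {
  F <- config$feature_size; H <- config$hidden_units; L <- config$num_layers
  U <- as.integer(n_unobserved)
  shapes <- list(feature.W = c(F, 2L), feature.b = F,
                 feature.gamma = F, feature.beta = F)
  for (dir in c("forward", "backward")) {
    for (l in seq_len(L)) {
      din <- if (l == 1L) F else H
      base <- sprintf("gru.%s.%d.", dir, l)
      shapes[[paste0(base, "Wz")]] <- c(H, din)
      shapes[[paste0(base, "Wr")]] <- c(H, din)
      shapes[[paste0(base, "Wh")]] <- c(H, din)
      shapes[[paste0(base, "Uz")]] <- c(H, H)
      shapes[[paste0(base, "Ur")]] <- c(H, H)
      shapes[[paste0(base, "Uh")]] <- c(H, H)
      shapes[[paste0(base, "bz")]] <- H
      shapes[[paste0(base, "br")]] <- H
      shapes[[paste0(base, "bh")]] <- H
    }
  }
  shapes$output.W <- c(2L, 2L * H, U)
  shapes$output.b <- c(2L, U)
  shapes
}

gen_n_params <- function(config, n_unobserved) {
  sum(vapply(gen_param_shapes(config, n_unobserved), prod, numeric(1)))
}

#' Pack / unpack generator parameters
#'
#' The trainer and the compiled forward/backward pass treat all generator
#' parameters as one flat vector. These helpers convert between that vector
#' and a named list of tensors (`feature.W`, `gru.forward.1.Wz`, ...,
#' `output.W`), which tests and inspection code use to address individual
#' weights.
#'
#' @param params named list of parameter tensors.
#' @param theta flat numeric parameter vector.
#' @param config a [generator_config()].
#' @param n_unobserved number of imputation targets of the region.
#' @return `pack_generator_params` returns a numeric vector;
#'   `unpack_generator_params` returns a named list of arrays.
#' @export
pack_generator_params <- function(params, config, n_unobserved) {
  shapes <- gen_param_shapes(config, n_unobserved)
  out <- numeric(0)
  for (nm in names(shapes)) {
    x <- params[[nm]]
    if (is.null(x)) stop("missing parameter tensor: ", nm)
    if (length(x) != prod(shapes[[nm]]))
      stop("parameter tensor ", nm, " has wrong length")
    out <- c(out, as.numeric(x))
  }
  out
}

#' @rdname pack_generator_params
#' @export
unpack_generator_params <- function(theta, config, n_unobserved) {
  shapes <- gen_param_shapes(config, n_unobserved)
  out <- list()
  pos <- 0L
  for (nm in names(shapes)) {
    n <- as.integer(prod(shapes[[nm]]))
    v <- theta[(pos + 1L):(pos + n)]
    dm <- shapes[[nm]]
    out[[nm]] <- if (length(dm) > 1L) array(v, dim = dm) else v
    pos <- pos + n
  }
  if (pos != length(theta)) stop("theta length mismatch")
  out
}

#' Initialise generator parameters
#'
#' Input-side weights are drawn uniformly from
#' `(-1/sqrt(fan_in), 1/sqrt(fan_in))` (the common recurrent-network
#' default); recurrent matrices are random orthogonal (the standard
#' initialisation for deep recurrent stacks, preserving state norm across
#' many timesteps); batch-norm scale starts at 1 and shift at 0. Uses the
#' current R random number generator state, so seeding happens at the call
#' site.
#'
#' @inheritParams pack_generator_params
#' @return flat numeric parameter vector.
#' @export
init_generator_theta <- function(config, n_unobserved) {
  shapes <- gen_param_shapes(config, n_unobserved)
  H <- config$hidden_units
  draw <- function(n, fan_in) runif(n, -1 / sqrt(fan_in), 1 / sqrt(fan_in))
  ortho <- function(h) {
    q <- qr.Q(qr(matrix(rnorm(h * h), h, h)))
    as.numeric(q)
  }
  out <- numeric(0)
  for (nm in names(shapes)) {
    n <- as.integer(prod(shapes[[nm]]))
    v <- if (nm == "feature.gamma") rep(1, n)
         else if (nm %in% c("feature.b", "feature.beta")) rep(0, n)
         else if (nm == "feature.W") draw(n, 2)
         else if (grepl("^gru\\..*\\.U[zrh]$", nm)) ortho(H)
         else if (startsWith(nm, "gru.")) draw(n, H)
         else if (startsWith(nm, "output.")) draw(n, 2 * H)
         else rep(0, n)
    out <- c(out, v)
  }
  out
}

# ---------------------------------------------------------------------------

#' One-hot encode a binary haplotype slice
#'
#' Allele 0 (reference) maps to `(1, 0)` and allele 1 (alternate) to
#' `(0, 1)`.
#'
#' @param x vector of alleles in `{0, 1}`.
#' @return numeric matrix `length(x) x 2`.
#' @export
one_hot_encode <- function(x) {
  x <- as.numeric(x)
  if (length(x) && !all(x %in% c(0, 1)))
    stop("alleles must be 0 or 1")
  cbind(ref = 1 - x, alt = x, deparse.level = 0)
}

#' Single GRU cell step
#'
#' Reference implementation of the gated recurrent unit used by the
#' generator: update and reset gates `sigmoid(W x + U a_prev + b)`, candidate
#' state `tanh(Wh x + r * (Uh a_prev) + bh)` (the reset gate multiplies the
#' recurrent term), and new state `z * candidate + (1 - z) * a_prev`.
#' The compiled training path implements the same cell; this function exists
#' for direct inspection of gate values and as an oracle in tests.
#'
#' @param x input vector.
#' @param a_prev previous hidden state.
#' @param weights list with `Wz, Wr, Wh` (hidden x input), `Uz, Ur, Uh`
#'   (hidden x hidden) and biases `bz, br, bh`.
#' @return list with `a` (new state), `update`, `reset`, `candidate`.
#' @export
gru_cell <- function(x, a_prev, weights) {
  sig <- function(v) 1 / (1 + exp(-v))
  w <- weights
  z <- sig(drop(w$Wz %*% x + w$Uz %*% a_prev) + w$bz)
  r <- sig(drop(w$Wr %*% x + w$Ur %*% a_prev) + w$br)
  hc <- tanh(drop(w$Wh %*% x) + r * drop(w$Uh %*% a_prev) + w$bh)
  a <- z * hc + (1 - z) * a_prev
  list(a = a, update = z, reset = r, candidate = hc)
}

#' Sequential feature layer
#'
#' Linear map of the one-hot allele encoding to `feature_size` channels,
#' leaky ReLU, then batch normalisation per channel. In training mode the
#' normalisation uses statistics of the current batch, computed over all
#' (haplotype, position) pairs; in evaluation mode it uses the supplied
#' running statistics. This is the reference implementation used at small
#' scale and in tests; training uses the compiled equivalent.
#'
#' @param encoded array `B x T x 2` of one-hot encodings (a `T x 2` matrix is
#'   treated as a single haplotype).
#' @param weights list with `W` (`feature_size x 2`), `b`, `gamma`, `beta`
#'   and, for evaluation mode, `running_mean` and `running_var`.
#' @param slope leaky ReLU negative slope.
#' @param train use batch statistics (`TRUE`) or running statistics.
#' @param normalize set `FALSE` to skip batch normalisation entirely.
#' @param eps numerical floor added to the variance.
#' @return array `B x T x feature_size`, with attribute `batch_stats`
#'   (list of per-channel mean and variance actually used).
#' @export
sequential_features <- function(encoded, weights, slope = 0.01, train = TRUE,
                                normalize = TRUE, eps = 1e-5) {
  if (is.matrix(encoded)) encoded <- array(encoded, c(1L, dim(encoded)))
  stopifnot(length(dim(encoded)) == 3L, dim(encoded)[3] == 2L)
  B <- dim(encoded)[1]; T <- dim(encoded)[2]
  F <- nrow(weights$W)
  if (!all(is.finite(encoded))) stop("non-finite values in encoded input")
  flat <- matrix(encoded, B * T, 2)              # (b,t) rows
  lin <- flat %*% t(weights$W)
  lin <- sweep(lin, 2, weights$b, "+")
  act <- pmax(lin, slope * lin)
  if (normalize) {
    if (train) {
      mu <- colMeans(act)
      v <- colMeans(act^2) - mu^2
      v <- pmax(v, 0)
    } else {
      if (is.null(weights$running_mean))
        stop("evaluation mode requires running statistics")
      mu <- weights$running_mean
      v <- weights$running_var
    }
    act <- sweep(act, 2, mu, "-")
    act <- sweep(act, 2, sqrt(v + eps), "/")
    act <- sweep(act, 2, weights$gamma, "*")
    act <- sweep(act, 2, weights$beta, "+")
  } else {
    mu <- rep(0, F); v <- rep(1, F)
  }
  out <- array(act, c(B, T, F))
  attr(out, "batch_stats") <- list(mean = mu, var = v)
  out
}

#' Anchor unobserved targets to flanking observed positions
#'
#' Each unobserved variant between consecutive observed variants `v_i` and
#' `v_(i+1)` is predicted from the forward GRU output at `v_i` and the
#' backward GRU output at `v_(i+1)`. Targets before the first (after the
#' last) observed variant use the nearest available pair: both anchors
#' clamp to the first (last) observed position.
#'
#' @param obs_pos sorted physical positions of the observed input variants.
#' @param target_pos physical positions of the unobserved targets.
#' @return list with integer vectors `left` and `right` (1-based indices
#'   into `obs_pos`).
#' @export
target_anchors <- function(obs_pos, target_pos) {
  if (!length(obs_pos)) stop("no observed variants to anchor targets to")
  if (is.unsorted(obs_pos, strictly = TRUE)) stop("obs_pos must be strictly increasing")
  left <- findInterval(target_pos, obs_pos)        # 0 if before first
  right <- pmin(left + 1L, length(obs_pos))
  left <- pmax(left, 1L)
  list(left = as.integer(left), right = as.integer(right))
}

#' Bidirectional GRU imputation pass (reference implementation)
#'
#' Runs the stacked forward and backward GRUs with residual skip-connections
#' over the feature sequence and produces, for every unobserved target, two
#' logits from the concatenated forward/backward outputs at its anchor
#' positions. Layer `l > 1` outputs `s_l = GRU_l(s_(l-1)) + s_(l-1)`; the
#' recurrent state inside each layer is the raw GRU state, the residual sum
#' is what flows to the next layer and to the output heads.
#'
#' This R implementation defines the semantics and is exercised at small
#' scale; [train_grud()] and [impute()] use the compiled equivalent, which
#' tests hold to agreement with this function.
#'
#' @param features array `B x T x feature_size` from [sequential_features()].
#' @param weights named parameter list as produced by
#'   [unpack_generator_params()] (entries `gru.*` and `output.*`).
#' @param left,right integer anchor indices from [target_anchors()].
#' @param config a [generator_config()].
#' @return array `B x U x 2` of logits.
#' @export
bigru_impute <- function(features, weights, left, right, config) {
  stopifnot(length(dim(features)) == 3L)
  B <- dim(features)[1]; T <- dim(features)[2]
  H <- config$hidden_units; L <- config$num_layers
  U <- length(left)
  stopifnot(length(right) == U, all(left >= 1), all(right <= T))
  run_stack <- function(dir) {
    ord <- if (dir == "forward") seq_len(T) else rev(seq_len(T))
    S <- lapply(seq_len(T), function(t) t(features[, t, , drop = FALSE][, 1, ]))
    if (B == 1L) S <- lapply(seq_len(T), function(t) matrix(features[1, t, ], ncol = 1))
    for (l in seq_len(L)) {
      w <- list(Wz = weights[[sprintf("gru.%s.%d.Wz", dir, l)]],
                Wr = weights[[sprintf("gru.%s.%d.Wr", dir, l)]],
                Wh = weights[[sprintf("gru.%s.%d.Wh", dir, l)]],
                Uz = weights[[sprintf("gru.%s.%d.Uz", dir, l)]],
                Ur = weights[[sprintf("gru.%s.%d.Ur", dir, l)]],
                Uh = weights[[sprintf("gru.%s.%d.Uh", dir, l)]],
                bz = weights[[sprintf("gru.%s.%d.bz", dir, l)]],
                br = weights[[sprintf("gru.%s.%d.br", dir, l)]],
                bh = weights[[sprintf("gru.%s.%d.bh", dir, l)]])
      a_new <- vector("list", T)
      aprev <- matrix(0, H, B)
      for (t in ord) {
        cells <- lapply(seq_len(B), function(b)
          gru_cell(S[[t]][, b], aprev[, b], w)$a)
        a_t <- do.call(cbind, cells)
        a_new[[t]] <- a_t
        aprev <- a_t
      }
      S <- if (l == 1L) a_new else Map(`+`, a_new, S)
    }
    S
  }
  Sf <- run_stack("forward")
  Sb <- run_stack("backward")
  Wo <- weights$output.W; bo <- weights$output.b
  logits <- array(NA_real_, c(B, U, 2))
  for (u in seq_len(U)) {
    FU <- rbind(Sf[[left[u]]], Sb[[right[u]]])   # 2H x B
    lg <- Wo[, , u] %*% FU + bo[, u]             # 2 x B
    logits[, u, ] <- t(lg)
  }
  logits
}

#' Softmax over the two allele classes
#'
#' Numerically stabilised (max-subtracted) softmax over the last dimension,
#' which must have length 2.
#'
#' @param logits matrix `n x 2` or array `B x U x 2` of finite values.
#' @return object of the same shape whose length-2 slices are probabilities
#'   summing to 1.
#' @export
generator_softmax <- function(logits) {
  if (any(is.na(logits))) stop("NaN logits")
  d <- dim(logits)
  if (is.null(d)) stop("logits must have a trailing dimension of 2")
  flat <- matrix(logits, ncol = 2)
  m <- pmax(flat[, 1], flat[, 2])
  e0 <- exp(flat[, 1] - m); e1 <- exp(flat[, 2] - m)
  out <- cbind(e0, e1) / (e0 + e1)
  array(out, d)
}

# shared probability clipping constant for both BCE losses
GRUD_EPS <- 1e-7

#' MAF-weighted generator loss
#'
#' Binary cross-entropy over unobserved variants with per-variant weight
#' `(2 * MAF_i)^gamma`:
#' `L_G = -(1/N) * sum_i (2 MAF_i)^gamma (z_i log zhat_i + (1 - z_i) log(1 - zhat_i))`,
#' averaged over the haplotypes of the batch. `gamma > 0` prioritises
#' common variants ("Higher"), `gamma < 0` rare variants ("Lower"),
#' `gamma = 0` is plain BCE ("Equivalent"). Predicted probabilities are
#' clipped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param z matrix (haplotypes x variants) or vector of true alleles in
#'   `{0, 1}`.
#' @param z_hat predicted alternate-allele probabilities, same shape.
#' @param maf per-variant minor allele frequencies from the training panel.
#' @param gamma weight exponent.
#' @param eps probability clipping constant.
#' @param weight_cap optional upper bound on the per-variant weight; with
#'   `gamma < 0` a zero-MAF variant otherwise has infinite weight (such
#'   sites should be removed upstream with [filter_rare()]).
#' @return nonnegative scalar loss.
#' @export
generator_loss <- function(z, z_hat, maf, gamma = 0, eps = GRUD_EPS,
                           weight_cap = NULL) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (is.null(dim(z_hat))) z_hat <- matrix(z_hat, nrow = 1)
  stopifnot(identical(dim(z), dim(z_hat)), ncol(z) == length(maf),
            all(z %in% c(0, 1)))
  w <- (2 * maf)^gamma
  if (!is.null(weight_cap)) w <- pmin(w, weight_cap)
  if (any(!is.finite(w)))
    stop("infinite MAF weight (gamma < 0 with MAF = 0); filter rare sites ",
         "or set weight_cap")
  p <- pmin(pmax(z_hat, eps), 1 - eps)
  per_hap <- -(sweep(z * log(p) + (1 - z) * log(1 - p), 2, w, "*"))
  mean(rowSums(per_hap) / ncol(z))
}

# loss + gradient wrt z_hat, for the training loop
generator_loss_grad <- function(z, z_hat, w, eps = GRUD_EPS) {
  p <- pmin(pmax(z_hat, eps), 1 - eps)
  B <- nrow(z); U <- ncol(z)
  loss <- mean(rowSums(-sweep(z * log(p) + (1 - z) * log(1 - p), 2, w, "*")) / U)
  dp <- -sweep(z / p - (1 - z) / (1 - p), 2, w, "*") / (U * B)
  list(loss = loss, dp = dp)
}

#' Initialise discriminator parameters
#'
#' Two stacked linear layers (`n_in -> hidden -> 2`) with a leaky ReLU
#' between them; the second layer feeds a two-class softmax.
#'
#' @param n_in input length (number of unobserved variants of the region).
#' @param hidden hidden layer width.
#' @return list with `W1`, `b1`, `W2`, `b2`.
#' @export
init_discriminator_params <- function(n_in, hidden = 100L) {
  list(W1 = matrix(runif(hidden * n_in, -1 / sqrt(n_in), 1 / sqrt(n_in)),
                   hidden, n_in),
       b1 = rep(0, hidden),
       W2 = matrix(runif(2 * hidden, -1 / sqrt(hidden), 1 / sqrt(hidden)),
                   2, hidden),
       b2 = rep(0, 2))
}

#' Discriminator forward pass
#'
#' Scores haplotype slices over the unobserved variants: input is the
#' alternate-allele probability vector per haplotype (exact 0/1 values for
#' real panel haplotypes), passed through two stacked linear layers with a
#' leaky ReLU between, then a two-class softmax. Class 2 is "real".
#'
#' @param y matrix (haplotypes x variants) of alternate-allele
#'   probabilities, or a `B x U x 2` probability array whose alternate
#'   channel is used.
#' @param weights list from [init_discriminator_params()].
#' @param slope leaky ReLU negative slope.
#' @return list with `p_real` (vector), `p` (matrix `B x 2`, rows sum to 1)
#'   and the hidden activations `h` used by the training backward pass.
#' @export
discriminator_forward <- function(y, weights, slope = 0.01) {
  if (length(dim(y)) == 3L) y <- y[, , 2, drop = TRUE]
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (ncol(y) != ncol(weights$W1))
    stop("input length ", ncol(y), " does not match discriminator layer (",
         ncol(weights$W1), ")")
  pre <- weights$W1 %*% t(y) + weights$b1          # hidden x B
  h <- pmax(pre, slope * pre)
  logit <- weights$W2 %*% h + weights$b2           # 2 x B
  m <- pmax(logit[1, ], logit[2, ])
  e0 <- exp(logit[1, ] - m); e1 <- exp(logit[2, ] - m)
  p_real <- e1 / (e0 + e1)
  list(p_real = as.numeric(p_real),
       p = cbind(fake = 1 - p_real, real = p_real),
       h = h, pre = pre)
}

#' Discriminator loss
#'
#' Mean binary cross-entropy between real/fake labels and the
#' discriminator's probability of "real".
#'
#' @param p labels in `{0, 1}` (1 = real panel haplotype).
#' @param p_hat predicted probability of "real".
#' @param eps probability clipping constant.
#' @return nonnegative scalar.
#' @export
discriminator_loss <- function(p, p_hat, eps = GRUD_EPS) {
  stopifnot(length(p) == length(p_hat), all(p %in% c(0, 1)))
  q <- pmin(pmax(p_hat, eps), 1 - eps)
  -mean(p * log(q) + (1 - p) * log(1 - q))
}

#' Joint loss
#'
#' The training objective is the plain sum of the discriminator and
#' generator losses.
#'
#' @param l_g generator loss.
#' @param l_d discriminator loss.
#' @return `l_g + l_d`.
#' @export
total_loss <- function(l_g, l_d) l_g + l_d

# ---------------------------------------------------------------------------
# discriminator backward + Adam (internal)

# returns gradients for the discriminator and d(loss)/d(input rows)
disc_backward <- function(y, fw, labels, weights, slope = 0.01,
                          eps = GRUD_EPS) {
  if (length(dim(y)) == 3L) y <- y[, , 2, drop = TRUE]
  B <- nrow(y)
  p <- pmin(pmax(fw$p_real, eps), 1 - eps)
  # d(mean BCE)/d(logit) through softmax: (p - label)/B on the "real" logit
  g <- (p - labels) / B
  dlogit <- rbind(-g, g)                            # 2 x B
  gW2 <- dlogit %*% t(fw$h)
  gb2 <- rowSums(dlogit)
  dh <- t(weights$W2) %*% dlogit                    # hidden x B
  m <- (fw$pre > 0) + slope * (fw$pre <= 0)
  dpre <- dh * m
  gW1 <- dpre %*% y
  gb1 <- rowSums(dpre)
  dy <- t(t(weights$W1) %*% dpre)                   # B x U
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2), dy = dy)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}
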
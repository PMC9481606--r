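# Minimal fully-connected network machinery (internal).  The deep CV
# trainers need nothing beyond small tanh MLPs with full-batch analytic
# gradients, so the forward/backward passes are written directly in matrix
# algebra; all initialisation is seed-deterministic.

mlp_init <- function(sizes, seed) {
  with_seed(derive_seed(seed, 11L), {
    L <- length(sizes) - 1L
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
      layers[[l]] <- list(
        W = matrix(runif(sizes[l] * sizes[l + 1L], -r, r),
                   sizes[l], sizes[l + 1L]),
        b = rep(0, sizes[l + 1L]))
    }
    layers
  })
}

.act <- function(z, kind) switch(kind, tanh = tanh(z), linear = z)
.act_grad <- function(a, kind) switch(kind, tanh = 1 - a^2,
                                      linear = matrix(1, nrow(a), ncol(a)))

# forward pass; activation applied to every layer except optionally the last
mlp_forward <- function(layers, X, activation, linear_output = FALSE) {
  L <- length(layers)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    kind <- if (linear_output && l == L) "linear" else activation
    acts[[l + 1L]] <- .act(Z, kind)
  }
  acts
}

# backward pass from dL/d(top activation); returns per-layer gradients
mlp_backward <- function(layers, acts, G_top, activation,
                         linear_output = FALSE) {
  L <- length(layers)
  grads <- vector("list", L)
  G <- G_top
  for (l in rev(seq_len(L))) {
    kind <- if (linear_output && l == L) "linear" else activation
    dZ <- G * .act_grad(acts[[l + 1L]], kind)
    grads[[l]] <- list(W = crossprod(acts[[l]], dZ), b = colSums(dZ))
    if (l > 1L) G <- dZ %*% t(layers[[l]]$W)
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    st <- state[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    mhW <- st$mW / (1 - beta1^t); vhW <- st$vW / (1 - beta2^t)
    mhb <- st$mb / (1 - beta1^t); vhb <- st$vb / (1 - beta2^t)
    layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[l]] <- st
  }
  list(layers = layers, state = state)
}
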
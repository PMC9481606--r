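# Neural-network collective variables.
#
# Deep-LDA: descriptors are fed through a small MLP and Fisher's ratio is
# maximised on the last hidden layer h; the CV is the closed-form LDA
# projection s = w'h, with the cubic transform s + s^3 applied by default.
# Deep-TICA: the MLP outputs a small basis whose leading generalized
# (TICA) eigenvalues are maximised under exp(beta V) frame reweighting; the
# CV is the leading eigenfunction.  Both trainers are full-batch Adam with
# a validation split and patience-based early stopping, and are
# seed-deterministic on one thread.

# closed-form Fisher quantities on a hidden representation
.fisher_on_h <- function(H, is_B, lambda) {
  sc <- scatter_matrices(H[is_B, , drop = FALSE], H[!is_B, , drop = FALSE])
  delta <- sc$mu_B - sc$mu_U
  A <- sc$S_w + lambda * diag(ncol(H))
  alpha <- solve(A, delta)
  list(J = sum(delta * alpha), alpha = alpha, sc = sc)
}

#' Train a Deep-LDA collective variable
#'
#' Maximises Fisher's ratio, evaluated in closed form on the last hidden
#' layer, over the network parameters; the final CV applies the closed-form
#' LDA projection to the trained hidden representation.
#'
#' @param X_B,X_U `n x d` descriptor matrices for the bound / unbound state
#' @param hidden hidden layer widths (the last entry is `N_h`)
#' @param activation `"tanh"` (default) or `"linear"` (for which the model
#'   provably collapses onto closed-form LDA)
#' @param lr Adam learning rate
#' @param epochs maximum training epochs (full batch)
#' @param reg_lambda ridge on the hidden within-scatter; default
#'   `0.05 * trace(S_w) / N_h`, recomputed each epoch
#' @param seed seed controlling initialisation and the validation split
#' @param val_frac validation fraction (per state)
#' @param patience early-stopping patience on the validation Fisher ratio
#' @param output_transform `"cubic"` (default) or `"identity"`
#' @return object of class `cv_model`
#' @export
train_deep_lda <- function(X_B, X_U, hidden = c(32L, 16L, 8L),
                           activation = c("tanh", "linear"), lr = 1e-3,
                           epochs = 200L, reg_lambda = NULL, seed = 1L,
                           val_frac = 0.2, patience = 20L,
                           output_transform = c("cubic", "identity")) {
  activation <- match.arg(activation)
  output_transform <- match.arg(output_transform)
  X_B <- as.matrix(X_B); X_U <- as.matrix(X_U)
  d <- ncol(X_B)
  stopifnot(ncol(X_U) == d, tail(hidden, 1L) >= 1L)
  # standardise inputs on the pooled data
  Xall <- rbind(X_B, X_U)
  ctr <- colMeans(Xall)
  scl <- apply(Xall, 2, sd); scl[scl < 1e-12] <- 1
  std <- function(X) sweep(sweep(X, 2, ctr), 2, scl, "/")
  ZB <- std(X_B); ZU <- std(X_U)
  nB <- nrow(ZB); nU <- nrow(ZU)
  split <- with_seed(derive_seed(seed, 21L), {
    list(B = sample(nB) <= round(val_frac * nB),
         U = sample(nU) <= round(val_frac * nU))
  })
  Ztr <- rbind(ZB[!split$B, , drop = FALSE], ZU[!split$U, , drop = FALSE])
  is_B_tr <- rep(c(TRUE, FALSE), c(sum(!split$B), sum(!split$U)))
  Zval <- rbind(ZB[split$B, , drop = FALSE], ZU[split$U, , drop = FALSE])
  is_B_val <- rep(c(TRUE, FALSE), c(sum(split$B), sum(split$U)))
  have_val <- sum(split$B) > 1L && sum(split$U) > 1L

  sizes <- c(d, hidden)
  layers <- mlp_init(sizes, seed)
  opt <- adam_init(layers)
  Nh <- tail(hidden, 1L)
  nBt <- sum(is_B_tr); nUt <- sum(!is_B_tr)
  best <- list(score = -Inf, layers = layers, epoch = 0L)
  wait <- 0L
  lam_of <- function(Sw) reg_lambda %||% (0.05 * sum(diag(Sw)) / Nh)
  for (ep in seq_len(epochs)) {
    acts <- mlp_forward(layers, Ztr, activation)
    H <- acts[[length(acts)]]
    sc <- scatter_matrices(H[is_B_tr, , drop = FALSE],
                           H[!is_B_tr, , drop = FALSE])
    lambda <- lam_of(sc$S_w)
    delta <- sc$mu_B - sc$mu_U
    A <- sc$S_w + lambda * diag(Nh)
    alpha <- solve(A, delta)
    if (!all(is.finite(alpha))) {
      stop("non-finite loss at epoch ", ep, call. = FALSE)
    }
    # dJ/dh: mean part +/- (2/n_s) alpha; scatter part through Sw
    Mneg <- -tcrossprod(alpha)          # dJ/dA
    G <- matrix(0, nrow(H), Nh)
    hB <- sweep(H[is_B_tr, , drop = FALSE], 2, sc$mu_B)
    hU <- sweep(H[!is_B_tr, , drop = FALSE], 2, sc$mu_U)
    G[is_B_tr, ] <- matrix(2 * alpha / nBt, nBt, Nh, byrow = TRUE) +
      (2 / (nBt - 1)) * hB %*% Mneg
    G[!is_B_tr, ] <- matrix(-2 * alpha / nUt, nUt, Nh, byrow = TRUE) +
      (2 / (nUt - 1)) * hU %*% Mneg
    grads <- mlp_backward(layers, acts, -G, activation)  # minimise -J
    upd <- adam_step(layers, grads, opt, lr, ep)
    layers <- upd$layers; opt <- upd$state
    score <- if (have_val) {
      Hv <- mlp_forward(layers, Zval, activation)
      .fisher_on_h(Hv[[length(Hv)]], is_B_val, lambda)$J
    } else sum(delta * alpha)
    if (score > best$score + 1e-12) {
      best <- list(score = score, layers = layers, epoch = ep)
      wait <- 0L
    } else if ((wait <- wait + 1L) >= patience) break
  }
  layers <- best$layers
  # final projection: closed-form LDA on the full hidden representation
  Hall <- mlp_forward(layers, rbind(ZB, ZU), activation)
  Hall <- Hall[[length(Hall)]]
  is_B_all <- rep(c(TRUE, FALSE), c(nB, nU))
  scA <- scatter_matrices(Hall[is_B_all, , drop = FALSE],
                          Hall[!is_B_all, , drop = FALSE])
  lamA <- lam_of(scA$S_w)
  w <- solve(scA$S_w + lamA * diag(Nh), scA$mu_B - scA$mu_U)
  w <- w / sqrt(sum(w^2))
  sB <- mean(Hall[is_B_all, , drop = FALSE] %*% w)
  sU <- mean(Hall[!is_B_all, , drop = FALSE] %*% w)
  if (sB < sU) w <- -w
  structure(list(kind = "deep_lda", layers = layers,
                 activation = activation, linear_output = FALSE,
                 w = as.numeric(w), input_center = ctr, input_scale = scl,
                 output_transform = output_transform,
                 descriptor_names = colnames(X_B),
                 meta = list(seed = seed, lr = lr, epochs = epochs,
                             best_epoch = best$epoch, lambda = lamA,
                             hidden = hidden,
                             val_score = best$score)),
            class = "cv_model")
}

#' Train a Deep-TICA collective variable
#'
#' The MLP outputs `n_out` basis functions whose leading TICA eigenvalues
#' (of `C(tau) v = lambda C(0) v` under `exp(beta V)` frame reweighting)
#' are maximised; the returned CV is the leading eigenfunction.
#'
#' @param X `n x d` descriptor matrix, rows ordered in time
#' @param lag lag time in frames (or in time units when `times` is given)
#' @param bias optional per-frame bias values (from a biased simulation);
#'   frames are reweighted by `exp(beta (V - max V))`; a zero/absent bias
#'   reduces to plain-time weighting
#' @param beta inverse temperature
#' @param times optional time stamps
#' @param hidden hidden widths before the linear output layer
#' @param n_out size of the learned basis
#' @param activation `"tanh"` (default) or `"linear"` (for which the model
#'   provably collapses onto linear TICA)
#' @param lr,epochs,seed,patience as in [train_deep_lda()]
#' @param val_frac final fraction of the trajectory held out for scoring
#' @param reg ridge on `C(0)`
#' @return object of class `cv_model` (output transform `"identity"`)
#' @export
train_deep_tica <- function(X, lag, bias = NULL, beta = 1, times = NULL,
                            hidden = c(32L, 16L), n_out = 2L,
                            activation = c("tanh", "linear"), lr = 1e-3,
                            epochs = 200L, seed = 1L, val_frac = 0.2,
                            patience = 20L, reg = 1e-8) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  lag_frames <- if (!is.null(times)) {
    max(1L, as.integer(round(lag / (times[2] - times[1]))))
  } else as.integer(lag)
  weights <- if (!is.null(bias)) exp(beta * (bias - max(bias))) else
    rep(1, n)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n_tr <- max(lag_frames + 2L, floor((1 - val_frac) * n))
  Ztr <- Z[seq_len(n_tr), , drop = FALSE]
  wtr <- weights[seq_len(n_tr)]
  sizes <- c(d, hidden, n_out)
  layers <- mlp_init(sizes, seed)
  opt <- adam_init(layers)
  score_of <- function(Y, w) {
    cc <- .tica_covariances(Y, lag_frames, w)
    C0 <- cc$C0 + reg * mean(diag(cc$C0)) * diag(n_out)
    ch <- chol(C0)
    Li <- backsolve(ch, diag(n_out))
    M <- t(Li) %*% cc$Ct %*% Li
    ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
    list(lam = ee$values, V = Li %*% ee$vectors, mu = cc$mu)
  }
  best <- list(score = -Inf, layers = layers, epoch = 0L)
  wait <- 0L
  idx0 <- seq_len(n_tr - lag_frames)
  idx1 <- idx0 + lag_frames
  wp <- wtr[idx0]; W <- sum(wp)
  for (ep in seq_len(epochs)) {
    acts <- mlp_forward(layers, Ztr, activation, linear_output = TRUE)
    Y <- acts[[length(acts)]]
    sol <- tryCatch(score_of(Y, wtr), error = function(e) NULL)
    if (is.null(sol) || !all(is.finite(sol$lam))) {
      stop("non-finite loss at epoch ", ep, call. = FALSE)
    }
    lam <- sol$lam; V <- sol$V
    # L = -sum lam^2; dL/dCt = -2 sum lam v v'; dL/dC0 = 2 sum lam^2 v v'
    Mt <- -2 * V %*% diag(lam, n_out) %*% t(V)
    M0 <- 2 * V %*% diag(lam^2, n_out) %*% t(V)
    Y0 <- sweep(Y[idx0, , drop = FALSE], 2, sol$mu)
    Y1 <- sweep(Y[idx1, , drop = FALSE], 2, sol$mu)
    G <- matrix(0, n_tr, n_out)
    G[idx0, ] <- G[idx0, ] + (wp / W) * (Y0 %*% M0 + Y1 %*% Mt)
    G[idx1, ] <- G[idx1, ] + (wp / W) * (Y1 %*% M0 + Y0 %*% Mt)
    grads <- mlp_backward(layers, acts, G, activation, linear_output = TRUE)
    upd <- adam_step(layers, grads, opt, lr, ep)
    layers <- upd$layers; opt <- upd$state
    # validation: eigenvalues of the full trajectory under current net
    actsF <- mlp_forward(layers, Z, activation, linear_output = TRUE)
    solF <- tryCatch(score_of(actsF[[length(actsF)]], weights),
                     error = function(e) NULL)
    score <- if (is.null(solF)) -Inf else sum(pmax(solF$lam, 0)^2)
    if (score > best$score + 1e-12) {
      best <- list(score = score, layers = layers, epoch = ep)
      wait <- 0L
    } else if ((wait <- wait + 1L) >= patience) break
  }
  layers <- best$layers
  actsF <- mlp_forward(layers, Z, activation, linear_output = TRUE)
  solF <- score_of(actsF[[length(actsF)]], weights)
  v1 <- solF$V[, 1]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  structure(list(kind = "deep_tica", layers = layers,
                 activation = activation, linear_output = TRUE,
                 w = as.numeric(v1), y_mean = as.numeric(solF$mu),
                 input_center = ctr, input_scale = scl,
                 output_transform = "identity",
                 descriptor_names = colnames(X),
                 meta = list(seed = seed, lr = lr, epochs = epochs,
                             best_epoch = best$epoch, lag = lag_frames,
                             n_out = n_out, hidden = hidden,
                             eigenvalues = solF$lam)),
            class = "cv_model")
}

#' Evaluate a learned collective variable
#'
#' @param object a `cv_model`
#' @param newdata `n x d` descriptor matrix
#' @param transform apply the model's output transform (cubic for Deep-LDA)
#' @param ... unused
#' @return numeric CV values
#' @export
predict.cv_model <- function(object, newdata, transform = TRUE, ...) {
  X <- as.matrix(newdata)
  Z <- sweep(sweep(X, 2, object$input_center), 2, object$input_scale, "/")
  acts <- mlp_forward(object$layers, Z, object$activation,
                      linear_output = isTRUE(object$linear_output))
  top <- acts[[length(acts)]]
  s <- if (object$kind == "deep_tica") {
    as.numeric(sweep(top, 2, object$y_mean) %*% object$w)
  } else {
    as.numeric(top %*% object$w)
  }
  if (transform && identical(object$output_transform, "cubic")) {
    s <- cubic_transform(s)
  }
  s
}

#' @export
print.cv_model <- function(x, ...) {
  cat("<cv_model> ", x$kind, " (", x$activation, "), hidden [",
      paste(x$meta$hidden, collapse = ", "), "], output transform ",
      x$output_transform, "\n", sep = "")
  cat("  trained ", x$meta$best_epoch, " epochs (seed ", x$meta$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Save / load a CV model as versioned JSON
#'
#' Weights are stored at full double precision; a restored model reproduces
#' outputs exactly.
#'
#' @param model a `cv_model`
#' @param path file path
#' @export
write_cv_model <- function(model, path) {
  stopifnot(inherits(model, "cv_model"))
  payload <- list(
    format = "aquaopes-cvmodel-1",
    kind = model$kind, activation = model$activation,
    linear_output = isTRUE(model$linear_output),
    layers = lapply(model$layers, function(l) list(W = l$W, b = l$b)),
    w = model$w, y_mean = model$y_mean,
    input_center = model$input_center, input_scale = model$input_scale,
    output_transform = model$output_transform,
    descriptor_names = model$descriptor_names, meta = model$meta)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cv_model
#' @export
read_cv_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$format, "aquaopes-cvmodel-1")) {
    stop("unrecognised CV model format", call. = FALSE)
  }
  layers <- lapply(seq_len(nrow_safe(p$layers)), function(i) {
    list(W = as.matrix(p$layers$W[[i]]), b = as.numeric(p$layers$b[[i]]))
  })
  structure(list(kind = p$kind, layers = layers,
                 activation = p$activation,
                 linear_output = isTRUE(p$linear_output),
                 w = as.numeric(p$w),
                 y_mean = if (is.null(p$y_mean)) NULL else
                   as.numeric(p$y_mean),
                 input_center = as.numeric(p$input_center),
                 input_scale = as.numeric(p$input_scale),
                 output_transform = p$output_transform,
                 descriptor_names = p$descriptor_names,
                 meta = as.list(p$meta)),
            class = "cv_model")
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
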
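# Time-lagged independent component analysis.  The slowest decorrelating
# linear combinations of descriptors solve the generalized eigenproblem
# C(tau) v = lambda C(0) v, with the instantaneous and time-lagged
# covariances built mean-free and (for reversibility) symmetrised over the
# pair (t, t + tau).  On data from biased runs, frames are reweighted by
# exp(beta V), approximating the rescaled-time average.

# symmetrised weighted covariance pair; lag in frames
.tica_covariances <- function(X, lag, weights) {
  n <- nrow(X)
  if (lag >= n) stop("lag must be shorter than the trajectory",
                     call. = FALSE)
  idx0 <- seq_len(n - lag)
  idx1 <- idx0 + lag
  w <- weights[idx0]
  if (any(w < 0) || sum(w) <= 0) stop("weights must be positive",
                                      call. = FALSE)
  W <- sum(w)
  X0 <- X[idx0, , drop = FALSE]
  X1 <- X[idx1, , drop = FALSE]
  mu <- colSums((X0 + X1) * w) / (2 * W)
  X0 <- sweep(X0, 2, mu); X1 <- sweep(X1, 2, mu)
  C0 <- (crossprod(X0 * w, X0) + crossprod(X1 * w, X1)) / (2 * W)
  Ct <- (crossprod(X0 * w, X1) + crossprod(X1 * w, X0)) / (2 * W)
  list(C0 = C0, Ct = Ct, mu = mu)
}

#' Time-lagged independent component analysis
#'
#' @param X `n x d` descriptor matrix (rows ordered in time, uniform
#'   spacing)
#' @param lag lag time; interpreted in frames unless `times` is given, in
#'   which case it is converted using the frame spacing
#' @param times optional time stamps (uniform spacing assumed)
#' @param weights optional positive per-frame weights; supply
#'   `exp(beta * V)` for biased data (see `bias`/`beta`)
#' @param bias optional per-frame bias column; when given, weights default
#'   to `exp(beta * (bias - max(bias)))`
#' @param beta inverse temperature used with `bias`
#' @param reg relative ridge added to `C(0)` before solving
#' @return object of class `tica_solution`: `eigenvalues` (descending),
#'   `eigenvectors` (columns, `C(0)`-orthonormal), `lag_time`,
#'   `implied_timescales = -lag / log(lambda)`, and the data mean `mu`
#' @export
tica <- function(X, lag, times = NULL, weights = NULL, bias = NULL,
                 beta = 1, reg = 1e-10) {
  X <- as.matrix(X)
  lag_frames <- if (!is.null(times)) {
    dt <- times[2] - times[1]
    max(1L, as.integer(round(lag / dt)))
  } else as.integer(lag)
  if (lag_frames < 1L) stop("lag must be at least one frame", call. = FALSE)
  if (is.null(weights)) {
    weights <- if (!is.null(bias)) exp(beta * (bias - max(bias))) else
      rep(1, nrow(X))
  }
  cc <- .tica_covariances(X, lag_frames, weights)
  d <- ncol(X)
  C0 <- cc$C0 + reg * mean(diag(cc$C0)) * diag(d)
  ch <- tryCatch(chol(C0), error = function(e) {
    stop("C(0) is not positive definite; increase 'reg'", call. = FALSE)
  })
  Li <- backsolve(ch, diag(d))              # C0^{-1/2} (upper-chol inverse)
  M <- t(Li) %*% cc$Ct %*% Li
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  V <- Li %*% ee$vectors                    # C0-orthonormal
  lam <- ee$values
  lag_time <- if (!is.null(times)) lag_frames * (times[2] - times[1]) else
    lag_frames
  its <- rep(NA_real_, length(lam))
  ok <- lam > 0 & lam < 1
  its[ok] <- -lag_time / log(lam[ok])
  structure(list(eigenvalues = lam, eigenvectors = V,
                 lag_time = lag_time, lag_frames = lag_frames,
                 implied_timescales = its, mu = cc$mu),
            class = "tica_solution")
}

#' @export
print.tica_solution <- function(x, ...) {
  cat("<tica_solution> lag =", x$lag_time, "\n")
  k <- min(5L, length(x$eigenvalues))
  cat("  eigenvalues:", paste(signif(x$eigenvalues[seq_len(k)], 4),
                              collapse = ", "), "\n")
  cat("  implied timescales:",
      paste(signif(x$implied_timescales[seq_len(k)], 4), collapse = ", "),
      "\n")
  invisible(x)
}
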
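# Linear discriminant analysis for two-state collective variables.
# Fisher's ratio  (w' Sb w) / (w' Sw w)  with the rank-one between-state
# scatter Sb = (mu_B - mu_U)(mu_B - mu_U)' and the within scatter
# Sw = S_B + S_U (per-state covariance matrices); its maximiser has the
# two-class closed form  w ~ (Sw + lambda I)^-1 (mu_B - mu_U).

#' Between/within scatter matrices of two descriptor sets
#'
#' @param X_B,X_U `n x d` descriptor matrices for the two states
#' @return list with `S_b` (rank-one, PSD), `S_w = S_B + S_U` (sample
#'   covariances), and the state means `mu_B`, `mu_U`
#' @export
scatter_matrices <- function(X_B, X_U) {
  X_B <- as.matrix(X_B); X_U <- as.matrix(X_U)
  if (ncol(X_B) != ncol(X_U)) stop("descriptor dimensions differ",
                                   call. = FALSE)
  if (nrow(X_B) < 2L || nrow(X_U) < 2L) stop("need >= 2 samples per state",
                                             call. = FALSE)
  mu_B <- colMeans(X_B); mu_U <- colMeans(X_U)
  d <- mu_B - mu_U
  list(S_b = tcrossprod(d), S_w = cov(X_B) + cov(X_U),
       mu_B = mu_B, mu_U = mu_U)
}

#' Fisher ratio of a projection direction
#'
#' @param w direction (any scale)
#' @param sc a [scatter_matrices()] list
#' @return `(w' Sb w) / (w' Sw w)`
#' @export
fisher_ratio <- function(w, sc) {
  as.numeric((t(w) %*% sc$S_b %*% w) / (t(w) %*% sc$S_w %*% w))
}

#' Closed-form LDA direction
#'
#' @param X_B,X_U `n x d` descriptor matrices for the two states
#' @param reg_lambda ridge regulariser added to `S_w` (use `> 0` when `S_w`
#'   is singular)
#' @return unit direction `w` maximising Fisher's ratio, oriented so the B
#'   state projects higher than U; attributes carry the achieved
#'   `fisher_ratio` and the scatter pair
#' @export
lda_direction <- function(X_B, X_U, reg_lambda = 0) {
  sc <- scatter_matrices(X_B, X_U)
  delta <- sc$mu_B - sc$mu_U
  if (sqrt(sum(delta^2)) < 1e-12) {
    stop("degenerate problem: the state means coincide", call. = FALSE)
  }
  A <- sc$S_w + reg_lambda * diag(ncol(sc$S_w))
  w <- tryCatch(solve(A, delta), error = function(e) {
    stop("singular within-scatter matrix; use reg_lambda > 0",
         call. = FALSE)
  })
  w <- w / sqrt(sum(w^2))
  if (sum(w * delta) < 0) w <- -w
  attr(w, "fisher_ratio") <- fisher_ratio(w, sc)
  attr(w, "scatter") <- sc
  w
}

#' Cubic output transform
#'
#' `s_w = s + s^3`, a strictly monotone widening applied to sharp CV
#' distributions to make them easier to bias.
#'
#' @param s numeric
#' @return `s + s^3`
#' @export
cubic_transform <- function(s) s + s^3
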
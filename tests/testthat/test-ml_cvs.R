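# Machine-learned collective variables: LDA, Deep-LDA, TICA, Deep-TICA.

make_two_clouds <- function(n = 2000, dim = 6, seed = 4) {
  d <- synth_two_state_descriptors(n, dim = dim, seed = seed)
  X <- as.matrix(d[, -1])
  list(B = X[d$state == "B", ], U = X[d$state == "U", ], X = X,
       state = d$state)
}

test_that("closed-form LDA maximises the Fisher ratio", {
  cl <- make_two_clouds()
  w <- lda_direction(cl$B, cl$U)
  sc <- attr(w, "scatter")
  expect_equal(sqrt(sum(w^2)), 1)
  set.seed(5)
  best_rand <- max(replicate(1e4, {
    v <- rnorm(6); fisher_ratio(v / sqrt(sum(v^2)), sc)
  }))
  expect_gte(attr(w, "fisher_ratio"), best_rand)
  # identity within-scatter: direction is the mean difference
  # (constructed data with empirical Sw, so test the formula directly)
  delta <- sc$mu_B - sc$mu_U
  w_formula <- solve(sc$S_w, delta); w_formula <- w_formula /
    sqrt(sum(w_formula^2))
  expect_equal(as.numeric(w), as.numeric(w_formula))
  # scale invariance of the normalised direction
  w2 <- lda_direction(cl$B * 3.7, cl$U * 3.7)
  expect_equal(as.numeric(w2), as.numeric(w), tolerance = 1e-8)
  expect_error(lda_direction(cl$B, cl$B), "coincide")
})

test_that("scatter matrices have the documented structure", {
  cl <- make_two_clouds(n = 500, dim = 4)
  sc <- scatter_matrices(cl$B, cl$U)
  expect_equal(sc$S_b, tcrossprod(sc$mu_B - sc$mu_U))
  ev <- eigen(sc$S_b, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-8), 1L)          # rank one
  expect_true(isSymmetric(sc$S_w))
  expect_gt(min(eigen(sc$S_w, only.values = TRUE)$values), 0)
})

test_that("cubic transform closed forms", {
  expect_identical(cubic_transform(0), 0)
  expect_identical(cubic_transform(1), 2)
  expect_identical(cubic_transform(-2), -10)
  s <- seq(-3, 3, 0.01)
  expect_true(all(diff(cubic_transform(s)) > 0))  # strictly monotone
})

test_that("Deep-LDA with linear activations collapses onto closed-form LDA", {
  cl <- make_two_clouds()
  m <- train_deep_lda(cl$B, cl$U, hidden = c(8, 8), activation = "linear",
                      epochs = 50, seed = 7)
  W <- diag(6)
  for (l in m$layers) W <- W %*% l$W
  weff <- as.vector(W %*% m$w); weff <- weff / sqrt(sum(weff^2))
  ctr <- colMeans(rbind(cl$B, cl$U)); scl <- apply(rbind(cl$B, cl$U), 2, sd)
  std <- function(X) sweep(sweep(X, 2, ctr), 2, scl, "/")
  wld <- lda_direction(std(cl$B), std(cl$U))
  expect_gte(abs(sum(weff * wld)), 0.99)
})

test_that("Deep-LDA separates held-out data and is seed-deterministic", {
  cl <- make_two_clouds(n = 2000)
  m <- train_deep_lda(cl$B[1:1500, ], cl$U[1:1500, ], epochs = 100,
                      seed = 8)
  sB <- predict(m, cl$B[1501:2000, ], transform = FALSE)
  sU <- predict(m, cl$U[1501:2000, ], transform = FALSE)
  sep <- abs(mean(sB) - mean(sU)) / sqrt((var(sB) + var(sU)) / 2)
  expect_gte(sep, 5)
  # cubic output transform by default, bound state on the high side
  expect_identical(m$output_transform, "cubic")
  sw <- predict(m, cl$B[1501:2000, ])
  expect_equal(sw, sB + sB^3)
  m2 <- train_deep_lda(cl$B[1:1500, ], cl$U[1:1500, ], epochs = 100,
                       seed = 8)
  expect_identical(m$layers, m2$layers)
  expect_identical(m$w, m2$w)
})

test_that("TICA recovers OU relaxation times and planted slow axes", {
  set.seed(11)
  n <- 1e6; Trel <- 50
  a <- exp(-1 / Trel)
  x <- as.numeric(stats::filter(rnorm(n, 0, sqrt(1 - a^2)), a,
                                method = "recursive"))
  X <- cbind(x, rnorm(n))
  ts <- tica(X, lag = 20)
  expect_equal(ts$eigenvalues[1], exp(-20 / Trel), tolerance = 0.02)
  expect_equal(ts$implied_timescales[1], Trel, tolerance = 0.1)
  v1 <- ts$eigenvectors[, 1]
  expect_gte(abs(v1[1]) / sqrt(sum(v1^2)), 0.99)
  # two OU components with distinct timescales: slow axis recovered
  b <- exp(-1 / 10)
  y <- as.numeric(stats::filter(rnorm(n, 0, sqrt(1 - b^2)), b,
                                method = "recursive"))
  R <- matrix(c(0.8, 0.6, -0.6, 0.8), 2)      # rotate the slow axis
  X2 <- cbind(x, y) %*% t(R)
  ts2 <- tica(X2, lag = 20)
  v <- ts2$eigenvectors[, 1]; v <- v / sqrt(sum(v^2))
  slow_axis <- R[, 1] / sqrt(sum(R[, 1]^2))
  # eigenvectors live in whitened space; compare recovered CV series
  s_rec <- as.vector(sweep(X2, 2, ts2$mu) %*% ts2$eigenvectors[, 1])
  expect_gte(abs(cor(s_rec, x)), 0.99)
})

test_that("white noise has no slow mode and the variational bound holds", {
  set.seed(12)
  tw <- tica(matrix(rnorm(6e5), ncol = 3), lag = 10)
  its <- tw$implied_timescales
  expect_true(all(is.na(its) | its <= 10))
  for (r in 1:5) {
    Xr <- matrix(rnorm(4e4 * 2), ncol = 2)
    expect_lte(max(tica(Xr, lag = 5)$eigenvalues), 1 + 1e-8)
  }
  expect_error(tica(matrix(rnorm(20), 10), lag = 10), "lag")
})

test_that("Deep-TICA collapses to linear TICA under linear activations", {
  set.seed(21)
  n <- 2e4; Trel <- 50
  a <- exp(-1 / Trel)
  y <- as.numeric(stats::filter(rnorm(n, 0, sqrt(1 - a^2)), a,
                                method = "recursive"))
  X <- cbind(y, rnorm(n),
             as.numeric(stats::filter(rnorm(n, 0, sqrt(1 - exp(-2 / 3))),
                                      exp(-1 / 3), method = "recursive")))
  m <- train_deep_tica(X, lag = 20, epochs = 100, seed = 6,
                       activation = "linear", hidden = c(6))
  tl <- tica(X, lag = 20)
  s_lin <- as.vector(sweep(X, 2, tl$mu) %*% tl$eigenvectors[, 1])
  expect_gte(abs(cor(predict(m, X), s_lin)), 0.98)
})

test_that("Deep-TICA recovers a planted nonlinear slow mode", {
  set.seed(22)
  n <- 2e4; Trel <- 50
  a <- exp(-1 / Trel)
  y <- as.numeric(stats::filter(rnorm(n, 0, sqrt(1 - a^2)), a,
                                method = "recursive"))
  f1 <- rnorm(n)
  X <- cbind(y + 0.3 * y^3 + 0.1 * f1, tanh(y) + 0.1 * rnorm(n),
             f1 + 0.05 * y, rnorm(n))
  m <- train_deep_tica(X, lag = 20, epochs = 120, seed = 5)
  st <- predict(m, X)
  expect_gte(abs(cor(st, y, method = "spearman")), 0.9)
  # zero bias column is identical to unbiased training
  m0 <- train_deep_tica(X[1:5000, ], lag = 10, epochs = 20, seed = 9,
                        bias = rep(0, 5000))
  m1 <- train_deep_tica(X[1:5000, ], lag = 10, epochs = 20, seed = 9)
  expect_identical(m0$layers, m1$layers)
})

test_that("CV models serialise to JSON and restore exactly", {
  cl <- make_two_clouds(n = 300, dim = 4, seed = 5)
  m <- train_deep_lda(cl$B, cl$U, epochs = 20, seed = 1)
  path <- tempfile(fileext = ".json")
  write_cv_model(m, path)
  m2 <- read_cv_model(path)
  expect_lt(max(abs(predict(m, cl$X) - predict(m2, cl$X))), 1e-12)
  set.seed(30)
  mt <- train_deep_tica(matrix(rnorm(2000 * 3), ncol = 3), lag = 5,
                        epochs = 10, seed = 2)
  path2 <- tempfile(fileext = ".json")
  write_cv_model(mt, path2)
  mt2 <- read_cv_model(path2)
  Xn <- matrix(rnorm(300), ncol = 3)
  expect_lt(max(abs(predict(mt, Xn) - predict(mt2, Xn))), 1e-12)
})
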
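# On-the-fly probability enhanced sampling.
#
# The sampled CV distribution is estimated on the fly as a weighted kernel
# sum
#     P_n(s) = sum_k w_k G(s, s_k) / sum_k w_k ,   w_k = exp(beta V_{k-1}(s_k))
# and converted into the well-tempered bias
#     V_n(s) = (1 - 1/gamma) (1/beta) log( P_n(s)/Z_n + epsilon )
# where Z_n measures the configuration space explored so far (here the mean
# of P_n over the deposited kernel centres) and epsilon bounds the
# deposited bias: with epsilon = exp(-beta DeltaE / (1 - 1/gamma)) the bias
# can never exceed the barrier parameter DeltaE.

#' Convert a barrier parameter into the OPES regulariser epsilon
#'
#' `epsilon = exp(-beta * delta_E / (1 - 1/gamma))`, so that the maximum
#' attainable bias is `delta_E`.
#'
#' @param delta_E barrier parameter (energy); the cap on the deposited bias
#' @param gamma bias factor, `> 1` (may be `Inf`)
#' @param beta inverse temperature `1/kT`
#' @return epsilon
#' @export
epsilon_from_barrier <- function(delta_E, gamma, beta = 1) {
  assert_scalar_pos(delta_E, "delta_E")
  assert_scalar_pos(beta, "beta")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 1) {
    stop("'gamma' must be > 1", call. = FALSE)
  }
  exp(-beta * delta_E / (1 - 1 / gamma))
}

#' Create an empty OPES bias state
#'
#' @param gamma bias factor `> 1` (`Inf` allowed: plain, non-tempered target)
#' @param beta inverse temperature
#' @param sigma per-CV-dimension Gaussian kernel bandwidth
#' @param barrier optional bias cap `DeltaE`; sets
#'   `epsilon = epsilon_from_barrier(barrier, gamma, beta)`
#' @param epsilon explicit regulariser (overrides `barrier`)
#' @param deposit_period steps between kernel deposits (metadata; the state
#'   itself is updated by explicit [deposit()] calls)
#' @param excluded_region optional [cv_region()]: deposits whose centre falls
#'   inside it are refused (OPES flooding)
#' @return object of class `bias_state`
#' @export
bias_state <- function(gamma, sigma, beta = 1, barrier = NULL,
                       epsilon = NULL, deposit_period = 500L,
                       excluded_region = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 1) {
    stop("'gamma' must be >= 1", call. = FALSE)
  }
  if (is.null(epsilon)) {
    epsilon <- if (is.null(barrier)) 1e-8 else
      epsilon_from_barrier(barrier, max(gamma, 1 + 1e-12), beta)
  }
  stopifnot(epsilon > 0, all(sigma > 0))
  structure(list(
    centers = matrix(numeric(0), 0, length(sigma)),
    weights = numeric(0), sum_w = 0, Z = 1,
    gamma = gamma, beta = beta, epsilon = epsilon, sigma = sigma,
    barrier = barrier, deposit_period = as.integer(deposit_period),
    excluded_region = excluded_region), class = "bias_state")
}

#' @export
print.bias_state <- function(x, ...) {
  cat("<bias_state> ", nrow(x$centers), " kernels, ncv = ", length(x$sigma),
      "\n  gamma = ", x$gamma, ", beta = ", x$beta,
      ", epsilon = ", signif(x$epsilon, 4),
      if (!is.null(x$barrier)) paste0(" (barrier ", x$barrier, ")"), "\n",
      "  sigma = ", paste(signif(x$sigma, 4), collapse = ", "),
      ", Z = ", signif(x$Z, 5), "\n", sep = "")
  invisible(x)
}

# unnormalised kernel matrix: rows = query points, cols = kernel centres
.kernel_matrix <- function(state, s) {
  n <- nrow(state$centers)
  s <- if (is.matrix(s)) s else matrix(s, ncol = ncol(state$centers))
  norm_const <- 1 / prod(state$sigma * sqrt(2 * pi))
  E <- matrix(0, nrow(s), n)
  for (d in seq_along(state$sigma)) {
    E <- E + outer(s[, d], state$centers[, d], "-")^2 / (2 * state$sigma[d]^2)
  }
  norm_const * exp(-E)
}

#' Evaluate the OPES bias (and optionally its gradient)
#'
#' Exact kernel-sum evaluation of the well-tempered bias.  An empty state
#' returns 0 everywhere (the convention `V_0 = 0`, forced by the weight
#' definition at the first deposit).
#'
#' @param state a [bias_state()]
#' @param s CV point(s): vector (one point per entry for 1 CV, or a single
#'   point for multi-CV states) or an `n x ncv` matrix
#' @param gradient if `TRUE`, attach the analytic gradient as attribute
#'   `"gradient"` (an `n x ncv` matrix)
#' @return numeric bias values (energy)
#' @export
evaluate_bias <- function(state, s, gradient = FALSE) {
  stopifnot(inherits(state, "bias_state"))
  ncv <- ncol(state$centers)
  s <- if (is.matrix(s)) s else matrix(s, ncol = ncv)
  if (any(!is.finite(s))) stop("non-finite CV value", call. = FALSE)
  n <- nrow(state$centers)
  if (n == 0L) {
    v <- rep(0, nrow(s))
    if (gradient) attr(v, "gradient") <- matrix(0, nrow(s), ncv)
    return(v)
  }
  pref <- (1 - 1 / state$gamma) / state$beta
  K <- .kernel_matrix(state, s)
  P <- as.vector(K %*% state$weights) / state$sum_w
  v <- pref * log(P / state$Z + state$epsilon)
  if (gradient) {
    g <- matrix(0, nrow(s), ncv)
    denom <- P / state$Z + state$epsilon
    for (d in seq_len(ncv)) {
      dK <- K * (-outer(s[, d], state$centers[, d], "-") / state$sigma[d]^2)
      dP <- as.vector(dK %*% state$weights) / state$sum_w
      g[, d] <- pref * (dP / state$Z) / denom
    }
    attr(v, "gradient") <- g
  }
  v
}

#' The bias floor of a state
#'
#' The bias value in never-visited regions, `(1 - 1/gamma)/beta * log(epsilon)`
#' (equal to `-DeltaE` when epsilon was set from a barrier).  An empty state
#' has floor 0 because its bias is identically 0.
#'
#' @param state a [bias_state()]
#' @return numeric scalar
#' @export
bias_floor <- function(state) {
  if (nrow(state$centers) == 0L) return(0)
  (1 - 1 / state$gamma) / state$beta * log(state$epsilon)
}

#' Deposit a kernel at a CV point
#'
#' Appends a Gaussian kernel at `s_k` with weight
#' `w_k = exp(beta V_{k-1}(s_k))`, then refreshes the weight sum and the
#' normalisation `Z_n` (mean of `P_n` over the deposited centres).  If the
#' state's excluded region contains `s_k`, no kernel is added and the state
#' is returned unchanged.
#'
#' @param state a [bias_state()]
#' @param s_k CV point (numeric vector of length ncv)
#' @return the updated `bias_state`
#' @export
deposit <- function(state, s_k) {
  stopifnot(inherits(state, "bias_state"))
  s_k <- as.numeric(s_k)
  if (any(!is.finite(s_k))) stop("non-finite deposit point", call. = FALSE)
  stopifnot(length(s_k) == ncol(state$centers) || nrow(state$centers) == 0L)
  if (!is.null(state$excluded_region) &&
      isTRUE(all(state$excluded_region(matrix(s_k, 1))))) {
    return(state)
  }
  w <- exp(state$beta * evaluate_bias(state, matrix(s_k, 1)))
  state$centers <- rbind(state$centers, s_k)
  rownames(state$centers) <- NULL
  state$weights <- c(state$weights, w)
  state$sum_w <- sum(state$weights)
  K <- .kernel_matrix(state, state$centers)
  P_at_centers <- as.vector(K %*% state$weights) / state$sum_w
  state$Z <- mean(P_at_centers)
  state
}

#' Configure an OPES run
#'
#' @param barrier bias cap `DeltaE` (energy); sets epsilon via
#'   [epsilon_from_barrier()].  `barrier = 0` disables biasing entirely.
#' @param gamma bias factor (`1` reduces exactly to unbiased sampling)
#' @param sigma kernel bandwidth per CV; `NULL` estimates it as
#'   `sigma_factor` times the CV standard deviation over a short unbiased
#'   segment (falling back to 10% of the grid range if degenerate)
#' @param sigma_factor multiplier for the estimated bandwidth
#' @param deposit_period integrator steps between deposits
#' @param grid CV lattice carrying the bias between deposits: list with
#'   `min`, `max`, `n` (recycled per CV dimension)
#' @param excluded_region optional [cv_region()] where deposition is refused
#' @param stride output stride (frames)
#' @return object of class `opes_config`
#' @export
opes_config <- function(barrier, gamma = 10, sigma = NULL, sigma_factor = 1,
                        deposit_period = 500L,
                        grid = list(min = -2.5, max = 2.5, n = 501L),
                        excluded_region = NULL, stride = 10L) {
  stopifnot(barrier >= 0)
  structure(list(barrier = barrier, gamma = gamma, sigma = sigma,
                 sigma_factor = sigma_factor,
                 deposit_period = as.integer(deposit_period), grid = grid,
                 excluded_region = excluded_region,
                 stride = as.integer(stride)),
            class = "opes_config")
}

# Bandwidth estimation from a short unbiased segment.  The scale of
# interest is the equilibrium fluctuation inside the starting basin, so a
# robust short-time estimator is used: the MAD of lagged differences
# (divided by sqrt(2)).  Unlike a plain standard deviation it is immune to
# a rare barrier crossing inside the estimation segment, which would
# otherwise inflate the bandwidth to the inter-basin distance.
estimate_sigma <- function(spec, cvmap, config, n_est = 5000L) {
  est_spec <- spec
  est_spec$n_steps <- n_est
  est_spec$seed <- derive_seed(spec$seed, 91L)
  ser <- run_langevin(est_spec, cv = cvmap, stride = 5L)
  ncv <- nrow(cvmap)
  gmin <- rep_len(config$grid$min, ncv); gmax <- rep_len(config$grid$max, ncv)
  sig <- numeric(ncv)
  for (r in seq_len(ncv)) {
    s <- ser[[rownames(cvmap)[r]]]
    # the MAD of lagged differences plateaus at the basin width once the
    # lag exceeds the correlation time; take the plateau over a few lags
    lags <- unique(pmin(c(10L, 50L, 200L), max(1L, length(s) %/% 4L)))
    sdev <- max(vapply(lags, function(l) {
      stats::mad(diff(s, lag = l)) / sqrt(2)
    }, numeric(1)))
    sig[r] <- if (is.finite(sdev) && sdev > 1e-12) {
      config$sigma_factor * sdev
    } else {
      0.1 * (gmax[r] - gmin[r])
    }
  }
  sig
}

#' Run an OPES simulation
#'
#' Couples the Langevin integrator with on-the-fly kernel deposition: every
#' `deposit_period` steps a kernel is added at the current CV value (unless
#' it falls in the excluded region) and the bias lattice is refreshed.  In
#' the long run the sampled CV marginal approaches the well-tempered target
#' `P(s)^{1/gamma}`.
#'
#' @param spec a [langevin_spec()]
#' @param config an [opes_config()]
#' @param cv CV map as in [run_langevin()]
#' @param stop optional [cv_stop()]
#' @param domain_bound divergence guard on coordinates
#' @return list with `series` (a `colvar_series` including the `opes.bias`
#'   column) and `state` (the final [bias_state()])
#' @export
run_opes <- function(spec, config, cv = NULL, stop = NULL, domain_bound = 50) {
  stopifnot(inherits(spec, "langevin_spec"), inherits(config, "opes_config"))
  dim <- spec$potential$dimension
  cvmap <- as_cv_map(cv, dim)
  ncv <- nrow(cvmap)
  beta <- 1 / spec$kT
  if (config$barrier <= 0) {
    ser <- run_langevin(spec, cv = cvmap, stride = config$stride,
                        stop = stop, domain_bound = domain_bound)
    st <- bias_state(gamma = max(config$gamma, 1), sigma = rep(1, ncv),
                     beta = beta, epsilon = 1,
                     deposit_period = config$deposit_period,
                     excluded_region = config$excluded_region)
    return(list(series = ser, state = st,
                acceleration = attr(ser, "acceleration"),
                exited = attr(ser, "exited"), t_exit = attr(ser, "t_exit")))
  }
  sigma <- config$sigma %||% estimate_sigma(spec, cvmap, config)
  sigma <- rep_len(sigma, ncv)
  gamma <- config$gamma
  epsilon <- if (gamma > 1) {
    epsilon_from_barrier(config$barrier, gamma, beta)
  } else 1  # gamma = 1: prefactor vanishes, bias identically zero
  gmin <- rep_len(config$grid$min, ncv)
  gmax <- rep_len(config$grid$max, ncv)
  gn <- rep_len(as.integer(config$grid$n %||% 501L), ncv)
  res <- cpp_run_engine(
    spec$potential$id, unname(spec$potential$params), spec$x0,
    spec$dt, spec$kT, spec$friction, spec$n_steps, config$stride,
    spec$seed, cvmap,
    TRUE, gamma, epsilon, sigma, config$deposit_period,
    gmin, gmax, gn,
    as_region_box(config$excluded_region, ncv),
    as_stop_spec(stop, cvmap, config$stride), domain_bound, NULL)
  st <- bias_state(gamma = gamma, sigma = sigma, beta = beta,
                   barrier = config$barrier, epsilon = epsilon,
                   deposit_period = config$deposit_period,
                   excluded_region = config$excluded_region)
  if (nrow(res$centers) > 0L) {
    st$centers <- res$centers
    st$weights <- res$weights
    st$sum_w <- res$sum_w
    st$Z <- res$Z
  }
  ser <- series_from_engine(res, cvmap, spec, extras = list(
    acceleration = res$boost_mean, exited = res$exited, t_exit = res$t_exit))
  list(series = ser, state = st, acceleration = res$boost_mean,
       exited = res$exited, t_exit = res$t_exit,
       n_frames = res$n_frames)
}

#' Serialise / restore a bias state as a JSON-lines kernel table
#'
#' One JSON object per line: a header line with the state scalars (format
#' version, gamma, beta, epsilon, sigma, Z) followed by one line per kernel
#' (`center`, `weight`).  The format is stable so that shared-bias walkers
#' can merge kernel tables later.
#'
#' @param state a [bias_state()]
#' @param path output file
#' @export
write_bias_state <- function(state, path) {
  stopifnot(inherits(state, "bias_state"))
  head <- jsonlite::toJSON(list(
    format = "aquaopes-kernels-1", ncv = ncol(state$centers),
    gamma = state$gamma, beta = state$beta, epsilon = state$epsilon,
    sigma = state$sigma, Z = state$Z, sum_w = state$sum_w,
    deposit_period = state$deposit_period,
    barrier = state$barrier), auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(head, con)
  if (nrow(state$centers) > 0L) {
    for (k in seq_len(nrow(state$centers))) {
      writeLines(jsonlite::toJSON(list(center = state$centers[k, ],
                                       weight = state$weights[k]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname write_bias_state
#' @return `read_bias_state` returns the restored [bias_state()]
#' @export
read_bias_state <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty bias state file", call. = FALSE)
  head <- jsonlite::fromJSON(lines[[1]])
  if (!identical(head$format, "aquaopes-kernels-1")) {
    stop("unrecognised bias state format", call. = FALSE)
  }
  st <- bias_state(gamma = head$gamma, sigma = head$sigma, beta = head$beta,
                   epsilon = head$epsilon,
                   deposit_period = head$deposit_period,
                   barrier = head$barrier)
  if (length(lines) > 1L) {
    rows <- lapply(lines[-1], jsonlite::fromJSON)
    st$centers <- do.call(rbind, lapply(rows, function(r) r$center))
    st$weights <- vapply(rows, function(r) r$weight, numeric(1))
    st$sum_w <- sum(st$weights)
    K <- .kernel_matrix(st, st$centers)
    st$Z <- mean(as.vector(K %*% st$weights) / st$sum_w)
  }
  st
}
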
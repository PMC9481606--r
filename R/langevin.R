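# Overdamped Langevin propagation (Euler-Maruyama) on the toy potentials.
# Dynamics are in reduced units: kT = 1, friction = 1, dt = 1e-3 by default.

#' Specify an overdamped Langevin run
#'
#' @param potential an [make_potential()] object
#' @param kT thermal energy (reduced units)
#' @param friction friction coefficient (1/time); the diffusion constant is
#'   `kT / friction`
#' @param dt integration time step
#' @param n_steps number of steps
#' @param seed integer seed; identical spec + seed gives a bitwise-identical
#'   trajectory
#' @param x0 initial coordinates (defaults to the origin shifted to -1 on the
#'   first axis for the double wells, i.e. inside a basin)
#' @return object of class `langevin_spec`
#' @export
langevin_spec <- function(potential, n_steps, seed,
                          kT = 1, friction = 1, dt = 1e-3, x0 = NULL) {
  stopifnot(inherits(potential, "aqua_potential"))
  assert_scalar_pos(kT, "kT")
  assert_scalar_pos(friction, "friction")
  assert_scalar_pos(dt, "dt")
  assert_scalar_pos(n_steps, "n_steps")
  if (is.null(x0)) {
    x0 <- rep(0, potential$dimension)
    if (potential$name %in% c("double_well_1d", "double_well_2d")) x0[1] <- -1
  }
  stopifnot(length(x0) == potential$dimension)
  structure(list(potential = potential, kT = kT, friction = friction,
                 dt = dt, n_steps = n_steps, seed = seed, x0 = x0),
            class = "langevin_spec")
}

# normalise a CV map to an (ncv x dim) matrix with row names
as_cv_map <- function(cv, dim) {
  if (is.null(cv)) {
    m <- diag(dim)
    rownames(m) <- if (dim == 1L) "s" else paste0("s", seq_len(dim))
  } else if (is.matrix(cv)) {
    m <- cv
    if (ncol(m) != dim) stop("cv map must have ", dim, " columns")
    if (is.null(rownames(m))) {
      rownames(m) <- if (nrow(m) == 1L) "s" else paste0("s", seq_len(nrow(m)))
    }
  } else {
    m <- matrix(cv, nrow = 1)
    if (ncol(m) != dim) stop("cv map must have length ", dim)
    rownames(m) <- "s"
  }
  if (nrow(m) > 2L) stop("at most two collective variables are supported")
  m
}

# normalise a stop predicate to the engine's c(index, threshold, dir, dwell)
as_stop_spec <- function(stop, cvmap, stride) {
  if (is.null(stop)) return(NULL)
  stopifnot(inherits(stop, "cv_stop"))
  dwell_steps <- max(1L, as.integer(stop$dwell * stride))
  c(stop$cv, stop$threshold, stop$dir, dwell_steps)
}

#' Define a stop predicate on a collective variable
#'
#' The predicate fires when the chosen CV stays beyond `above` (or below
#' `below`) for `dwell` consecutive output frames; the commitment dwell
#' guards against counting transient recrossings as events.
#'
#' @param cv index of the CV (row of the CV map)
#' @param above,below threshold; give exactly one
#' @param dwell commitment dwell, in output frames
#' @return object of class `cv_stop`
#' @export
cv_stop <- function(cv = 1L, above = NULL, below = NULL, dwell = 10L) {
  if (is.null(above) == is.null(below)) {
    stop("give exactly one of 'above' or 'below'")
  }
  structure(list(cv = as.integer(cv),
                 threshold = if (!is.null(above)) above else below,
                 dir = if (!is.null(above)) 1 else -1,
                 dwell = as.integer(dwell)),
            class = "cv_stop")
}

#' Define a rectangular region in CV space
#'
#' Used as an excluded region for bias deposition (OPES flooding) and as a
#' generic CV-space predicate.  A point is inside when every CV lies within
#' its `[min, max]` interval.
#'
#' @param min,max numeric vectors, one entry per CV (use `-Inf` / `Inf` for
#'   half-open constraints, e.g. `cv_region(min = 6)` is "s1 > 6")
#' @return object of class `cv_region`; call it on a CV vector/matrix to test
#'   membership
#' @export
cv_region <- function(min = -Inf, max = Inf) {
  n <- base::max(length(min), length(max))
  lo <- rep_len(min, n); hi <- rep_len(max, n)
  f <- function(s) {
    s <- if (is.matrix(s)) s else matrix(s, ncol = n)
    ok <- rep(TRUE, nrow(s))
    for (d in seq_len(n)) ok <- ok & s[, d] >= lo[d] & s[, d] <= hi[d]
    ok
  }
  structure(f, class = c("cv_region", "function"), lo = lo, hi = hi)
}

as_region_box <- function(region, ncv) {
  if (is.null(region)) return(NULL)
  stopifnot(inherits(region, "cv_region"))
  lo <- rep_len(attr(region, "lo"), ncv)
  hi <- rep_len(attr(region, "hi"), ncv)
  rbind(lo, hi)
}

#' Run overdamped Langevin dynamics
#'
#' Euler-Maruyama propagation, optionally under a fixed external bias
#' evaluated in CV space.  Without bias the stationary CV histogram converges
#' to `exp(-U/kT)`.
#'
#' @param spec a [langevin_spec()]
#' @param bias optional fixed bias: a [bias_state()] (evaluated exactly on a
#'   lattice once, then interpolated) or a constant numeric bias value
#' @param cv CV map: `ncv x dim` matrix (CV = cv %*% x), a length-`dim`
#'   vector for one CV, or `NULL` for the identity map
#' @param stride output every `stride` steps
#' @param stop optional [cv_stop()] predicate
#' @param grid lattice for evaluating a `bias_state`: list with `min`, `max`,
#'   `n` per CV dimension (defaults to `[-5, 5] x 501`)
#' @param domain_bound abort with a diagnostic if any coordinate exceeds this
#' @return a `colvar_series` data frame (`time`, positions `x*`, CVs, and a
#'   `opes.bias` column) with the run metadata in attributes
#' @export
run_langevin <- function(spec, bias = NULL, cv = NULL, stride = 10L,
                         stop = NULL, grid = NULL, domain_bound = 50) {
  stopifnot(inherits(spec, "langevin_spec"))
  dim <- spec$potential$dimension
  cvmap <- as_cv_map(cv, dim)
  ncv <- nrow(cvmap)
  static_bias <- NULL
  if (!is.null(bias)) {
    grid <- grid %||% list(min = rep(-5, ncv), max = rep(5, ncv),
                           n = rep(501L, ncv))
    gmin <- rep_len(grid$min, ncv); gmax <- rep_len(grid$max, ncv)
    gn <- rep_len(as.integer(grid$n), ncv)
    nodes <- lapply(seq_len(ncv), function(d) seq(gmin[d], gmax[d],
                                                  length.out = gn[d]))
    pts <- as.matrix(expand.grid(nodes))
    vv <- if (is.numeric(bias) && length(bias) == 1L) {
      rep(bias, nrow(pts))
    } else {
      evaluate_bias(bias, pts)
    }
    static_bias <- list(grid_min = gmin, grid_max = gmax, grid_n = gn, V = vv)
  }
  res <- cpp_run_engine(
    spec$potential$id, unname(spec$potential$params), spec$x0,
    spec$dt, spec$kT, spec$friction, spec$n_steps, as.integer(stride),
    spec$seed, cvmap,
    FALSE, 1, 1, rep(1, ncv), 0L,
    rep(0, ncv), rep(1, ncv), rep(2L, ncv),
    NULL, as_stop_spec(stop, cvmap, stride), domain_bound, static_bias)
  series_from_engine(res, cvmap, spec, extras = list(
    acceleration = res$boost_mean, exited = res$exited, t_exit = res$t_exit))
}

series_from_engine <- function(res, cvmap, spec, extras = list()) {
  dim <- ncol(res$x)
  df <- data.frame(time = res$time)
  for (c in seq_len(dim)) df[[paste0("x", c)]] <- res$x[, c]
  for (r in seq_len(nrow(cvmap))) df[[rownames(cvmap)[r]]] <- res$cv[, r]
  df[["opes.bias"]] <- res$bias
  attr(df, "cv_map") <- cvmap
  attr(df, "kT") <- spec$kT
  attr(df, "spec") <- spec
  for (nm in names(extras)) attr(df, nm) <- extras[[nm]]
  class(df) <- c("colvar_series", "data.frame")
  df
}

#' Unbiased first-passage (escape) times by brute force
#'
#' Repeatedly propagates the unbiased dynamics from `spec$x0` until the stop
#' predicate commits, recording each first-passage time.  This is the ground
#' truth against which OPES-flooding rates are validated.
#'
#' @param spec a [langevin_spec()]; `spec$n_steps` is ignored in favour of
#'   `max_total_steps`
#' @param stop a [cv_stop()] predicate defining the escape
#' @param n_events number of independent events to collect
#' @param cv CV map as in [run_langevin()]
#' @param max_total_steps total step budget across all events; exhausted
#'   budget before `n_events` complete is an error
#' @return numeric vector of `n_events` first-passage times
#' @export
brute_force_escape_times <- function(spec, stop, n_events, cv = NULL,
                                     max_total_steps = 1e9) {
  stopifnot(inherits(spec, "langevin_spec"), inherits(stop, "cv_stop"))
  dim <- spec$potential$dimension
  cvmap <- as_cv_map(cv, dim)
  sp <- c(stop$cv, stop$threshold, stop$dir, max(1L, stop$dwell))
  res <- cpp_first_passage(spec$potential$id, unname(spec$potential$params),
                           spec$x0, spec$dt, spec$kT, spec$friction,
                           cvmap, sp, max_total_steps, spec$seed,
                           as.integer(n_events))
  if (!all(res$completed)) {
    stop("step budget exhausted after ", sum(res$completed), " of ",
         n_events, " events", call. = FALSE)
  }
  res$times
}
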
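# Analytic toy potentials.  These are desk-scale stand-ins for the molecular
# interaction potential: a symmetric double well (the canonical barrier
# crossing benchmark), its 2D extension, and a two-dimensional "binding
# funnel" in which escape along the exit coordinate is gated by a second,
# solvation-like coordinate.

.pot_table <- list(
  double_well_1d = list(
    id = 1L, dimension = 1L,
    defaults = c(h = 5),
    doc = "U(x) = h (x^2 - 1)^2; minima at x = +/-1, barrier U(0) = h"
  ),
  double_well_2d = list(
    id = 2L, dimension = 2L,
    defaults = c(h = 5, ky = 2),
    doc = "U(x, y) = h (x^2 - 1)^2 + ky y^2 / 2"
  ),
  binding_funnel_2d = list(
    id = 3L, dimension = 2L,
    defaults = c(D = 6, s0 = 0.7, H = 4, c = 1, zb = 2, sb = 0.5, kappa = 2),
    doc = paste(
      "U(z, w) = -D exp(-z^2 / 2 s0^2)",
      "+ H (1 + c (w - 1)^2) exp(-(z - zb)^2 / 2 sb^2) + kappa w^2 / 2;",
      "a bound well near z = 0 whose exit barrier at z = zb is lowest when",
      "the gating coordinate w opens towards w = 1")
  )
)

#' Create an analytic toy potential
#'
#' @param name one of `"double_well_1d"`, `"double_well_2d"`,
#'   `"binding_funnel_2d"`.
#' @param params named numeric vector of parameters; unspecified entries take
#'   the documented defaults.  `double_well_1d` has barrier height `h` (in kT
#'   when `kT = 1`); `double_well_2d` adds a harmonic stiffness `ky`; the
#'   funnel couples a bound well of depth `D` (width `s0`) to a gate: the
#'   exit barrier of height `H (1 + c (w - 1)^2)` at `z = zb` (width `sb`) is
#'   cheapest to cross when the solvation coordinate `w` pays the harmonic
#'   price `kappa w^2 / 2` to approach 1.
#' @return an object of class `aqua_potential` with elements `name`,
#'   `params`, `dimension`, and closures `energy(x)` / `gradient(x)` accepting
#'   a coordinate vector or an `n x d` matrix of coordinates.
#' @examples
#' pot <- make_potential("double_well_1d", c(h = 5))
#' pot$energy(c(-1, 0, 1))   # 0, 5, 0
#' @export
make_potential <- function(name, params = NULL) {
  if (!name %in% names(.pot_table)) {
    stop("unknown potential '", name, "'; available: ",
         paste(names(.pot_table), collapse = ", "), call. = FALSE)
  }
  entry <- .pot_table[[name]]
  p <- entry$defaults
  if (!is.null(params)) {
    if (is.null(names(params)) || any(!names(params) %in% names(p))) {
      stop("params for '", name, "' must be named among: ",
           paste(names(p), collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(params))) stop("non-finite potential parameters",
                                      call. = FALSE)
    p[names(params)] <- params
  }
  dim <- entry$dimension
  id <- entry$id
  pv <- unname(p)
  as_mat <- function(x) {
    if (is.matrix(x)) {
      if (ncol(x) != dim) stop("coordinates must have ", dim, " columns")
      x
    } else {
      matrix(x, ncol = dim, byrow = (dim > 1L && length(x) > dim))
    }
  }
  obj <- list(
    name = name, params = p, dimension = dim, id = id,
    energy = function(x) cpp_pot_energy(id, pv, as_mat(x)),
    gradient = function(x) cpp_pot_grad(id, pv, as_mat(x))
  )
  class(obj) <- "aqua_potential"
  obj
}

#' @export
print.aqua_potential <- function(x, ...) {
  cat("<aqua_potential> ", x$name, " (dimension ", x$dimension, ")\n", sep = "")
  cat("  ", .pot_table[[x$name]]$doc, "\n", sep = "")
  cat("  params: ", paste(names(x$params), signif(x$params, 4), sep = "=",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Locate the lowest saddle of a 2D potential by a grid minimax over paths
#'
#' Brute-force oracle: on a lattice, the barrier between two basins is the
#' minimum over lattice paths of the maximum energy along the path, computed
#' with a Dijkstra-type sweep on the "max-energy-so-far" cost.  Used to
#' validate closed-form barrier claims for the shipped 2D potentials.
#'
#' @param potential an [make_potential()] object with `dimension == 2`
#' @param from,to coordinates of the two basin representatives
#' @param lower,upper numeric length-2 lattice bounds
#' @param n lattice nodes per dimension
#' @return list with `barrier` (energy of the minimax path relative to
#'   `from`'s basin minimum on the lattice) and `saddle_energy` (absolute)
#' @export
grid_minimax_barrier <- function(potential, from, to,
                                 lower, upper, n = 101L) {
  stopifnot(potential$dimension == 2L)
  gx <- seq(lower[1], upper[1], length.out = n)
  gy <- seq(lower[2], upper[2], length.out = n)
  XY <- cbind(rep(gx, times = n), rep(gy, each = n))
  U <- matrix(potential$energy(XY), nrow = n)  # [ix, iy]
  idx_of <- function(p) c(which.min(abs(gx - p[1])), which.min(abs(gy - p[2])))
  a <- idx_of(from); b <- idx_of(to)
  # Dijkstra on cost(node) = minimal over paths of max U along path
  cost <- matrix(Inf, n, n)
  done <- matrix(FALSE, n, n)
  cost[a[1], a[2]] <- U[a[1], a[2]]
  # simple binary-heap-free loop; n^2 ~ 1e4 nodes is fine
  for (iter in seq_len(n * n)) {
    m <- which.min(ifelse(done, Inf, cost))
    if (!is.finite(cost[m])) break
    i <- (m - 1L) %% n + 1L; j <- (m - 1L) %/% n + 1L
    if (i == b[1] && j == b[2]) break
    done[m] <- TRUE
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1L || ii > n || jj < 1L || jj > n) next
      newc <- max(cost[i, j], U[ii, jj])
      if (newc < cost[ii, jj]) cost[ii, jj] <- newc
    }
  }
  saddle <- cost[b[1], b[2]]
  list(barrier = saddle - min(U), saddle_energy = saddle)
}
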
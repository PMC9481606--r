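# Funnel-restrained binding thermodynamics.
#
# The unbound ligand is confined to a cone-plus-cylinder volume around the
# exit axis; the apparent free-energy profile W(z) along the axis is then
# converted to a standard-state binding free energy via
#   DeltaF = (1/beta) log( C0 pi R_cyl^2 Int_B dz exp(-beta (W(z) - W_U)) )
# with C0 = 1/1660 A^-3 the standard concentration and W_U the unbound
# plateau reference.  The sign convention reports a stable binder as a
# positive DeltaF (the reversible work of unbinding to standard
# concentration).

#' Funnel restraint geometry
#'
#' A cone of half-opening slope `cone_slope` around `axis` for
#' `z < z_switch`, continued by a cylinder of radius `R_cyl` for
#' `z >= z_switch`; the allowed radius is
#' `r_max(z) = R_cyl + cone_slope * max(0, z_switch - z)`, continuous at
#' the switch.
#'
#' @param R_cyl cylinder radius (Angstrom)
#' @param z_switch axial distance where the cone meets the cylinder
#' @param cone_slope radial shrink per unit z (dimensionless, `>= 0`)
#' @param wall_k harmonic wall stiffness (energy / Angstrom^2)
#' @param axis funnel axis (normalised internally)
#' @param origin binding-site point the axis emanates from
#' @return object of class `funnel_geometry`
#' @export
funnel_geometry <- function(R_cyl, z_switch = 10, cone_slope = 0.6,
                            wall_k = 10, axis = c(0, 0, 1),
                            origin = c(0, 0, 0)) {
  assert_scalar_pos(R_cyl, "R_cyl")
  assert_scalar_pos(wall_k, "wall_k")
  stopifnot(cone_slope >= 0, length(axis) == 3L, length(origin) == 3L)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(R_cyl = R_cyl, z_switch = z_switch,
                 cone_slope = cone_slope, wall_k = wall_k, axis = axis,
                 origin = origin), class = "funnel_geometry")
}

funnel_rmax <- function(geom, z) {
  geom$R_cyl + geom$cone_slope * pmax(0, geom$z_switch - z)
}

#' Funnel wall restraint energy (and gradient)
#'
#' Zero inside the funnel; half-harmonic
#' `wall_k/2 (r - r_max(z))^2` outside.  Continuous and once-differentiable
#' across the funnel surface.
#'
#' @param position length-3 vector or `n x 3` matrix
#' @param geom a [funnel_geometry()]
#' @param gradient attach the analytic gradient as attribute `"gradient"`
#' @return energy values
#' @export
funnel_wall_energy <- function(position, geom, gradient = FALSE) {
  stopifnot(inherits(geom, "funnel_geometry"))
  P <- if (is.matrix(position)) position else matrix(position, ncol = 3L)
  rel <- sweep(P, 2, geom$origin)
  z <- as.vector(rel %*% geom$axis)
  radial <- rel - outer(z, geom$axis)
  r <- sqrt(rowSums(radial^2))
  rmax <- funnel_rmax(geom, z)
  excess <- pmax(0, r - rmax)
  E <- 0.5 * geom$wall_k * excess^2
  if (gradient) {
    G <- matrix(0, nrow(P), 3L)
    out <- excess > 0 & r > 1e-12
    if (any(out)) {
      runit <- radial[out, , drop = FALSE] / r[out]
      drmax_dz <- ifelse(z[out] < geom$z_switch, -geom$cone_slope, 0)
      G[out, ] <- geom$wall_k * excess[out] *
        (runit - outer(drmax_dz, geom$axis))
    }
    attr(E, "gradient") <- G
  }
  E
}

#' Standard-state funnel correction for the binding free energy
#'
#' Integrates the apparent axial free-energy profile `W(z)` over the bound
#' region and applies the cylinder cross-section and standard concentration:
#' `DeltaF = (1/beta) log( C0 pi R_cyl^2 Int_B dz exp(-beta (W - W_U)) )`,
#' with `W_U` the mean of `W` over the unbound reference interval.  The
#' result is invariant under constant shifts of `W`, monotone increasing
#' in `R_cyl`, and positive for a stable binder (unbinding work).
#'
#' @param fes_1d an `fes_grid` (or data frame whose first column is `z` and
#'   which has a `free_energy` column) covering both intervals
#' @param R_cyl funnel cylinder radius (Angstrom)
#' @param beta inverse temperature in the energy units of `W`
#' @param bound_region,unbound_region length-2 z-intervals
#' @param C0 standard concentration (1/1660 Angstrom^-3)
#' @return `DeltaF` (same units as `W`), with the integral and `W_U`
#'   attached as attributes
#' @export
funnel_correction <- function(fes_1d, R_cyl, beta, bound_region,
                              unbound_region, C0 = 1 / 1660) {
  assert_scalar_pos(R_cyl, "R_cyl")
  assert_scalar_pos(beta, "beta")
  z <- fes_1d[[1]]
  W <- fes_1d$free_energy %||% fes_1d[[2]]
  in_B <- z >= bound_region[1] & z <= bound_region[2]
  in_U <- z >= unbound_region[1] & z <= unbound_region[2]
  if (sum(in_B) < 2L || sum(in_U) < 1L) {
    stop("bound/unbound intervals not covered by the profile grid",
         call. = FALSE)
  }
  if (any(!is.finite(W[in_B]))) {
    stop("non-finite free energy inside the bound region", call. = FALSE)
  }
  W_U <- mean(W[in_U])
  integral <- trapz(z[in_B], exp(-beta * (W[in_B] - W_U)))
  dF <- log(C0 * pi * R_cyl^2 * integral) / beta
  attr(dF, "W_U") <- W_U
  attr(dF, "integral") <- integral
  dF
}

#' Enthalpy/entropy decomposition from multi-temperature free energies
#'
#' Weighted linear fit of `DeltaF(T) = DeltaU - T DeltaS` across
#' temperatures (known per-point uncertainties; generalized least squares,
#' so the parameter covariance is `(X' W X)^-1` without residual scaling).
#'
#' @param dF_by_T data frame (or matrix) with columns `T`, `dF`, `sigma`
#' @param T_ref reference temperature at which `DeltaF` and `-T DeltaS`
#'   are reported
#' @return object of class `thermo_result`: `dF`, `dU`, `minus_TdS` at
#'   `T_ref` with 1-sigma uncertainties, plus `dS` and the temperatures
#' @export
thermo_decomposition <- function(dF_by_T, T_ref = 300) {
  df <- as.data.frame(dF_by_T)
  need <- c("T", "dF", "sigma")
  if (!all(need %in% names(df))) {
    stop("need columns T, dF, sigma", call. = FALSE)
  }
  if (length(unique(df$T)) < 2L) {
    stop("need at least two distinct temperatures", call. = FALSE)
  }
  if (any(df$sigma <= 0) || any(!is.finite(df$sigma))) {
    stop("uncertainties must be positive", call. = FALSE)
  }
  X <- cbind(1, -df$T)
  Winv <- 1 / df$sigma^2
  XtWX <- crossprod(X * Winv, X)
  theta <- solve(XtWX, crossprod(X * Winv, df$dF))
  Cov <- solve(XtWX)
  dU <- theta[1]; dS <- theta[2]
  a <- c(1, -T_ref)
  dF_ref <- sum(a * theta)
  se_dF <- sqrt(as.numeric(t(a) %*% Cov %*% a))
  structure(list(dF = dF_ref, dF_se = se_dF,
                 dU = dU, dU_se = sqrt(Cov[1, 1]),
                 minus_TdS = -T_ref * dS,
                 minus_TdS_se = T_ref * sqrt(Cov[2, 2]),
                 dS = dS, dS_se = sqrt(Cov[2, 2]),
                 T_ref = T_ref, temperatures = df$T,
                 covariance = Cov), class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("<thermo_result> at T =", x$T_ref, "\n")
  cat(sprintf("  dF = %.4g +/- %.2g\n", x$dF, x$dF_se))
  cat(sprintf("  dU = %.4g +/- %.2g\n", x$dU, x$dU_se))
  cat(sprintf("  -T dS = %.4g +/- %.2g\n", x$minus_TdS, x$minus_TdS_se))
  invisible(x)
}
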
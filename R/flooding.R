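# OPES flooding: rate-safe biasing.  The bias is capped below the barrier
# and never deposited in the excluded transition region, so the physical
# residence time follows from the hyperdynamics relation
#     t = < e^{beta V} >_V  t_MD
# where the average runs along the trajectory.  The Eq.-2 bias is defined up
# to a constant; the boost uses the gauge in which the bias vanishes in
# never-visited regions (V - V_floor, with floor 0 before the first
# deposit), which is the gauge in which the transition state is unbiased.

#' Acceleration factor of a biased trajectory
#'
#' `mean(exp(beta * (v - floor)))` over the recorded frames.  With `v`
#' identically zero this is exactly 1; with a constant bias `V0` (and
#' `floor = 0`) it is exactly `exp(beta V0)`.
#'
#' @param v per-frame bias values
#' @param beta inverse temperature
#' @param floor bias gauge constant subtracted before exponentiation
#' @return dimensionless acceleration factor
#' @export
acceleration_factor <- function(v, beta = 1, floor = 0) {
  mean(exp(beta * (v - floor)))
}

#' Run one OPES-flooding simulation
#'
#' Propagates under OPES with deposition suppressed inside
#' `excluded_region`, accumulates the running boost `exp(beta (V - floor))`
#' at every output frame, and stops when the stop predicate commits (ligand
#' escaped) or the step budget is exhausted (censored run).
#'
#' @param spec a [langevin_spec()]; `spec$n_steps` is the step budget
#' @param config an [opes_config()] whose `barrier` must lie below the true
#'   barrier and whose `excluded_region` must cover the transition state
#' @param stop a [cv_stop()] defining the escape
#' @param cv CV map as in [run_langevin()]
#' @return object of class `flooding_run`: list with `t_MD`, `acceleration`,
#'   `t_physical = acceleration * t_MD`, `exit_flag`, `bias_trace`, `series`,
#'   and the final `state`
#' @export
run_flooding <- function(spec, config, stop, cv = NULL) {
  stopifnot(inherits(config, "opes_config"), inherits(stop, "cv_stop"))
  if (is.null(config$excluded_region) && config$barrier > 0) {
    warning("flooding without an excluded region: bias may reach the ",
            "transition state and invalidate the rate")
  }
  res <- run_opes(spec, config, cv = cv, stop = stop)
  t_MD <- if (isTRUE(res$exited)) res$t_exit else spec$n_steps * spec$dt
  accel <- res$acceleration
  out <- list(t_MD = t_MD, acceleration = accel,
              t_physical = accel * t_MD,
              exit_flag = isTRUE(res$exited),
              bias_trace = res$series[["opes.bias"]],
              series = res$series, state = res$state)
  class(out) <- "flooding_run"
  out
}

#' @export
print.flooding_run <- function(x, ...) {
  cat("<flooding_run> ", if (x$exit_flag) "escaped" else "censored",
      "\n  t_MD = ", signif(x$t_MD, 5),
      ", acceleration = ", signif(x$acceleration, 5),
      ", t_physical = ", signif(x$t_physical, 5), "\n", sep = "")
  invisible(x)
}

#' Collect physical residence times from repeated flooding runs
#'
#' Convenience driver: `n_runs` independent flooding simulations with child
#' seeds derived from `seed`, returning completed physical times and
#' censored ones separately.
#'
#' @inheritParams run_flooding
#' @param n_runs number of independent runs
#' @param seed master seed
#' @return list with `times` (completed `t_physical`), `censored`, and the
#'   per-run `runs`
#' @export
residence_time_sample <- function(spec, config, stop, n_runs, seed,
                                  cv = NULL) {
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    sp <- spec
    sp$seed <- derive_seed(seed, i)
    runs[[i]] <- run_flooding(sp, config, stop, cv = cv)
  }
  exit <- vapply(runs, function(r) r$exit_flag, logical(1))
  list(times = vapply(runs[exit], function(r) r$t_physical, numeric(1)),
       censored = vapply(runs[!exit], function(r) r$t_physical, numeric(1)),
       runs = runs)
}

# two-sided Kolmogorov-Smirnov distance to Exp(tau)
.ks_stat_exp <- function(t, tau) {
  t <- sort(t)
  n <- length(t)
  Fx <- 1 - exp(-t / tau)
  max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
}

#' Fit an exponential residence-time model
#'
#' Maximum-likelihood fit of the homogeneous (Poisson) model
#' `p(t) = (1/tau) exp(-t/tau)`.  For uncensored data the MLE is the sample
#' mean; censored runs (no event before the budget) enter the likelihood as
#' survival terms: `tau = (sum(times) + sum(censored)) / n_events`.  The fit
#' quality is a Kolmogorov-Smirnov p-value; because tau is estimated from
#' the same sample, the default p-value is calibrated by a parametric
#' bootstrap (plain asymptotic KS is available for comparison).
#'
#' @param times completed physical residence times (`>= 5` events)
#' @param censored optional censored times (runs that never escaped);
#'   included in the MLE, excluded from the KS statistic
#' @param n_boot bootstrap resamples for the p-value calibration
#' @param seed seed for the bootstrap
#' @param method `"bootstrap"` (default) or `"plain"` (asymptotic KS)
#' @return object of class `rate_fit`: `tau`, `k_off = 1/tau`, `p_value`,
#'   `mu`, `sigma`, `n_events`
#' @export
fit_exponential <- function(times, censored = NULL, n_boot = 1000L,
                            seed = 1L, method = c("bootstrap", "plain")) {
  method <- match.arg(method)
  times <- as.numeric(times)
  if (length(times) < 5L) stop("need at least 5 completed events",
                               call. = FALSE)
  if (any(times <= 0) || any(!is.finite(times))) {
    stop("residence times must be positive and finite", call. = FALSE)
  }
  n <- length(times)
  tau <- (sum(times) + sum(censored)) / n
  D <- .ks_stat_exp(times, tau)
  if (method == "bootstrap") {
    p <- with_seed(derive_seed(seed, 7L), {
      exceed <- 0L
      for (b in seq_len(n_boot)) {
        tb <- rexp(n, rate = 1 / tau)
        Db <- .ks_stat_exp(tb, mean(tb))
        if (Db >= D) exceed <- exceed + 1L
      }
      (exceed + 1) / (n_boot + 1)
    })
  } else {
    p <- suppressWarnings(
      stats::ks.test(times, "pexp", rate = 1 / tau)$p.value)
  }
  structure(list(tau = tau, k_off = 1 / tau, p_value = p,
                 mu = mean(times), sigma = sd(times), n_events = n,
                 n_censored = length(censored), method = method),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> exponential residence-time model\n")
  cat(sprintf("  tau = %.4g, k_off = %.4g, p-value = %.3g (%s)\n",
              x$tau, x$k_off, x$p_value, x$method))
  cat(sprintf("  mu = %.4g, sigma = %.4g, n = %d events", x$mu, x$sigma,
              x$n_events))
  if (x$n_censored > 0) cat(sprintf(" (+%d censored)", x$n_censored))
  cat("\n")
  invisible(x)
}

#' Fit two mechanism populations separately
#'
#' Splits completed events into two user-labelled groups (e.g. a faster and
#' a slower unbinding mechanism) and fits each with [fit_exponential()],
#' reporting the ratio of characteristic times.
#'
#' @param times completed physical residence times
#' @param labels a factor/vector with exactly two levels partitioning
#'   `times`; both groups must be non-empty
#' @param ... passed to [fit_exponential()]
#' @return list with the two `rate_fit`s (named by label), `tau_ratio`
#'   (larger tau / smaller tau)
#' @export
split_and_fit <- function(times, labels, ...) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) == 0L)) {
    stop("'labels' must partition the events into two non-empty groups",
         call. = FALSE)
  }
  fits <- lapply(levels(labels), function(l) {
    fit_exponential(times[labels == l], ...)
  })
  names(fits) <- levels(labels)
  taus <- vapply(fits, function(f) f$tau, numeric(1))
  list(fits = fits, tau = taus, tau_ratio = max(taus) / min(taus))
}

#' Summarise rate fits as a residence-time table
#'
#' One row per fit with columns `tau`, `k_off`, `p_value`, `mu`, `sigma`,
#' `n` -- the layout of a ligand residence-time summary table.
#'
#' @param fits a `rate_fit` or list of them (named)
#' @return data.frame
#' @export
rate_table <- function(fits) {
  if (inherits(fits, "rate_fit")) fits <- list(all = fits)
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(label = nm, tau = f$tau, k_off = f$k_off,
               p_value = f$p_value, mu = f$mu, sigma = f$sigma,
               n = f$n_events)
  }))
}
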
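# Shared fixtures.  Expensive simulation products are computed once per
# test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

dw1 <- function(h) make_potential("double_well_1d", c(h = h))

# moderate converged OPES run on the h = 5 double well, reused by several
# opes/fes tests
opes_run_h5 <- function() {
  fixture("opes_run_h5", {
    spec <- langevin_spec(dw1(5), n_steps = 4e6, seed = 71, friction = 100)
    run_opes(spec, opes_config(barrier = 6, gamma = 10))
  })
}

# exact mean first-passage time for overdamped 1D dynamics in potential U,
# from x0 to absorbing level b (natural reflecting boundary far left):
#   T = (1/D) int_x0^b dy e^{U(y)/kT} int_lo^y e^{-U(z)/kT} dz
mfpt_quadrature <- function(U, x0, b, kT = 1, friction = 1, lo = -4,
                            n = 4001L) {
  D <- kT / friction
  z <- seq(lo, b, length.out = n)
  dz <- z[2] - z[1]
  f <- exp(-U(z) / kT)
  inner <- (cumsum(f) - f / 2 - f[1] / 2) * dz   # trapezoid cumulative
  g <- exp(U(z) / kT) * inner
  sel <- z >= x0
  zz <- z[sel]; gg <- g[sel]
  sum((gg[-1] + gg[-length(gg)]) / 2 * diff(zz)) / D
}

count_transitions <- function(s, core = 0.5) {
  r <- rle(sign(s[abs(s) > core]))
  sum(diff(r$values) != 0)
}
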
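# shared fixtures and independent oracles

# canonical formulation used across tests (spec-worked values)
ref_params <- function() asls_params(E0 = 1000, E1 = 1000, eta1 = 10000)

# realistic gel formulation (adipose-range equilibrium modulus)
gel_params <- function(phi = 0) {
  asls_params(E0 = 3000, E1 = 2000, eta1 = 4e4, eta2 = 5e5, phi = phi)
}

ref_transport <- function(...) {
  transport_params(r_h = 1e-9, kappa = 1e-16, mu = 1e-3, T = 298.15, ...)
}

# independent classical-SLS oracle: integrate the Zener constitutive ODE
#   sigma_dot = (E0*eps + eta*(1 + E0/E1)*eps_dot - sigma) * E1/eta
# under eps = edot*t with fixed-step RK4; shares no code with asls_stress()
sls_stress_ode <- function(t_out, edot, E0, E1, eta, n_sub = 2000L) {
  f <- function(t, s) (E0 * edot * t + eta * (1 + E0 / E1) * edot - s) * E1 / eta
  t_end <- max(t_out)
  h <- t_end / n_sub
  tt <- seq(0, t_end, by = h)
  s <- numeric(length(tt))
  for (i in seq_along(tt)[-1]) {
    t0 <- tt[i - 1]; s0 <- s[i - 1]
    k1 <- f(t0, s0)
    k2 <- f(t0 + h / 2, s0 + h / 2 * k1)
    k3 <- f(t0 + h / 2, s0 + h / 2 * k2)
    k4 <- f(t0 + h, s0 + h * k3)
    s[i] <- s0 + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  stats::approx(tt, s, xout = t_out)$y
}

# brute-force through-origin regression: scan a dense slope grid, pick the
# SSE minimiser (oracle for apparent_modulus)
brute_force_slope <- function(eps, sig, lo, hi, n = 200001L) {
  slopes <- seq(lo, hi, length.out = n)
  sse <- vapply(slopes, function(b) sum((sig - b * eps)^2), numeric(1))
  slopes[which.min(sse)]
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# random valid aSLS parameter draws under a fixed seed
random_asls <- function(n, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    asls_params(E0 = stats::runif(1, 10, 1e4),
                E1 = stats::runif(1, 10, 1e4),
                eta1 = stats::runif(1, 100, 1e6),
                eta2 = stats::runif(1, 0, 1e6),
                phi = stats::runif(1, 0, 0.1))
  })
}
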
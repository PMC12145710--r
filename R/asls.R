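#' Lumped parameters of the adapted standard linear solid (aSLS)
#'
#' The aSLS is a standard linear solid (spring `E0` in parallel with a
#' Maxwell arm: spring `E1` in series with a dashpot) in which the Maxwell
#' dashpot carries a second viscosity `eta2` in parallel with `eta1`,
#' weighted by the volumetric fraction of dextran `phi` in the gel liquid
#' phase. The effective dashpot viscosity is `eta_eff = eta1 + phi * eta2`.
#'
#' @param E0 Equilibrium spring modulus \[Pa\], >= 0.
#' @param E1 Maxwell-arm spring modulus \[Pa\], >= 0.
#' @param eta1 Base dashpot viscosity \[Pa s\], >= 0.
#' @param eta2 Dextran-associated dashpot viscosity \[Pa s\], >= 0.
#' @param phi Dextran volumetric fraction, in \[0, 1\].
#' @return An object of class `asls_params`.
#' @examples
#' p <- asls_params(E0 = 1000, E1 = 1000, eta1 = 10000)
#' descriptors_from_params(p)
#' @export
asls_params <- function(E0, E1, eta1, eta2 = 0, phi = 0) {
  stopifnot(
    is.numeric(E0), length(E0) == 1L, is.finite(E0),
    is.numeric(E1), length(E1) == 1L, is.finite(E1),
    is.numeric(eta1), length(eta1) == 1L, is.finite(eta1),
    is.numeric(eta2), length(eta2) == 1L, is.finite(eta2),
    is.numeric(phi), length(phi) == 1L, is.finite(phi)
  )
  if (E0 < 0 || E1 < 0 || eta1 < 0 || eta2 < 0)
    stop("asls_params: E0, E1, eta1, eta2 must all be >= 0", call. = FALSE)
  if (phi < 0 || phi > 1)
    stop("asls_params: phi must lie in [0, 1]", call. = FALSE)
  eta_eff <- eta1 + phi * eta2
  if (E1 > 0 && eta_eff <= 0)
    stop("asls_params: effective viscosity eta1 + phi*eta2 must be > 0 when E1 > 0 (degenerate Maxwell arm)",
         call. = FALSE)
  structure(
    list(E0 = E0, E1 = E1, eta1 = eta1, eta2 = eta2, phi = phi),
    class = "asls_params"
  )
}

#' Effective dashpot viscosity eta1 + phi * eta2
#' @param params An [asls_params()] object.
#' @return Effective viscosity \[Pa s\].
#' @export
eta_eff <- function(params) {
  stopifnot(inherits(params, "asls_params"))
  params$eta1 + params$phi * params$eta2
}

#' @export
print.asls_params <- function(x, ...) {
  cat("aSLS lumped parameters\n")
  cat(sprintf("  E0   = %g Pa\n  E1   = %g Pa\n", x$E0, x$E1))
  cat(sprintf("  eta1 = %g Pa.s\n  eta2 = %g Pa.s\n  phi  = %g\n",
              x$eta1, x$eta2, x$phi))
  cat(sprintf("  eta_eff = %g Pa.s\n", eta_eff(x)))
  invisible(x)
}

#' Constant-strain-rate loading protocol
#'
#' Describes one epsilon-dot compression test: a strain ramp
#' `eps(t) = strain_rate * t` sampled on a uniform time grid.
#'
#' @param strain_rate Strain rate \[1/s\], >= 0 (0 means no loading, used by
#'   the decoupled limit of [coupled_virtual_test()]).
#' @param t_end Test duration \[s\], > 0.
#' @param n_samples Number of output samples, >= 2.
#' @param strain_limit Cap of the small-strain linear region used for the
#'   apparent modulus, default 0.05 (5 % strain).
#' @return An object of class `loading_protocol`.
#' @export
loading_protocol <- function(strain_rate, t_end, n_samples = 100L,
                             strain_limit = 0.05) {
  stopifnot(is.numeric(strain_rate), length(strain_rate) == 1L,
            is.numeric(t_end), length(t_end) == 1L,
            is.numeric(n_samples), length(n_samples) == 1L,
            is.numeric(strain_limit), length(strain_limit) == 1L)
  if (strain_rate < 0) stop("loading_protocol: strain_rate must be >= 0", call. = FALSE)
  if (t_end <= 0) stop("loading_protocol: t_end must be > 0", call. = FALSE)
  if (n_samples < 2) stop("loading_protocol: n_samples must be >= 2", call. = FALSE)
  if (strain_rate > 0 &&
      (strain_limit <= 0 || strain_limit > strain_rate * t_end))
    stop("loading_protocol: strain_limit must lie in (0, strain_rate * t_end]",
         call. = FALSE)
  structure(
    list(strain_rate = strain_rate, t_end = t_end,
         n_samples = as.integer(n_samples), strain_limit = strain_limit),
    class = "loading_protocol"
  )
}

#' Sampled mechanical test curve
#'
#' Container for one constant-strain-rate test: sampled `(time, strain,
#' stress)` triplets plus the nominal strain rate. Strains are unsigned
#' magnitudes (the compression sign convention is abstracted away).
#'
#' @param time Sample times \[s\], strictly increasing, first value 0.
#' @param strain Strain \[-\], same length as `time`, `strain[1] = 0`.
#' @param stress Stress \[Pa\], same length, `stress[1] = 0` within tolerance
#'   (relative to the stress scale; noisy data are admitted).
#' @param strain_rate Nominal strain rate \[1/s\].
#' @return A `data.frame` of class `mechanical_curve` with columns
#'   `time`, `strain`, `stress` and attribute `strain_rate`.
#' @export
mechanical_curve <- function(time, strain, stress, strain_rate) {
  stopifnot(is.numeric(time), is.numeric(strain), is.numeric(stress),
            is.numeric(strain_rate), length(strain_rate) == 1L)
  n <- length(time)
  if (n < 2L || length(strain) != n || length(stress) != n)
    stop("mechanical_curve: time, strain, stress must have equal length >= 2",
         call. = FALSE)
  if (any(diff(time) <= 0))
    stop("mechanical_curve: time must be strictly increasing", call. = FALSE)
  if (abs(time[1]) > 1e-12)
    stop("mechanical_curve: time must start at 0", call. = FALSE)
  if (abs(strain[1]) > 1e-12)
    stop("mechanical_curve: strain(0) must be 0", call. = FALSE)
  scale <- max(abs(stress), 1e-300)
  if (abs(stress[1]) > 0.05 * scale)
    stop("mechanical_curve: stress(0) must be 0 within tolerance", call. = FALSE)
  out <- data.frame(time = time, strain = strain, stress = stress)
  attr(out, "strain_rate") <- strain_rate
  class(out) <- c("mechanical_curve", "data.frame")
  out
}

#' Time-dependent elastic modulus of the aSLS under epsilon-dot loading
#'
#' Evaluates the transfer function of the aSLS model for a constant strain
#' rate input,
#' \deqn{E(t) = E_0 + \frac{\eta_{eff}}{t}\left(1 - e^{-E_1 t/\eta_{eff}}\right),
#'       \qquad \eta_{eff} = \eta_1 + \varphi\,\eta_2,}
#' i.e. the ratio `sigma(t) / (strain_rate * t)` of the stress response to
#' the ramp strain. The removable singularity at `t = 0` is resolved by its
#' analytic limit `E0 + E1`. `E(t)` decreases monotonically from the
#' instantaneous modulus `E0 + E1` to the equilibrium modulus `E0`.
#'
#' @param t Time(s) \[s\], >= 0 (vectorised).
#' @param params An [asls_params()] object.
#' @return Modulus E(t) \[Pa\], same length as `t`, within `[E0, E0 + E1]`.
#' @examples
#' p <- asls_params(1000, 1000, 10000)
#' asls_modulus(c(0, 10, 1e5), p)  # 2000, ~1632.12, ~1000
#' @export
asls_modulus <- function(t, params) {
  stopifnot(inherits(params, "asls_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("asls_modulus: t must be finite and >= 0", call. = FALSE)
  eta <- eta_eff(params)
  E0 <- params$E0
  E1 <- params$E1
  if (E1 == 0) return(rep(E0, length(t)))
  if (eta <= 0)
    stop("asls_modulus: degenerate model, eta_eff = 0 with E1 > 0", call. = FALSE)
  out <- numeric(length(t))
  zero <- t == 0
  out[zero] <- E0 + E1
  tt <- t[!zero]
  # -expm1(-x) is accurate for small x; the ratio tends to E1 as t -> 0
  out[!zero] <- E0 + (eta / tt) * (-expm1(-E1 * tt / eta))
  # guard round-off at the band edges
  pmin(pmax(out, E0), E0 + E1)
}

#' Stress response of the aSLS to a constant strain rate
#'
#' Closed-form stress under the ramp `eps(t) = strain_rate * t`:
#' \deqn{\sigma(t) = \dot\varepsilon\left[E_0 t +
#'   \eta_{eff}\left(1 - e^{-E_1 t/\eta_{eff}}\right)\right].}
#' Satisfies `sigma(t) = strain_rate * t * E(t)` with [asls_modulus()].
#'
#' @param protocol A [loading_protocol()] (strain_rate must be > 0).
#' @param params An [asls_params()] object.
#' @return A [mechanical_curve()] sampled on a uniform grid of
#'   `protocol$n_samples` points over `[0, t_end]`.
#' @export
stress_response <- function(protocol, params) {
  stopifnot(inherits(protocol, "loading_protocol"),
            inherits(params, "asls_params"))
  if (protocol$strain_rate <= 0)
    stop("stress_response: strain_rate must be > 0", call. = FALSE)
  tt <- seq(0, protocol$t_end, length.out = protocol$n_samples)
  sigma <- asls_stress(tt, protocol$strain_rate, params$E0, params$E1,
                       eta_eff(params))
  mechanical_curve(time = tt, strain = protocol$strain_rate * tt,
                   stress = sigma, strain_rate = protocol$strain_rate)
}

# closed-form sigma(t); internal workhorse shared with the fitting module.
# E1 = 0 or eta = 0 both collapse the Maxwell arm: sigma = edot * E0 * t.
asls_stress <- function(t, edot, E0, E1, eta) {
  if (E1 <= 0 || eta <= 0) return(edot * E0 * t)
  edot * (E0 * t + eta * (-expm1(-E1 * t / eta)))
}

#' Viscoelastic descriptors of one formulation
#'
#' Maps the aSLS lumped parameters to the descriptors experiments report:
#' equilibrium modulus `E_eq = E0`, instantaneous modulus `E_inst = E0 + E1`
#' and characteristic relaxation time `tau_rel = (eta1 + phi*eta2) / E1`.
#'
#' @param params An [asls_params()] with `E1 > 0`.
#' @param E_app Optional apparent modulus \[Pa\] from [apparent_modulus()].
#' @return An object of class `viscoelastic_descriptors` with fields
#'   `E_eq`, `E_inst`, `tau_rel`, `E_app`.
#' @export
descriptors_from_params <- function(params, E_app = NA_real_) {
  stopifnot(inherits(params, "asls_params"))
  if (params$E1 <= 0)
    stop("descriptors_from_params: relaxation time undefined for E1 = 0",
         call. = FALSE)
  viscoelastic_descriptors(
    E_eq = params$E0,
    E_inst = params$E0 + params$E1,
    tau_rel = eta_eff(params) / params$E1,
    E_app = E_app
  )
}

#' @rdname descriptors_from_params
#' @param E_eq,E_inst,tau_rel Descriptor values (Pa, Pa, s).
#' @export
viscoelastic_descriptors <- function(E_eq, E_inst, tau_rel, E_app = NA_real_) {
  stopifnot(is.numeric(E_eq), is.numeric(E_inst), is.numeric(tau_rel))
  if (E_eq < 0 || E_inst < E_eq)
    stop("viscoelastic_descriptors: need E_inst >= E_eq >= 0", call. = FALSE)
  if (!is.na(tau_rel) && tau_rel <= 0)
    stop("viscoelastic_descriptors: tau_rel must be > 0", call. = FALSE)
  structure(list(E_eq = E_eq, E_inst = E_inst, tau_rel = tau_rel,
                 E_app = E_app),
            class = "viscoelastic_descriptors")
}

#' @export
print.viscoelastic_descriptors <- function(x, ...) {
  cat("Viscoelastic descriptors\n")
  cat(sprintf("  E_eq    = %g Pa\n  E_inst  = %g Pa\n  tau_rel = %g s\n",
              x$E_eq, x$E_inst, x$tau_rel))
  if (!is.na(x$E_app)) cat(sprintf("  E_app   = %g Pa\n", x$E_app))
  invisible(x)
}

#' Apparent elastic modulus from a stress-strain curve
#'
#' Least-squares slope of stress versus strain restricted to the linear
#' viscoelastic region `strain <= strain_limit` (default 5 % strain). The
#' fit is constrained through the origin because `sigma(0) = eps(0) = 0` by
#' construction; set `intercept = TRUE` for real noisy data with an offset.
#'
#' @param curve A [mechanical_curve()].
#' @param strain_limit Upper strain bound of the regression window.
#' @param intercept If `TRUE`, fit an unconstrained line and return its slope.
#' @return Apparent modulus E_app \[Pa\].
#' @export
apparent_modulus <- function(curve, strain_limit = 0.05, intercept = FALSE) {
  stopifnot(inherits(curve, "mechanical_curve"),
            is.numeric(strain_limit), strain_limit > 0)
  keep <- curve$strain <= strain_limit
  eps <- curve$strain[keep]
  sig <- curve$stress[keep]
  if (sum(eps > 0) < (if (intercept) 2L else 1L) || length(eps) < 2L)
    stop("apparent_modulus: fewer than 2 samples within the strain limit",
         call. = FALSE)
  if (intercept) {
    unname(stats::coef(stats::lm(sig ~ eps))[["eps"]])
  } else {
    sum(sig * eps) / sum(eps * eps)
  }
}
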
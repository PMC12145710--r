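#' Boltzmann constant \[J/K\]
#' @keywords internal
.kB <- 1.380649e-23

#' Transport and structural parameters of a dextran-permeated gel
#'
#' Everything the hindered-diffusion law, the mesh-size law and the
#' reaction-diffusion model need: solute hydrodynamic radius, hydraulic
#' permeability, liquid-phase viscosity, temperature, porosity, degree of
#' gelation, zero-order dextran-water binding rate and the nominal dextran
#' concentration.
#'
#' @param r_h Solute hydrodynamic radius \[m\], > 0.
#' @param kappa Hydraulic permeability \[m^2\], > 0.
#' @param mu Liquid-phase viscosity \[Pa s\], > 0.
#' @param T Absolute temperature \[K\], > 0. Default 298.15 K (room
#'   temperature, matching mechanical testing); use 310.15 K for culture.
#' @param p Gel porosity, in (0, 1\].
#' @param alpha Degree of agarose gelation, in (0, 1\]; default 0.65.
#' @param k_r Dextran-water binding rate \[1/s\], >= 0 (zero-order sink
#'   `R_dex = k_r * c0`).
#' @param c0 Nominal dextran concentration \[mg/mL\], >= 0.
#' @return An object of class `transport_params`.
#' @examples
#' tp <- transport_params(r_h = 1e-9, kappa = 1e-16, mu = 1e-3)
#' xi <- mesh_size(5000, tp)
#' apparent_diffusion(xi, tp)
#' @export
transport_params <- function(r_h, kappa, mu, T = 298.15, p = 0.9,
                             alpha = 0.65, k_r = 0, c0 = 0) {
  vals <- c(r_h = r_h, kappa = kappa, mu = mu, T = T)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("transport_params: r_h, kappa, mu, T must be finite and > 0",
         call. = FALSE)
  if (p <= 0 || p > 1 || alpha <= 0 || alpha > 1)
    stop("transport_params: p and alpha must lie in (0, 1]", call. = FALSE)
  if (k_r < 0 || c0 < 0)
    stop("transport_params: k_r and c0 must be >= 0", call. = FALSE)
  structure(list(r_h = r_h, kappa = kappa, mu = mu, T = T, p = p,
                 alpha = alpha, k_r = k_r, c0 = c0, k_B = .kB),
            class = "transport_params")
}

#' Average mesh size of the agarose network from the current modulus
#'
#' Rubber-elasticity estimate of the distance between adjacent crosslinks,
#' \deqn{\xi_{avg} = \left(\frac{18\,k_B T}{\pi\,\alpha^{2/3}\,E(t)}\right)^{1/3},}
#' where `alpha` is the degree of gelation and `E(t)` the current
#' time-dependent modulus. Because the gel relaxes under load, `E(t)`
#' decreases and the mesh opens during an epsilon-dot test.
#'
#' @param E_t Current elastic modulus \[Pa\], > 0 (vectorised).
#' @param params A [transport_params()] object (uses `T`, `alpha`).
#' @return Mesh size \[m\], same length as `E_t`.
#' @export
mesh_size <- function(E_t, params) {
  stopifnot(inherits(params, "transport_params"), is.numeric(E_t))
  if (any(!is.finite(E_t)) || any(E_t <= 0))
    stop("mesh_size: E_t must be finite and > 0", call. = FALSE)
  (18 * .kB * params$T / (pi * params$alpha^(2 / 3) * E_t))^(1 / 3)
}

#' Apparent diffusion coefficient of dextran in the gel
#'
#' Stokes-Einstein free diffusion attenuated by mesh obstruction and by the
#' Brinkmann drag of the porous network:
#' \deqn{D_{app} = \frac{k_B T}{6\pi\mu r_h}\;
#'   \frac{e^{-r_h/(2\xi_{avg})}}{1 + r_h/\sqrt{\kappa} + r_h^2/(3\kappa)}.}
#' The hindrance factor (exponential times the reciprocal Brinkmann
#' bracket) lies in (0, 1], so `D_app` never exceeds the free diffusivity
#' `D0 = k_B T / (6 pi mu r_h)`.
#'
#' @param xi Mesh size \[m\], > 0 (vectorised).
#' @param params A [transport_params()] object.
#' @return Apparent diffusion coefficient \[m^2/s\].
#' @export
apparent_diffusion <- function(xi, params) {
  stopifnot(inherits(params, "transport_params"), is.numeric(xi))
  if (any(!is.finite(xi)) || any(xi <= 0))
    stop("apparent_diffusion: xi must be finite and > 0", call. = FALSE)
  D0 <- stokes_einstein(params)
  D0 * hindrance_factor(xi, params)
}

#' @rdname apparent_diffusion
#' @export
stokes_einstein <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  .kB * params$T / (6 * pi * params$mu * params$r_h)
}

# obstruction x Brinkmann correction, isolated so the grouping of the
# (typographically ambiguous) exponent can be swapped in one place
hindrance_factor <- function(xi, params) {
  r <- params$r_h
  k <- params$kappa
  exp(-r / (2 * xi)) / (1 + r / sqrt(k) + r^2 / (3 * k))
}

#' Characteristic diffusion time over a length scale
#'
#' `tau_diff = L^2 / D_app`: the time for the solute to explore a region of
#' size `L`. Used to compare liquid-phase transport timescales across
#' formulations.
#'
#' @param L Characteristic length \[m\], > 0.
#' @param D_app Apparent diffusion coefficient \[m^2/s\], > 0.
#' @return Diffusion time \[s\].
#' @export
diffusion_time <- function(L, D_app) {
  if (any(!is.finite(L)) || any(L <= 0))
    stop("diffusion_time: L must be finite and > 0", call. = FALSE)
  if (any(D_app <= 0))
    stop("diffusion_time: D_app must be > 0", call. = FALSE)
  L^2 / D_app
}

#' Carman-Kozeny estimate of hydraulic permeability (approximation)
#'
#' Optional helper `kappa = r_f^2 p^3 / (C (1 - p)^2)` relating permeability
#' to fibre radius `r_f` and porosity `p`. This is an order-of-magnitude
#' approximation for fibrous networks; measured permeabilities should be
#' preferred when available.
#'
#' @param r_f Fibre radius \[m\], > 0.
#' @param p Porosity, in (0, 1).
#' @param C Kozeny constant, default 20 (fibrous media).
#' @return Permeability \[m^2\].
#' @export
carman_kozeny_permeability <- function(r_f, p, C = 20) {
  if (r_f <= 0 || p <= 0 || p >= 1 || C <= 0)
    stop("carman_kozeny_permeability: need r_f > 0, p in (0,1), C > 0",
         call. = FALSE)
  r_f^2 * p^3 / (C * (1 - p)^2)
}
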
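#' Noise model for synthetic measurements
#'
#' @param kind `"multiplicative-gaussian"` (default; mechanical-test noise
#'   scales with the signal) or `"additive-gaussian"`.
#' @param level Relative (multiplicative) or absolute (additive) noise scale,
#'   >= 0. Default 0.01 (1 %).
#' @param seed RNG seed; every generator is a pure function of its arguments
#'   and this seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative-gaussian", "additive-gaussian"),
                        level = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  if (level < 0) stop("noise_model: level must be >= 0", call. = FALSE)
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate noisy constant-strain-rate stress curves from known parameters
#'
#' Forward model for parameter-recovery tests: evaluates the exact aSLS
#' stress response for each protocol and adds seeded noise to the stress
#' column only. The generating truth is recorded in the `true_params`
#' attribute of each curve.
#'
#' @param params An [asls_params()] object (the generating truth).
#' @param protocols A [loading_protocol()] or list of them.
#' @param noise A [noise_model()].
#' @param n_replicates Replicate curves per protocol.
#' @return A list of [mechanical_curve()] objects with attributes
#'   `true_params`, `protocol`, `replicate`.
#' @examples
#' p <- asls_params(3000, 2000, 40000)
#' curves <- generate_epsdot_curves(p, loading_protocol(0.01, 60),
#'                                  noise_model(level = 0.01, seed = 3), 2)
#' length(curves)
#' @export
generate_epsdot_curves <- function(params, protocols, noise = noise_model(),
                                   n_replicates = 1L) {
  stopifnot(inherits(params, "asls_params"), inherits(noise, "noise_model"),
            n_replicates >= 1L)
  if (inherits(protocols, "loading_protocol")) protocols <- list(protocols)
  stopifnot(all(vapply(protocols, inherits, logical(1), "loading_protocol")))
  set.seed(noise$seed)
  out <- list()
  for (pi in seq_along(protocols)) {
    base <- stress_response(protocols[[pi]], params)
    for (r in seq_len(n_replicates)) {
      sigma <- base$stress
      if (noise$level > 0) {
        z <- stats::rnorm(length(sigma))
        sigma <- switch(noise$kind,
          "multiplicative-gaussian" = sigma * (1 + noise$level * z),
          "additive-gaussian" = sigma + noise$level * z)
        sigma[1] <- 0   # the unloaded start is measured exactly
      }
      cv <- mechanical_curve(base$time, base$strain, sigma,
                             attr(base, "strain_rate"))
      attr(cv, "true_params") <- params
      attr(cv, "protocol") <- protocols[[pi]]
      attr(cv, "replicate") <- r
      out[[length(out) + 1L]] <- cv
    }
  }
  out
}

#' Generate a synthetic segmented-cell measurement table
#'
#' Emulates region measurements exported from image segmentation: per cell, a
#' cytosolic area `A`, perimeter `P`, nuclear area `A_N` and mean gray
#' intensities `GI_nuc`, `GI_cyt`. Cells are drawn from two morphotypes:
#' "round" (cell shape index near 1, small area — stem-like) and "spread"
#' (low shape index, large area — differentiating), mixed per
#' `shape_mix`. Nuclear/cytosolic intensities are drawn so that the
#' total-signal YAP ratio matches the per-morphotype targets on average.
#'
#' @param n_cells Number of cells, >= 0.
#' @param shape_mix List with `round_fraction` and `spread_fraction` summing
#'   to 1.
#' @param intensity_params List with `yap_nc_round`, `yap_nc_spread` (target
#'   mean YAP N/C ratios), `gi_cyt_mean`, `gi_cyt_sd`.
#' @param seed RNG seed.
#' @param condition Condition label for all rows.
#' @return A data.frame with columns `condition, A, P, A_N, GI_nuc, GI_cyt`
#'   and attribute `morphotype` recording each cell's generator class.
#' @export
generate_cell_table <- function(n_cells,
                                shape_mix = list(round_fraction = 0.5,
                                                 spread_fraction = 0.5),
                                intensity_params = list(yap_nc_round = 0.05,
                                                        yap_nc_spread = 1.0,
                                                        gi_cyt_mean = 100,
                                                        gi_cyt_sd = 10),
                                seed = 1L, condition = "synthetic") {
  fr <- shape_mix$round_fraction
  fs <- shape_mix$spread_fraction
  if (is.null(fr) || is.null(fs) || fr < 0 || fs < 0 ||
      abs(fr + fs - 1) > 1e-9)
    stop("generate_cell_table: shape fractions must be >= 0 and sum to 1",
         call. = FALSE)
  cols <- c("condition", "A", "P", "A_N", "GI_nuc", "GI_cyt")
  if (n_cells == 0L) {
    out <- data.frame(condition = character(0), A = numeric(0), P = numeric(0),
                      A_N = numeric(0), GI_nuc = numeric(0),
                      GI_cyt = numeric(0))
    return(out)
  }
  set.seed(seed)
  round_cell <- stats::runif(n_cells) < fr
  # areas in um^2: round stem-like cells ~ 800, spread cells ~ 3000
  A <- ifelse(round_cell,
              stats::rlnorm(n_cells, log(800), 0.25),
              stats::rlnorm(n_cells, log(3000), 0.25))
  csi <- ifelse(round_cell,
                stats::runif(n_cells, 0.82, 0.98),
                stats::runif(n_cells, 0.2, 0.6))
  P <- sqrt(4 * pi * A / csi)            # invert CSI = 4*pi*A/P^2
  A_N <- pmin(A * stats::runif(n_cells, 0.10, 0.30), A)
  GI_cyt <- pmax(stats::rnorm(n_cells, intensity_params$gi_cyt_mean,
                              intensity_params$gi_cyt_sd), 1)
  target <- ifelse(round_cell, intensity_params$yap_nc_round,
                   intensity_params$yap_nc_spread) *
    stats::rlnorm(n_cells, 0, 0.1)
  # total-signal reading: ratio = GI_nuc * A_N / (GI_cyt * A)
  GI_nuc <- target * GI_cyt * A / A_N
  out <- data.frame(condition = condition, A = A, P = P, A_N = A_N,
                    GI_nuc = GI_nuc, GI_cyt = GI_cyt)
  attr(out, "morphotype") <- ifelse(round_cell, "round", "spread")
  stopifnot(identical(names(out), cols))
  out
}

#' Generate an analytic initial concentration field
#'
#' Initial conditions for the reaction-diffusion model: a uniform field, a
#' single cosine eigenmode of the no-flux box along x (`c0 + amplitude *
#' cos(pi x / Lx)`, the analytic decay oracle), or a centred Gaussian blob
#' (`c0 + amplitude * exp(-|r - r0|^2 / (2 s^2))`, `s = Lx/8`).
#'
#' @param grid A [grid_spec()].
#' @param profile `"uniform"`, `"cosine-mode"` or `"gaussian-blob"`.
#' @param c0 Baseline concentration \[mg/mL\].
#' @param amplitude Mode/blob amplitude \[mg/mL\]; must keep c >= 0.
#' @param sigma Blob standard deviation \[m\]; default `extents[1]/8`.
#' @return A [concentration_field()].
#' @export
generate_concentration_field <- function(grid,
                                         profile = c("uniform", "cosine-mode",
                                                     "gaussian-blob"),
                                         c0 = 1, amplitude = 0,
                                         sigma = NULL) {
  profile <- match.arg(profile)
  stopifnot(inherits(grid, "grid_spec"))
  n <- grid$n
  L <- grid$extents
  x <- seq(0, L[1], length.out = n[1])
  y <- seq(0, L[2], length.out = n[2])
  z <- seq(0, L[3], length.out = n[3])
  a <- switch(profile,
    "uniform" = array(c0, dim = n),
    "cosine-mode" = {
      c0 + amplitude * array(cos(pi * x / L[1]), dim = n)
    },
    "gaussian-blob" = {
      if (is.null(sigma)) sigma <- L[1] / 8
      g1 <- function(u, Lu) exp(-(u - Lu / 2)^2 / (2 * sigma^2))
      c0 + amplitude * outer(outer(g1(x, L[1]), g1(y, L[2])), g1(z, L[3]))
    })
  if (min(a) < 0)
    stop("generate_concentration_field: requested profile goes negative; ",
         "reduce |amplitude|", call. = FALSE)
  concentration_field(a, grid)
}
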
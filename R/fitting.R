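#' Configuration for aSLS curve fitting
#'
#' @param initial_guess Optional named list/vector with elements `E0`, `E1`,
#'   `eta_eff` seeding the optimiser; when `NULL`, moment-style estimators
#'   derived from the data are used (final slope for `E0`, initial minus
#'   final slope for `E1`, `E1` times the 63 % rise time for `eta_eff`).
#' @param lower,upper Per-parameter bounds, named as above; lower bounds must
#'   be >= 0 (the model is physical).
#' @param tol Convergence tolerance passed to the optimiser (factr-style
#'   relative tolerance).
#' @param max_iter Iteration cap per start.
#' @param n_starts Number of multi-start restarts from jittered seeds.
#' @param seed RNG seed making the multi-start deterministic.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(initial_guess = NULL, lower = c(E0 = 0, E1 = 0, eta_eff = 0),
                       upper = c(E0 = Inf, E1 = Inf, eta_eff = Inf),
                       tol = 1e-10, max_iter = 500L, n_starts = 8L, seed = 1L) {
  if (any(lower < 0)) stop("fit_config: lower bounds must be >= 0", call. = FALSE)
  if (tol <= 0) stop("fit_config: tol must be > 0", call. = FALSE)
  structure(list(initial_guess = initial_guess, lower = lower, upper = upper,
                 tol = tol, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "fit_config")
}

# moment-style starting values: E0 from the final chord slope of sigma vs
# (edot t), E1 from the initial slope excess, eta_eff from the 63 % rise
# time of the transient
initial_guess_moments <- function(time, stress, edot) {
  x <- edot * time
  n <- length(time)
  tail_idx <- which(x >= 0.8 * max(x))
  if (length(tail_idx) < 2L) tail_idx <- (n - 1L):n
  E0 <- max(stats::coef(stats::lm(stress[tail_idx] ~ x[tail_idx]))[[2]], 0)
  head_idx <- which(x <= 0.1 * max(x) & x > 0)
  if (length(head_idx) < 2L) head_idx <- 2:min(4L, n)
  slope0 <- sum(stress[head_idx] * x[head_idx]) / sum(x[head_idx]^2)
  E1 <- max(slope0 - E0, 1e-6 * max(slope0, 1))
  transient <- stress - edot * E0 * time
  plateau <- stats::median(transient[tail_idx])
  tau <- if (plateau > 0) {
    i63 <- which(transient >= 0.63 * plateau)[1]
    if (is.na(i63)) max(time) / 3 else max(time[i63], diff(range(time)) / n)
  } else max(time) / 3
  c(E0 = E0, E1 = E1, eta_eff = E1 * tau)
}

# residual sum of squares of the joint fit; rows carry their curve's edot
fit_rss <- function(theta, time, stress, edot) {
  pred <- asls_stress(time, edot, theta[1], theta[2], theta[3])
  sum((stress - pred)^2)
}

#' Fit the aSLS model to curves from one formulation
#'
#' Jointly fits \eqn{\sigma(t) = \dot\varepsilon[E_0 t + \eta_{eff}(1 -
#' e^{-E_1 t/\eta_{eff}})]} to one or more constant-strain-rate curves
#' sharing a formulation, by bounded non-linear least squares (multi-start
#' L-BFGS-B, best residual sum of squares wins, ties broken by lower `E1`).
#' Only the lumped effective viscosity `eta_eff = eta1 + phi * eta2` is
#' identifiable from a single formulation; the `eta1`/`eta2` split requires
#' [fit_across_formulations()].
#'
#' @param curves A [mechanical_curve()] or list of them (different strain
#'   rates allowed).
#' @param phi Dextran volumetric fraction of the formulation (recorded in
#'   the result; does not affect the lumped fit).
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `params` (an [asls_params()]
#'   with `eta1` holding the lumped `eta_eff` and `eta2 = 0`), `eta_eff`,
#'   `descriptors`, `rss`, `r2`, `per_curve_residuals`,
#'   `eta_unidentifiable` (TRUE when the data are consistent with a pure
#'   spring so `eta_eff`/`tau_rel` are meaningless), `convergence`.
#' @examples
#' p <- asls_params(1000, 1000, 10000)
#' curve <- stress_response(loading_protocol(0.01, 60, 80), p)
#' fit <- fit_single_formulation(curve, phi = 0, fit_config(seed = 7))
#' fit$params
#' @export
fit_single_formulation <- function(curves, phi = 0, config = fit_config()) {
  if (inherits(curves, "mechanical_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "mechanical_curve")),
            inherits(config, "fit_config"))
  time <- unlist(lapply(curves, `[[`, "time"))
  stress <- unlist(lapply(curves, `[[`, "stress"))
  edot <- unlist(lapply(curves, function(cv)
    rep(attr(cv, "strain_rate"), nrow(cv))))
  if (length(unique(time)) < 3L)
    stop("fit_single_formulation: need at least 3 distinct time points",
         call. = FALSE)

  guess <- if (is.null(config$initial_guess)) {
    initial_guess_moments(time, stress, edot)
  } else {
    g <- unlist(config$initial_guess)[c("E0", "E1", "eta_eff")]
    if (any(is.na(g))) stop("fit_single_formulation: initial_guess needs E0, E1, eta_eff",
                            call. = FALSE)
    g
  }
  lower <- config$lower[c("E0", "E1", "eta_eff")]
  upper <- config$upper[c("E0", "E1", "eta_eff")]
  # strictly positive floor for the optimiser: the eta_eff -> 0 boundary is
  # handled analytically by asls_stress but makes gradients degenerate
  lo <- pmax(lower, c(0, 0, 0)) + c(0, 0, 1e-12)

  set.seed(config$seed)
  jitters <- matrix(stats::rlnorm(3L * config$n_starts, 0, 0.5),
                    ncol = 3L)
  jitters[1, ] <- 1     # first start is the unjittered guess
  best <- NULL
  conv <- integer(0)
  for (s in seq_len(config$n_starts)) {
    start <- pmin(pmax(guess * jitters[s, ], lo), pmin(upper, guess * 1e6 + 1))
    o <- stats::optim(start, fit_rss, method = "L-BFGS-B",
                      lower = lo, upper = upper,
                      control = list(maxit = config$max_iter,
                                     factr = config$tol / .Machine$double.eps),
                      time = time, stress = stress, edot = edot)
    conv <- c(conv, o$convergence)
    better <- is.null(best) || o$value < best$value * (1 - 1e-12) ||
      (abs(o$value - best$value) <= 1e-12 * max(best$value, 1e-300) &&
         o$par[2] < best$par[2])
    if (better) best <- o
  }
  if (is.null(best) || !is.finite(best$value))
    stop("fit_single_formulation: optimiser failed to converge (all starts); ",
         "check data scaling and initial guesses", call. = FALSE)

  theta <- best$par
  names(theta) <- c("E0", "E1", "eta_eff")
  rss <- best$value
  tss <- sum((stress - mean(stress))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  # pure-spring degeneracy: if a plain spring (sigma = edot * E0 * t) fits
  # essentially as well as the full model, or the Maxwell arm's best-fit
  # contribution is negligible, eta_eff (and hence tau_rel) is unidentifiable
  x <- edot * time
  rss_spring <- {
    b <- sum(stress * x) / sum(x * x)
    sum((stress - b * x)^2)
  }
  arm_scale <- max(abs(asls_stress(time, edot, 0, theta[2], theta[3])))
  eta_unident <- arm_scale <= 1e-6 * max(abs(stress)) ||
    (rss_spring - rss) <= 1e-9 * max(tss, 1e-300)

  per_curve <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    res <- cv$stress - asls_stress(cv$time, attr(cv, "strain_rate"),
                                   theta[1], theta[2], theta[3])
    data.frame(curve = i, n = nrow(cv), rss = sum(res^2),
               rmse = sqrt(mean(res^2)))
  }))

  params <- asls_params(E0 = theta[["E0"]], E1 = theta[["E1"]],
                        eta1 = theta[["eta_eff"]], eta2 = 0, phi = phi)
  desc <- if (!eta_unident && theta[["E1"]] > 0) {
    descriptors_from_params(params)
  } else {
    viscoelastic_descriptors(E_eq = theta[["E0"]],
                             E_inst = theta[["E0"]] + theta[["E1"]],
                             tau_rel = NA_real_)
  }
  structure(list(params = params, phi = phi, eta_eff = theta[["eta_eff"]],
                 descriptors = desc, rss = rss, r2 = r2,
                 per_curve_residuals = per_curve,
                 eta_unidentifiable = eta_unident,
                 convergence = conv),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("aSLS fit (single formulation, lumped eta_eff)\n")
  cat(sprintf("  E0 = %g Pa, E1 = %g Pa, eta_eff = %g Pa.s (phi = %g)\n",
              x$params$E0, x$params$E1, x$eta_eff, x$phi))
  cat(sprintf("  rss = %g Pa^2, r2 = %.6f\n", x$rss, x$r2))
  if (x$eta_unidentifiable)
    cat("  note: pure-spring data; eta_eff and tau_rel unidentifiable\n")
  invisible(x)
}

#' Fit formulations jointly and split eta1 / eta2 across dextran fractions
#'
#' Fits each formulation with [fit_single_formulation()], then regresses the
#' recovered lumped viscosities on the dextran volumetric fraction,
#' `eta_eff = eta1 + phi * eta2`, to recover the shared dashpot viscosities.
#' Requires at least two distinct `phi` values.
#'
#' @param curve_sets List of `list(curves = , phi = )` entries, one per
#'   formulation.
#' @param config A [fit_config()].
#' @return A list of class `multi_fit_result`: `fits` (per-formulation
#'   [fit_single_formulation()] results), `eta1`, `eta2`, their standard
#'   errors (`eta1_se`, `eta2_se`, NA with only two formulations), and the
#'   underlying `lm` fit as `regression`.
#' @export
fit_across_formulations <- function(curve_sets, config = fit_config()) {
  stopifnot(is.list(curve_sets), length(curve_sets) >= 2L)
  phis <- vapply(curve_sets, function(s) as.numeric(s$phi), numeric(1))
  if (length(unique(phis)) < 2L)
    stop("fit_across_formulations: all phi equal; eta1/eta2 split is unidentifiable",
         call. = FALSE)
  fits <- lapply(seq_along(curve_sets), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    fit_single_formulation(curve_sets[[i]]$curves, phi = phis[i], cfg)
  })
  etas <- vapply(fits, `[[`, numeric(1), "eta_eff")
  reg <- stats::lm(etas ~ phis)
  co <- summary(reg)$coefficients
  structure(list(fits = fits, phi = phis, eta_eff = etas,
                 eta1 = unname(co["(Intercept)", "Estimate"]),
                 eta2 = unname(co["phis", "Estimate"]),
                 eta1_se = unname(co["(Intercept)", "Std. Error"]),
                 eta2_se = unname(co["phis", "Std. Error"]),
                 regression = reg),
            class = "multi_fit_result")
}

#' @export
print.multi_fit_result <- function(x, ...) {
  cat(sprintf("aSLS joint fit over %d formulations (phi: %s)\n",
              length(x$fits), paste(signif(x$phi, 3), collapse = ", ")))
  cat(sprintf("  eta1 = %g Pa.s (se %g), eta2 = %g Pa.s (se %g)\n",
              x$eta1, x$eta1_se, x$eta2, x$eta2_se))
  invisible(x)
}
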
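#' Cell mechanical sensing window
#'
#' Focal-adhesion timescales bounding what a cell can "see" of substrate
#' relaxation: the binding time `tau_b` (time to assemble an adhesion) and
#' the range of adhesion lifetimes `[tau_L_min, tau_L_max]`. For
#' adipose-derived stem cells the literature values are `tau_b ~ 1 s` and
#' `tau_L` between 10 and 100 s, the package defaults.
#'
#' @param tau_b Focal-adhesion binding time \[s\], > 0.
#' @param tau_L_min,tau_L_max Minimum/maximum focal-adhesion lifetime \[s\],
#'   with `0 < tau_b <= tau_L_min <= tau_L_max`.
#' @return An object of class `cell_sensing_window`.
#' @export
cell_sensing_window <- function(tau_b = 1, tau_L_min = 10, tau_L_max = 100) {
  if (!(tau_b > 0 && tau_b <= tau_L_min && tau_L_min <= tau_L_max))
    stop("cell_sensing_window: need 0 < tau_b <= tau_L_min <= tau_L_max",
         call. = FALSE)
  structure(list(tau_b = tau_b, tau_L_min = tau_L_min, tau_L_max = tau_L_max),
            class = "cell_sensing_window")
}

#' Cell-perceived Deborah number
#'
#' `De = tau_rel / tau_L`: the ratio of the substrate stress-relaxation time
#' to the focal-adhesion lifetime. `De >> 1` or `De << 1` means the cell
#' senses a mechanically static substrate (respectively un-relaxed or fully
#' relaxed); `De ~ 1` means the substrate visibly changes during the life of
#' an adhesion.
#'
#' @param tau_rel Substrate relaxation time \[s\], >= 0; `Inf` allowed
#'   (purely elastic substrate such as tissue-culture plastic).
#' @param tau_L Focal-adhesion lifetime \[s\], > 0.
#' @return De \[-\] (vectorised).
#' @examples
#' deborah_number(1, 100)    # 0.01
#' deborah_number(Inf, 100)  # Inf
#' @export
deborah_number <- function(tau_rel, tau_L) {
  if (any(is.na(tau_rel)) || any(tau_rel < 0))
    stop("deborah_number: tau_rel must be >= 0", call. = FALSE)
  if (any(!is.finite(tau_L)) || any(tau_L <= 0))
    stop("deborah_number: tau_L must be finite and > 0", call. = FALSE)
  tau_rel / tau_L
}

#' Classify the cell-perceived Deborah regime of a substrate
#'
#' Structural mode (default) places `tau_rel` against the sensing window:
#' relaxation completed before adhesions form (`tau_rel <= tau_b`) gives
#' `below_one`; relaxation inside the window (`tau_b < tau_rel <= tau_L_max`)
#' gives `near_one`; slower relaxation (including `Inf`) gives `above_one`.
#' Boundary ties go to the lower regime. The alternative `"band"` mode
#' classifies the numeric `De = tau_rel / tau_L_max` against a band
#' (default `[0.1, 10)`): below the band is `below_one`, inside is
#' `near_one`, at or above its upper edge `above_one`. Both modes reproduce
#' the canonical assignments De = 0.01 -> below_one, De = 0.2, 0.3 ->
#' near_one, De -> Inf -> above_one.
#'
#' @param tau_rel Relaxation time(s) \[s\], >= 0, `Inf` allowed (vectorised).
#' @param window A [cell_sensing_window()].
#' @param mode `"structural"` or `"band"`.
#' @param band Numeric De band `c(lower, upper)` for `"band"` mode.
#' @return Factor with levels `below_one`, `near_one`, `above_one`.
#' @export
classify_regime <- function(tau_rel, window = cell_sensing_window(),
                            mode = c("structural", "band"),
                            band = c(0.1, 10)) {
  mode <- match.arg(mode)
  stopifnot(inherits(window, "cell_sensing_window"))
  if (any(is.na(tau_rel)) || any(tau_rel < 0))
    stop("classify_regime: tau_rel must be >= 0", call. = FALSE)
  levs <- c("below_one", "near_one", "above_one")
  out <- if (mode == "structural") {
    ifelse(tau_rel <= window$tau_b, "below_one",
           ifelse(tau_rel <= window$tau_L_max, "near_one", "above_one"))
  } else {
    stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1])
    De <- deborah_number(tau_rel, window$tau_L_max)
    ifelse(De < band[1], "below_one",
           ifelse(De < band[2], "near_one", "above_one"))
  }
  factor(out, levels = levs)
}

#' Deborah assessment of one formulation
#'
#' @param tau_rel Relaxation time \[s\].
#' @param window A [cell_sensing_window()].
#' @param ... Passed to [classify_regime()].
#' @return An object of class `deborah_assessment` with `De_point` (De at
#'   `tau_L_max`, the value quoted for a formulation), `De_range` (ascending,
#'   De over the lifetime range) and `regime`.
#' @export
deborah_assessment <- function(tau_rel, window = cell_sensing_window(), ...) {
  stopifnot(inherits(window, "cell_sensing_window"), length(tau_rel) == 1L)
  structure(list(
    De_point = deborah_number(tau_rel, window$tau_L_max),
    De_range = c(deborah_number(tau_rel, window$tau_L_max),
                 deborah_number(tau_rel, window$tau_L_min)),
    regime = classify_regime(tau_rel, window, ...),
    tau_rel = tau_rel
  ), class = "deborah_assessment")
}

#' Calibration table of fitted formulations
#'
#' One row per `(agarose, dextran)` formulation carrying either aSLS lumped
#' parameters (`E0_Pa, E1_Pa, eta1_Pa_s, eta2_Pa_s, phi`) or descriptors
#' (`E_eq_Pa, E_inst_Pa, tau_rel_s`, optionally `E_app_Pa`). Descriptors are
#' derived from parameters when absent. Values come from fits of measured or
#' simulated curves, not from hard-coded literature numbers.
#'
#' @param df A data.frame with columns `agarose_mg_ml`, `dextran_mg_ml` and
#'   one of the column sets above.
#' @return `df` augmented with descriptor columns, class `calibration_table`.
#' @export
calibration_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L)
    stop("calibration_table: empty table", call. = FALSE)
  need <- c("agarose_mg_ml", "dextran_mg_ml")
  if (!all(need %in% names(df)))
    stop("calibration_table: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (any(df$agarose_mg_ml < 0) || any(df$dextran_mg_ml < 0))
    stop("calibration_table: concentrations must be >= 0", call. = FALSE)
  if (anyDuplicated(df[, need]))
    stop("calibration_table: duplicate (agarose, dextran) keys", call. = FALSE)
  par_cols <- c("E0_Pa", "E1_Pa", "eta1_Pa_s", "eta2_Pa_s", "phi")
  desc_cols <- c("E_eq_Pa", "E_inst_Pa", "tau_rel_s")
  if (all(par_cols %in% names(df))) {
    for (i in seq_len(nrow(df))) {
      p <- asls_params(df$E0_Pa[i], df$E1_Pa[i], df$eta1_Pa_s[i],
                       df$eta2_Pa_s[i], df$phi[i])
      d <- descriptors_from_params(p)
      df$E_eq_Pa[i] <- d$E_eq
      df$E_inst_Pa[i] <- d$E_inst
      df$tau_rel_s[i] <- d$tau_rel
    }
  } else if (!all(desc_cols %in% names(df))) {
    stop("calibration_table: need parameter columns (", paste(par_cols, collapse = ", "),
         ") or descriptor columns (", paste(desc_cols, collapse = ", "), ")",
         call. = FALSE)
  }
  if (!"E_app_Pa" %in% names(df)) df$E_app_Pa <- NA_real_
  class(df) <- c("calibration_table", "data.frame")
  df
}

#' Target tissue stiffness band
#'
#' @param E_low,E_high Stiffness bounds \[Pa\], `0 < E_low <= E_high`.
#' @param label Tissue name, e.g. `"adipose"` (2-6 kPa, the default).
#' @return An object of class `tissue_target`.
#' @export
tissue_target <- function(E_low = 2000, E_high = 6000, label = "adipose") {
  if (!(E_low > 0 && E_high >= E_low))
    stop("tissue_target: need 0 < E_low <= E_high", call. = FALSE)
  structure(list(E_low = E_low, E_high = E_high, label = label),
            class = "tissue_target")
}

#' Select agarose concentrations matching a tissue stiffness target
#'
#' Step one of the design: among rows at the reference dextran concentration,
#' return the agarose concentrations whose modulus (apparent `E_app_Pa` by
#' default, or equilibrium `E_eq_Pa`) falls within the tissue band. When no
#' row qualifies and the tabulated modulus is monotone in concentration, a
#' linearly interpolated concentration at the band midpoint is suggested and
#' flagged.
#'
#' @param table A [calibration_table()].
#' @param target A [tissue_target()].
#' @param metric `"E_app"` or `"E_eq"`.
#' @param dextran_mg_ml Dextran concentration at which to compare rows
#'   (default 0, the plain gel).
#' @return A list: `selected` (agarose concentrations, possibly empty),
#'   `interpolated` (flag), `suggestion` (interpolated concentration or NA).
#' @export
select_agarose_concentration <- function(table, target,
                                         metric = c("E_app", "E_eq"),
                                         dextran_mg_ml = 0) {
  stopifnot(inherits(table, "calibration_table"),
            inherits(target, "tissue_target"))
  metric <- match.arg(metric)
  col <- if (metric == "E_app") "E_app_Pa" else "E_eq_Pa"
  rows <- table[table$dextran_mg_ml == dextran_mg_ml, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("select_agarose_concentration: no rows at dextran = ", dextran_mg_ml,
         " mg/mL", call. = FALSE)
  E <- rows[[col]]
  if (all(is.na(E)) && metric == "E_app") {
    col <- "E_eq_Pa"; E <- rows[[col]]   # fall back when E_app was not measured
  }
  ok <- !is.na(E) & E >= target$E_low & E <= target$E_high
  sel <- sort(unique(rows$agarose_mg_ml[ok]))
  if (length(sel) > 0L)
    return(list(selected = sel, interpolated = FALSE, suggestion = NA_real_))
  ord <- order(rows$agarose_mg_ml)
  cc <- rows$agarose_mg_ml[ord]
  Ee <- E[ord]
  suggestion <- NA_real_
  if (length(cc) >= 2L && !any(is.na(Ee)) &&
      (all(diff(Ee) > 0) || all(diff(Ee) < 0))) {
    mid <- (target$E_low + target$E_high) / 2
    if (mid >= min(Ee) && mid <= max(Ee))
      suggestion <- stats::approx(Ee, cc, xout = mid)$y
  }
  list(selected = numeric(0), interpolated = TRUE, suggestion = suggestion)
}

#' Select dextran concentrations producing a target Deborah regime
#'
#' Step two of the design: among rows at the chosen agarose concentration,
#' return the dextran concentrations whose fitted relaxation time classifies
#' into the requested regime under [classify_regime()].
#'
#' @param table A [calibration_table()].
#' @param agarose_mg_ml Agarose concentration to filter on.
#' @param window A [cell_sensing_window()].
#' @param target_regime `"below_one"`, `"near_one"` or `"above_one"`.
#' @param ... Passed to [classify_regime()] (`mode`, `band`).
#' @return Sorted dextran concentrations \[mg/mL\] (possibly empty).
#' @export
select_dextran_concentration <- function(table, agarose_mg_ml, window,
                                         target_regime = c("near_one",
                                                           "below_one",
                                                           "above_one"),
                                         ...) {
  stopifnot(inherits(table, "calibration_table"),
            inherits(window, "cell_sensing_window"))
  target_regime <- match.arg(target_regime)
  rows <- table[table$agarose_mg_ml == agarose_mg_ml, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("select_dextran_concentration: no rows at agarose = ", agarose_mg_ml,
         " mg/mL", call. = FALSE)
  reg <- classify_regime(rows$tau_rel_s, window, ...)
  sort(rows$dextran_mg_ml[reg == target_regime])
}

#' Two-step design report
#'
#' Runs the full selection (agarose by tissue stiffness, then dextran per
#' Deborah regime) and assembles a structured report: one entry per
#' formulation with its descriptors, `De_point`, `De_range` and regime, plus
#' the per-regime dextran selections for every qualifying agarose
#' concentration.
#'
#' @param table A [calibration_table()].
#' @param target A [tissue_target()].
#' @param window A [cell_sensing_window()].
#' @param metric Stiffness metric for step one, see
#'   [select_agarose_concentration()].
#' @param ... Passed to [classify_regime()].
#' @return An object of class `design_report`; serialise with
#'   [write_design_report()].
#' @export
design_report <- function(table, target = tissue_target(),
                          window = cell_sensing_window(),
                          metric = "E_app", ...) {
  stopifnot(inherits(table, "calibration_table"),
            inherits(target, "tissue_target"),
            inherits(window, "cell_sensing_window"))
  # reference dextran level for the stiffness step: the plain gel when
  # present, otherwise the lowest dextran concentration tabulated
  ref_dex <- min(table$dextran_mg_ml)
  step1 <- select_agarose_concentration(table, target, metric = metric,
                                        dextran_mg_ml = ref_dex)
  formulations <- lapply(seq_len(nrow(table)), function(i) {
    a <- deborah_assessment(table$tau_rel_s[i], window, ...)
    list(agarose_mg_ml = table$agarose_mg_ml[i],
         dextran_mg_ml = table$dextran_mg_ml[i],
         E_eq_Pa = table$E_eq_Pa[i], E_inst_Pa = table$E_inst_Pa[i],
         tau_rel_s = table$tau_rel_s[i], E_app_Pa = table$E_app_Pa[i],
         De_point = a$De_point, De_range = a$De_range,
         regime = as.character(a$regime))
  })
  regimes <- c("below_one", "near_one", "above_one")
  step2 <- list()
  for (conc in step1$selected) {
    step2[[as.character(conc)]] <- lapply(stats::setNames(regimes, regimes),
      function(r) select_dextran_concentration(table, conc, window,
                                               target_regime = r, ...))
  }
  structure(list(target = unclass(target),
                 window = unclass(window),
                 agarose_selection = step1,
                 dextran_selection = step2,
                 formulations = formulations),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("Deborah-number design report (target: %s, %g-%g Pa)\n",
              x$target$label, x$target$E_low, x$target$E_high))
  if (length(x$agarose_selection$selected)) {
    cat("  agarose selected [mg/mL]:",
        paste(x$agarose_selection$selected, collapse = ", "), "\n")
  } else {
    cat(sprintf("  no agarose row in band; interpolated suggestion: %s mg/mL\n",
                format(x$agarose_selection$suggestion)))
  }
  for (f in x$formulations)
    cat(sprintf("  agarose %g + dextran %g mg/mL: tau_rel = %.3g s, De = %.3g, %s\n",
                f$agarose_mg_ml, f$dextran_mg_ml, f$tau_rel_s, f$De_point,
                f$regime))
  invisible(x)
}
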
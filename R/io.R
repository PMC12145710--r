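#' Read a mechanical test curve from CSV
#'
#' Dialect: UTF-8, '.' decimal separator, header `time_s,strain,stress_Pa`;
#' one file per strain rate. When the `strain` column is absent it is
#' reconstructed as `strain_rate * time_s` and the curve is flagged with
#' attribute `strain_reconstructed = TRUE`.
#'
#' @param path CSV file path.
#' @param strain_rate Nominal strain rate \[1/s\]; required when the file has
#'   no `strain` column, otherwise inferred from the strain ramp when `NULL`.
#' @return A [mechanical_curve()].
#' @export
read_mechanical_curve <- function(path, strain_rate = NULL) {
  if (!file.exists(path))
    stop("read_mechanical_curve: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("time_s", "stress_Pa") %in% names(df)))
    stop("read_mechanical_curve: ", path,
         ": header must contain time_s and stress_Pa (line 1)", call. = FALSE)
  if (nrow(df) < 2L)
    stop("read_mechanical_curve: ", path, ": need at least 2 samples",
         call. = FALSE)
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop("read_mechanical_curve: ", path, ": time_s not strictly increasing at data line ",
         bad[1] + 1L, call. = FALSE)
  reconstructed <- FALSE
  if (!"strain" %in% names(df)) {
    if (is.null(strain_rate))
      stop("read_mechanical_curve: ", path,
           ": no strain column and no strain_rate given", call. = FALSE)
    df$strain <- strain_rate * df$time_s
    reconstructed <- TRUE
  }
  if (is.null(strain_rate)) {
    fit <- df$strain[-1] / df$time_s[-1]
    strain_rate <- stats::median(fit)
  }
  out <- mechanical_curve(df$time_s, df$strain, df$stress_Pa, strain_rate)
  attr(out, "strain_reconstructed") <- reconstructed
  out
}

#' @rdname read_mechanical_curve
#' @param curve A [mechanical_curve()] to write.
#' @export
write_mechanical_curve <- function(curve, path) {
  stopifnot(inherits(curve, "mechanical_curve"))
  df <- data.frame(time_s = curve$time, strain = curve$strain,
                   stress_Pa = curve$stress)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a calibration table CSV
#'
#' Dialect: header `agarose_mg_ml,dextran_mg_ml` plus either lumped-parameter
#' columns `E0_Pa,E1_Pa,eta1_Pa_s,eta2_Pa_s,phi` or descriptor columns
#' `E_eq_Pa,E_inst_Pa,tau_rel_s` (optionally `E_app_Pa`).
#'
#' @param path CSV file path.
#' @return A [calibration_table()].
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path))
    stop("read_calibration_table: no such file: ", path, call. = FALSE)
  calibration_table(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_calibration_table
#' @param table A [calibration_table()] to write.
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a segmented-cell measurement table CSV
#'
#' Dialect: header `condition,A,P,A_N,GI_nuc,GI_cyt`.
#'
#' @param path CSV file path.
#' @return Data.frame validated against the dialect.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path))
    stop("read_cell_table: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("condition", "A", "P", "A_N", "GI_nuc", "GI_cyt")
  if (!all(need %in% names(df)))
    stop("read_cell_table: ", path, ": header must contain ",
         paste(need, collapse = ","), call. = FALSE)
  df
}

#' Export simulation traces as CSV
#'
#' Writes `time_s,total_mass_mg,D_app_m2s,xi_m` for a
#' [solve_reaction_diffusion()] / [coupled_virtual_test()] result.
#'
#' @param result A `simulation_result`.
#' @param path Output CSV path.
#' @export
write_simulation_traces <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  df <- data.frame(time_s = result$times, total_mass_mg = result$total_mass,
                   D_app_m2s = result$D_app_trace, xi_m = result$xi_trace)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# known config sections and the keys each accepts
.config_schema <- list(
  asls = c("E0", "E1", "eta1", "eta2", "phi"),
  transport = c("r_h", "kappa", "mu", "T", "p", "alpha", "k_r", "c0"),
  # "nodes", not "n": YAML 1.1 reads a bare `n` key as boolean FALSE
  grid = c("extents", "nodes", "boundary", "bc_value"),
  protocol = c("strain_rate", "t_end", "n_samples", "strain_limit"),
  fit = c("initial_guess", "lower", "upper", "tol", "max_iter", "n_starts",
          "seed"),
  design = c("E_low", "E_high", "label", "tau_b", "tau_L_min", "tau_L_max",
             "metric", "mode", "band", "target_regime"),
  noise = c("kind", "level", "seed")
)

#' Read and validate a run configuration (YAML)
#'
#' Nested sections `asls`, `transport`, `grid`, `protocol`, `fit`, `design`,
#' `noise`; SI units throughout (Pa, s, m, K) except concentrations in
#' mg/mL. Unknown sections or keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return Named list of validated sections, class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("read_run_config: no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("read_run_config: top level must be a mapping",
                          call. = FALSE)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("read_run_config: unknown section(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop("read_run_config: unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Serialise a design report (or any result list) to JSON
#'
#' @param report A [design_report()] or plain list.
#' @param path Output JSON path.
#' @export
write_design_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
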
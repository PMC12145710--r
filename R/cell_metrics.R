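#' Cell shape index (circularity)
#'
#' `CSI = 4 pi A / P^2`: 1 for a circle, approaching 0 for elongated shapes
#' (isoperimetric inequality for simple closed contours). Values above 1 can
#' arise from noisy perimeter measurements and are reported with a warning,
#' not clamped.
#'
#' @param A Cytosolic area \[um^2 or px^2\], > 0 (vectorised).
#' @param P Cytosolic perimeter \[um or px\], > 0 (same length).
#' @return CSI \[-\].
#' @examples
#' cell_shape_index(pi, 2 * pi)  # circle of radius 1 -> 1
#' cell_shape_index(1, 4)        # unit square -> pi/4
#' @export
cell_shape_index <- function(A, P) {
  if (any(!is.finite(A)) || any(!is.finite(P)) || any(A <= 0) || any(P <= 0))
    stop("cell_shape_index: A and P must be finite and > 0", call. = FALSE)
  csi <- 4 * pi * A / P^2
  if (any(csi > 1 + 1e-12))
    warning("cell_shape_index: CSI > 1 for ", sum(csi > 1 + 1e-12),
            " cell(s); perimeter likely under-measured", call. = FALSE)
  csi
}

#' YAP nuclear / cytosolic distribution ratio
#'
#' Quantifies YAP localisation from mean gray intensities and region areas.
#' Two readings are supported:
#' * `"total"` (default): `(GI_nuc * A_N) / (GI_cyt * A)` — ratio of total
#'   nuclear to total cytosolic signal (mean intensity times area).
#' * `"density"`: `(GI_nuc / A_N) / (GI_cyt / A)` — ratio of per-area signal
#'   densities.
#' Nuclear translocation drives the ratio up; full cytosolic localisation
#' gives ~0 under the `"total"` reading.
#'
#' @param GI_nuc Nuclear mean gray intensity \[a.u.\], >= 0 (vectorised).
#' @param A_N Nuclear area, >= 0, `A_N <= A`.
#' @param GI_cyt Cytosolic mean gray intensity \[a.u.\], > 0.
#' @param A Cytosolic area, > 0.
#' @param mode `"total"` or `"density"`.
#' @return YAP N/C ratio \[-\].
#' @examples
#' yap_nc_ratio(200, 50, 100, 400)  # 0.25
#' @export
yap_nc_ratio <- function(GI_nuc, A_N, GI_cyt, A, mode = c("total", "density")) {
  mode <- match.arg(mode)
  if (any(GI_cyt <= 0))
    stop("yap_nc_ratio: zero or negative cytosolic signal; ratio undefined",
         call. = FALSE)
  if (any(A <= 0) || any(A_N < 0) || any(GI_nuc < 0))
    stop("yap_nc_ratio: need A > 0, A_N >= 0, GI_nuc >= 0", call. = FALSE)
  if (any(A_N > A))
    stop("yap_nc_ratio: nuclear area exceeds cytosolic area", call. = FALSE)
  switch(mode,
         total = (GI_nuc * A_N) / (GI_cyt * A),
         density = ifelse(A_N == 0 & GI_nuc == 0, 0,
                          (GI_nuc / A_N) / (GI_cyt / A)))
}

#' Per-condition morphometric summaries
#'
#' Computes cell shape index and YAP N/C ratio per cell, then groups by the
#' `condition` column: n, mean and SD of area, CSI and YAP ratio. SD is `NA`
#' (flagged) for single-cell groups. Rows are ordered by condition label.
#'
#' @param table Data.frame with columns `condition, A, P, A_N, GI_nuc,
#'   GI_cyt` (the dialect of [read_cell_table()]).
#' @param mode YAP reading, see [yap_nc_ratio()].
#' @return Data.frame with one row per condition.
#' @export
summarize_by_condition <- function(table, mode = "total") {
  need <- c("condition", "A", "P", "A_N", "GI_nuc", "GI_cyt")
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("summarize_by_condition: empty measurement table", call. = FALSE)
  if (!all(need %in% names(table)))
    stop("summarize_by_condition: missing columns ",
         paste(setdiff(need, names(table)), collapse = ", "), call. = FALSE)
  table$CSI <- cell_shape_index(table$A, table$P)
  table$YAP_NC <- yap_nc_ratio(table$GI_nuc, table$A_N, table$GI_cyt,
                               table$A, mode = mode)
  conds <- sort(unique(as.character(table$condition)))
  out <- do.call(rbind, lapply(conds, function(cond) {
    g <- table[table$condition == cond, ]
    sdev <- function(v) if (nrow(g) > 1L) stats::sd(v) else NA_real_
    data.frame(condition = cond, n = nrow(g),
               A_mean = mean(g$A), A_sd = sdev(g$A),
               CSI_mean = mean(g$CSI), CSI_sd = sdev(g$CSI),
               YAP_NC_mean = mean(g$YAP_NC), YAP_NC_sd = sdev(g$YAP_NC))
  }))
  rownames(out) <- NULL
  out
}
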
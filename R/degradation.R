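#' Degradation efficiency from residual masses
#'
#' Efficiency of oil removal for one fraction, defined as
#' `(control - treatment) / control` on residual masses (g): the proportion
#' of the abiotic-control residue removed by the bacterial treatment. Values
#' are at most 1; negative values (treatment residue exceeding the control,
#' as can happen for resins and asphaltenes) are reported, not clipped.
#'
#' @param control residual mass in the uninoculated control (g), > 0.
#' @param treatment residual mass under the bacterial treatment (g), >= 0.
#' @return Efficiency as a fraction (vectorized).
#' @export
degradation_efficiency <- function(control, treatment) {
  if (any(!is.finite(control)) || any(control <= 0))
    stop("control residual mass must be positive", call. = FALSE)
  if (any(!is.finite(treatment)) || any(treatment < 0))
    stop("treatment residual mass must be non-negative", call. = FALSE)
  (control - treatment) / control
}

#' Oil fractions tracked by the degradation records
#' @export
OIL_FRACTIONS <- c("TPH", "saturates", "aromatics", "resins", "asphaltenes")

#' Assemble degradation records
#'
#' One row per sample and oil fraction, carrying residual masses for control
#' and treatment and the computed efficiency.
#'
#' @param sample_id sample identifier (aligns with the abundance table).
#' @param generation generation label.
#' @param replicate replicate index.
#' @param fraction one of [OIL_FRACTIONS].
#' @param residual_control,residual_treatment residual masses (g).
#' @return A `data.frame` of class `degradation_record`.
#' @export
degradation_record <- function(sample_id, generation, replicate, fraction,
                               residual_control, residual_treatment) {
  if (!all(fraction %in% OIL_FRACTIONS))
    stop("unknown oil fraction", call. = FALSE)
  df <- data.frame(sample_id = as.character(sample_id),
                   generation = as.character(generation),
                   replicate = as.integer(replicate),
                   fraction = as.character(fraction),
                   residual_control = as.numeric(residual_control),
                   residual_treatment = as.numeric(residual_treatment),
                   stringsAsFactors = FALSE)
  df$efficiency <- degradation_efficiency(df$residual_control,
                                          df$residual_treatment)
  class(df) <- c("degradation_record", "data.frame")
  df
}

#' Read / write degradation records as CSV
#'
#' @param path file path.
#' @return For the reader, a `degradation_record` data frame.
#' @export
read_degradation_records <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  degradation_record(df$sample_id, df$generation, df$replicate, df$fraction,
                     df$residual_control, df$residual_treatment)
}

#' @rdname read_degradation_records
#' @param records a `degradation_record` data frame.
#' @export
write_degradation_records <- function(records, path) {
  out <- as.data.frame(records)
  for (col in c("residual_control", "residual_treatment", "efficiency"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
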
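# Absolute-count normalization: from gated event counts to cells per
# microliter of whole blood, and the log10 analysis scale.

#' Dilution factor of a blood sample
#'
#' @param blood_volume Whole-blood volume in the tube (uL, > 0).
#' @param diluent_volume Diluent/anticoagulant volume (uL, >= 0).
#' @return `(blood_volume + diluent_volume) / blood_volume`, the factor by
#'   which suspension concentrations are scaled back to whole blood.
#' @export
dilution_factor <- function(blood_volume, diluent_volume) {
  if (any(blood_volume <= 0)) stop("blood_volume must be > 0", call. = FALSE)
  if (any(diluent_volume < 0)) stop("diluent_volume must be >= 0",
                                    call. = FALSE)
  (blood_volume + diluent_volume) / blood_volume
}

#' Absolute count in whole blood
#'
#' Converts a gated event count to cells per microliter of whole blood:
#' the suspension concentration (`gate_count / acquired_volume`) scaled by
#' the blood-to-total-suspension dilution factor. With the standard tube
#' (50 uL blood in 500 uL diluent) the factor is 11.
#'
#' @param gate_count Number of events in the gate (>= 0).
#' @param acquired_volume Acquired suspension volume in uL (> 0).
#' @param blood_volume,diluent_volume Tube volumes in uL.
#' @return Cells/uL of whole blood (vectorized).
#' @export
absolute_count <- function(gate_count, acquired_volume, blood_volume,
                           diluent_volume) {
  if (any(gate_count < 0)) stop("gate_count must be >= 0", call. = FALSE)
  if (any(acquired_volume <= 0)) stop("acquired_volume must be > 0",
                                      call. = FALSE)
  (gate_count / acquired_volume) *
    dilution_factor(blood_volume, diluent_volume)
}

#' Log10 analysis transform for concentrations
#'
#' `log10(value + offset)` with a default offset of 1 cell/uL so that zero
#' counts stay representable (`log10(1) = 0`). The offset used is recorded
#' on the result.
#'
#' @param values Non-negative concentrations.
#' @param offset Non-negative offset; `offset = 0` requires strictly
#'   positive values.
#' @return Numeric vector with attribute `"offset"`.
#' @export
log10_series <- function(values, offset = 1) {
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  if (offset < 0) stop("offset must be >= 0", call. = FALSE)
  if (offset == 0 && any(values == 0))
    stop("offset 0 with zero values: log10 undefined", call. = FALSE)
  structure(log10(values + offset), offset = offset)
}

#' Absolute counts for every gated subset of a study
#'
#' Joins stacked gating results ([gate_study()]) with each sample's
#' acquisition volumes and returns the tidy per-subset concentration table
#' used by the variance and group analyses.
#'
#' @param gated Data frame from [gate_study()].
#' @param study The `cyto_study` (or a list of [event_table()]s) the gating
#'   was run on; provides the per-sample volumes.
#' @param reported_only Keep only reported subset variables (default TRUE).
#' @param offset Log offset, see [log10_series()].
#' @return Data frame: `sample_id`, `animal_id`, `timepoint`, `group`,
#'   `block`, `node`, `count`, `cells_per_uL`, `log10_value`.
#' @export
quantify_study <- function(gated, study, reported_only = TRUE, offset = 1) {
  samples <- if (inherits(study, "cyto_study")) study$samples else study
  meta <- do.call(rbind, lapply(samples, function(et)
    data.frame(sample_id = et$sample_id,
               acquired_volume = et$acquired_volume,
               blood_volume = et$blood_volume,
               diluent_volume = et$diluent_volume,
               stringsAsFactors = FALSE)))
  out <- merge(gated, meta, by = "sample_id", sort = FALSE)
  if (reported_only) out <- out[out$reported, , drop = FALSE]
  out$cells_per_uL <- absolute_count(out$count, out$acquired_volume,
                                     out$blood_volume, out$diluent_volume)
  out$log10_value <- as.numeric(log10_series(out$cells_per_uL,
                                             offset = offset))
  rownames(out) <- NULL
  out[, c("sample_id", "animal_id", "timepoint", "group", "block", "node",
          "count", "cells_per_uL", "log10_value")]
}
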
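#' Construct an event table
#'
#' One acquired cytometry sample: an event-by-channel intensity matrix
#' (arbitrary fluorescence units, linear as acquired) plus the acquisition
#' metadata needed for absolute-count normalization.
#'
#' @param events Numeric matrix, one row per event, one column per channel;
#'   column names are channel names (marker names plus scatter channels).
#' @param sample_id,animal_id,timepoint,group,block Sample metadata labels
#'   (`group`/`block` may be `NA` outside challenge studies).
#' @param acquired_volume Volume of cell suspension acquired, in uL.
#' @param blood_volume Whole-blood volume drawn into the tube, in uL.
#' @param diluent_volume Diluent/anticoagulant volume in the tube, in uL.
#' @param transformed Logical: are fluorescence channels already
#'   asinh-transformed? Used internally by the gating engine.
#' @return An object of class `event_table`.
#' @export
event_table <- function(events, sample_id, animal_id = NA_character_,
                        timepoint = NA_character_, group = NA_character_,
                        block = NA_character_, acquired_volume,
                        blood_volume, diluent_volume = 0,
                        transformed = FALSE) {
  events <- as.matrix(events)
  if (ncol(events) < 1L) stop("event matrix needs at least one channel",
                              call. = FALSE)
  if (is.null(colnames(events))) stop("event matrix must have channel names",
                                      call. = FALSE)
  if (!all(is.finite(events))) stop("event intensities must be finite",
                                    call. = FALSE)
  if (!is.numeric(acquired_volume) || acquired_volume <= 0)
    stop("acquired_volume must be > 0", call. = FALSE)
  if (!is.numeric(blood_volume) || blood_volume <= 0)
    stop("blood_volume must be > 0", call. = FALSE)
  if (!is.numeric(diluent_volume) || diluent_volume < 0)
    stop("diluent_volume must be >= 0", call. = FALSE)
  structure(list(
    sample_id = as.character(sample_id),
    animal_id = as.character(animal_id),
    timepoint = as.character(timepoint),
    group = as.character(group),
    block = as.character(block),
    events = events,
    channel_names = colnames(events),
    acquired_volume = as.numeric(acquired_volume),
    blood_volume = as.numeric(blood_volume),
    diluent_volume = as.numeric(diluent_volume),
    transformed = isTRUE(transformed)),
    class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", x$sample_id, ": ", nrow(x$events), " events x ",
      ncol(x$events), " channels", if (x$transformed) " (transformed)", "\n",
      sep = "")
  cat("  animal ", x$animal_id, ", timepoint ", x$timepoint,
      if (!is.na(x$group)) paste0(", group ", x$group), "\n", sep = "")
  cat("  volumes (uL): acquired ", signif(x$acquired_volume, 5), ", blood ",
      x$blood_volume, ", diluent ", x$diluent_volume, "\n", sep = "")
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$events)
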
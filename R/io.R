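# File-format adapters: a minimal FCS 3.1 reader/writer (list mode, 32-bit
# float, little-endian) and plain tabular event files, plus study export
# with ground-truth sidecars.

# Fixed-width numeric fields keep the TEXT segment length independent of
# the offsets written into it.
.fcs_offset_fmt <- "%010d"

#' Write an event table as an FCS 3.1 file
#'
#' Writes list-mode single-dataset FCS 3.1: 32-bit little-endian floats,
#' one parameter per channel, with `$PnN`/`$PnS` set to the channel name
#' and acquisition volumes stored as custom keywords (`CYTOVAR$ACQVOL`,
#' `CYTOVAR$BLOODVOL`, `CYTOVAR$DILVOL`, in uL).
#'
#' @param events An [event_table()] (untransformed intensities).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  if (events$transformed)
    stop("write untransformed intensities to FCS", call. = FALSE)
  m <- events$events
  n <- nrow(m); p <- ncol(m)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = sprintf(.fcs_offset_fmt, 0),
    "$ENDDATA" = sprintf(.fcs_offset_fmt, 0),
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(p), "$TOT" = as.character(n),
    "CYTOVAR$SAMPLEID" = events$sample_id,
    "CYTOVAR$ANIMAL" = events$animal_id,
    "CYTOVAR$TIMEPOINT" = events$timepoint,
    "CYTOVAR$ACQVOL" = format(events$acquired_volume, digits = 12),
    "CYTOVAR$BLOODVOL" = format(events$blood_volume, digits = 12),
    "CYTOVAR$DILVOL" = format(events$diluent_volume, digits = 12))
  for (j in seq_len(p)) {
    kw[sprintf("$P%dN", j)] <- colnames(m)[j]
    kw[sprintf("$P%dS", j)] <- colnames(m)[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- format(ceiling(max(m[, j], 1)), scientific = FALSE)
  }
  build_text <- function(kw) {
    paste0("/", paste0(names(kw), "/", unname(kw), "/", collapse = ""))
  }
  header_len <- 58L
  text <- build_text(kw)
  text_begin <- header_len
  text_end <- text_begin + nchar(text, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n * p - 1L
  kw["$BEGINDATA"] <- sprintf(.fcs_offset_fmt, data_begin)
  kw["$ENDDATA"] <- sprintf(.fcs_offset_fmt, data_end)
  text <- build_text(kw)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 file into an event table
#'
#' Supports list-mode single-dataset files with `$DATATYPE` F (32-bit
#' float) or D (64-bit double) and little- or big-endian `$BYTEORD`.
#' Channel names come from `$PnS` with `$PnN` as fallback; the decoded
#' event count is checked against `$TOT`.
#'
#' @param path FCS file path.
#' @param ... Metadata overrides passed to [event_table()]
#'   (`acquired_volume`, `blood_volume`, `diluent_volume`, `sample_id`,
#'   ...); values stored in the file's custom keywords are used otherwise.
#' @return An [event_table()].
#' @export
read_fcs <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (!grepl("^FCS3\\.[01]", header))
    stop("not an FCS 3.0/3.1 file (malformed header): ", path, call. = FALSE)
  off <- suppressWarnings(as.integer(substring(
    header, 10 + 8 * (0:3) + 1, 10 + 8 * (1:4))))
  if (any(is.na(off[1:2])))
    stop("malformed FCS header offsets in ", path, call. = FALSE)
  seek(con, off[1])
  text <- readChar(con, off[2] - off[1] + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        parts[seq(1, length(parts), 2)])
  need <- function(k) {
    if (is.na(kw[k])) stop("required FCS keyword missing: ", k, call. = FALSE)
    kw[[k]]
  }
  n <- as.integer(need("$TOT"))
  p <- as.integer(need("$PAR"))
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("F", "D"))
    stop("unsupported $DATATYPE '", dtype, "' (only F/D)", call. = FALSE)
  size <- if (dtype == "F") 4L else 8L
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  data_begin <- if (!is.na(kw["$BEGINDATA"]) &&
                    as.numeric(kw[["$BEGINDATA"]]) > 0)
    as.numeric(kw[["$BEGINDATA"]]) else off[3]
  seek(con, data_begin)
  vals <- readBin(con, "numeric", n = n * p, size = size, endian = endian)
  if (length(vals) != n * p)
    stop("FCS integrity check failed in ", path, ": $TOT declares ", n,
         " events (", n * p, " values) but only ", length(vals),
         " values were decodable (", length(vals) %/% max(p, 1L),
         " events)", call. = FALSE)
  m <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  chan <- vapply(seq_len(p), function(j) {
    s <- kw[sprintf("$P%dS", j)]
    if (!is.na(s) && nzchar(s)) s else need(sprintf("$P%dN", j))
  }, "")
  colnames(m) <- chan
  meta <- list(...)
  get_meta <- function(name, key, default) {
    if (!is.null(meta[[name]])) meta[[name]]
    else if (!is.na(kw[key])) kw[[key]]
    else default
  }
  event_table(
    m,
    sample_id = get_meta("sample_id", "CYTOVAR$SAMPLEID",
                         tools::file_path_sans_ext(basename(path))),
    animal_id = get_meta("animal_id", "CYTOVAR$ANIMAL", NA_character_),
    timepoint = get_meta("timepoint", "CYTOVAR$TIMEPOINT", NA_character_),
    group = if (is.null(meta$group)) NA_character_ else meta$group,
    block = if (is.null(meta$block)) NA_character_ else meta$block,
    acquired_volume = as.numeric(get_meta("acquired_volume",
                                          "CYTOVAR$ACQVOL", NA)),
    blood_volume = as.numeric(get_meta("blood_volume",
                                       "CYTOVAR$BLOODVOL", NA)),
    diluent_volume = as.numeric(get_meta("diluent_volume",
                                         "CYTOVAR$DILVOL", 0)))
}

#' Read an event file (FCS or tabular) into an event table
#'
#' @param path File path. Format is detected from the extension (`.fcs`
#'   vs anything else = delimited text with a header row of channel names)
#'   unless given.
#' @param format `"auto"`, `"fcs"` or `"tabular"`.
#' @param ... Metadata (volumes, ids) passed through; required for tabular
#'   files, optional for FCS written by this package.
#' @return An [event_table()].
#' @export
read_events <- function(path, format = c("auto", "fcs", "tabular"), ...) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs"
              else "tabular"
  if (format == "fcs") return(read_fcs(path, ...))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  event_table(as.matrix(df), ...)
}

#' Write an event table to a delimited text file
#'
#' @param events An [event_table()].
#' @param path Output path (CSV, one row per event, channel-name header).
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events$events), path, row.names = FALSE)
  invisible(path)
}

#' Export a synthetic study to disk
#'
#' Writes every sample (FCS 3.1 or CSV), the per-sample metadata sidecar
#' (ids, volumes), the ground-truth concentration table, and the simulation
#' settings, so the exported study is self-describing.
#'
#' @param study A `cyto_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @param format `"fcs"` or `"csv"` event files.
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir, format = c("fcs", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(study, "cyto_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  meta <- list()
  for (et in study$samples) {
    f <- file.path(dir, paste0(et$sample_id,
                               if (format == "fcs") ".fcs" else ".csv"))
    if (format == "fcs") write_fcs(et, f) else write_events_csv(et, f)
    files <- c(files, f)
    meta[[length(meta) + 1L]] <- data.frame(
      sample_id = et$sample_id, animal_id = et$animal_id,
      timepoint = et$timepoint, group = et$group, block = et$block,
      acquired_volume = et$acquired_volume,
      blood_volume = et$blood_volume, diluent_volume = et$diluent_volume,
      file = basename(f), stringsAsFactors = FALSE)
  }
  meta_f <- file.path(dir, "samples.csv")
  utils::write.csv(do.call(rbind, meta), meta_f, row.names = FALSE)
  truth_f <- file.path(dir, "ground_truth.csv")
  utils::write.csv(study$truth, truth_f, row.names = FALSE)
  cfg <- study$config
  cfg_f <- file.path(dir, "simulation.yaml")
  yaml::write_yaml(list(
    panel = cfg$panel$name,
    n_animals = cfg$n_animals, n_timepoints = cfg$n_timepoints,
    events_per_sample = cfg$events_per_sample,
    sigma_inter = cfg$sigma_inter, sigma_intra = cfg$sigma_intra,
    sigma_resid = cfg$sigma_resid,
    blood_volume = cfg$blood_volume, diluent_volume = cfg$diluent_volume,
    seed = cfg$seed,
    populations = lapply(cfg$populations, function(p)
      list(name = p$name, concentration = p$concentration,
           signature = as.list(p$signature)))), cfg_f)
  invisible(c(files, meta_f, truth_f, cfg_f))
}
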
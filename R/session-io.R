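#' Bundle event tables into a session object
#'
#' A session is the unit all analyses operate on: spikes, stimulation pulses,
#' trial/phase labels and the electrode-array map, plus free-form metadata
#' (seed, generator parameters, ground truth when synthetic).
#'
#' @param spikes Spike table ([spike_table()]).
#' @param pulses Pulse table ([stim_train()]), may have zero rows.
#' @param trials Trial table: `trial_id`, `condition`, `phase_start_s`,
#'   `phase_end_s` and optional `amplitude_level_ua`, `cued_digit`,
#'   `target_id`, `baseline_start_s`, `baseline_end_s`.
#' @param array Array map: `electrode_id`, `array_id`, `region` ("M1"/"S1"),
#'   `grid_row`, `grid_col`, `wired`, `pf_digit` (S1 only), `pitch_um`.
#' @param truth Optional ground-truth object for synthetic sessions.
#' @param meta Named list of metadata.
#' @return An object of class `icms_session`.
#' @export
icms_session <- function(spikes, pulses, trials, array, truth = NULL,
                         meta = list()) {
  structure(
    list(spikes = spikes, pulses = pulses, trials = trials, array = array,
         truth = truth, meta = meta),
    class = "icms_session"
  )
}

#' @export
print.icms_session <- function(x, ...) {
  cat("<icms_session>\n")
  cat("  spikes:", nrow(x$spikes), "events on",
      dplyr::n_distinct(x$spikes$channel_id), "channels\n")
  cat("  pulses:", nrow(x$pulses), "in",
      dplyr::n_distinct(x$pulses$train_id), "trains\n")
  cat("  trials:", dplyr::n_distinct(x$trials$trial_id), "\n")
  if (!is.null(x$meta$seed)) cat("  seed:", x$meta$seed, "\n")
  invisible(x)
}

SCHEMA_VERSION <- "1.0"

REQUIRED_COLS <- list(
  spikes = c("channel_id", "unit_id", "time_s"),
  pulses = c("train_id", "stim_channel", "pulse_time_s", "amplitude_ua"),
  trials = c("trial_id", "condition", "phase_start_s", "phase_end_s"),
  arraymap = c("electrode_id", "array_id", "region", "grid_row", "grid_col",
               "wired", "pf_digit", "pitch_um")
)

#' Write / read session event tables
#'
#' Sessions are stored as four delimited text files (`spikes.tsv`,
#' `pulses.tsv`, `trials.tsv`, `arraymap.tsv`) plus a JSON sidecar
#' (`session.json`) carrying the schema version, units and metadata. The
#' representation is canonical: writing, reading and writing again yields
#' byte-identical files.
#'
#' @param session An `icms_session`.
#' @param dir Directory to write to (created if absent).
#' @return `write_event_tables()` returns `dir` invisibly;
#'   `read_event_tables()` returns an `icms_session` (ground truth is not
#'   persisted).
#' @export
write_event_tables <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(canonical_times(session$spikes), file.path(dir, "spikes.tsv"))
  readr::write_tsv(canonical_times(session$pulses), file.path(dir, "pulses.tsv"))
  readr::write_tsv(canonical_times(session$trials), file.path(dir, "trials.tsv"))
  readr::write_tsv(session$array, file.path(dir, "arraymap.tsv"))
  sidecar <- list(
    schema_version = SCHEMA_VERSION,
    units = list(time = "s", rate = "Hz", amplitude = "uA"),
    meta = session$meta
  )
  jsonlite::write_json(sidecar, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

TIME_COLS <- c("time_s", "pulse_time_s", "phase_start_s", "phase_end_s",
               "baseline_start_s", "baseline_end_s")

# Times live on the 30-kHz acquisition clock; writing them snapped and with
# fixed 10-decimal formatting makes the files canonical (write-read-write is
# byte identical, immune to last-ulp float parsing).
canonical_times <- function(tbl) {
  for (cc in intersect(TIME_COLS, names(tbl))) {
    tbl[[cc]] <- sprintf("%.10f", snap_to_clock(tbl[[cc]]))
  }
  tbl
}

resnap_times <- function(tbl) {
  for (cc in intersect(TIME_COLS, names(tbl))) {
    tbl[[cc]] <- snap_to_clock(as.numeric(tbl[[cc]]))
  }
  tbl
}

read_table_checked <- function(path, what) {
  x <- resnap_times(readr::read_tsv(path, show_col_types = FALSE,
                                    progress = FALSE))
  missing <- setdiff(REQUIRED_COLS[[what]], names(x))
  if (length(missing) > 0) {
    stop("schema error in ", basename(path), ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname write_event_tables
#' @export
read_event_tables <- function(dir) {
  spikes <- read_table_checked(file.path(dir, "spikes.tsv"), "spikes")
  o <- order(spikes$channel_id)
  same_chan <- diff(spikes$channel_id[o]) == 0
  if (any(diff(spikes$time_s[o])[same_chan] < 0)) {
    warning("spike times unsorted within channel; sorting")
  }
  spikes <- dplyr::arrange(spikes, .data$channel_id, .data$time_s)
  pulses <- read_table_checked(file.path(dir, "pulses.tsv"), "pulses")
  trials <- read_table_checked(file.path(dir, "trials.tsv"), "trials")
  array <- read_table_checked(file.path(dir, "arraymap.tsv"), "arraymap")
  sidecar_path <- file.path(dir, "session.json")
  meta <- if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!identical(sc$schema_version, SCHEMA_VERSION)) {
      stop("schema version mismatch: file has ", sc$schema_version,
           ", package expects ", SCHEMA_VERSION, call. = FALSE)
    }
    sc$meta
  } else {
    list()
  }
  icms_session(spikes, pulses, trials, array, truth = NULL,
               meta = as.list(meta))
}
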